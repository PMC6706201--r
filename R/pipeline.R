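#' Load a scenario run configuration from YAML
#'
#' A run configuration names a species preset and optionally overrides
#' scenario, parentage and IBM fields:
#' \preformatted{
#' species: parkia
#' scenario:
#'   n_days: 31
#'   n_offspring: 120
#' parentage:
#'   n_confidence_sims: 1500
#' ibm:
#'   n_days: 50
#' }
#' Two demo configurations are bundled under `inst/extdata`
#' (`parkia_demo.yaml`, `leonia_demo.yaml`), mirroring the contrast between
#' the sparse canopy-tree and dense understory systems.
#'
#' @param path Path to a YAML file.
#' @return List with `scenario` (a [scenario_config()]), `parentage` and
#'   `ibm` (named override lists, possibly empty).
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$species)) stop("run config needs a 'species' field", call. = FALSE)
  sc <- do.call(scenario_config,
                c(list(species = raw$species), raw$scenario %||% list()))
  list(scenario = sc,
       species = raw$species,
       parentage = raw$parentage %||% list(),
       ibm = raw$ibm %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a bundled demo run configuration
#'
#' @param name `"parkia"` or `"leonia"`.
#' @return Path to the YAML file inside the installed package.
#' @export
demo_config <- function(name = c("parkia", "leonia")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, "_demo.yaml"), package = "frugidisp",
              mustWork = TRUE)
}

#' Run a full synthetic scenario through all five estimators
#'
#' One reproducible end-to-end run: generate the synthetic system (landscape,
#' genotypes, offspring and seed coats, movement tracks, dispersal events,
#' gut-passage observations), apply the five estimators (OSD, GSC, PAS, CMG,
#' IBM), compare the resulting distance samples, and write every table plus a
#' run manifest to `out_dir`. All randomness derives from `seed` through a
#' fixed per-stage splitting rule, so the same config + seed reproduce every
#' output byte-identically.
#'
#' @param config A path to a YAML run configuration, a [load_run_config()]
#'   result, or a bare [scenario_config()].
#' @param out_dir Output directory (created).
#' @param seed Master integer seed (overrides the config seed).
#' @return Invisibly, a list with the five [distance_sample()]s, the
#'   [compare_methods()] report, the ground-truth tables and the manifest.
#' @export
run_scenario <- function(config, out_dir, seed = 1L) {
  if (is.character(config)) config <- load_run_config(config)
  if (inherits(config, "scenario_config")) {
    config <- list(scenario = config,
                   species = if (grepl("^parkia", config$species_name)) "parkia" else "leonia",
                   parentage = list(), ibm = list())
  }
  cfg <- config$scenario
  cfg$seed <- as.integer(seed)
  cfg <- validate_scenario_config(unclass(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message("[1/7] synthetic system (seed ", seed, ")")
  land <- generate_landscape(cfg)
  genos <- generate_genotypes(land$adults, cfg)
  fam <- generate_offspring_and_seedcoats(land$adults, genos, cfg)
  tracks <- generate_tracks(cfg, boundary = land$boundary)
  events <- generate_dispersal_events(tracks, land$adults, cfg)
  gut_obs <- generate_gut_samples(cfg)

  message("[2/7] OSD: ", nrow(events$events), " observed events")
  osd <- estimate_osd(events$events, species = cfg$species_name)

  message("[3/7] GSC: matching ", length(fam$seed_coats_obs$ids), " seed coats")
  seed_locs <- data.frame(id = fam$seed_coats_obs$ids,
                          x = fam$locations$x, y = fam$locations$y,
                          stringsAsFactors = FALSE)
  gsc <- match_seed_coats(fam$seed_coats_obs, genos$observed, land$adults,
                          seed_locs, species = cfg$species_name)

  message("[4/7] PAS: parentage of ", length(fam$offspring_obs$ids), " seedlings")
  pcfg <- do.call(parentage_config, utils::modifyList(
    list(n_candidates = nrow(land$adults),
         proportion_sampled = 0.99,
         genotyping_error = 0.01,
         min_typed_loci = if (cfg$n_loci >= 11L) 6L else 5L),
    config$parentage))
  freqs <- allele_frequencies(genos$observed)
  dcrit <- critical_delta(freqs, pcfg, seed = child_seed(cfg$seed, "parentage"))
  assign <- assign_parentage(fam$offspring_obs, genos$observed, freqs, pcfg, dcrit)
  pas <- estimate_pas(assign, fam$locations, land$adults, pcfg,
                      species = cfg$species_name)

  message("[5/7] CMG: interval distances over ", cfg$n_days, " days")
  gw <- gut_passage_window(gut_obs)
  # half the scan interval: a lag within that margin of the window edge is
  # closer to inside than outside, and the widened window always spans at
  # least one achievable scan lag
  cmg <- estimate_cmg(tracks, gw, lag_tolerance_min = cfg$scan_interval_min / 2,
                      species = cfg$species_name)

  message("[6/7] IBM: simulating")
  icfg <- do.call(ibm_config, utils::modifyList(
    list(species = config$species,
         gut_window_min = unname(cfg$gut_window_min),
         home_range_area_ha = cfg$home_range_area_ha,
         seed = child_seed(cfg$seed, "ibm")),
    config$ibm))
  ibm <- simulate_ibm(icfg)
  ibm_sample <- distance_sample("IBM", cfg$species_name, ibm$records$distance_m)

  message("[7/7] comparison and outputs")
  samples <- list(OSD = osd, GSC = gsc$sample, PAS = pas, CMG = cmg,
                  IBM = ibm_sample)
  report <- compare_methods(samples, seed = child_seed(cfg$seed, "stats"))

  # tables
  write_locations(rbind(land$adults, fam$locations), file.path(out_dir, "locations.csv"))
  write_genotypes(genos$observed, file.path(out_dir, "genotypes_adults.csv"))
  write_genotypes(fam$offspring_obs, file.path(out_dir, "genotypes_offspring.csv"))
  write_genotypes(fam$seed_coats_obs, file.path(out_dir, "genotypes_seedcoats.csv"))
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  write_truth(fam$truth, file.path(out_dir, "truth.csv"))
  utils::write.csv(gsc$assignments, file.path(out_dir, "gsc_assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(assign, file.path(out_dir, "pas_assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  all_rec <- rbind(
    events$records,
    ibm$records[names(events$records)]
  )
  write_distances(all_rec, file.path(out_dir, "records.csv"))
  dist_long <- do.call(rbind, lapply(samples, function(s)
    data.frame(method = s$method, species = s$species, distance_m = s$values,
               stringsAsFactors = FALSE)))
  utils::write.csv(dist_long, file.path(out_dir, "distances.csv"),
                   row.names = FALSE, quote = FALSE)
  write_comparison(report, file.path(out_dir, "comparison"))

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("frugidisp")),
    master_seed = as.integer(seed),
    stage_seeds = as.list(vapply(
      c("landscape", "genotypes", "offspring", "tracks", "events", "gut",
        "parentage", "ibm", "stats"),
      function(s) child_seed(cfg$seed, s), integer(1))),
    config = unclass(cfg),
    critical_delta = dcrit$threshold,
    counts = list(
      adults = nrow(land$adults),
      offspring = length(fam$offspring$ids),
      osd = length(osd$values), gsc = length(gsc$sample$values),
      pas = length(pas$values), cmg = length(cmg$values),
      ibm = length(ibm_sample$values)
    ),
    file_md5 = {
      md5 <- unname(tools::md5sum(file.path(out_dir, files)))
      as.list(stats::setNames(md5, files))
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(samples = samples, report = report, truth = fam$truth,
                 gsc = gsc, assignments = assign, manifest = manifest,
                 landscape = land, tracks = tracks, events = events,
                 ibm = ibm))
}

#' Write the small deterministic fixtures used by the test suite
#'
#' Produces a toy 19-scan track, a toy genotype panel and a toy landscape as
#' plain CSV; regenerating with the same seed reproduces identical files.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scenario_config("parkia", home_range_area_ha = 9, adult_density_per_ha = 1,
                         n_loci = 5L, alleles_per_locus = 4L, seed = as.integer(seed))
  land <- generate_landscape(cfg)
  genos <- generate_genotypes(land$adults, cfg)
  tracks <- generate_tracks(cfg, n_days = 1L, boundary = land$boundary)
  p1 <- write_locations(land$adults, file.path(out_dir, "toy_landscape.csv"))
  p2 <- write_genotypes(genos$true, file.path(out_dir, "toy_genotypes.csv"))
  p3 <- write_tracks(tracks, file.path(out_dir, "toy_track.csv"))
  invisible(c(p1, p2, p3))
}
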