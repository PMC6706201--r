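#' Generate a synthetic adult-tree landscape
#'
#' Adults are placed by a homogeneous Poisson process inside a square home
#' range of the configured area: the count is Poisson(density x area) and
#' positions are uniform. Draws with fewer than two adults are rejected and
#' redrawn (a message records the retries) because every downstream step
#' needs at least a mother and a father.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed (default derived from `cfg$seed`).
#' @return A list with `adults` (data frame `id,role,species,x,y`) and
#'   `boundary` (`c(xmin, xmax, ymin, ymax)`, metres).
#' @export
generate_landscape <- function(cfg, seed = child_seed(cfg$seed, "landscape")) {
  stopifnot(inherits(cfg, "scenario_config"))
  side <- sqrt(cfg$home_range_area_ha * 1e4)
  if (!is.finite(side) || side <= 0) stop("degenerate home-range area", call. = FALSE)
  set.seed(seed)
  lambda <- cfg$adult_density_per_ha * cfg$home_range_area_ha
  n <- stats::rpois(1L, lambda)
  tries <- 0L
  while (n < 2L) {
    tries <- tries + 1L
    n <- stats::rpois(1L, lambda)
  }
  if (tries > 0L) message("generate_landscape(): redrew adult count ", tries, " time(s)")
  adults <- data.frame(
    id = sprintf("A%03d", seq_len(n)),
    role = "adult",
    species = cfg$species_name,
    x = stats::runif(n, 0, side),
    y = stats::runif(n, 0, side),
    stringsAsFactors = FALSE
  )
  list(adults = adults, boundary = c(xmin = 0, xmax = side, ymin = 0, ymax = side))
}

# draw one multilocus genotype set in Hardy-Weinberg proportions
rhw_genotypes <- function(ids, freqs) {
  L <- length(freqs)
  n <- length(ids)
  a1 <- matrix(0L, n, L)
  a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    codes <- as.integer(names(freqs[[l]]))
    a1[, l] <- sample(codes, n, replace = TRUE, prob = freqs[[l]])
    a2[, l] <- sample(codes, n, replace = TRUE, prob = freqs[[l]])
  }
  genotype_set(ids, names(freqs), a1, a2)
}

# apply per-locus genotyping error (replace call by a fresh HW draw) and
# missing-data rate to a copy of g
corrupt_genotypes <- function(g, freqs, error_rate, missing_rate) {
  a1 <- g$a1; a2 <- g$a2
  n <- nrow(a1)
  for (l in seq_along(g$loci)) {
    if (error_rate > 0) {
      hit <- stats::runif(n) < error_rate
      k <- sum(hit)
      if (k) {
        codes <- as.integer(names(freqs[[l]]))
        a1[hit, l] <- sample(codes, k, replace = TRUE, prob = freqs[[l]])
        a2[hit, l] <- sample(codes, k, replace = TRUE, prob = freqs[[l]])
      }
    }
    if (missing_rate > 0) {
      gone <- stats::runif(n) < missing_rate
      a1[gone, l] <- 0L
      a2[gone, l] <- 0L
    }
  }
  genotype_set(g$ids, g$loci, a1, a2)
}

#' Generate adult genotypes in Hardy-Weinberg proportions
#'
#' Per-locus allele frequencies are drawn once from a symmetric Dirichlet
#' (concentration `cfg$dirichlet_conc` over `cfg$alleles_per_locus` alleles);
#' adult genotypes are then independent Hardy-Weinberg draws. Genotyping
#' error (per-locus replacement by a random HW call) and missing data are
#' applied to an observed copy; both true and observed sets are returned.
#'
#' @param adults Adult table from [generate_landscape()] (ids are reused).
#' @param cfg A [scenario_config()].
#' @param seed Integer seed.
#' @return List with `freqs` (generating allele frequencies), `true` and
#'   `observed` ([genotype_set()]s).
#' @export
generate_genotypes <- function(adults, cfg, seed = child_seed(cfg$seed, "genotypes")) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$alleles_per_locus < 2L) stop("need >= 2 alleles per locus", call. = FALSE)
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(cfg$n_loci))
  freqs <- lapply(loci, function(l) {
    w <- stats::rgamma(cfg$alleles_per_locus, shape = cfg$dirichlet_conc)
    # guard against a degenerate draw where one allele takes all mass
    w <- w + 1e-6
    f <- w / sum(w)
    names(f) <- as.character(seq_along(f))
    f
  })
  names(freqs) <- loci
  true <- rhw_genotypes(adults$id, freqs)
  observed <- corrupt_genotypes(true, freqs, cfg$genotyping_error, cfg$missing_rate)
  list(freqs = freqs, true = true, observed = observed)
}

# mendelian transmission: one random allele from each parent
mate <- function(ids, mothers_gs, fathers_gs, mi, fi) {
  L <- length(mothers_gs$loci)
  n <- length(ids)
  pickm <- matrix(stats::runif(n * L) < 0.5, n, L)
  pickf <- matrix(stats::runif(n * L) < 0.5, n, L)
  m1 <- mothers_gs$a1[mi, , drop = FALSE]; m2 <- mothers_gs$a2[mi, , drop = FALSE]
  f1 <- fathers_gs$a1[fi, , drop = FALSE]; f2 <- fathers_gs$a2[fi, , drop = FALSE]
  am <- ifelse(pickm, m1, m2)
  af <- ifelse(pickf, f1, f2)
  genotype_set(ids, mothers_gs$loci, am, af)
}

#' Generate offspring, seed coats and ground truth
#'
#' For each offspring a mother is sampled uniformly from the adults and a
#' father uniformly from the remaining adults (or, with probability
#' `cfg$pollen_immigration`, drawn as an unsampled Hardy-Weinberg pollen
#' donor from outside the population). Offspring inherit one allele per locus
#' from each parent; the seed-coat genotype is an exact copy of the mother's
#' (seed coats are maternal tissue). Deposition is the mother's location plus
#' a displacement drawn from the ground-truth kernel with uniform direction.
#'
#' @param adults Adult table from [generate_landscape()].
#' @param genos Result of [generate_genotypes()].
#' @param cfg A [scenario_config()].
#' @param n_offspring Number of offspring (default `cfg$n_offspring`).
#' @param seed Integer seed.
#' @return List with `offspring` and `seed_coats` (true [genotype_set()]s),
#'   `offspring_obs` / `seed_coats_obs` (with error/missing applied),
#'   `locations` (deposition points, `id,role,species,x,y`) and `truth`
#'   (`offspring_id,mother_id,father_id,true_distance_m` plus deposition
#'   coordinates; `father_id` is `NA` for immigrant pollen donors).
#' @export
generate_offspring_and_seedcoats <- function(adults, genos, cfg,
                                             n_offspring = cfg$n_offspring,
                                             seed = child_seed(cfg$seed, "offspring")) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (n_offspring < 1L) stop("n_offspring must be >= 1", call. = FALSE)
  n_ad <- nrow(adults)
  if (n_ad < 2L) stop("need >= 2 adults", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("O%04d", seq_len(n_offspring))
  mi <- sample.int(n_ad, n_offspring, replace = TRUE)
  fi <- vapply(mi, function(m) {
    repeat {
      f <- sample.int(n_ad, 1L)
      if (f != m) return(f)
    }
  }, integer(1))
  immigrant <- stats::runif(n_offspring) < cfg$pollen_immigration
  # immigrant pollen donors: fresh HW genotypes not present among adults
  ext <- rhw_genotypes(paste0("EXT", seq_len(max(1L, sum(immigrant)))), genos$freqs)
  fathers_gs <- genos$true
  fidx <- fi
  if (any(immigrant)) {
    # splice immigrant rows into a combined father pool
    fathers_gs <- genotype_set(
      c(genos$true$ids, ext$ids), genos$true$loci,
      rbind(genos$true$a1, ext$a1), rbind(genos$true$a2, ext$a2))
    fidx[immigrant] <- n_ad + seq_len(sum(immigrant))
  }
  offspring <- mate(ids, genos$true, fathers_gs, mi, fidx)
  coats <- genotype_set(sub("^O", "S", ids), genos$true$loci,
                        genos$true$a1[mi, , drop = FALSE],
                        genos$true$a2[mi, , drop = FALSE])
  # deposition: mother location + kernel displacement, uniform direction
  r <- stats::rexp(n_offspring, rate = 1 / cfg$true_kernel$mean_m)
  th <- stats::runif(n_offspring, 0, 2 * pi)
  dep_x <- adults$x[mi] + r * cos(th)
  dep_y <- adults$y[mi] + r * sin(th)
  locations <- data.frame(
    id = ids, role = "seedling", species = cfg$species_name,
    x = dep_x, y = dep_y, stringsAsFactors = FALSE)
  truth <- data.frame(
    offspring_id = ids,
    mother_id = adults$id[mi],
    father_id = ifelse(immigrant, NA_character_, adults$id[fi]),
    mother_x = adults$x[mi], mother_y = adults$y[mi],
    dep_x = dep_x, dep_y = dep_y,
    true_distance_m = r,
    stringsAsFactors = FALSE)
  list(
    offspring = offspring,
    seed_coats = coats,
    offspring_obs = corrupt_genotypes(offspring, genos$freqs,
                                      cfg$genotyping_error, cfg$missing_rate),
    seed_coats_obs = corrupt_genotypes(coats, genos$freqs,
                                       cfg$genotyping_error, cfg$missing_rate),
    locations = locations,
    truth = truth
  )
}

#' Generate gut-passage-time samples
#'
#' Draws feeding-to-defecation intervals uniformly on the species gut window;
#' used to exercise the window-estimation step of the movement x gut-passage
#' model on synthetic data.
#'
#' @param cfg A [scenario_config()].
#' @param n Number of observations (default `cfg$n_gut_obs`).
#' @param seed Integer seed.
#' @return Numeric vector of gut passage times in minutes.
#' @export
generate_gut_samples <- function(cfg, n = cfg$n_gut_obs,
                                 seed = child_seed(cfg$seed, "gut")) {
  stopifnot(inherits(cfg, "scenario_config"), n >= 1)
  set.seed(seed)
  stats::runif(n, cfg$gut_window_min[1], cfg$gut_window_min[2])
}
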