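test_that("landscape generation is Poisson-distributed, in bounds and deterministic", {
  cfg <- scenario_config("parkia", seed = 3L)
  land <- generate_landscape(cfg)
  b <- land$boundary
  expect_true(all(land$adults$x >= b["xmin"] & land$adults$x <= b["xmax"]))
  expect_true(all(land$adults$y >= b["ymin"] & land$adults$y <= b["ymax"]))
  expect_gte(nrow(land$adults), 2L)
  land2 <- generate_landscape(cfg)
  expect_identical(land, land2)
  # counts across seeds behave like Poisson(density x area): mean and variance
  counts <- vapply(1:200, function(s) nrow(generate_landscape(cfg, seed = s)$adults),
                   integer(1))
  lambda <- cfg$adult_density_per_ha * cfg$home_range_area_ha
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  expect_lt(abs(var(counts) / lambda - 1), 0.35)
})

test_that("scenario validation rejects degenerate configurations", {
  expect_error(scenario_config("parkia", gut_window_min = c(240, 120)), "lower < upper")
  expect_error(scenario_config("parkia", alleles_per_locus = 1L), ">= 2")
  expect_error(scenario_config("parkia", home_range_area_ha = 1,
                               adult_density_per_ha = 0.5), ">= 2")
  expect_error(scenario_config("parkia", nonsense_field = 1), "unknown")
})

test_that("generated genotypes are Hardy-Weinberg with the full locus panel", {
  cfg <- scenario_config("leonia", home_range_area_ha = 50, adult_density_per_ha = 6,
                         seed = 13L)
  land <- generate_landscape(cfg)
  genos <- generate_genotypes(land$adults, cfg)
  expect_equal(ncol(genos$true$a1), 11L)
  # error 0, missing 0: observed is the true set
  expect_identical(genos$observed, genos$true)
  # observed heterozygosity matches 1 - sum p^2 within 3 SE per locus
  n <- nrow(land$adults)
  for (l in seq_along(genos$freqs)) {
    he <- 1 - sum(genos$freqs[[l]]^2)
    ho <- mean(genos$true$a1[, l] != genos$true$a2[, l])
    expect_lt(abs(ho - he), 3 * sqrt(he * (1 - he) / n) + 1e-12)
  }
})

test_that("offspring are Mendelian, seed coats copy the mother, kernel mean is recovered", {
  cfg <- scenario_config("parkia", n_offspring = 1000L, seed = 17L)
  land <- generate_landscape(cfg)
  genos <- generate_genotypes(land$adults, cfg)
  fam <- generate_offspring_and_seedcoats(land$adults, genos, cfg)
  expect_error(generate_offspring_and_seedcoats(land$adults, genos, cfg,
                                                n_offspring = 0L), ">= 1")
  mi <- match(fam$truth$mother_id, genos$true$ids)
  # seed coat is an exact maternal copy: zero mismatches at every locus
  for (i in seq_len(50)) {
    mm <- mismatch_count(fam$seed_coats, genos$true, i, mi[i])
    expect_equal(unname(mm), c(cfg$n_loci, 0L))
  }
  # every offspring allele comes from a parent
  fi <- match(fam$truth$father_id, genos$true$ids)
  for (i in seq_len(50)) {
    for (l in seq_len(cfg$n_loci)) {
      o <- c(fam$offspring$a1[i, l], fam$offspring$a2[i, l])
      par_alleles_m <- c(genos$true$a1[mi[i], l], genos$true$a2[mi[i], l])
      par_alleles_f <- c(genos$true$a1[fi[i], l], genos$true$a2[fi[i], l])
      expect_true(any(o %in% par_alleles_m))
      expect_true(any(o %in% par_alleles_f))
    }
  }
  # law of large numbers on the generating kernel
  mu <- cfg$true_kernel$mean_m
  expect_lt(abs(mean(fam$truth$true_distance_m) - mu), 3 * mu / sqrt(1000))
  # deposition = mother + displacement of the recorded length
  d <- euclidean_distance(cbind(fam$truth$mother_x, fam$truth$mother_y),
                          cbind(fam$truth$dep_x, fam$truth$dep_y))
  expect_equal(d, fam$truth$true_distance_m, tolerance = 1e-9)
})

test_that("tracks have the scan design, stay in bounds, and daily paths match the target range", {
  cfg <- scenario_config("parkia", seed = 23L)
  tracks <- generate_tracks(cfg, n_days = 200L)
  per_day <- table(tracks$day)
  expect_true(all(per_day == 19L)) # 9 h at 30 min
  side <- sqrt(cfg$home_range_area_ha * 1e4)
  expect_true(all(tracks$x >= 0 & tracks$x <= side))
  expect_true(all(tracks$y >= 0 & tracks$y <= side))
  paths <- vapply(split(tracks, tracks$day), function(tr)
    sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)), numeric(1))
  expect_gt(mean(paths), 600)
  expect_lt(mean(paths), 3000)
  expect_lt(abs(mean(paths) - 1700), 250)
  # determinism
  expect_identical(tracks, generate_tracks(cfg, n_days = 200L))
})

test_that("dispersal events honour the gut window and cannot outrun the path", {
  cfg <- scenario_config("parkia", n_days = 40L, seed = 29L)
  land <- generate_landscape(cfg)
  tracks <- generate_tracks(cfg, boundary = land$boundary)
  ev <- generate_dispersal_events(tracks, land$adults, cfg)
  gw <- cfg$gut_window_min
  expect_true(all(ev$events$gut_min >= gw[1] & ev$events$gut_min <= gw[2]))
  expect_equal(nrow(ev$records), nrow(ev$events))
  # SDD <= distance from tree to the feeding scan + path length walked during
  # the gut interval (cumulative-path oracle)
  for (i in seq_len(nrow(ev$events))) {
    e <- ev$events[i, ]
    tr <- tracks[tracks$day == e$day, ]
    tt <- tr$minutes_since_start
    seg <- which(tt >= e$t_feed_min & tt <= e$t_dep_min)
    pts <- rbind(cbind(tr$x[seg], tr$y[seg]), c(e$dep_x, e$dep_y))
    path <- sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
    feed_scan <- c(tr$x[which(tt == e$t_feed_min)], tr$y[which(tt == e$t_feed_min)])
    slack <- euclidean_distance(c(e$feed_x, e$feed_y), feed_scan)
    expect_lte(ev$records$distance_m[i], slack + path + 1e-6)
  }
  # flagged events are deposited at the final scan
  fl <- ev$events[ev$events$flagged_day_end, ]
  if (nrow(fl)) {
    for (i in seq_len(nrow(fl))) {
      tr <- tracks[tracks$day == fl$day[i], ]
      expect_equal(c(fl$dep_x[i], fl$dep_y[i]),
                   c(tr$x[nrow(tr)], tr$y[nrow(tr)]), tolerance = 1e-9)
    }
  }
})

test_that("gut samples fall inside the configured window and are deterministic", {
  cfg <- scenario_config("leonia", seed = 37L)
  g <- generate_gut_samples(cfg, n = 50L)
  expect_true(all(g >= 120 & g <= 240))
  expect_identical(g, generate_gut_samples(cfg, n = 50L))
})
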