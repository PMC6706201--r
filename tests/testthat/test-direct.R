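test_that("estimate_osd measures feeding-to-defecation distances and flags oddities", {
  ev <- data.frame(feed_x = c(0, 5, NA), feed_y = c(0, 5, 0),
                   dep_x = c(0, 5, 1), dep_y = c(160, 5, 1))
  expect_warning(s <- estimate_osd(ev), "skipped")
  expect_equal(s$values, c(160, 0))
  expect_equal(attr(s, "n_zero"), 1L)
  expect_equal(attr(s, "n_skipped"), 1L)
  expect_error(estimate_osd(data.frame(x = 1)), "columns")
})

test_that("OSD on synthetic events reproduces the ground-truth distances exactly", {
  cfg <- scenario_config("parkia", n_days = 10L, seed = 41L)
  land <- generate_landscape(cfg)
  tracks <- generate_tracks(cfg, boundary = land$boundary)
  ev <- generate_dispersal_events(tracks, land$adults, cfg)
  s <- estimate_osd(ev$events, species = cfg$species_name)
  expect_equal(s$values, ev$truth$true_distance_m, tolerance = 1e-12)
})

test_that("seed-coat matching assigns unique exact matches and refuses ties", {
  loci <- sprintf("L%d", 1:6)
  adults <- tiny_genotypes(
    c("A1", "A2", "A3"), loci,
    list(c("1/2", "3/4", "5/6"), c("1/1", "2/2", "3/3"), c("2/2", "4/4", "6/6"),
         c("1/2", "1/2", "1/2"), c("3/4", "3/4", "3/4"), c("5/6", "5/6", "5/6")))
  locs <- data.frame(id = c("A1", "A2", "A3"), x = c(0, 100, 200), y = 0)
  coat_unique <- adults[1]
  coat_unique$ids <- "S1"
  coat_unique <- genotype_set("S1", loci, coat_unique$a1, coat_unique$a2)
  seed_locs <- data.frame(id = "S1", x = 0, y = 120)
  r <- match_seed_coats(coat_unique, adults, locs, seed_locs)
  expect_equal(r$assignments$status, "assigned")
  expect_equal(r$assignments$mother_id, "A1")
  expect_equal(r$assignments$distance_m, 120)
  expect_equal(r$sample$values, 120)
  # clonal duplicates produce an ambiguous, unassigned coat
  dup <- genotype_set(c("A1", "A2", "A3", "A1b"), loci,
                      rbind(adults$a1, adults$a1[1, ]),
                      rbind(adults$a2, adults$a2[1, ]))
  r2 <- match_seed_coats(coat_unique, dup,
                         data.frame(id = dup$ids, x = 0, y = 0), seed_locs)
  expect_equal(r2$assignments$status, "ambiguous (2 matches)")
  expect_true(is.na(r2$assignments$mother_id))
  # a coat typed at too few loci never matches
  sparse <- genotype_set("S2", loci,
                         matrix(c(1L, 3L, 0L, 0L, 0L, 0L), 1),
                         matrix(c(2L, 4L, 0L, 0L, 0L, 0L), 1))
  r3 <- match_seed_coats(sparse, adults, locs, data.frame(id = "S2", x = 0, y = 0),
                         min_loci = 5L)
  expect_equal(r3$assignments$status, "no match")
  expect_error(match_seed_coats(coat_unique, adults[0], locs, seed_locs), "no adult")
})

test_that("maternity recovery is perfect without error and degrades monotonically with it", {
  res <- numeric(3)
  errs <- c(0, 0.01, 0.05)
  for (k in seq_along(errs)) {
    cfg <- scenario_config("leonia", alleles_per_locus = 6L, n_offspring = 200L,
                           genotyping_error = errs[k], seed = 43L)
    land <- generate_landscape(cfg)
    genos <- generate_genotypes(land$adults, cfg)
    genos$observed <- genos$true # error applies to coats only in this check
    fam <- generate_offspring_and_seedcoats(land$adults, genos, cfg)
    seed_locs <- data.frame(id = fam$seed_coats_obs$ids,
                            x = fam$locations$x, y = fam$locations$y)
    r <- match_seed_coats(fam$seed_coats_obs, genos$true, land$adults, seed_locs)
    ok <- r$assignments$status == "assigned"
    res[k] <- mean(ok)
    if (errs[k] == 0) {
      expect_equal(mean(ok), 1)
      expect_true(all(r$assignments$mother_id[ok] == fam$truth$mother_id[ok]))
    }
  }
  expect_true(res[1] > res[2] && res[2] > res[3])
})

test_that("chance-match expectation from allele frequencies predicts simulated false matches", {
  # a deliberately weak panel so that chance matches are observable
  set.seed(47)
  freqs <- uniform_freqs(n_loci = 3L, k = 2L) # match prob per locus is high
  n_adults <- 60L
  n_rep <- 200L
  target <- genotype_set("t", names(freqs), matrix(c(1L, 1L, 1L), 1),
                         matrix(c(2L, 2L, 2L), 1))
  expc <- expected_false_matches(target, freqs, n_adults)
  counts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    pool <- frugidisp:::rhw_genotypes(sprintf("a%d", seq_len(n_adults)), freqs)
    counts[r] <- sum(pool$a1[, 1] == 1L & pool$a2[, 1] == 2L &
                     pool$a1[, 2] == 1L & pool$a2[, 2] == 2L &
                     pool$a1[, 3] == 1L & pool$a2[, 3] == 2L)
  }
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expc), 3 * se + 1e-9)
})
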