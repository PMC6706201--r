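test_that("single-parent LOD matches the hand-derived transition probability", {
  # offspring (A,B), candidate (A,A), p_A = p_B = 0.5, e = 0:
  # T = P(transmit A) * p_B = 0.5, P(g_o) = 2 p_A p_B = 0.5 -> ratio 1, LOD 0
  off <- tiny_genotypes("o", "L1", list("1/2"))
  can <- tiny_genotypes("c", "L1", list("1/1"))
  fr <- list(L1 = c("1" = 0.5, "2" = 0.5))
  expect_equal(single_parent_lod(off, can, fr, e = 0)$lod, 0)
  # heterozygous candidate sharing one allele: T = 0.5 * p_B -> ratio 1/(4 p_A)
  can2 <- tiny_genotypes("c2", "L1", list("1/3"))
  fr3 <- list(L1 = c("1" = 0.2, "2" = 0.3, "3" = 0.5))
  expect_equal(single_parent_lod(off, can2, fr3, e = 0)$lod,
               log(1 / (4 * 0.2)))
  # brute-force oracle: enumerate parent-offspring genotype pairs and verify
  # that T sums to the HW offspring distribution when candidates are random
  k <- 3; p <- c(0.2, 0.3, 0.5)
  for (a in 1:k) for (b in a:k) {
    Po <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
    tot <- 0
    for (c1 in 1:k) for (c2 in 1:k) {
      M <- function(t) if (a == b) (t == a) * p[a] else (t == a) * p[b] + (t == b) * p[a]
      tot <- tot + p[c1] * p[c2] * 0.5 * (M(c1) + M(c2))
    }
    expect_equal(tot, Po, tolerance = 1e-12)
  }
})

test_that("a candidate sharing no allele is excluded at e = 0", {
  off <- tiny_genotypes("o", "L1", list("1/2"))
  bad <- tiny_genotypes("b", "L1", list("3/3"))
  fr <- list(L1 = c("1" = 0.4, "2" = 0.3, "3" = 0.3))
  expect_identical(single_parent_lod(off, bad, fr, e = 0)$lod, -Inf)
  # with e > 0 the score is finite but strongly negative
  expect_lt(single_parent_lod(off, bad, fr, e = 0.01)$lod, -3)
})

test_that("LOD is additive over loci and invariant to locus order", {
  loci <- c("L1", "L2", "L3")
  off <- tiny_genotypes("o", loci, list("1/2", "2/2", "1/3"))
  can <- tiny_genotypes("c", loci, list("1/1", "2/3", "3/3"))
  fr <- stats::setNames(rep(list(c("1" = 0.2, "2" = 0.3, "3" = 0.5)), 3), loci)
  full <- single_parent_lod(off, can, fr, e = 0.01)$lod
  parts <- vapply(seq_along(loci), function(l) {
    o1 <- genotype_set("o", loci[l], off$a1[, l, drop = FALSE], off$a2[, l, drop = FALSE])
    c1 <- genotype_set("c", loci[l], can$a1[, l, drop = FALSE], can$a2[, l, drop = FALSE])
    single_parent_lod(o1, c1, fr[l], e = 0.01)$lod
  }, numeric(1))
  expect_equal(full, sum(parts), tolerance = 1e-12)
  perm <- c(3, 1, 2)
  offp <- genotype_set("o", loci[perm], off$a1[, perm, drop = FALSE],
                       off$a2[, perm, drop = FALSE])
  canp <- genotype_set("c", loci[perm], can$a1[, perm, drop = FALSE],
                       can$a2[, perm, drop = FALSE])
  expect_equal(single_parent_lod(offp, canp, fr[perm], e = 0.01)$lod, full,
               tolerance = 1e-12)
})

test_that("true parents outscore random non-parents on average", {
  set.seed(53)
  cfg <- scenario_config("parkia", n_offspring = 40L, seed = 53L)
  land <- generate_landscape(cfg)
  genos <- generate_genotypes(land$adults, cfg)
  fam <- generate_offspring_and_seedcoats(land$adults, genos, cfg)
  freqs <- allele_frequencies(genos$true)
  lod_true <- lod_rand <- numeric(40)
  for (i in 1:40) {
    mo <- match(fam$truth$mother_id[i], genos$true$ids)
    other <- setdiff(seq_along(genos$true$ids),
                     match(c(fam$truth$mother_id[i], fam$truth$father_id[i]),
                           genos$true$ids))
    lod_true[i] <- single_parent_lod(fam$offspring, genos$true, freqs, 0.01, i, mo)$lod
    lod_rand[i] <- single_parent_lod(fam$offspring, genos$true, freqs, 0.01, i,
                                     sample(other, 1))$lod
  }
  expect_gt(mean(lod_true), mean(lod_rand))
})

test_that("the critical delta is deterministic and increases as sampling gets sparser", {
  fr <- uniform_freqs(10L, 8L)
  cfg99 <- parentage_config(n_candidates = 33L, proportion_sampled = 0.99,
                            n_confidence_sims = 3000L)
  d1 <- critical_delta(fr, cfg99, seed = 5)
  d1b <- critical_delta(fr, cfg99, seed = 5)
  expect_identical(d1, d1b)
  cfg15 <- parentage_config(n_candidates = 33L, proportion_sampled = 0.15,
                            n_confidence_sims = 3000L)
  d2 <- critical_delta(fr, cfg15, seed = 5)
  expect_gt(d2$threshold, d1$threshold)
  # fully sampled, error-free, polymorphic: threshold near zero, nearly all assigned
  cfg_easy <- parentage_config(n_candidates = 33L, proportion_sampled = 1,
                               genotyping_error = 0, n_confidence_sims = 3000L)
  d3 <- critical_delta(fr, cfg_easy, seed = 5)
  expect_lt(d3$threshold, 0.5)
  expect_gt(d3$prop_assignable, 0.97)
})

test_that("assignment enforces the typed-loci filter and Mendelian exclusion", {
  set.seed(59)
  cfg <- scenario_config("parkia", n_offspring = 30L, seed = 59L)
  land <- generate_landscape(cfg)
  genos <- generate_genotypes(land$adults, cfg)
  fam <- generate_offspring_and_seedcoats(land$adults, genos, cfg)
  freqs <- allele_frequencies(genos$true)
  pcfg <- parentage_config(n_candidates = nrow(land$adults),
                           genotyping_error = 0, min_typed_loci = 5L,
                           n_confidence_sims = 500L)
  # blank out most loci of the first offspring
  off <- fam$offspring
  off$a1[1, 1:6] <- 0L
  off$a2[1, 1:6] <- 0L
  off <- genotype_set(off$ids, off$loci, off$a1, off$a2)
  asn <- assign_parentage(off, genos$true, freqs, pcfg, delta = 0)
  expect_false(off$ids[1] %in% asn$offspring_id)
  expect_equal(attr(asn, "n_excluded_few_loci"), 1L)
  # at e = 0, every assigned parent is Mendelian-compatible
  for (r in seq_len(nrow(asn))) {
    i <- match(asn$offspring_id[r], off$ids)
    j <- match(asn$parent_id[r], genos$true$ids)
    expect_equal(mendelian_incompatibilities(off, genos$true, i, j), 0L)
  }
})

test_that("estimate_pas pools pair distances and applies the 700 m rule", {
  asn <- data.frame(offspring_id = c("O1", "O1"), parent_id = c("P1", "P2"),
                    rank = 1:2, lod = c(5, 4), delta = c(2, 2),
                    confident = TRUE, stringsAsFactors = FALSE)
  off_locs <- data.frame(id = "O1", x = 0, y = 0)
  ad_locs <- data.frame(id = c("P1", "P2"), x = c(100, 900), y = 0)
  pcfg <- parentage_config()
  s <- estimate_pas(asn, off_locs, ad_locs, pcfg)
  expect_equal(s$values, 100)
  expect_equal(attr(s, "n_excluded_distance"), 1L)
  expect_error(estimate_pas(asn[0, ], off_locs, ad_locs, pcfg), "no parentage")
})
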