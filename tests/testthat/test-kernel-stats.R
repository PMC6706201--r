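test_that("bootstrap of a constant sample has zero-width interval at the constant", {
  b <- bootstrap_mean(c(50, 50, 50), n_boot = 500, seed = 3)
  expect_equal(b$mean, 50)
  expect_equal(unname(diff(b$ci)), 0)
  expect_error(bootstrap_mean(numeric(0)), "empty")
})

test_that("bootstrap means are reproducible and centred on the sample mean", {
  set.seed(7)
  x <- rexp(100, 1 / 200)
  b1 <- bootstrap_mean(x, n_boot = 2000, seed = 11)
  b2 <- bootstrap_mean(x, n_boot = 2000, seed = 11)
  expect_identical(b1, b2)
  # Monte-Carlo error of the mean of n_boot bootstrap means is ~ SE / sqrt(n_boot)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(b1$mean - mean(x)), 5 * se / sqrt(2000))
  expect_true(b1$ci[1] < mean(x) && mean(x) < b1$ci[2])
})

test_that("bootstrap percentile intervals achieve near-nominal coverage", {
  set.seed(13)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    x <- rnorm(50, 100, 15)
    b <- bootstrap_mean(x, n_boot = 400, seed = r)
    if (b$ci[1] <= 100 && 100 <= b$ci[2]) hits <- hits + 1L
  }
  cover <- hits / n_rep
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / n_rep) - 0.02)
})

test_that("kernel densities integrate to one, are non-negative, and find both modes", {
  set.seed(17)
  x <- c(rnorm(150, 100, 15), rnorm(150, 300, 15))
  k <- kernel_density(x, n_boot = 50, seed = 5)
  expect_true(all(k$density >= 0))
  integral <- sum(diff(k$grid) * (head(k$density, -1) + tail(k$density, -1)) / 2)
  expect_lt(abs(integral - 1), 0.01)
  expect_equal(k$bandwidth, stats::bw.nrd0(x))
  # two interior local maxima near the generating modes
  dens <- k$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1L
  peak_locs <- k$grid[peaks]
  expect_true(any(abs(peak_locs - 100) < 40))
  expect_true(any(abs(peak_locs - 300) < 40))
  # envelope brackets the point estimate everywhere
  expect_true(all(k$lower <= k$density + 1e-12))
  expect_true(all(k$upper >= k$density - 1e-12))
  expect_error(kernel_density(rep(5, 20)), "zero variance")
  expect_error(kernel_density(c(1, 2, 3)), "n >= 5")
})

test_that("mass conservation holds across random samples", {
  set.seed(19)
  for (r in 1:20) {
    x <- rexp(sample(20:200, 1), 1 / runif(1, 50, 400))
    k <- kernel_density(x, n_boot = 10, seed = r)
    integral <- sum(diff(k$grid) * (head(k$density, -1) + tail(k$density, -1)) / 2)
    expect_lt(abs(integral - 1), 0.01)
  }
})

test_that("KS statistic equals a brute-force ECDF sweep", {
  a <- c(12, 40, 41, 55, 80, 85, 90, 120)
  b <- c(30, 33, 60, 61, 62, 100, 130, 150)
  r <- ks_two_sample(a, b)
  # oracle: evaluate |ECDF_a - ECDF_b| at every data point
  pts <- sort(unique(c(a, b)))
  D_oracle <- max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
  expect_equal(r$D, D_oracle, tolerance = 1e-12)
  expect_equal(ks_two_sample(a, a)$D, 0)
  expect_equal(ks_two_sample(1:5, 6:10)$D, 1)
})

test_that("Kruskal-Wallis matches the hand-computed tie-corrected statistic", {
  g <- list(a = c(1.2, 3.4, 5.1), b = c(2.2, 4.1, 4.1, 8), c = c(0.5, 6.3))
  r <- kruskal_wallis(g)
  # oracle: direct rank formula with tie correction
  vals <- unlist(g)
  rk <- rank(vals)
  n <- length(vals)
  idx <- rep(seq_along(g), lengths(g))
  H <- 12 / (n * (n + 1)) * sum(tapply(rk, idx, sum)^2 / lengths(g)) - 3 * (n + 1)
  ties <- table(vals)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(r$H, H, tolerance = 1e-12)
  expect_equal(r$df, 2L)
  expect_equal(r$p, 1 - pchisq(H, 2), tolerance = 1e-12)
  # identical groups: H = 0, p = 1 after tie correction
  same <- kruskal_wallis(list(c(1, 2), c(1, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  # five methods give four degrees of freedom
  five <- kruskal_wallis(stats::setNames(lapply(1:5, function(i) rnorm(10, i)),
                                         c("OSD", "GSC", "PAS", "CMG", "IBM")))
  expect_equal(five$df, 4L)
})

test_that("pairwise Wilcoxon uses the C(k,2) Bonferroni multiplier and the exact U", {
  set.seed(23)
  g5 <- stats::setNames(lapply(1:5, function(i) rnorm(12, i / 2)), letters[1:5])
  m <- pairwise_wilcoxon(g5)
  expect_equal(dim(m), c(5L, 5L))
  expect_equal(sum(!is.na(m)), 20L) # 10 comparisons, symmetric
  expect_equal(m, t(m))
  raw <- suppressWarnings(stats::wilcox.test(g5$a, g5$b, exact = FALSE)$p.value)
  expect_equal(m["a", "b"], min(1, raw * 10), tolerance = 1e-12)
  # identical groups: all adjusted p = 1
  same <- pairwise_wilcoxon(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same["x", "y"], 1)
  # U statistic equals the exhaustive concordant-pair count
  a <- c(3, 9, 12, 20)
  b <- c(1, 7, 15, 22, 30)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  W <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$statistic)
  expect_equal(unname(W), U)
})

test_that("compare_methods assembles a coherent report and round-trips its CSVs", {
  set.seed(29)
  x <- rexp(60, 1 / 200)
  same5 <- stats::setNames(lapply(1:5, function(i) x), c("OSD", "GSC", "PAS", "CMG", "IBM"))
  rep_same <- compare_methods(same5, n_boot_mean = 300, n_boot_kernel = 10, seed = 1)
  expect_equal(rep_same$kw$p, 1)
  expect_true(all(rep_same$wilcoxon[upper.tri(rep_same$wilcoxon)] == 1))
  expect_true(all(rep_same$ks_D[upper.tri(rep_same$ks_D)] == 0))
  expect_error(compare_methods(list(a = 1:3, b = numeric(0))), "empty")
  tmp <- withr::local_tempdir()
  paths <- write_comparison(rep_same, tmp)
  expect_true(all(file.exists(file.path(tmp, c("means.csv", "kw.csv",
                                               "wilcoxon_matrix.csv",
                                               "ks_D_matrix.csv", "ks_p_matrix.csv")))))
  back <- utils::read.csv(file.path(tmp, "means.csv"))
  expect_equal(back$mean, rep_same$means$mean, tolerance = 1e-6)
})

test_that("shifted distributions are detected with high power", {
  detected <- 0L
  for (s in 1:20) {
    set.seed(s)
    g <- list(a = rexp(200, 1 / 200), b = 100 + rexp(200, 1 / 200))
    if (kruskal_wallis(g)$p < 0.05) detected <- detected + 1L
  }
  expect_gte(detected, 19L)
})
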