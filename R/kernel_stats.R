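#' Bootstrap mean of a distance sample
#'
#' Resamples with replacement (`n_boot` resamplings of the full sample size),
#' reporting the mean of the bootstrap means and a percentile confidence
#' interval. Percentile (rather than BCa) intervals are used as the simplest
#' method consistent with plain mean bootstrapping.
#'
#' @param x Numeric vector (or [distance_sample()]), `n >= 1`; `n >= 2`
#'   needed for a non-degenerate interval.
#' @param n_boot Number of resamplings (default 10,000).
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @param seed Integer seed.
#' @return List: `mean` (bootstrap mean of means), `ci` (`c(lower, upper)`),
#'   `sample_mean`, `n`, `n_boot`.
#' @export
bootstrap_mean <- function(x, n_boot = 10000L, conf = 0.95, seed = 1L) {
  if (inherits(x, "distance_sample")) x <- x$values
  x <- as.numeric(x)
  if (!length(x)) stop("bootstrap_mean(): empty sample", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(x)
  # resample in blocks to bound memory at large n_boot
  block <- max(1L, min(n_boot, as.integer(5e6 / n)))
  means <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    m <- min(block, n_boot - done)
    idx <- matrix(sample.int(n, n * m, replace = TRUE), n, m)
    means[done + seq_len(m)] <- colMeans(matrix(x[idx], n, m))
    done <- done + m
  }
  a <- (1 - conf) / 2
  list(mean = mean(means),
       ci = stats::quantile(means, c(a, 1 - a), names = FALSE),
       sample_mean = mean(x), n = n, n_boot = as.integer(n_boot))
}

#' Dispersal-kernel density estimate with bootstrap envelope
#'
#' Nonparametric smooth estimate of the distance kernel: a Gaussian kernel
#' density with the rule-of-thumb bandwidth `0.9 min(sd, IQR/1.34) n^{-1/5}`
#' ([stats::bw.nrd0()], the default of `density()`), evaluated on a 512-point
#' grid from 0 to `1.1 * max(sample)`. Probability mass that would fall below
#' zero is reflected at the origin, so the density integrates to 1 on the
#' positive half-line. The confidence envelope comes from `n_boot` bootstrap
#' resamples (pointwise 2.5%/97.5% percentiles, widened where necessary to
#' contain the point estimate).
#'
#' @param x Numeric vector (or [distance_sample()]) of distances, `n >= 5`,
#'   with positive spread.
#' @param n_boot Bootstrap resamplings for the envelope (default 100).
#' @param seed Integer seed.
#' @param n_grid Grid size (default 512).
#' @return List of class `kernel_estimate`: `grid`, `density`, `bandwidth`,
#'   `lower`, `upper`, `n_boot`, `n`.
#' @export
kernel_density <- function(x, n_boot = 100L, seed = 1L, n_grid = 512L) {
  if (inherits(x, "distance_sample")) x <- x$values
  x <- as.numeric(x)
  if (length(x) < 5L) stop("kernel_density(): need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("kernel_density(): sample has zero variance", call. = FALSE)
  set.seed(as.integer(seed))
  # grid spans 1.1 x the sample maximum, extended by 4 bandwidths where the
  # smoother would otherwise push visible mass past the grid edge
  h0 <- stats::bw.nrd0(x)
  grid <- seq(0, max(max(x) * 1.1, max(x) + 4 * h0), length.out = n_grid)
  est <- reflected_kde(x, grid)
  boot <- matrix(NA_real_, n_boot, n_grid)
  for (b in seq_len(n_boot)) {
    xb <- sample(x, replace = TRUE)
    if (stats::sd(xb) == 0) xb <- x # degenerate resample: fall back on the sample
    boot[b, ] <- reflected_kde(xb, grid)$density
  }
  lo <- apply(boot, 2L, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(boot, 2L, stats::quantile, probs = 0.975, names = FALSE)
  structure(list(grid = grid, density = est$density, bandwidth = est$bandwidth,
                 lower = pmin(lo, est$density), upper = pmax(hi, est$density),
                 n_boot = as.integer(n_boot), n = length(x)),
            class = "kernel_estimate")
}

# Gaussian KDE with reflection at the origin, evaluated on a grid
reflected_kde <- function(x, grid) {
  h <- stats::bw.nrd0(x)
  z <- outer(grid, x, "-") / h
  zr <- outer(grid, -x, "-") / h
  dens <- (rowSums(stats::dnorm(z)) + rowSums(stats::dnorm(zr))) / (length(x) * h)
  list(density = dens, bandwidth = h)
}

#' @export
print.kernel_estimate <- function(x, ...) {
  cat(sprintf("<kernel_estimate> n = %d, bandwidth = %.2f m, grid 0-%.0f m (%d points)\n",
              x$n, x$bandwidth, max(x$grid), length(x$grid)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical cumulative
#' distribution functions; the p-value uses the asymptotic Kolmogorov
#' distribution by default (the test is sensitive to differences in both
#' location and shape).
#'
#' @param a,b Numeric vectors (or [distance_sample()]s), each `n >= 2`.
#' @param exact Passed to [stats::ks.test()] (default `FALSE`: asymptotic).
#' @return List: `D`, `p`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (inherits(a, "distance_sample")) a <- a$values
  if (inherits(b, "distance_sample")) b <- b$values
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  r <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(r$statistic), p = unname(r$p.value))
}

#' Kruskal-Wallis rank-sum test across method samples
#'
#' Rank-based H with tie correction and chi-square p-value on `k - 1` degrees
#' of freedom (wrapping [stats::kruskal.test()]); five methods give 4 df.
#'
#' @param groups Named list of numeric vectors (or [distance_sample()]s).
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) if (inherits(g, "distance_sample")) g$values else g)
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L),
            sum(lengths(groups)) >= 3L)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  r <- stats::kruskal.test(vals, g)
  list(H = unname(r$statistic), df = unname(r$parameter), p = unname(r$p.value))
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Mann-Whitney/Wilcoxon rank-sum test for every unordered pair of groups,
#' normal approximation with continuity correction; p-values are multiplied
#' by the number of comparisons `choose(k, 2)` and capped at 1.
#'
#' @param groups Named list of numeric vectors (or [distance_sample()]s).
#' @param correction `"bonferroni"` (default) or any [stats::p.adjust()] method.
#' @return Symmetric k x k matrix of adjusted p-values (`NA` diagonal).
#' @export
pairwise_wilcoxon <- function(groups, correction = "bonferroni") {
  groups <- lapply(groups, function(g) if (inherits(g, "distance_sample")) g$values else g)
  k <- length(groups)
  stopifnot(k >= 2L)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  raw <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      p <- if (identical(groups[[i]], groups[[j]])) 1 else
        suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]],
                                            exact = FALSE, correct = TRUE))$p.value
      raw[i, j] <- raw[j, i] <- p
    }
  }
  up <- raw[upper.tri(raw)]
  adj <- stats::p.adjust(up, method = correction, n = choose(k, 2L))
  out <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  out[upper.tri(out)] <- adj
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Full method-comparison report
#'
#' Assembles, for two or more per-method distance samples, the bootstrap
#' means with percentile intervals, the Kruskal-Wallis test, the pairwise
#' Wilcoxon matrix (Bonferroni-adjusted), the pairwise Kolmogorov-Smirnov D
#' and p matrices, and a kernel-density estimate per method.
#'
#' @param samples Named list of [distance_sample()]s or numeric vectors
#'   (names default to the method tags).
#' @param n_boot_mean,n_boot_kernel Bootstrap sizes (defaults 10,000 and 100).
#' @param seed Integer seed.
#' @return Object of class `sdd_comparison`: `means` (data frame), `kw`,
#'   `wilcoxon` (adjusted p matrix), `ks_D`, `ks_p` (matrices), `kernels`
#'   (list; `NULL` where a sample is too small or degenerate).
#' @export
compare_methods <- function(samples, n_boot_mean = 10000L, n_boot_kernel = 100L,
                            seed = 1L) {
  if (length(samples) < 2L) stop("compare_methods(): need >= 2 samples", call. = FALSE)
  nm <- names(samples)
  if (is.null(nm)) {
    nm <- vapply(samples, function(s)
      if (inherits(s, "distance_sample")) s$method else NA_character_, character(1))
  }
  vals <- lapply(samples, function(s) if (inherits(s, "distance_sample")) s$values else as.numeric(s))
  names(vals) <- nm
  empty <- nm[lengths(vals) == 0L]
  if (length(empty)) {
    stop("compare_methods(): empty sample(s): ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  k <- length(vals)
  means <- data.frame(method = nm, n = lengths(vals),
                      mean = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    bm <- bootstrap_mean(vals[[i]], n_boot = n_boot_mean, seed = seed + i)
    means$mean[i] <- bm$mean
    means$ci_lower[i] <- bm$ci[1]
    means$ci_upper[i] <- bm$ci[2]
  }
  kw <- kruskal_wallis(vals)
  wil <- pairwise_wilcoxon(vals)
  ksD <- ksP <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- ks_two_sample(vals[[i]], vals[[j]])
      ksD[i, j] <- ksD[j, i] <- r$D
      ksP[i, j] <- ksP[j, i] <- r$p
    }
  }
  kernels <- lapply(seq_len(k), function(i) {
    v <- vals[[i]]
    if (length(v) >= 5L && stats::sd(v) > 0) {
      kernel_density(v, n_boot = n_boot_kernel, seed = seed + 100L + i)
    } else NULL
  })
  names(kernels) <- nm
  structure(list(means = means, kw = kw, wilcoxon = wil, ks_D = ksD,
                 ks_p = ksP, kernels = kernels),
            class = "sdd_comparison")
}

#' @export
print.sdd_comparison <- function(x, ...) {
  cat("Seed dispersal distance: method comparison\n")
  cat(sprintf("  Kruskal-Wallis: H(%d) = %.2f, p = %.3g\n", x$kw$df, x$kw$H, x$kw$p))
  m <- x$means
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-4s n = %4d  mean = %7.1f m  [%.1f, %.1f]\n",
                m$method[i], m$n[i], m$mean[i], m$ci_lower[i], m$ci_upper[i]))
  }
  invisible(x)
}

#' Write a method-comparison report as CSV files
#'
#' Writes `means.csv`, `kw.csv`, `wilcoxon_matrix.csv`, `ks_D_matrix.csv`,
#' `ks_p_matrix.csv` and one `kernel_<method>.csv` (grid, density, lo, hi)
#' per non-degenerate kernel into `dir`.
#'
#' @param report An `sdd_comparison` from [compare_methods()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_comparison <- function(report, dir) {
  stopifnot(inherits(report, "sdd_comparison"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "means.csv")
  utils::write.csv(report$means, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "kw.csv")
  utils::write.csv(data.frame(H = report$kw$H, df = report$kw$df, p = report$kw$p),
                   p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)
  for (fn in c("wilcoxon", "ks_D", "ks_p")) {
    p <- file.path(dir, paste0(fn, "_matrix.csv"))
    utils::write.csv(report[[fn]], p, row.names = TRUE, quote = FALSE)
    paths <- c(paths, p)
  }
  for (m in names(report$kernels)) {
    ke <- report$kernels[[m]]
    if (is.null(ke)) next
    p <- file.path(dir, paste0("kernel_", m, ".csv"))
    utils::write.csv(data.frame(grid_m = ke$grid, density = ke$density,
                                lo = ke$lower, hi = ke$upper),
                     p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
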