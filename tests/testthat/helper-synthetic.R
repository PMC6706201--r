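# shared test helpers: small genotype panels and summary utilities

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# uniform allele frequencies: n_loci loci with k equifrequent alleles
uniform_freqs <- function(n_loci = 10L, k = 8L) {
  f <- stats::setNames(rep(1 / k, k), as.character(seq_len(k)))
  stats::setNames(lapply(seq_len(n_loci), function(i) f),
                  sprintf("L%02d", seq_len(n_loci)))
}

# a tiny deterministic genotype set from explicit allele pairs:
# calls is a list of length-n character vectors like "1/2" per locus
tiny_genotypes <- function(ids, loci, calls) {
  n <- length(ids)
  a1 <- matrix(0L, n, length(loci))
  a2 <- matrix(0L, n, length(loci))
  for (l in seq_along(loci)) {
    parts <- strsplit(calls[[l]], "/", fixed = TRUE)
    a1[, l] <- as.integer(vapply(parts, `[`, "", 1L))
    a2[, l] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  genotype_set(ids, loci, a1, a2)
}

# brute-force double-loop oracle for within-day interval distances
brute_interval_distances <- function(track) {
  out <- list()
  for (d in unique(track$day)) {
    tr <- track[track$day == d, ]
    n <- nrow(tr)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i < j) {
          out[[length(out) + 1L]] <- data.frame(
            day = d,
            lag_min = tr$minutes_since_start[j] - tr$minutes_since_start[i],
            distance_m = sqrt((tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2))
        }
      }
    }
  }
  do.call(rbind, out)
}
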