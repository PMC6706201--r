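#' Diploid multilocus genotype sets
#'
#' Container for diploid microsatellite genotypes: one row per sample, one
#' unordered pair of positive integer allele codes per locus. Allele code 0 is
#' the missing-data sentinel (GenAlex convention); a call with either allele
#' equal to 0 is treated as fully missing and normalised to 0/0. Pairs are
#' stored sorted (`a1 <= a2`) so that unordered comparison is a plain
#' elementwise test.
#'
#' @param ids Character vector of unique sample identifiers.
#' @param loci Character vector of locus names (shared order for the dataset).
#' @param a1,a2 Integer matrices (`length(ids)` x `length(loci)`) of allele
#'   codes; 0 marks missing.
#' @return An object of class `genotype_set`.
#' @export
genotype_set <- function(ids, loci, a1, a2) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  if (!identical(dim(a1), dim(a2)) ||
      nrow(a1) != length(ids) || ncol(a1) != length(loci)) {
    stop("allele matrices must be length(ids) x length(loci)", call. = FALSE)
  }
  if (any(a1 < 0, na.rm = TRUE) || any(a2 < 0, na.rm = TRUE) ||
      anyNA(a1) || anyNA(a2)) {
    stop("allele codes must be non-negative integers (0 = missing)", call. = FALSE)
  }
  # half-missing calls become fully missing
  miss <- a1 == 0L | a2 == 0L
  a1[miss] <- 0L; a2[miss] <- 0L
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = lo, a2 = hi),
            class = "genotype_set")
}

#' @export
length.genotype_set <- function(x) length(x$ids)

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d samples x %d loci (%s)\n",
              length(x$ids), length(x$loci),
              paste(utils::head(x$loci, 4), collapse = ", ")))
  invisible(x)
}

#' Subset a genotype set by sample
#'
#' @param x A `genotype_set`.
#' @param i Integer, logical or character (sample id) index.
#' @param ... Ignored.
#' @return A `genotype_set` with the selected samples.
#' @export
`[.genotype_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown sample id in genotype subset", call. = FALSE)
  genotype_set(x$ids[i], x$loci, x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE])
}

n_typed_loci <- function(g) rowSums(g$a1 > 0L)

check_shared_loci <- function(g1, g2) {
  if (!identical(g1$loci, g2$loci)) {
    if (!length(intersect(g1$loci, g2$loci))) {
      stop("genotype sets share no loci", call. = FALSE)
    }
    stop("genotype sets must use the same locus panel in the same order",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed over all non-missing allele copies at each locus.
#' A locus with zero non-missing calls is reported with a warning and excluded
#' (its entry is `NULL`).
#'
#' @param g A [genotype_set()].
#' @return A named list (one element per locus) of named numeric vectors:
#'   allele code -> frequency, summing to 1. Attribute `n_copies` on each
#'   element records the number of allele copies counted.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_set"))
  out <- vector("list", length(g$loci))
  names(out) <- g$loci
  dropped <- character(0)
  for (l in seq_along(g$loci)) {
    alleles <- c(g$a1[, l], g$a2[, l])
    alleles <- alleles[alleles > 0L]
    if (!length(alleles)) {
      dropped <- c(dropped, g$loci[l])
      next
    }
    tab <- table(alleles)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    attr(f, "n_copies") <- sum(tab)
    out[[l]] <- f
  }
  if (length(dropped)) {
    warning("loci with no non-missing calls excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    out <- out[!vapply(out, is.null, logical(1))]
  }
  out
}

#' Count comparable and mismatching loci between two genotypes
#'
#' A locus is compared only when both genotypes are typed there; it mismatches
#' when the unordered allele pairs differ. Used for exact-match maternity
#' identification from seed coats ("no mismatches allowed").
#'
#' @param g1,g2 `genotype_set`s of a single sample each (or supply `i`/`j`).
#' @param i,j Row indices into `g1`/`g2` (default 1).
#' @return Named integer vector `c(n_compared = , n_mismatch = )`.
#' @export
mismatch_count <- function(g1, g2, i = 1L, j = 1L) {
  check_shared_loci(g1, g2)
  a1 <- g1$a1[i, ]; a2 <- g1$a2[i, ]
  b1 <- g2$a1[j, ]; b2 <- g2$a2[j, ]
  both <- a1 > 0L & b1 > 0L
  mism <- both & (a1 != b1 | a2 != b2)
  c(n_compared = sum(both), n_mismatch = sum(mism))
}

#' Count Mendelian-incompatible loci between offspring and a candidate parent
#'
#' A locus is incompatible when both genotypes are typed and the candidate
#' shares no allele with the offspring, i.e. the candidate could not have
#' transmitted either offspring allele. This exclusion count precedes the
#' likelihood-based parentage analysis.
#'
#' @param offspring,candidate Single-sample `genotype_set`s (or use `i`/`j`).
#' @param i,j Row indices (default 1).
#' @return Integer: number of incompatible loci.
#' @export
mendelian_incompatibilities <- function(offspring, candidate, i = 1L, j = 1L) {
  check_shared_loci(offspring, candidate)
  o1 <- offspring$a1[i, ]; o2 <- offspring$a2[i, ]
  c1 <- candidate$a1[j, ]; c2 <- candidate$a2[j, ]
  both <- o1 > 0L & c1 > 0L
  share <- c1 == o1 | c1 == o2 | c2 == o1 | c2 == o2
  sum(both & !share)
}
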