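#' Seed dispersal distances from observed events (OSD)
#'
#' The most direct estimate: one Euclidean distance per observed event,
#' feeding location to defecation location. Events missing a coordinate are
#' skipped with a warning. Zero-distance events (defecation at the feeding
#' tree) are retained — a dispersal event is defined by defecation content,
#' not by a minimum distance — but counted in the `n_zero` attribute.
#'
#' @param events Data frame with columns `feed_x`, `feed_y`, `dep_x`, `dep_y`
#'   (and optionally `source_id`), e.g. from [generate_dispersal_events()].
#' @param species Species label for the resulting sample.
#' @return A [distance_sample()] with method `"OSD"`; attributes `n_skipped`
#'   (events missing locations) and `n_zero` (zero-distance events).
#' @export
estimate_osd <- function(events, species = "unknown") {
  need <- c("feed_x", "feed_y", "dep_x", "dep_y")
  if (!all(need %in% names(events))) {
    stop("estimate_osd(): events need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ok <- stats::complete.cases(events[need])
  if (any(!ok)) {
    warning(sum(!ok), " event(s) missing a location were skipped", call. = FALSE)
  }
  ev <- events[ok, , drop = FALSE]
  d <- euclidean_distance(cbind(ev$feed_x, ev$feed_y), cbind(ev$dep_x, ev$dep_y))
  out <- distance_sample("OSD", species, d)
  attr(out, "n_skipped") <- sum(!ok)
  attr(out, "n_zero") <- sum(d == 0)
  out
}

#' Maternity assignment by exact seed-coat genotype matching (GSC)
#'
#' The seed coat is maternal tissue, so an exact multilocus match between a
#' seed-coat genotype and an adult genotype identifies the mother. An adult
#' matches when there are zero mismatching loci over at least `min_loci`
#' compared loci (loci missing in either genotype are ignored). A seed coat
#' is assigned only when exactly one adult matches; zero or multiple matches
#' leave it unassigned with the reason recorded — ties are never broken by
#' distance.
#'
#' @param seed_coats [genotype_set()] of seed-coat genotypes.
#' @param adults [genotype_set()] of adult genotypes (same locus panel).
#' @param adult_locs Data frame `id,x,y` (and optionally more) for adults.
#' @param seed_locs Data frame `id,x,y` for seed deposition points; ids must
#'   match `seed_coats$ids`.
#' @param min_loci Minimum number of compared loci for a valid match
#'   (default 5, mirroring the parentage minimum-typed-loci thresholds).
#' @param species Species label.
#' @return List with `assignments` (data frame `seed_id,mother_id,status,
#'   n_matches,n_loci_compared,distance_m`) and `sample` (a
#'   [distance_sample()] with method `"GSC"` built from unique matches only).
#' @export
match_seed_coats <- function(seed_coats, adults, adult_locs, seed_locs,
                             min_loci = 5L, species = "unknown") {
  stopifnot(inherits(seed_coats, "genotype_set"), inherits(adults, "genotype_set"))
  if (!length(adults$ids)) stop("no adult genotypes supplied", call. = FALSE)
  check_shared_loci(seed_coats, adults)
  n_c <- length(seed_coats$ids)
  A1 <- adults$a1; A2 <- adults$a2
  typedA <- A1 > 0L
  res <- data.frame(
    seed_id = seed_coats$ids,
    mother_id = NA_character_,
    status = NA_character_,
    n_matches = 0L,
    n_loci_compared = NA_integer_,
    distance_m = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_c)) {
    c1 <- seed_coats$a1[i, ]; c2 <- seed_coats$a2[i, ]
    typed <- c1 > 0L
    both <- typedA & rep(typed, each = nrow(A1))
    dim(both) <- dim(A1)
    mism <- both & (A1 != rep(c1, each = nrow(A1)) | A2 != rep(c2, each = nrow(A1)))
    n_comp <- rowSums(both)
    n_mism <- rowSums(mism)
    hits <- which(n_mism == 0L & n_comp >= min_loci)
    res$n_matches[i] <- length(hits)
    if (length(hits) == 1L) {
      res$mother_id[i] <- adults$ids[hits]
      res$status[i] <- "assigned"
      res$n_loci_compared[i] <- n_comp[hits]
    } else if (length(hits) == 0L) {
      res$status[i] <- "no match"
      res$n_loci_compared[i] <- max(n_comp)
    } else {
      res$status[i] <- sprintf("ambiguous (%d matches)", length(hits))
      res$n_loci_compared[i] <- min(n_comp[hits])
    }
  }
  ok <- res$status == "assigned"
  if (any(ok)) {
    mi <- match(res$mother_id[ok], adult_locs$id)
    si <- match(res$seed_id[ok], seed_locs$id)
    if (anyNA(mi) || anyNA(si)) {
      stop("assigned ids missing from location tables", call. = FALSE)
    }
    res$distance_m[ok] <- euclidean_distance(
      cbind(adult_locs$x[mi], adult_locs$y[mi]),
      cbind(seed_locs$x[si], seed_locs$y[si]))
  }
  list(assignments = res,
       sample = distance_sample("GSC", species, res$distance_m[ok]))
}

#' Expected number of chance full-genotype matches
#'
#' For an unrelated adult drawn from Hardy-Weinberg proportions, the
#' probability of matching a given multilocus genotype exactly is the product
#' over loci of the HW probability of that genotype; summing over adults
#' gives the expected number of false matches per seed coat. Useful for
#' checking that exact matching identifies mothers essentially uniquely.
#'
#' @param g Single-sample [genotype_set()] (the seed-coat genotype).
#' @param freqs Allele frequencies as from [allele_frequencies()].
#' @param n_adults Number of unrelated adults screened.
#' @param i Row index into `g`.
#' @return Expected number of chance matches (numeric).
#' @export
expected_false_matches <- function(g, freqs, n_adults, i = 1L) {
  p <- 1
  for (l in seq_along(g$loci)) {
    a <- g$a1[i, l]; b <- g$a2[i, l]
    if (a == 0L) next
    f <- freqs[[g$loci[l]]]
    pa <- unname(f[as.character(a)]); pb <- unname(f[as.character(b)])
    if (is.na(pa) || is.na(pb)) return(0)
    p <- p * if (a == b) pa^2 else 2 * pa * pb
  }
  n_adults * p
}
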