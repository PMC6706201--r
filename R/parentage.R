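#' Parentage-analysis configuration
#'
#' Settings for the likelihood-based parentage analysis of seedlings and
#' saplings: LOD scoring, the simulation that calibrates the strict
#' confidence threshold on the delta statistic, and the distance filter that
#' removes likely pollen-driven parent-offspring pairs.
#'
#' @param n_candidates Number of candidate parents in the confidence
#'   simulation (33 for the sparse canopy-tree system, 194 for the dense
#'   understory system).
#' @param proportion_sampled Probability that the true parent is among the
#'   candidates (0.99 when the adult inventory is complete, 0.15 when ~15%
#'   of the home range was sampled).
#' @param genotyping_error Per-locus probability `e` that an observed call is
#'   replaced by a random Hardy-Weinberg draw (default 0.01).
#' @param min_typed_loci Minimum typed loci for an offspring to enter the
#'   analysis (6 or 5 in the two systems).
#' @param confidence_level Strict confidence level for assignment (0.95).
#' @param n_confidence_sims Offspring simulated when calibrating the delta
#'   threshold (default 10,000).
#' @param max_distance_m Parent-offspring pairs farther apart than this are
#'   excluded from the distance sample (default 700 m, the tamarin home-range
#'   diameter; the boundary value is kept).
#' @param max_parents 1 or 2 parents assignable per offspring (default 2:
#'   with nuclear markers alone either assigned parent may be the mother, so
#'   both enter the distance pooling).
#' @return A validated list of class `parentage_config`.
#' @export
parentage_config <- function(n_candidates = 33L,
                             proportion_sampled = 0.99,
                             genotyping_error = 0.01,
                             min_typed_loci = 5L,
                             confidence_level = 0.95,
                             n_confidence_sims = 10000L,
                             max_distance_m = 700,
                             max_parents = 2L) {
  stopifnot(proportion_sampled > 0, proportion_sampled <= 1,
            genotyping_error >= 0, genotyping_error < 1,
            min_typed_loci >= 1, confidence_level > 0, confidence_level < 1,
            n_confidence_sims >= 100, max_distance_m > 0,
            max_parents %in% c(1L, 2L))
  structure(list(n_candidates = as.integer(n_candidates),
                 proportion_sampled = proportion_sampled,
                 genotyping_error = genotyping_error,
                 min_typed_loci = as.integer(min_typed_loci),
                 confidence_level = confidence_level,
                 n_confidence_sims = as.integer(n_confidence_sims),
                 max_distance_m = max_distance_m,
                 max_parents = as.integer(max_parents)),
            class = "parentage_config")
}

# frequency lookup with a small floor for alleles absent from the reference
# table (e.g. a mutation or an immigrant allele); keeps likelihoods finite
freq_lookup <- function(f, alleles, floor = 1e-4) {
  p <- unname(f[as.character(alleles)])
  p[is.na(p)] <- floor
  p
}

# Vectorised per-candidate LOD of one offspring against many candidates.
# off_a1/off_a2: length-L integer vectors; cand_a1/cand_a2: n x L matrices.
# Returns list(lod = numeric n, n_loci = integer n shared typed loci).
lod_against_candidates <- function(off_a1, off_a2, cand_a1, cand_a2, freqs, e) {
  n <- nrow(cand_a1)
  lod <- numeric(n)
  nl <- integer(n)
  for (l in seq_along(freqs)) {
    a <- off_a1[l]; b <- off_a2[l]
    if (a == 0L) next
    f <- freqs[[l]]
    pa <- freq_lookup(f, a); pb <- freq_lookup(f, b)
    Po <- if (a == b) pa * pa else 2 * pa * pb
    c1 <- cand_a1[, l]; c2 <- cand_a2[, l]
    typed <- c1 > 0L
    if (a == b) {
      M1 <- (c1 == a) * pa
      M2 <- (c2 == a) * pa
    } else {
      M1 <- (c1 == a) * pb + (c1 == b) * pa
      M2 <- (c2 == a) * pb + (c2 == b) * pa
    }
    Tt <- 0.5 * (M1 + M2)
    contrib <- log(((1 - e) * Tt + e * Po) / Po)
    lod <- lod + ifelse(typed, contrib, 0)
    nl <- nl + typed
  }
  list(lod = lod, n_loci = nl)
}

#' Single-parent LOD score
#'
#' Log-likelihood ratio (natural log) that a candidate is a parent of the
#' offspring versus an unrelated Hardy-Weinberg individual, summed over loci:
#' `LOD = sum_l ln[((1 - e) T(g_o | g_c) + e P(g_o)) / P(g_o)]`, where `T` is
#' the single-parent Mendelian transition probability (the other parent drawn
#' from HW proportions), `P` the HW genotype probability, and `e` the
#' genotyping-error rate (observed call replaced by a random HW draw with
#' probability `e`). Loci missing in either genotype are skipped. With
#' `e = 0`, a Mendelian-incompatible locus gives `-Inf` (exclusion).
#'
#' @param offspring,candidate Single-sample [genotype_set()]s (or use
#'   `i`/`j` row indices).
#' @param freqs Allele frequencies as from [allele_frequencies()].
#' @param e Genotyping-error rate.
#' @param i,j Row indices (default 1).
#' @return Named list: `lod` and `n_loci` (shared typed loci). `lod` is `NA`
#'   when no locus could be compared.
#' @export
single_parent_lod <- function(offspring, candidate, freqs, e = 0.01,
                              i = 1L, j = 1L) {
  check_shared_loci(offspring, candidate)
  r <- lod_against_candidates(offspring$a1[i, ], offspring$a2[i, ],
                              candidate$a1[j, , drop = FALSE],
                              candidate$a2[j, , drop = FALSE],
                              freqs[offspring$loci], e)
  if (r$n_loci[1] == 0L) {
    warning("no shared typed loci: LOD undefined", call. = FALSE)
    return(list(lod = NA_real_, n_loci = 0L))
  }
  list(lod = r$lod[1], n_loci = r$n_loci[1])
}

#' Simulation-derived critical delta at strict confidence
#'
#' Calibrates the assignment threshold on the delta statistic (LOD of the
#' best candidate minus LOD of the second best) by simulating offspring from
#' random Hardy-Weinberg parents: each simulated candidate set of size
#' `n_candidates` contains the true parent with probability
#' `proportion_sampled` and unrelated HW individuals otherwise; genotyping
#' error `e` is applied to all observed genotypes. The threshold is the
#' smallest delta such that, among simulated top candidates with delta at or
#' above it, at least `confidence_level` are the true parent.
#'
#' @param freqs Allele frequencies as from [allele_frequencies()].
#' @param cfg A [parentage_config()].
#' @param seed Integer seed; identical seed gives an identical threshold.
#' @return List of class `critical_delta`: `threshold`, `confidence_level`,
#'   `n_sims`, `accuracy_at_threshold`, `prop_assignable` (share of simulated
#'   offspring whose delta clears the threshold).
#' @export
critical_delta <- function(freqs, cfg, seed = 1L) {
  stopifnot(inherits(cfg, "parentage_config"))
  set.seed(as.integer(seed))
  e <- cfg$genotyping_error
  n_cand <- cfg$n_candidates
  n_sims <- cfg$n_confidence_sims
  L <- length(freqs)
  codes <- lapply(freqs, function(f) as.integer(names(f)))
  chunk <- max(1L, min(n_sims, as.integer(2e6 / n_cand)))
  deltas <- numeric(0)
  correct <- logical(0)
  done <- 0L
  while (done < n_sims) {
    m <- min(chunk, n_sims - done)
    done <- done + m
    nc <- m * n_cand
    # per-locus allele matrices
    lodm <- matrix(0, m, n_cand)
    incl <- stats::runif(m) < cfg$proportion_sampled
    for (l in seq_len(L)) {
      f <- freqs[[l]]; cd <- codes[[l]]
      mo1 <- sample(cd, m, TRUE, f); mo2 <- sample(cd, m, TRUE, f)
      fa1 <- sample(cd, m, TRUE, f); fa2 <- sample(cd, m, TRUE, f)
      o1 <- ifelse(stats::runif(m) < 0.5, mo1, mo2)
      o2 <- ifelse(stats::runif(m) < 0.5, fa1, fa2)
      # observation error on the offspring
      if (e > 0) {
        err <- stats::runif(m) < e
        k <- sum(err)
        if (k) { o1[err] <- sample(cd, k, TRUE, f); o2[err] <- sample(cd, k, TRUE, f) }
      }
      # candidates: column 1 is the true parent (mother) where included
      C1 <- matrix(sample(cd, nc, TRUE, f), m, n_cand)
      C2 <- matrix(sample(cd, nc, TRUE, f), m, n_cand)
      C1[incl, 1L] <- mo1[incl]
      C2[incl, 1L] <- mo2[incl]
      if (e > 0) {
        err <- stats::runif(nc) < e
        k <- sum(err)
        if (k) { C1[err] <- sample(cd, k, TRUE, f); C2[err] <- sample(cd, k, TRUE, f) }
      }
      # unordered offspring pair
      a <- pmin(o1, o2); b <- pmax(o1, o2)
      pa <- freq_lookup(f, a); pb <- freq_lookup(f, b)
      hom <- a == b
      Po <- ifelse(hom, pa * pa, 2 * pa * pb)
      M1 <- (C1 == a) * ifelse(hom, pa, pb) + (!hom) * (C1 == b) * pa
      M2 <- (C2 == a) * ifelse(hom, pa, pb) + (!hom) * (C2 == b) * pa
      Tt <- 0.5 * (M1 + M2)
      lodm <- lodm + log(((1 - e) * Tt + e * Po) / Po)
    }
    best <- max.col(lodm, ties.method = "first")
    best_lod <- lodm[cbind(seq_len(m), best)]
    lodm[cbind(seq_len(m), best)] <- -Inf
    second_lod <- lodm[cbind(seq_len(m), max.col(lodm, ties.method = "first"))]
    ok <- is.finite(best_lod)
    deltas <- c(deltas, (best_lod - second_lod)[ok])
    correct <- c(correct, (best == 1L & incl)[ok])
  }
  if (!length(deltas)) stop("no assignable simulated offspring", call. = FALSE)
  ord <- order(deltas, decreasing = TRUE)
  cum_acc <- cumsum(correct[ord]) / seq_along(ord)
  eligible <- which(cum_acc >= cfg$confidence_level)
  if (!length(eligible)) {
    warning(sprintf(
      "no delta threshold reaches %.0f%% confidence (best achievable %.1f%%); using the maximum simulated delta",
      100 * cfg$confidence_level, 100 * max(cum_acc)), call. = FALSE)
    k <- 1L
  } else {
    k <- max(eligible)
  }
  structure(list(threshold = deltas[ord][k],
                 confidence_level = cfg$confidence_level,
                 n_sims = n_sims,
                 accuracy_at_threshold = cum_acc[k],
                 prop_assignable = k / n_sims),
            class = "critical_delta")
}

#' @export
print.critical_delta <- function(x, ...) {
  cat(sprintf(
    "<critical_delta> threshold = %.3f at %.0f%% confidence (%d sims; %.1f%% accurate, %.1f%% assignable)\n",
    x$threshold, 100 * x$confidence_level, x$n_sims,
    100 * x$accuracy_at_threshold, 100 * x$prop_assignable))
  invisible(x)
}

#' Assign parents to offspring by LOD and the delta criterion
#'
#' For each offspring with at least `min_typed_loci` typed loci, candidates
#' are ranked by LOD. The top candidate is assigned when its delta (LOD lead
#' over the second best) meets the critical threshold; when `max_parents = 2`
#' the second candidate is then assessed against the field excluding the
#' best (its delta is its lead over the third), so that both potential
#' parents of an offspring can be recovered — with nuclear markers alone
#' either one may be the mother. Candidates with `-Inf` LOD (Mendelian
#' exclusion at `e = 0`) are never assigned.
#'
#' @param offspring [genotype_set()] of seedlings/saplings.
#' @param candidates [genotype_set()] of candidate parents.
#' @param freqs Allele frequencies (from the adult reference sample).
#' @param cfg A [parentage_config()].
#' @param delta Either a [critical_delta()] object or a numeric threshold.
#' @return Data frame `offspring_id,parent_id,rank,lod,delta,confident` with
#'   one row per assigned parent (0-2 per offspring); attribute
#'   `n_excluded_few_loci` counts offspring dropped by the typed-loci filter.
#' @export
assign_parentage <- function(offspring, candidates, freqs, cfg, delta) {
  stopifnot(inherits(cfg, "parentage_config"))
  check_shared_loci(offspring, candidates)
  thr <- if (inherits(delta, "critical_delta")) delta$threshold else as.numeric(delta)
  typed_ok <- n_typed_loci(offspring) >= cfg$min_typed_loci
  rows <- list()
  for (i in which(typed_ok)) {
    r <- lod_against_candidates(offspring$a1[i, ], offspring$a2[i, ],
                                candidates$a1, candidates$a2,
                                freqs[offspring$loci], cfg$genotyping_error)
    lods <- r$lod
    lods[r$n_loci < 1L] <- -Inf
    ord <- order(lods, decreasing = TRUE)
    l1 <- lods[ord[1]]
    l2 <- if (length(lods) >= 2L) lods[ord[2]] else -Inf
    if (is.finite(l1) && (l1 - l2) >= thr) {
      rows[[length(rows) + 1L]] <- data.frame(
        offspring_id = offspring$ids[i], parent_id = candidates$ids[ord[1]],
        rank = 1L, lod = l1, delta = l1 - l2, confident = TRUE,
        stringsAsFactors = FALSE)
      if (cfg$max_parents == 2L && length(lods) >= 3L) {
        l3 <- lods[ord[3]]
        if (is.finite(l2) && (l2 - l3) >= thr) {
          rows[[length(rows) + 1L]] <- data.frame(
            offspring_id = offspring$ids[i], parent_id = candidates$ids[ord[2]],
            rank = 2L, lod = l2, delta = l2 - l3, confident = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offspring_id = character(0), parent_id = character(0),
               rank = integer(0), lod = numeric(0), delta = numeric(0),
               confident = logical(0), stringsAsFactors = FALSE)
  attr(out, "n_excluded_few_loci") <- sum(!typed_ok)
  out
}

#' Distance sample from parentage assignments (PAS)
#'
#' One Euclidean distance per assigned parent-offspring pair (up to two per
#' offspring, both treated as potential maternal sources), then truncated at
#' `cfg$max_distance_m`: pairs farther apart than a disperser home-range
#' diameter are most likely linked by pollen rather than seed movement.
#'
#' @param assignments Output of [assign_parentage()].
#' @param offspring_locs Data frame `id,x,y` for offspring.
#' @param adult_locs Data frame `id,x,y` for candidate parents.
#' @param cfg A [parentage_config()].
#' @param species Species label.
#' @return A [distance_sample()] with method `"PAS"`; attribute
#'   `n_excluded_distance` counts pairs removed by the distance filter.
#' @export
estimate_pas <- function(assignments, offspring_locs, adult_locs, cfg,
                         species = "unknown") {
  stopifnot(inherits(cfg, "parentage_config"))
  if (!nrow(assignments)) {
    stop("estimate_pas(): no parentage assignments to measure", call. = FALSE)
  }
  oi <- match(assignments$offspring_id, offspring_locs$id)
  pi <- match(assignments$parent_id, adult_locs$id)
  if (anyNA(oi) || anyNA(pi)) stop("assignment ids missing from location tables",
                                   call. = FALSE)
  rec <- dispersal_records(assignments$parent_id,
                           cbind(x = adult_locs$x[pi], y = adult_locs$y[pi]),
                           cbind(x = offspring_locs$x[oi], y = offspring_locs$y[oi]),
                           method = "PAS", species = species)
  kept <- filter_max_distance(rec, cfg$max_distance_m)
  out <- distance_sample("PAS", species, kept$distance_m)
  attr(out, "n_excluded_distance") <- attr(kept, "n_removed")
  out
}
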