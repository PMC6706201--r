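#' Planar Euclidean distance between locations
#'
#' All coordinates in this package are planar metres (UTM-like easting /
#' northing); distances are straight-line (Euclidean) distances in the plane,
#' the universal definition of seed dispersal distance used throughout.
#' No geodesy is performed.
#'
#' @param a,b Either numeric vectors `c(x, y)` or data frames / matrices with
#'   columns `x` and `y`. When both have more than one row they are matched
#'   row-wise (recycling a single row against many is allowed).
#' @return Numeric vector of distances in metres.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(a, b) {
  a <- as_xy(a)
  b <- as_xy(b)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("euclidean_distance(): coordinates must be finite", call. = FALSE)
  }
  na <- nrow(a)
  nb <- nrow(b)
  if (na != nb) {
    if (na == 1L) a <- a[rep(1L, nb), , drop = FALSE]
    else if (nb == 1L) b <- b[rep(1L, na), , drop = FALSE]
    else stop("euclidean_distance(): incompatible numbers of points", call. = FALSE)
  }
  sqrt((a[, 1L] - b[, 1L])^2 + (a[, 2L] - b[, 2L])^2)
}

# coerce locations to a 2-column matrix (x, y)
as_xy <- function(p) {
  if (is.numeric(p) && is.null(dim(p))) {
    if (length(p) != 2L) stop("a location must be a length-2 (x, y) vector", call. = FALSE)
    return(matrix(as.numeric(p), 1L, 2L))
  }
  if (is.data.frame(p)) {
    if (!all(c("x", "y") %in% names(p))) {
      stop("location tables need 'x' and 'y' columns", call. = FALSE)
    }
    return(cbind(as.numeric(p$x), as.numeric(p$y)))
  }
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("location matrices need exactly 2 columns", call. = FALSE)
    return(p)
  }
  stop("cannot interpret locations of class ", paste(class(p), collapse = "/"),
       call. = FALSE)
}

#' Build a table of dispersal records
#'
#' A dispersal record pairs a seed source (usually an adult tree) with a
#' deposition location; its Euclidean length is one seed dispersal distance
#' (SDD) observation. The `distance_m` column is always recomputed from the
#' coordinates so that the cached value is consistent by construction.
#'
#' @param source_id Character vector of source identifiers (`NA` if unknown).
#' @param source Source locations (data frame/matrix with `x`, `y` or one
#'   `c(x, y)` point).
#' @param deposition Deposition locations, same formats.
#' @param method One of `"OSD"`, `"GSC"`, `"PAS"`, `"CMG"`, `"IBM"`.
#' @param species Species label attached to every record.
#' @return A data frame with columns `method`, `species`, `source_id`,
#'   `source_x`, `source_y`, `dep_x`, `dep_y`, `distance_m`.
#' @export
dispersal_records <- function(source_id, source, deposition, method, species = "unknown") {
  method <- match.arg(method, c("OSD", "GSC", "PAS", "CMG", "IBM"))
  s <- as_xy(source)
  d <- as_xy(deposition)
  n <- max(nrow(s), nrow(d))
  out <- data.frame(
    method = rep(method, n),
    species = rep(species, n),
    source_id = as.character(source_id),
    source_x = rep(s[, 1L], length.out = n),
    source_y = rep(s[, 2L], length.out = n),
    dep_x = rep(d[, 1L], length.out = n),
    dep_y = rep(d[, 2L], length.out = n),
    stringsAsFactors = FALSE
  )
  out$distance_m <- euclidean_distance(cbind(out$source_x, out$source_y),
                                       cbind(out$dep_x, out$dep_y))
  out
}

#' Filter dispersal records by a maximum plausible distance
#'
#' Parent-offspring pairs separated by more than the diameter of a disperser
#' home range are most likely the signature of pollen rather than seed
#' movement, so parentage-based distance samples are truncated at a maximum
#' distance (700 m by default for tamarin home ranges). "Beyond" is read as
#' strictly greater: a record at exactly `max_m` is kept.
#'
#' @param records A data frame with a `distance_m` column (as produced by
#'   [dispersal_records()]).
#' @param max_m Maximum distance in metres retained (default 700).
#' @return The kept records, with an attribute `n_removed` giving the number
#'   of records excluded.
#' @export
filter_max_distance <- function(records, max_m = 700) {
  stopifnot(is.data.frame(records), "distance_m" %in% names(records),
            is.numeric(max_m), length(max_m) == 1L, max_m >= 0)
  keep <- records$distance_m <= max_m
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Construct a per-method sample of dispersal distances
#'
#' @param method Method tag (`"OSD"`, `"GSC"`, `"PAS"`, `"CMG"`, `"IBM"`).
#' @param species Species label.
#' @param values Numeric vector of distances in metres (all `>= 0`).
#' @return An object of class `distance_sample`.
#' @export
distance_sample <- function(method, species, values) {
  method <- match.arg(method, c("OSD", "GSC", "PAS", "CMG", "IBM"))
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) {
    stop("distance_sample(): values must be non-negative and non-missing", call. = FALSE)
  }
  structure(list(method = method, species = species, values = values),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("<distance_sample> %s / %s: n = %d, mean = %.1f m, median = %.1f m\n",
              x$method, x$species, length(x$values),
              if (length(x$values)) mean(x$values) else NA_real_,
              if (length(x$values)) stats::median(x$values) else NA_real_))
  invisible(x)
}

#' @export
length.distance_sample <- function(x) length(x$values)
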