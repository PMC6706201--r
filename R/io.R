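#' Read and write plant location tables
#'
#' Location tables are plain CSV with header `id,role,species,x,y`; `x`/`y`
#' are planar metres (UTM-like), dot decimal, UTF-8. Roles are one of
#' `adult`, `seedling`, `sapling`, `seed`, `seed_coat`.
#'
#' @param path File path.
#' @return `read_locations()`: a data frame with the five columns above.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("id", "role", "species", "x", "y")
  if (!all(need %in% names(df))) {
    stop("locations CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  if (anyDuplicated(df$id)) stop("duplicate ids in locations CSV", call. = FALSE)
  bad <- setdiff(unique(df$role), c("adult", "seedling", "sapling", "seed", "seed_coat"))
  if (length(bad)) stop("unknown roles in locations CSV: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("non-finite coordinates in locations CSV", call. = FALSE)
  }
  df
}

#' @rdname read_locations
#' @param locs Data frame with columns `id,role,species,x,y`.
#' @export
write_locations <- function(locs, path) {
  utils::write.csv(locs[c("id", "role", "species", "x", "y")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write genotypes in GenAlex-dialect CSV
#'
#' Two columns per locus, named `<locus>_1` and `<locus>_2`, preceded by a
#' `sample_id` column; allele code 0 marks missing data.
#'
#' @param path File path.
#' @return `read_genotypes()`: a [genotype_set()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (names(df)[1] != "sample_id") stop("first column must be sample_id", call. = FALSE)
  cols <- names(df)[-1]
  l1 <- grep("_1$", cols, value = TRUE)
  loci <- sub("_1$", "", l1)
  if (!length(loci) || !all(paste0(loci, "_2") %in% cols)) {
    stop("genotypes CSV needs paired <locus>_1/<locus>_2 columns", call. = FALSE)
  }
  a1 <- as.matrix(df[paste0(loci, "_1")])
  a2 <- as.matrix(df[paste0(loci, "_2")])
  genotype_set(df$sample_id, loci, a1, a2)
}

#' @rdname read_genotypes
#' @param g A [genotype_set()].
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_set"))
  out <- data.frame(sample_id = g$ids, stringsAsFactors = FALSE)
  for (l in seq_along(g$loci)) {
    out[[paste0(g$loci[l], "_1")]] <- g$a1[, l]
    out[[paste0(g$loci[l], "_2")]] <- g$a2[, l]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write movement tracks
#'
#' Tracks CSV: `day,scan_index,minutes_since_start,x,y`, one row per scan
#' point, timestamps strictly increasing within a day.
#'
#' @param path File path.
#' @return `read_tracks()`: a data frame with the five columns above.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "scan_index", "minutes_since_start", "x", "y")
  if (!all(need %in% names(df))) {
    stop("tracks CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' @rdname read_tracks
#' @param tracks Data frame of scan points.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[c("day", "scan_index", "minutes_since_start", "x", "y")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write dispersal-record tables
#'
#' Distances CSV: `method,species,source_id,source_x,source_y,dep_x,dep_y,distance_m`.
#'
#' @param path File path.
#' @return `read_distances()`: a data frame of dispersal records.
#' @export
read_distances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("method", "species", "source_id", "source_x", "source_y",
            "dep_x", "dep_y", "distance_m")
  if (!all(need %in% names(df))) {
    stop("distances CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' @rdname read_distances
#' @param records Data frame as produced by [dispersal_records()].
#' @export
write_distances <- function(records, path) {
  utils::write.csv(records[c("method", "species", "source_id", "source_x",
                             "source_y", "dep_x", "dep_y", "distance_m")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write ground-truth parentage tables
#'
#' Truth CSV: `offspring_id,mother_id,father_id,true_distance_m`.
#'
#' @param path File path.
#' @return `read_truth()`: a data frame with the four columns above.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("offspring_id", "mother_id", "father_id", "true_distance_m")
  if (!all(need %in% names(df))) {
    stop("truth CSV needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' @rdname read_truth
#' @param truth Data frame with truth columns.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth[c("offspring_id", "mother_id", "father_id", "true_distance_m")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
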