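#' Construct a genotype table
#'
#' The central container: a plants-by-markers dosage matrix together with
#' per-sample metadata. Dosage counts copies of \code{allele_b} of the
#' marker map: 0 and 2 are the two homozygotes, 1 is the heterozygote, and
#' \code{NA} is a missing call.
#'
#' @param calls integer matrix (samples x markers), values 0/1/2/NA. Column
#'   order must match the marker map (columns are reordered by name when
#'   marker ids are given as colnames).
#' @param samples data.frame with columns \code{sample_id}, \code{stand_id},
#'   \code{year} and optionally \code{transect_index} (integer >= 0 order of
#'   collection along a transect, NA when unknown).
#' @param map a \code{\link{marker_map}}.
#' @return An object of class \code{genotype_table}: a list with elements
#'   \code{samples}, \code{calls}, \code{map}.
#' @export
genotype_table <- function(calls, samples, map) {
  stopifnot(inherits(map, "marker_map"))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!is.null(colnames(calls))) {
    if (!setequal(colnames(calls), map$marker_id)) {
      bad <- setdiff(colnames(calls), map$marker_id)
      if (length(bad)) stop("unknown marker column(s): ", paste(utils::head(bad, 5), collapse = ", "))
      stop("call matrix is missing markers present in the map")
    }
    calls <- calls[, map$marker_id, drop = FALSE]
  } else {
    if (ncol(calls) != nrow(map)) stop("call matrix width does not match marker map")
    colnames(calls) <- map$marker_id
  }
  bad <- which(!(calls %in% c(0L, 1L, 2L) | is.na(calls)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(calls)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(calls)) + 1L
    stop(
      "invalid dosage value ", calls[bad[1]], " for sample '",
      samples$sample_id[i], "' at marker '", colnames(calls)[j],
      "' (must be 0, 1, 2 or NA)"
    )
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "stand_id", "year")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
  if (!"transect_index" %in% names(samples)) samples$transect_index <- NA_integer_
  samples <- samples[, c("sample_id", "stand_id", "year", "transect_index")]
  samples$sample_id <- as.character(samples$sample_id)
  samples$stand_id <- as.character(samples$stand_id)
  samples$year <- as.integer(samples$year)
  samples$transect_index <- as.integer(samples$transect_index)
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (nrow(samples) != nrow(calls)) stop("sample metadata and call matrix disagree in length")
  rownames(calls) <- samples$sample_id
  rownames(samples) <- NULL
  structure(list(samples = samples, calls = calls, map = map),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(
    "genotype_table:", nrow(x$calls), "samples x", ncol(x$calls), "markers,",
    length(unique(x$samples$stand_id)), "stands,",
    sprintf("%.2f%% missing calls\n", 100 * mean(is.na(x$calls)))
  )
  invisible(x)
}

#' Number of samples / markers in a genotype table
#' @param table a \code{\link{genotype_table}}.
#' @return integer count.
#' @export
n_samples <- function(table) nrow(table$calls)

#' @rdname n_samples
#' @export
n_markers <- function(table) ncol(table$calls)

#' Read a genotype table from TSV
#'
#' The file must have a header with columns \code{sample_id},
#' \code{stand_id}, \code{year}, optionally \code{transect_index}, followed
#' by one column per marker id. Marker columns may appear in any order; they
#' are canonicalised to the map order. Dosages are 0/1/2, missing calls
#' \code{NA} (empty or "NA").
#'
#' @param path file path.
#' @param map a \code{\link{marker_map}}.
#' @return A \code{\link{genotype_table}}.
#' @export
read_genotype_table <- function(path, map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("sample_id", "stand_id", "year", "transect_index"), names(df))
  marker_cols <- setdiff(names(df), meta_cols)
  unknown <- setdiff(marker_cols, map$marker_id)
  if (length(unknown)) {
    stop("unknown marker column(s) in ", path, ": ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  absent <- setdiff(map$marker_id, marker_cols)
  if (length(absent)) {
    stop("genotype file lacks marker column(s): ", paste(utils::head(absent, 5), collapse = ", "))
  }
  calls <- as.matrix(df[, map$marker_id, drop = FALSE])
  raw <- df[, map$marker_id, drop = FALSE]
  ok <- vapply(raw, function(v) all(is.na(v) | v %in% c("0", "1", "2", 0L, 1L, 2L)), logical(1))
  if (!all(ok)) {
    j <- which(!ok)[1]
    v <- raw[[j]]
    i <- which(!(is.na(v) | v %in% c("0", "1", "2", 0L, 1L, 2L)))[1]
    stop(
      "invalid dosage value '", v[i], "' at row ", i, ", marker '",
      names(raw)[j], "' in ", path
    )
  }
  suppressWarnings(storage.mode(calls) <- "integer")
  genotype_table(calls, df[, meta_cols, drop = FALSE], map)
}

#' Write a genotype table to TSV
#' @param table a \code{\link{genotype_table}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  out <- cbind(table$samples, as.data.frame(table$calls, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a stand metadata table
#'
#' @param stand_id character vector of unique stand ids.
#' @param site_type "rural" or "urban" per stand.
#' @param x,y planar coordinates in meters (projected; Euclidean distances
#'   are used throughout).
#' @param capacity optional stand size class / carrying capacity.
#' @return data.frame of class \code{stand_table}.
#' @export
stand_table <- function(stand_id, site_type, x, y, capacity = NA_integer_) {
  stand_id <- as.character(stand_id)
  if (anyDuplicated(stand_id)) stop("stand ids must be unique")
  site_type <- as.character(site_type)
  if (!all(site_type %in% c("rural", "urban"))) {
    stop("site_type must be 'rural' or 'urban'")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("stand coordinates must be finite")
  df <- data.frame(
    stand_id = stand_id, site_type = site_type, x = x, y = y,
    capacity = rep_len(as.integer(capacity), length(stand_id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("stand_table", "data.frame")
  df
}

#' Read / write stand metadata (TSV: stand_id, site_type, x, y[, capacity])
#' @param path file path.
#' @return A \code{\link{stand_table}}.
#' @export
read_stand_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cap <- if ("capacity" %in% names(df)) df$capacity else NA_integer_
  stand_table(df$stand_id, df$site_type, df$x, df$y, cap)
}

#' @rdname read_stand_table
#' @param stands a \code{\link{stand_table}}.
#' @export
write_stand_table <- function(stands, path) {
  utils::write.table(as.data.frame(stands), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Subset a genotype table by sample or stand
#' @param table a \code{\link{genotype_table}}.
#' @param samples sample ids (or logical/integer index) to keep.
#' @param stands stand ids to keep (applied after \code{samples}).
#' @return A \code{\link{genotype_table}}.
#' @export
subset_table <- function(table, samples = NULL, stands = NULL) {
  keep <- rep(TRUE, n_samples(table))
  if (!is.null(samples)) {
    if (is.character(samples)) keep <- table$samples$sample_id %in% samples
    else { keep <- rep(FALSE, n_samples(table)); keep[samples] <- TRUE }
  }
  if (!is.null(stands)) keep <- keep & table$samples$stand_id %in% stands
  genotype_table(table$calls[keep, , drop = FALSE],
    table$samples[keep, , drop = FALSE], table$map)
}
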