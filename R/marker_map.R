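#' Construct a marker map
#'
#' A marker map defines the linear order of biallelic SNP markers along a
#' small genome (chromosomes numbered from 1). Marker order is canonical:
#' rows are sorted by chromosome, then base-pair position.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom integer chromosome index (1-based) per marker.
#' @param pos 1-based base-pair position per marker; must be strictly
#'   increasing within a chromosome (after sorting).
#' @param allele_a,allele_b single-base allele labels; dosage counts copies
#'   of \code{allele_b}.
#' @return A \code{data.frame} of class \code{marker_map} with columns
#'   \code{marker_id}, \code{chrom}, \code{pos}, \code{allele_a},
#'   \code{allele_b}, in canonical marker order.
#' @export
marker_map <- function(marker_id, chrom, pos, allele_a = "A", allele_b = "T") {
  marker_id <- as.character(marker_id)
  if (length(marker_id) < 1L) stop("a marker map needs at least one marker")
  if (anyDuplicated(marker_id)) stop("marker ids must be unique")
  chrom <- as.integer(chrom)
  pos <- as.integer(pos)
  if (anyNA(chrom) || anyNA(pos)) stop("chrom and pos must be non-missing integers")
  df <- data.frame(
    marker_id = marker_id, chrom = chrom, pos = pos,
    allele_a = rep_len(as.character(allele_a), length(marker_id)),
    allele_b = rep_len(as.character(allele_b), length(marker_id)),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Read a marker map from a TSV file
#'
#' Expected columns: \code{marker_id}, \code{chrom}, \code{pos},
#' \code{allele_a}, \code{allele_b}.
#'
#' @param path file path.
#' @return A \code{\link{marker_map}}.
#' @export
read_marker_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marker map file lacks columns: ", paste(miss, collapse = ", "))
  marker_map(df$marker_id, df$chrom, df$pos, df$allele_a, df$allele_b)
}

#' Write a marker map to TSV
#' @param map a \code{\link{marker_map}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
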