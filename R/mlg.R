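#' Identify multilocus genotypes (MLGs)
#'
#' Partitions samples into multilocus genotypes. Two samples carry the same
#' MLG when their call vectors are identical; with missing data, samples
#' whose call rates are both at least \code{min_call_rate} are merged when
#' they agree at every marker where both are called (wildcard rule), and
#' the partition is the transitive closure of this pairwise compatibility.
#' Samples below the call-rate threshold only join an MLG through exact
#' pattern equality.
#'
#' Canonical MLG calls are the per-marker majority over member samples
#' (ties resolved towards the smaller dosage); transitive closure can merge
#' samples that conflict at a marker one intermediate sample lacks, which
#' the majority rule resolves deterministically.
#'
#' @param table a \code{\link{genotype_table}}.
#' @param min_call_rate minimum fraction of called markers for a sample to
#'   participate in wildcard merging (default 0.95).
#' @return An object of class \code{mlg_table}: list with
#'   \code{assignment} (data.frame sample_id, stand_id, mlg_id),
#'   \code{mlg_calls} (canonical dosage matrix, one row per MLG),
#'   \code{n_mlg}, \code{n_fully_homozygous}, and \code{freq}
#'   (per-stand MLG counts).
#' @export
identify_mlgs <- function(table, min_call_rate = 0.95) {
  calls <- table$calls
  n <- nrow(calls)
  if (n < 1L) stop("need at least one sample")
  L <- ncol(calls)

  key <- apply(calls, 1L, function(r) paste(ifelse(is.na(r), "N", r), collapse = ""))
  pat_key <- unique(key)
  U <- length(pat_key)
  pat_idx <- match(key, pat_key)            # sample -> pattern
  first_of <- match(pat_key, key)           # pattern -> representative sample row
  P <- calls[first_of, , drop = FALSE]
  call_rate <- rowMeans(!is.na(P))
  has_na <- rowSums(is.na(P)) > 0L

  parent <- seq_len(U)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  eligible <- call_rate >= min_call_rate
  # only patterns with missing calls can merge with anything non-identical
  for (i in which(has_na & eligible)) {
    others <- setdiff(which(eligible), i)
    if (!length(others)) next
    Pi <- P[i, ]
    M <- P[others, , drop = FALSE]
    conf <- sweep(M, 2L, Pi, function(a, b) !is.na(a) & !is.na(b) & a != b)
    comp <- rowSums(conf) == 0L
    for (j in others[comp]) union_(i, j)
  }
  root <- vapply(seq_len(U), find, integer(1))
  comp_id <- match(root, unique(root))      # ordered by first pattern occurrence
  n_mlg <- max(comp_id)

  width <- max(3L, nchar(as.character(n_mlg)))
  mlg_ids <- sprintf(paste0("MLG%0", width, "d"), seq_len(n_mlg))
  sample_mlg <- mlg_ids[comp_id[pat_idx]]

  # canonical calls per MLG: per-marker majority over member samples
  mlg_calls <- matrix(NA_integer_, n_mlg, L, dimnames = list(mlg_ids, colnames(calls)))
  for (m in seq_len(n_mlg)) {
    rows <- calls[comp_id[pat_idx] == m, , drop = FALSE]
    if (nrow(rows) == 1L) { mlg_calls[m, ] <- rows[1L, ]; next }
    c0 <- colSums(rows == 0L, na.rm = TRUE)
    c1 <- colSums(rows == 1L, na.rm = TRUE)
    c2 <- colSums(rows == 2L, na.rm = TRUE)
    counts <- rbind(c0, c1, c2)
    any_called <- colSums(counts) > 0L
    win <- max.col(t(counts), ties.method = "first") - 1L  # smaller dosage wins ties
    mlg_calls[m, any_called] <- win[any_called]
  }

  assignment <- data.frame(
    sample_id = table$samples$sample_id,
    stand_id = table$samples$stand_id,
    mlg_id = sample_mlg,
    stringsAsFactors = FALSE
  )
  freq <- as.data.frame(table(stand_id = assignment$stand_id, mlg_id = assignment$mlg_id),
    stringsAsFactors = FALSE
  )
  freq <- freq[freq$Freq > 0L, ]
  names(freq)[3] <- "count"
  rownames(freq) <- NULL

  structure(list(
    assignment = assignment,
    mlg_calls = mlg_calls,
    n_mlg = n_mlg,
    n_fully_homozygous = sum(rowSums(mlg_calls == 1L, na.rm = TRUE) == 0L),
    freq = freq
  ), class = "mlg_table")
}

#' @export
print.mlg_table <- function(x, ...) {
  cat(
    "mlg_table:", nrow(x$assignment), "samples in", x$n_mlg, "MLGs (",
    x$n_fully_homozygous, "fully homozygous )\n"
  )
  invisible(x)
}

#' Per-stand census of samples, MLGs and heterozygous individuals
#'
#' A stand is monotypic when all its sampled plants carry a single MLG
#' (under the wildcard identity rule, so isolated missing calls do not
#' break monotypy). A heterozygous individual carries at least one
#' dosage-1 call.
#'
#' @param table a \code{\link{genotype_table}}.
#' @param mlgs optional precomputed \code{\link{identify_mlgs}} result.
#' @return data.frame: stand_id, n, n_mlg, monotypic, n_het.
#' @export
stand_census <- function(table, mlgs = NULL) {
  if (is.null(mlgs)) mlgs <- identify_mlgs(table)
  het <- rowSums(table$calls == 1L, na.rm = TRUE) > 0L
  st <- table$samples$stand_id
  ids <- unique(st)
  out <- data.frame(
    stand_id = ids,
    n = as.integer(tabulate(match(st, ids))),
    n_mlg = vapply(ids, function(s) length(unique(mlgs$assignment$mlg_id[st == s])), integer(1)),
    n_het = vapply(ids, function(s) sum(het[st == s]), integer(1)),
    stringsAsFactors = FALSE
  )
  out$monotypic <- out$n_mlg == 1L
  rownames(out) <- NULL
  out[, c("stand_id", "n", "n_mlg", "monotypic", "n_het")]
}

#' MLGs shared between stands
#'
#' Lists every unordered pair of stands that share an MLG, with the
#' Euclidean distance between the stands in kilometers.
#'
#' @param mlgs an \code{\link{identify_mlgs}} result.
#' @param stands a \code{\link{stand_table}} with coordinates in meters.
#' @return data.frame: mlg_id, stand_1, stand_2, distance_km.
#' @export
shared_mlgs_between_stands <- function(mlgs, stands) {
  a <- unique(mlgs$assignment[, c("mlg_id", "stand_id")])
  out <- list()
  for (m in unique(a$mlg_id)) {
    sts <- sort(a$stand_id[a$mlg_id == m])
    if (length(sts) < 2L) next
    pr <- utils::combn(sts, 2L)
    for (k in seq_len(ncol(pr))) {
      i <- match(pr[1, k], stands$stand_id)
      j <- match(pr[2, k], stands$stand_id)
      if (is.na(i) || is.na(j)) stop("stand coordinates missing for shared-MLG pair")
      d <- sqrt((stands$x[i] - stands$x[j])^2 + (stands$y[i] - stands$y[j])^2) / 1000
      out[[length(out) + 1L]] <- data.frame(
        mlg_id = m, stand_1 = pr[1, k], stand_2 = pr[2, k],
        distance_km = d, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      mlg_id = character(0), stand_1 = character(0),
      stand_2 = character(0), distance_km = numeric(0)
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
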