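#' Allele-sharing distance between two genotypes
#'
#' d = 1 - (mean over jointly called markers of shared-allele count / 2).
#' The shared-allele count between dosages d1, d2 is 2 - |d1 - d2|, so for
#' biallelic dosage data this distance equals the Gregorius distance
#' (\code{\link{dg_distance}}).
#'
#' @param g1,g2 dosage vectors on the same marker map.
#' @return distance in [0, 1].
#' @export
allele_sharing_distance <- function(g1, g2) dg_distance(g1, g2)

#' Pairwise allele-sharing distance matrix
#'
#' Computes the full symmetric matrix of allele-sharing distances between
#' rows of a dosage matrix, with pairwise deletion of missing calls.
#'
#' @param calls dosage matrix (individuals or MLGs x markers) or a
#'   \code{\link{genotype_table}}.
#' @return symmetric numeric matrix, zero diagonal, entries in [0, 1].
#' @export
genetic_distance_matrix <- function(calls) {
  if (inherits(calls, "genotype_table")) calls <- calls$calls
  X <- as.matrix(calls)
  n <- nrow(X)
  N <- (!is.na(X)) * 1
  joint <- N %*% t(N)
  if (any(joint[lower.tri(joint)] == 0)) {
    stop("some pair of genotypes has no jointly called marker")
  }
  I0 <- (!is.na(X) & X == 0L) * 1
  I1 <- (!is.na(X) & X == 1L) * 1
  I2 <- (!is.na(X) & X == 2L) * 1
  # sum over joint markers of |d1 - d2|
  num <- 2 * (I0 %*% t(I2) + I2 %*% t(I0)) +
    (I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1))
  D <- num / (2 * joint)
  diag(D) <- 0
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Non-redundant MLG representatives for clustering
#'
#' One representative call vector per MLG per (stand, year), mirroring
#' cladogram construction on non-redundant genotypes.
#'
#' @param table a \code{\link{genotype_table}}.
#' @param mlgs optional precomputed \code{\link{identify_mlgs}} result.
#' @return dosage matrix with rownames \code{stand.year.mlg}.
#' @export
nonredundant_mlgs <- function(table, mlgs = NULL) {
  if (is.null(mlgs)) mlgs <- identify_mlgs(table)
  key <- paste(table$samples$stand_id, table$samples$year,
    mlgs$assignment$mlg_id, sep = ".")
  first <- !duplicated(key)
  out <- table$calls[first, , drop = FALSE]
  rownames(out) <- key[first]
  out
}

#' Agglomerative clustering of genotypes
#'
#' Deterministic hierarchical clustering of a distance matrix; rows are
#' ordered by label before clustering so ties are broken by label order.
#'
#' @param dist_matrix symmetric distance matrix with labels.
#' @param method linkage passed to \code{\link[stats]{hclust}}
#'   (default "ward.D2"; use "average" to reproduce ultrametric inputs).
#' @return an \code{\link[stats]{hclust}} tree.
#' @export
cluster_genotypes <- function(dist_matrix, method = "ward.D2") {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) < 2L) stop("need at least 2 genotypes to cluster")
  if (is.null(rownames(dist_matrix))) {
    rownames(dist_matrix) <- colnames(dist_matrix) <- paste0("g", seq_len(nrow(dist_matrix)))
  }
  ord <- order(rownames(dist_matrix))
  dist_matrix <- dist_matrix[ord, ord]
  stats::hclust(stats::as.dist(dist_matrix), method = method)
}

#' Export a dendrogram as a Newick string or file
#'
#' @param hc an \code{\link[stats]{hclust}} tree.
#' @param path optional file path; when given the tree is written there.
#' @return the Newick string, invisibly when written to file.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# within-cluster dispersion W_k = sum_r (1/(2 n_r)) * sum_{i,j in r} d_ij
# (both orderings), from cutting a tree at k clusters. Indexing is by
# label: the tree reorders leaves relative to the matrix.
wk_dispersion <- function(D, hc, k) {
  cl <- stats::cutree(hc, k = k)
  w <- 0
  for (r in unique(cl)) {
    sel <- match(names(cl)[cl == r], rownames(D))
    if (length(sel) > 1L) w <- w + sum(D[sel, sel]) / (2 * length(sel))
  }
  w
}

#' Gap statistic for cluster-number selection
#'
#' Within-cluster dispersion W_k from the agglomerative tree cut at k,
#' compared with B reference datasets built by permuting each marker's
#' dosages independently across individuals (preserving marker allele
#' frequencies while destroying inter-marker association).
#' gap(k) = mean_b log W*_kb - log W_k; the chosen K is the smallest k
#' with gap(k) >= gap(k+1) - se(k+1).
#'
#' @param calls dosage matrix of non-redundant genotypes (rows).
#' @param k_max largest number of clusters considered (>= 2, < n).
#' @param B reference draws (default 100).
#' @param method linkage method (default "ward.D2").
#' @param seed optional RNG seed.
#' @return list of class \code{gap_result}: K_hat, per-k gap and se
#'   vectors, B, and log W curves.
#' @export
gap_statistic <- function(calls, k_max, B = 100, method = "ward.D2", seed = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (k_max < 2) stop("k_max must be >= 2")
  if (k_max > n - 1) stop("k_max must be at most n - 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("g%04d", seq_len(n))
  }
  D <- genetic_distance_matrix(calls)
  if (all(D[lower.tri(D)] == 0)) {
    return(structure(list(K_hat = 1L, gap = NULL, se = NULL, B = B,
      degenerate = TRUE), class = "gap_result"))
  }
  hc <- cluster_genotypes(D, method = method)
  logW <- vapply(seq_len(k_max), function(k) log(wk_dispersion(D, hc, k)), numeric(1))
  logWref <- matrix(NA_real_, B, k_max)
  for (b in seq_len(B)) {
    ref <- apply(calls, 2, function(col) col[sample.int(n)])
    rownames(ref) <- rownames(calls)
    Dref <- genetic_distance_matrix(ref)
    hcref <- cluster_genotypes(Dref, method = method)
    logWref[b, ] <- vapply(seq_len(k_max), function(k) log(wk_dispersion(Dref, hcref, k)), numeric(1))
  }
  gap <- colMeans(logWref) - logW
  se <- apply(logWref, 2, stats::sd) * sqrt(1 + 1 / B)
  K_hat <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (!is.na(gap[k]) && gap[k] >= gap[k + 1] - se[k + 1]) { K_hat <- k; break }
  }
  structure(list(K_hat = as.integer(K_hat), gap = gap, se = se, B = B,
    logW = logW, logW_ref_mean = colMeans(logWref), degenerate = FALSE),
    class = "gap_result")
}

#' Within- versus between-stand pairwise distance distributions
#'
#' Splits all pairwise genetic distances by whether the two genotypes come
#' from the same stand, and compares the two sets with a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param dist_matrix symmetric distance matrix on individual genotypes.
#' @param stand_ids stand label per row of the matrix.
#' @param exclude_zero also report the comparison with zero distances
#'   (identical genotypes) removed from the within set (default TRUE).
#' @return list of class \code{within_between}: within and between
#'   distance vectors, summary data.frame, p_value (NA when degenerate),
#'   n_zero_within, and optional p_value_nonzero.
#' @export
within_between_distributions <- function(dist_matrix, stand_ids, exclude_zero = TRUE) {
  D <- as.matrix(dist_matrix)
  n <- nrow(D)
  if (length(stand_ids) != n) stop("stand_ids must match the matrix")
  if (length(unique(stand_ids)) < 2L) {
    warning("only one stand: between-stand list is empty")
  }
  lt <- which(lower.tri(D), arr.ind = TRUE)
  v <- D[lower.tri(D)]
  same <- stand_ids[lt[, 1]] == stand_ids[lt[, 2]]
  within <- v[same]; between <- v[!same]
  degenerate <- length(within) == 0 || length(between) == 0 ||
    (stats::sd(v) == 0)
  p <- p_nz <- NA_real_
  if (!degenerate) {
    p <- suppressWarnings(stats::wilcox.test(within, between)$p.value)
    if (exclude_zero && any(within > 0)) {
      p_nz <- suppressWarnings(stats::wilcox.test(within[within > 0], between)$p.value)
    }
  }
  summary <- data.frame(
    set = c("within", "between"),
    n = c(length(within), length(between)),
    mean = c(mean(within), mean(between)),
    sd = c(stats::sd(within), stats::sd(between)),
    stringsAsFactors = FALSE
  )
  structure(list(
    within = within, between = between, summary = summary,
    n_zero_within = sum(within == 0), p_value = p,
    p_value_nonzero = p_nz, degenerate = degenerate
  ), class = "within_between")
}

#' Compare a per-stand statistic between site types
#'
#' Mann-Whitney (Wilcoxon rank-sum) comparison of a subsample-corrected
#' stand statistic (e.g. He or F_IS) between rural and urban stands, with
#' exact p-values for small groups (no ties) and the normal approximation
#' otherwise.
#'
#' @param values named numeric vector (names = stand ids) or data.frame
#'   with columns stand_id and the statistic in column \code{stat}.
#' @param site_type named character vector mapping stand ids to
#'   "rural"/"urban", or a \code{\link{stand_table}}.
#' @param stat column name when \code{values} is a data.frame.
#' @return list of class \code{group_comparison}: per-group summary
#'   data.frame, U statistic, two-sided p_value.
#' @export
compare_site_types <- function(values, site_type, stat = "F_IS") {
  if (is.data.frame(values)) {
    v <- values[[stat]]
    names(v) <- values$stand_id
  } else v <- values
  if (inherits(site_type, "stand_table") || is.data.frame(site_type)) {
    st <- site_type$site_type
    names(st) <- site_type$stand_id
  } else st <- site_type
  grp <- st[names(v)]
  if (anyNA(grp)) stop("site type missing for some stands")
  keep <- !is.na(v)
  v <- v[keep]; grp <- grp[keep]
  g1 <- v[grp == "rural"]; g2 <- v[grp == "urban"]
  if (length(g1) < 2L || length(g2) < 2L) stop("need at least 2 stands per group")
  if (stats::sd(c(g1, g2)) == 0) {
    # no variation at all: groups indistinguishable by construction
    wt <- list(statistic = c(W = length(g1) * length(g2) / 2), p.value = 1)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g1, g2))
  }
  qs <- function(x) c(mean = mean(x), median = stats::median(x),
    lo = unname(stats::quantile(x, 0.025)), hi = unname(stats::quantile(x, 0.975)))
  summary <- data.frame(
    group = c("rural", "urban"), n = c(length(g1), length(g2)),
    rbind(qs(g1), qs(g2)), stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(summary = summary, U = unname(wt$statistic),
    p_value = wt$p.value, statistic = stat), class = "group_comparison")
}
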