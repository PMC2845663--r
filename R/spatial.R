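#' Contiguous distance classes for correlograms
#'
#' @param n_classes number of classes.
#' @param class_width width of each class in kilometers.
#' @return object of class \code{distance_classes}: data.frame with
#'   \code{class}, \code{lower_km}, \code{upper_km}. Classes are
#'   half-open (lower, upper], starting at 0.
#' @export
distance_classes <- function(n_classes, class_width) {
  if (n_classes < 1 || class_width <= 0) stop("need n_classes >= 1 and class_width > 0")
  df <- data.frame(
    class = seq_len(n_classes),
    lower_km = (seq_len(n_classes) - 1) * class_width,
    upper_km = seq_len(n_classes) * class_width
  )
  class(df) <- c("distance_classes", "data.frame")
  df
}

#' Mantel test for matrix association
#'
#' Pearson correlation between the off-diagonal entries of two square
#' symmetric matrices, with significance from joint row/column
#' permutations of one matrix. The p-value is one-sided (upper):
#' p = (number of permutations with statistic >= observed + 1) /
#' (n_perms + 1).
#'
#' @param m1,m2 square symmetric matrices with matching dimensions
#'   (e.g. genetic and geographic distances on the same labels).
#' @param n_perms number of permutations (default 500).
#' @param seed optional RNG seed.
#' @return list of class \code{mantel_result}: statistic, p_value, n_perms.
#' @export
mantel_test <- function(m1, m2, n_perms = 500, seed = NULL) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  if (!all(dim(m1) == dim(m2)) || nrow(m1) != ncol(m1)) {
    stop("matrices must be square with matching dimensions")
  }
  if (!isTRUE(all.equal(m1, t(m1))) || !isTRUE(all.equal(m2, t(m2)))) {
    stop("matrices must be symmetric")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]; v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("Mantel statistic undefined: a distance matrix has zero variance")
  }
  obs <- stats::cor(v1, v2)
  hits <- 0L
  for (k in seq_len(n_perms)) {
    p <- sample.int(n)
    if (stats::cor(m1[p, p][lt], v2) >= obs) hits <- hits + 1L
  }
  structure(
    list(statistic = obs, p_value = (hits + 1) / (n_perms + 1), n_perms = n_perms),
    class = "mantel_result"
  )
}

# assign each unordered pair to a distance class; pairs beyond the last
# upper bound fall out of range (class NA)
pair_classes <- function(coords, classes) {
  d <- as.matrix(stats::dist(coords)) / 1000   # meters -> km
  lt <- which(lower.tri(d), arr.ind = TRUE)
  dk <- d[lower.tri(d)]
  cls <- findInterval(dk, c(classes$lower_km[1], classes$upper_km), left.open = TRUE)
  cls[dk == classes$lower_km[1]] <- 1L         # distance exactly 0 -> first class
  cls[cls > nrow(classes) | cls < 1L] <- NA_integer_
  list(i = lt[, 1], j = lt[, 2], d_km = dk, class = cls)
}

# Per-class Moran's I for a score matrix Y (individuals x markers),
# binary within-class weights, averaged over polymorphic markers.
morans_i_classes <- function(Y, pc, n_classes, n) {
  Z <- sweep(Y, 2, colMeans(Y))
  denom <- colSums(Z^2)
  keep <- denom > 0
  if (!any(keep)) return(rep(NA_real_, n_classes))
  Z <- Z[, keep, drop = FALSE]
  denom <- denom[keep]
  out <- rep(NA_real_, n_classes)
  for (cl in seq_len(n_classes)) {
    sel <- which(!is.na(pc$class) & pc$class == cl)
    if (!length(sel)) next
    cross <- colSums(Z[pc$i[sel], , drop = FALSE] * Z[pc$j[sel], , drop = FALSE])
    s0 <- 2 * length(sel)                     # ordered pairs
    out[cl] <- mean((n / s0) * (2 * cross) / denom)
  }
  out
}

#' Moran's I spatial correlogram
#'
#' Per marker, each individual gets an allele-frequency score 0, 0.5 or 1
#' (dosage/2; missing calls are mean-imputed per marker). Moran's I is
#' computed per distance class with binary class-membership weights
#' (row-unstandardised) and averaged over polymorphic markers with equal
#' weight. The permutation envelope comes from shuffling genotypes over
#' locations jointly across markers.
#'
#' @param calls dosage matrix (individuals x markers) or a
#'   \code{\link{genotype_table}}.
#' @param coords two-column matrix of planar coordinates in meters, one
#'   row per individual.
#' @param classes a \code{\link{distance_classes}} spec.
#' @param n_perms permutations for the null envelope (default 500).
#' @param seed optional RNG seed.
#' @return data.frame of class \code{correlogram}: per class the observed
#'   statistic, pair count, permutation mean, 95% envelope and a
#'   significance flag. Attribute \code{n_out_of_range} counts pairs beyond
#'   the last class.
#' @export
morans_i_correlogram <- function(calls, coords, classes, n_perms = 500, seed = NULL) {
  if (inherits(calls, "genotype_table")) calls <- calls$calls
  coords <- as.matrix(coords)
  n <- nrow(calls)
  if (n < 2L) stop("need at least 2 individuals")
  if (nrow(coords) != n) stop("coords must have one row per individual")
  if (!is.null(seed)) set.seed(seed)
  Y <- calls / 2
  # mean-impute missing scores per marker
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
  }
  if (all(apply(Y, 2, function(y) length(unique(y)) == 1L))) {
    stop("all markers are monomorphic: Moran's I undefined")
  }
  pc <- pair_classes(coords, classes)
  k <- nrow(classes)
  obs <- morans_i_classes(Y, pc, k, n)
  perm <- matrix(NA_real_, n_perms, k)
  for (b in seq_len(n_perms)) {
    perm[b, ] <- morans_i_classes(Y[sample.int(n), , drop = FALSE], pc, k, n)
  }
  correlogram_frame("morans_i", classes, pc, obs, perm)
}

#' Gregorius genetic distance between two genotypes
#'
#' Mean over jointly called loci of half the absolute difference of the
#' individuals' allele-frequency vectors; for biallelic dosages this is
#' mean(|d1 - d2|)/2, which coincides with one minus the mean shared-allele
#' fraction (see \code{\link{allele_sharing_distance}}).
#'
#' @param g1,g2 dosage vectors on the same marker map.
#' @return distance in [0, 1].
#' @export
dg_distance <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no jointly called marker")
  mean(abs(g1[ok] - g2[ok])) / 2
}

#' Distogram of Gregorius genetic distance
#'
#' Mean pairwise genetic distance per geographic distance class, with a
#' permutation envelope built by shuffling genotypes over locations.
#'
#' @inheritParams morans_i_correlogram
#' @return data.frame of class \code{correlogram} (statistic \code{dg}).
#' @export
dg_distogram <- function(calls, coords, classes, n_perms = 500, seed = NULL) {
  if (inherits(calls, "genotype_table")) calls <- calls$calls
  coords <- as.matrix(coords)
  n <- nrow(calls)
  if (n < 2L) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  D <- genetic_distance_matrix(calls)
  if (all(D[lower.tri(D)] == 0)) stop("all individuals identical: distogram degenerate")
  pc <- pair_classes(coords, classes)
  k <- nrow(classes)
  class_mean <- function(Dm) {
    v <- Dm[cbind(pc$i, pc$j)]
    vapply(seq_len(k), function(cl) {
      sel <- !is.na(pc$class) & pc$class == cl
      if (any(sel)) mean(v[sel]) else NA_real_
    }, numeric(1))
  }
  obs <- class_mean(D)
  perm <- matrix(NA_real_, n_perms, k)
  for (b in seq_len(n_perms)) {
    p <- sample.int(n)
    perm[b, ] <- class_mean(D[p, p])
  }
  correlogram_frame("dg", classes, pc, obs, perm)
}

correlogram_frame <- function(stat, classes, pc, obs, perm) {
  k <- nrow(classes)
  env <- apply(perm, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  pm <- colMeans(perm, na.rm = TRUE)
  n_pairs <- vapply(seq_len(k), function(cl) sum(!is.na(pc$class) & pc$class == cl), integer(1))
  out <- data.frame(
    class = classes$class, lower_km = classes$lower_km, upper_km = classes$upper_km,
    n_pairs = n_pairs, observed = obs, perm_mean = pm,
    env_low = env[1, ], env_high = env[2, ],
    significant = !is.na(obs) & (obs < env[1, ] | obs > env[2, ])
  )
  attr(out, "statistic") <- stat
  attr(out, "n_out_of_range") <- sum(is.na(pc$class))
  class(out) <- c("correlogram", "data.frame")
  out
}

#' Clark-Evans aggregation index
#'
#' R = mean observed nearest-neighbour distance divided by the expectation
#' 0.5/sqrt(n/area) under complete spatial randomness (CSR). R < 1
#' indicates clumping, R about 1 randomness, R > 1 overdispersion.
#' Significance of clumping is assessed by Monte-Carlo simulation of CSR
#' in a square of the same area.
#'
#' @param coords two-column matrix of point coordinates (meters).
#' @param area study area in square meters; default the bounding-box area.
#' @param n_sims CSR simulations (default 199; 0 skips the test).
#' @param seed optional RNG seed.
#' @return list of class \code{aggregation_result}: R, expected distance,
#'   n, area, p_clumped.
#' @export
aggregation_index <- function(coords, area = NULL, n_sims = 199, seed = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points")
  if (is.null(area)) {
    area <- diff(range(coords[, 1])) * diff(range(coords[, 2]))
    if (area <= 0) area <- 1
  }
  if (area <= 0) stop("area must be positive")
  if (!is.null(seed)) set.seed(seed)
  nn_mean <- function(xy) {
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  r_obs <- nn_mean(coords)
  expect <- 0.5 / sqrt(n / area)
  R <- r_obs / expect
  p <- NA_real_
  if (n_sims > 0) {
    side <- sqrt(area)
    sims <- vapply(seq_len(n_sims), function(s) {
      nn_mean(cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))) / expect
    }, numeric(1))
    p <- (sum(sims <= R) + 1) / (n_sims + 1)
  }
  structure(
    list(R = R, expected_nn = expect, observed_nn = r_obs, n = n, area = area,
      p_clumped = p, n_sims = n_sims),
    class = "aggregation_result"
  )
}

#' Within-stand transect clustering statistics C2 and C3
#'
#' Along a transect of consecutively collected plants, C2 is the
#' proportion of individuals with at least one identical neighbour
#' (identity = same MLG; ends have a single neighbour) over all n plants;
#' C3 is the proportion of interior individuals flanked by two identical
#' neighbours, over the n - 2 interior plants.
#'
#' @param mlg_seq vector of MLG ids in transect order.
#' @return list: C2, C3 (NA when fewer than 3 plants), n.
#' @export
transect_clustering <- function(mlg_seq) {
  n <- length(mlg_seq)
  if (n < 2L) stop("need at least 2 individuals in transect order")
  same_next <- mlg_seq[-n] == mlg_seq[-1]
  has_identical <- c(same_next, FALSE) | c(FALSE, same_next)
  c2 <- mean(has_identical)
  c3 <- if (n >= 3L) {
    interior <- 2:(n - 1)
    mean(mlg_seq[interior] == mlg_seq[interior - 1] & mlg_seq[interior] == mlg_seq[interior + 1])
  } else NA_real_
  list(C2 = c2, C3 = c3, n = n)
}

#' Per-stand transect statistics for a genotype table
#'
#' Computes C2/C3 for every stand whose samples carry transect indices
#' (at least 3 plants with non-missing, distinct indices).
#'
#' @param table a \code{\link{genotype_table}}.
#' @param mlgs optional precomputed \code{\link{identify_mlgs}} result.
#' @return data.frame: stand_id, n, C2, C3.
#' @export
transect_stats <- function(table, mlgs = NULL) {
  if (is.null(mlgs)) mlgs <- identify_mlgs(table)
  ass <- mlgs$assignment
  rows <- list()
  for (st in unique(table$samples$stand_id)) {
    sel <- table$samples$stand_id == st & !is.na(table$samples$transect_index)
    if (sum(sel) < 3L) next
    ord <- order(table$samples$transect_index[sel])
    seq_ids <- ass$mlg_id[sel][ord]
    tc <- transect_clustering(seq_ids)
    rows[[st]] <- data.frame(
      stand_id = st, n = tc$n, C2 = tc$C2, C3 = tc$C3,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(stand_id = character(0), n = integer(0), C2 = numeric(0), C3 = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression of F_IS on transect clustering
#'
#' Ordinary least squares of per-stand F_IS on C3 (and C2), with Pearson
#' correlation and two-sided p-value. Tests whether within-stand spatial
#' clustering of identical genotypes predicts homozygosity (a Wahlund-type
#' signal).
#'
#' @param tstats data.frame from \code{\link{transect_stats}}.
#' @param diversity data.frame with stand_id and F_IS (e.g. from
#'   \code{\link{subsampled_stand_stats}}).
#' @return data.frame: one row per predictor (C3, C2) with slope, r2, r,
#'   p_value, n; NA values (flagged) for a constant predictor.
#' @export
cluster_vs_fis_regression <- function(tstats, diversity) {
  df <- merge(tstats, diversity[, c("stand_id", "F_IS")], by = "stand_id")
  df <- df[stats::complete.cases(df[, c("C2", "C3", "F_IS")]), ]
  if (nrow(df) < 3L) stop("need at least 3 stands with both statistics")
  one <- function(pred) {
    x <- df[[pred]]
    if (stats::sd(x) == 0) {
      return(data.frame(predictor = pred, slope = NA_real_, r2 = NA_real_,
        r = NA_real_, p_value = NA_real_, n = nrow(df), constant = TRUE))
    }
    fit <- stats::lm(df$F_IS ~ x)
    ct <- stats::cor.test(x, df$F_IS)
    data.frame(
      predictor = pred, slope = unname(stats::coef(fit)[2]),
      r2 = summary(fit)$r.squared, r = unname(ct$estimate),
      p_value = ct$p.value, n = nrow(df), constant = FALSE
    )
  }
  out <- rbind(one("C3"), one("C2"))
  rownames(out) <- NULL
  out
}
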