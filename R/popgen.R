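#' Expected heterozygosity at one marker
#'
#' Nei's unbiased gene diversity over the 2n called alleles of a stand:
#' He = (2n/(2n-1)) * (1 - sum p_i^2).
#'
#' @param dosages integer vector of dosages (0/1/2/NA) for one marker in
#'   one stand.
#' @return He, or NA when fewer than 2 individuals are called.
#' @export
expected_heterozygosity <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n < 2L) return(NA_real_)
  p <- sum(d) / (2 * n)
  (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
}

#' 1 - Q(interindividual) at one marker
#'
#' Q is the probability that two alleles, one drawn at random from each of
#' two distinct individuals of the stand, are identical; averaged over all
#' unordered pairs of called individuals.
#'
#' @param dosages integer vector of dosages for one marker in one stand.
#' @return 1 - Q, or NA when fewer than 2 individuals are called.
#' @export
one_minus_q <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  if (n < 2L) return(NA_real_)
  f <- d / 2                       # per-individual frequency of allele b
  sf <- sum(f); sf2 <- sum(f^2)
  g <- 1 - f
  sg <- sum(g); sg2 <- sum(g^2)
  # sum over ordered pairs i != j of f_i f_j + g_i g_j
  q_sum <- (sf^2 - sf2) + (sg^2 - sg2)
  1 - q_sum / (n * (n - 1))
}

# Per-stand per-marker summaries used by the Weir-Cockerham machinery:
# counts of called individuals, allele-b frequencies, heterozygote
# proportions. Returns three stands-by-markers matrices.
stand_marker_summaries <- function(calls, stand_ids) {
  st <- unique(stand_ids)
  idx <- match(stand_ids, st)
  L <- ncol(calls)
  n <- matrix(0L, length(st), L, dimnames = list(st, colnames(calls)))
  p <- matrix(NA_real_, length(st), L, dimnames = list(st, colnames(calls)))
  h <- matrix(NA_real_, length(st), L, dimnames = list(st, colnames(calls)))
  for (k in seq_along(st)) {
    sub <- calls[idx == k, , drop = FALSE]
    nk <- colSums(!is.na(sub))
    n[k, ] <- nk
    p[k, ] <- ifelse(nk > 0, colSums(sub, na.rm = TRUE) / (2 * nk), NA_real_)
    h[k, ] <- ifelse(nk > 0, colSums(sub == 1L, na.rm = TRUE) / nk, NA_real_)
  }
  list(n = n, p = p, h = h)
}

# Weir & Cockerham (1984) per-locus variance components a (among
# populations), b (among individuals within populations), c (within
# individuals), computed for the allele-b indicator. Populations with
# fewer than 1 called individual are dropped per locus; loci with fewer
# than 2 called individuals in total, or monomorphic overall, yield
# all-zero components with used = FALSE.
wc_components <- function(n, p, h) {
  L <- ncol(n)
  a <- b <- cc <- numeric(L)
  used <- logical(L)
  for (l in seq_len(L)) {
    keep <- n[, l] > 0L
    ni <- n[keep, l]; pi <- p[keep, l]; hi <- h[keep, l]
    r <- length(ni)
    ntot <- sum(ni)
    if (r < 1L || ntot < 2L) next
    nbar <- ntot / r
    pbar <- sum(ni * pi) / ntot
    hbar <- sum(ni * hi) / ntot
    if (pbar <= 0 || pbar >= 1) next
    if (nbar <= 1) next
    if (r > 1L) {
      nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      a[l] <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
      b[l] <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    } else {
      a[l] <- NA_real_   # among-population component undefined for one stand
      b[l] <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    }
    cc[l] <- hbar / 2
    used[l] <- TRUE
  }
  list(a = a, b = b, c = cc, used = used)
}

#' Multilocus Weir-Cockerham F-statistics
#'
#' Estimates F_IS, F_ST (theta) and F_IT from per-locus variance components
#' a, b, c, combined across loci as ratios of component sums. Monomorphic
#' loci contribute nothing. With a single stand only F_IS is defined.
#'
#' @param table a \code{\link{genotype_table}} (stands are the populations),
#'   or an integer dosage matrix if \code{stand_ids} is given.
#' @param stand_ids optional vector of population labels, one per row of
#'   the dosage matrix.
#' @return An object of class \code{wc_fstats}: list with \code{F_IS},
#'   \code{F_ST}, \code{F_IT}, \code{n_loci_used}, \code{defined} (FALSE
#'   when every locus was monomorphic), and \code{per_locus} components.
#' @export
wc_f_statistics <- function(table, stand_ids = NULL) {
  if (inherits(table, "genotype_table")) {
    calls <- table$calls
    stand_ids <- table$samples$stand_id
  } else {
    calls <- table
    if (is.null(stand_ids)) stop("stand_ids required with a bare dosage matrix")
  }
  sm <- stand_marker_summaries(calls, stand_ids)
  comp <- wc_components(sm$n, sm$p, sm$h)
  multi <- wc_combine(comp)
  structure(c(multi, list(per_locus = comp, n_stands = length(unique(stand_ids)))),
    class = "wc_fstats"
  )
}

# Combine per-locus components into multilocus ratio-of-sums estimates.
wc_combine <- function(comp) {
  u <- comp$used
  if (!any(u)) {
    return(list(
      F_IS = NA_real_, F_ST = NA_real_, F_IT = NA_real_,
      n_loci_used = 0L, defined = FALSE
    ))
  }
  sa <- sum(comp$a[u])                      # NA when single stand
  sb <- sum(comp$b[u]); sc <- sum(comp$c[u])
  fis <- if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_
  fst <- if (!is.na(sa) && sa + sb + sc > 0) sa / (sa + sb + sc) else NA_real_
  fit <- if (!is.na(sa) && sa + sb + sc > 0) 1 - sc / (sa + sb + sc) else NA_real_
  list(F_IS = fis, F_ST = fst, F_IT = fit, n_loci_used = sum(u), defined = TRUE)
}

#' @export
print.wc_fstats <- function(x, ...) {
  cat(sprintf(
    "Weir-Cockerham F-statistics (%d loci used, %d stands)\n  F_IS = %s  F_ST = %s  F_IT = %s\n",
    x$n_loci_used, x$n_stands,
    format(x$F_IS, digits = 4), format(x$F_ST, digits = 4), format(x$F_IT, digits = 4)
  ))
  invisible(x)
}

#' Effective outcrossing rate from F_IS
#'
#' At inbreeding equilibrium under partial self-fertilisation,
#' F = s/(2 - s), so the outcrossing fraction implied by an observed
#' inbreeding coefficient is OC = 1 - 2*F_IS/(1 + F_IS) = (1 - F_IS)/(1 + F_IS).
#' This measures the effective rate of heterozygote generation, not
#' necessarily the true mating rate (near-neighbour mating among relatives
#' depresses it).
#'
#' @param f_is inbreeding coefficient(s) in (-1, 1].
#' @return OC on the same scale (fraction, not percent). NA (with a
#'   warning) where F_IS = -1, where the transform is undefined.
#' @export
effective_outcrossing <- function(f_is) {
  bad <- !is.na(f_is) & (f_is <= -1 | f_is > 1)
  if (any(bad)) {
    warning("effective outcrossing undefined for F_IS outside (-1, 1]; returning NA")
  }
  out <- (1 - f_is) / (1 + f_is)
  out[bad] <- NA_real_
  out
}

#' Format an outcrossing fraction as a percentage
#' @param oc outcrossing fraction(s) from \code{\link{effective_outcrossing}}.
#' @param digits decimal places (default 1, reporting convention).
#' @return numeric percentage(s), rounded.
#' @export
outcrossing_percent <- function(oc, digits = 1) round(100 * oc, digits)

# per-marker He / 1-Q / Ho / WC(b,c) for a dosage matrix of one stand
stand_marker_stats <- function(sub) {
  nk <- colSums(!is.na(sub))
  p <- ifelse(nk > 0, colSums(sub, na.rm = TRUE) / (2 * nk), NA_real_)
  h <- ifelse(nk > 0, colSums(sub == 1L, na.rm = TRUE) / nk, NA_real_)
  two_n <- 2 * nk
  he <- ifelse(nk >= 2, (two_n / (two_n - 1)) * (1 - p^2 - (1 - p)^2), NA_real_)
  f <- sub / 2
  sf <- colSums(f, na.rm = TRUE); sf2 <- colSums(f^2, na.rm = TRUE)
  g <- (2 - sub) / 2
  sg <- colSums(g, na.rm = TRUE); sg2 <- colSums(g^2, na.rm = TRUE)
  qq <- ifelse(nk >= 2, ((sf^2 - sf2) + (sg^2 - sg2)) / (nk * (nk - 1)), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1 & nk >= 2
  b <- ifelse(poly,
    (nk / (nk - 1)) * (p * (1 - p) - ((2 * nk - 1) / (4 * nk)) * h), 0
  )
  cc <- ifelse(poly, h / 2, 0)
  list(he = he, omq = 1 - qq, ho = h, b = b, c = cc, n = nk, poly = poly)
}

#' Size-corrected per-stand diversity via subsampling
#'
#' For every stand with at least \code{subsample_size} samples: draw
#' \code{n_reps} random subsamples of \code{subsample_size} individuals
#' without replacement, compute per-marker He, 1-Q, Ho and the
#' Weir-Cockerham within-stand components per replicate, average per marker
#' across replicates, then across the genome. Monomorphic markers enter the
#' genome means of He, 1-Q and Ho as zeros but contribute nothing to the
#' multilocus F_IS ratio. 95% confidence intervals come from a bootstrap
#' over loci (\code{bootstrap_reps} draws, percentile intervals), the
#' standard multilocus procedure. The effective-outcrossing transform of
#' F_IS is reported alongside.
#'
#' @param table a \code{\link{genotype_table}}.
#' @param subsample_size individuals per subsample (default 10).
#' @param n_reps subsample replicates (default 100).
#' @param bootstrap_reps locus-bootstrap draws for CIs (default 1000).
#' @param min_n minimum stand size; smaller stands are excluded
#'   (default = subsample_size, mirroring the n >= 10 filter).
#' @param seed optional RNG seed.
#' @return data.frame of class \code{diversity_result}: one row per
#'   retained stand with point estimates and CI bounds.
#' @export
subsampled_stand_stats <- function(table, subsample_size = 10, n_reps = 100,
                                   bootstrap_reps = 1000, min_n = subsample_size,
                                   seed = NULL) {
  if (subsample_size < 2) stop("subsample_size must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  st_ids <- unique(table$samples$stand_id)
  rows <- list()
  for (st in st_ids) {
    idx <- which(table$samples$stand_id == st)
    n <- length(idx)
    if (n < min_n) next
    L <- ncol(table$calls)
    acc <- list(he = 0, omq = 0, ho = 0, b = 0, c = 0)
    for (r in seq_len(n_reps)) {
      take <- if (n > subsample_size) sample(idx, subsample_size) else idx
      s <- stand_marker_stats(table$calls[take, , drop = FALSE])
      acc$he <- acc$he + ifelse(is.na(s$he), 0, s$he)
      acc$omq <- acc$omq + ifelse(is.na(s$omq), 0, s$omq)
      acc$ho <- acc$ho + ifelse(is.na(s$ho), 0, s$ho)
      acc$b <- acc$b + s$b
      acc$c <- acc$c + s$c
    }
    he_m <- acc$he / n_reps; omq_m <- acc$omq / n_reps; ho_m <- acc$ho / n_reps
    b_m <- acc$b / n_reps; c_m <- acc$c / n_reps
    gen <- function(j) {  # genome summaries from a set of locus indices
      sb <- sum(b_m[j]); sc <- sum(c_m[j])
      c(
        he = mean(he_m[j]), omq = mean(omq_m[j]), ho = mean(ho_m[j]),
        fis = if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_
      )
    }
    pt <- gen(seq_len(L))
    boot <- matrix(NA_real_, bootstrap_reps, 4)
    for (bb in seq_len(bootstrap_reps)) {
      boot[bb, ] <- gen(sample.int(L, L, replace = TRUE))
    }
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    oc <- effective_outcrossing(pt[["fis"]])
    rows[[st]] <- data.frame(
      stand_id = st, n = n, n_used = min(n, subsample_size),
      He = pt[["he"]], He_lo = ci[1, 1], He_hi = ci[2, 1],
      one_minus_Q = pt[["omq"]], one_minus_Q_lo = ci[1, 2], one_minus_Q_hi = ci[2, 2],
      Ho = pt[["ho"]], Ho_lo = ci[1, 3], Ho_hi = ci[2, 3],
      F_IS = pt[["fis"]], F_IS_lo = ci[1, 4], F_IS_hi = ci[2, 4],
      OC = oc,
      OC_lo = if (is.na(pt[["fis"]])) NA_real_ else effective_outcrossing(min(ci[2, 4], 1)),
      OC_hi = if (is.na(pt[["fis"]])) NA_real_ else effective_outcrossing(max(ci[1, 4], -0.999)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    stop("no stand reaches the minimum size of ", min_n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_result", "data.frame")
  out
}

#' Direct (uncorrected) per-stand diversity
#'
#' Full-sample analogue of \code{\link{subsampled_stand_stats}}: genome-mean
#' He, 1-Q, Ho and multilocus within-stand F_IS per stand, no subsampling,
#' no CIs. Stands with fewer than 2 samples are skipped.
#'
#' @param table a \code{\link{genotype_table}}.
#' @return data.frame: stand_id, n, He, one_minus_Q, Ho, F_IS, OC.
#' @export
stand_diversity <- function(table) {
  st_ids <- unique(table$samples$stand_id)
  rows <- list()
  for (st in st_ids) {
    idx <- which(table$samples$stand_id == st)
    if (length(idx) < 2L) next
    s <- stand_marker_stats(table$calls[idx, , drop = FALSE])
    sb <- sum(s$b); sc <- sum(s$c)
    fis <- if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_
    rows[[st]] <- data.frame(
      stand_id = st, n = length(idx),
      He = mean(ifelse(is.na(s$he), 0, s$he)),
      one_minus_Q = mean(ifelse(is.na(s$omq), 0, s$omq)),
      Ho = mean(ifelse(is.na(s$ho), 0, s$ho)),
      F_IS = fis, OC = effective_outcrossing(fis),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise F_ST between two stands (or stand-year samples) with
#' size-matched subsampling
#'
#' When the two samples differ in size, the larger is subsampled to the
#' size of the smaller; theta is computed per replicate and per-locus
#' components are averaged over \code{n_reps} replicates before the
#' multilocus ratio. CIs by locus bootstrap.
#'
#' @param table_a,table_b \code{\link{genotype_table}}s holding the two
#'   samples (e.g. the same stand in two years).
#' @param n_reps subsample replicates (default 100).
#' @param bootstrap_reps locus-bootstrap draws (default 1000).
#' @param seed optional RNG seed.
#' @return list of class \code{fst_result}: theta, CI bounds, n per sample.
#' @export
year_pair_fst <- function(table_a, table_b, n_reps = 100, bootstrap_reps = 1000,
                          seed = NULL) {
  if (!identical(table_a$map$marker_id, table_b$map$marker_id)) {
    stop("the two samples must share a marker map")
  }
  if (!is.null(seed)) set.seed(seed)
  na <- nrow(table_a$calls); nb <- nrow(table_b$calls)
  if (na < 2L || nb < 2L) stop("need at least 2 samples on each side")
  m <- min(na, nb)
  big <- if (na >= nb) table_a$calls else table_b$calls
  small <- if (na >= nb) table_b$calls else table_a$calls
  L <- ncol(big)
  accA <- accB <- accC <- numeric(L)
  reps <- if (na == nb) 1L else n_reps
  for (r in seq_len(reps)) {
    sub <- big[sample(nrow(big), m), , drop = FALSE]
    calls <- rbind(sub, small)
    ids <- rep(c("A", "B"), c(m, nrow(small)))
    sm <- stand_marker_summaries(calls, ids)
    comp <- wc_components(sm$n, sm$p, sm$h)
    accA <- accA + ifelse(comp$used, comp$a, 0)
    accB <- accB + ifelse(comp$used, comp$b, 0)
    accC <- accC + ifelse(comp$used, comp$c, 0)
  }
  accA <- accA / reps; accB <- accB / reps; accC <- accC / reps
  theta_of <- function(j) {
    den <- sum(accA[j] + accB[j] + accC[j])
    if (den > 0) sum(accA[j]) / den else NA_real_
  }
  theta <- theta_of(seq_len(L))
  boot <- vapply(
    seq_len(bootstrap_reps),
    function(b) theta_of(sample.int(L, L, replace = TRUE)), numeric(1)
  )
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  structure(list(
    theta = theta, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    n_a = na, n_b = nb, n_subsample = m, n_reps = reps,
    degenerate = is.na(theta)
  ), class = "fst_result")
}

#' Pairwise F_ST matrix across stands
#'
#' Weir-Cockerham theta for every unordered pair of stands with at least
#' \code{min_n} samples (no subsampling; use \code{\link{year_pair_fst}}
#' for size-matched comparisons).
#'
#' @param table a \code{\link{genotype_table}}.
#' @param min_n minimum stand size to include (default 2).
#' @return symmetric matrix of theta values (NA diagonal).
#' @export
pairwise_fst <- function(table, min_n = 2L) {
  st <- table$samples$stand_id
  ids <- names(which(table(st) >= min_n))
  sm <- stand_marker_summaries(table$calls, st)
  sel <- match(ids, rownames(sm$n))
  k <- length(ids)
  out <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      pick <- sel[c(i, j)]
      comp <- wc_components(sm$n[pick, , drop = FALSE],
        sm$p[pick, , drop = FALSE], sm$h[pick, , drop = FALSE])
      u <- comp$used
      den <- sum(comp$a[u] + comp$b[u] + comp$c[u])
      out[i, j] <- out[j, i] <- if (any(u) && den > 0) sum(comp$a[u]) / den else NA_real_
    }
  }
  out
}

#' Bootstrap confidence intervals for multilocus F-statistics
#'
#' Percentile CIs for the multilocus Weir-Cockerham estimates by
#' resampling either stands (capturing between-stand sampling variance,
#' appropriate when stands are the independent replicates) or loci
#' (Weir's classical procedure; anti-conservative when loci share
#' genealogy, as in highly selfing samples).
#'
#' @param table a \code{\link{genotype_table}}.
#' @param n_boot bootstrap replicates (default 200).
#' @param unit "stand" (default) or "locus".
#' @param seed optional RNG seed.
#' @return data.frame with rows F_IS, F_ST, F_IT and columns estimate,
#'   ci_low, ci_high.
#' @export
wc_bootstrap_ci <- function(table, n_boot = 200, unit = c("stand", "locus"),
                            seed = NULL) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  sm <- stand_marker_summaries(table$calls, table$samples$stand_id)
  comp_all <- wc_components(sm$n, sm$p, sm$h)
  point <- wc_combine(comp_all)
  n_st <- nrow(sm$n)
  draws <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    if (unit == "stand") {
      rows <- sample.int(n_st, n_st, replace = TRUE)
      comp <- wc_components(sm$n[rows, , drop = FALSE],
        sm$p[rows, , drop = FALSE], sm$h[rows, , drop = FALSE])
      est <- wc_combine(comp)
    } else {
      u <- which(comp_all$used)
      j <- sample(u, length(u), replace = TRUE)
      sa <- sum(comp_all$a[j]); sb <- sum(comp_all$b[j]); sc <- sum(comp_all$c[j])
      est <- list(
        F_IS = if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_,
        F_ST = if (!is.na(sa) && sa + sb + sc > 0) sa / (sa + sb + sc) else NA_real_,
        F_IT = if (!is.na(sa) && sa + sb + sc > 0) 1 - sc / (sa + sb + sc) else NA_real_
      )
    }
    draws[b, ] <- c(est$F_IS, est$F_ST, est$F_IT)
  }
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  data.frame(
    statistic = c("F_IS", "F_ST", "F_IT"),
    estimate = c(point$F_IS, point$F_ST, point$F_IT),
    ci_low = ci[1, ], ci_high = ci[2, ],
    stringsAsFactors = FALSE
  )
}
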