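# Shared fixture builders and independent oracles.

# small evenly spaced map: L markers on `chroms` chromosomes
tiny_map <- function(L = 6, chroms = 1, spacing = 1e5) {
  per <- ceiling(L / chroms)
  chrom <- rep(seq_len(chroms), each = per)[seq_len(L)]
  pos <- unlist(lapply(seq_len(chroms), function(c) seq_len(sum(chrom == c)) * spacing))
  marker_map(sprintf("M%03d", seq_len(L)), chrom, pos)
}

# genotype table from a plain dosage matrix
make_table <- function(calls, stand_ids, map = NULL, year = 2007,
                       transect_index = NA_integer_) {
  calls <- as.matrix(calls)
  if (is.null(map)) map <- tiny_map(ncol(calls))
  genotype_table(
    calls,
    data.frame(
      sample_id = sprintf("s%03d", seq_len(nrow(calls))),
      stand_id = stand_ids, year = year, transect_index = transect_index,
      stringsAsFactors = FALSE
    ),
    map
  )
}

# Independent Weir-Cockerham oracle via ANOVA mean squares on the
# allele-b gene indicator: MSG (within individuals), MSI (among
# individuals within populations), MSP (among populations);
# c = MSG, b = (MSI - MSG)/2, a = (MSP - MSI)/(2 n_c).
wc_anova_oracle <- function(calls, pops) {
  L <- ncol(calls)
  A <- B <- C <- numeric(L)
  used <- logical(L)
  for (l in seq_len(L)) {
    d <- calls[, l]
    ok <- !is.na(d)
    dd <- d[ok]; pp <- pops[ok]
    if (length(dd) < 2) next
    ybar_pop <- tapply(dd / 2, pp, mean)
    ni <- tapply(dd, pp, length)
    ybar <- mean(dd / 2)
    if (ybar <= 0 || ybar >= 1) next
    r <- length(ni); ntot <- sum(ni)
    if (mean(ni) <= 1) next
    SSG <- sum(dd == 1) * 0.5            # each het: genes 0,1 around mean 0.5
    MSG <- SSG / ntot
    SSI <- 2 * sum((dd / 2 - ybar_pop[as.character(pp)])^2)
    MSI <- SSI / (ntot - r)
    if (r > 1) {
      SSP <- 2 * sum(ni * (ybar_pop - ybar)^2)
      MSP <- SSP / (r - 1)
      nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
      A[l] <- (MSP - MSI) / (2 * nc)
    } else {
      A[l] <- NA_real_
    }
    B[l] <- (MSI - MSG) / 2
    C[l] <- MSG
    used[l] <- TRUE
  }
  u <- used
  sa <- sum(A[u]); sb <- sum(B[u]); sc <- sum(C[u])
  list(
    F_IS = if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_,
    F_ST = if (!is.na(sa) && sa + sb + sc > 0) sa / (sa + sb + sc) else NA_real_,
    used = used
  )
}

# Brute-force MLG oracle: transitive closure of pairwise compatibility
# (agree wherever both called; both call rates >= min_call_rate), with
# exact-pattern equality always merging. Returns number of classes.
mlg_closure_oracle <- function(calls, min_call_rate = 0.95) {
  n <- nrow(calls)
  rate <- rowMeans(!is.na(calls))
  same <- function(i, j) {
    exact <- identical(calls[i, ], calls[j, ])
    if (exact) return(TRUE)
    if (rate[i] < min_call_rate || rate[j] < min_call_rate) return(FALSE)
    both <- !is.na(calls[i, ]) & !is.na(calls[j, ])
    all(calls[i, both] == calls[j, both])
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) adj[i, j] <- same(i, j)
  # transitive closure (Warshall)
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ]) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) { cid <- cid + 1L; comp[adj[i, ]] <- cid }
  }
  list(n_classes = length(unique(comp)), comp = comp)
}

# exhaustive minimum-breakpoint oracle for RIL painting: labels forced
# where determined, free over {A,B} at U/NA positions; minimises switches
# per chromosome
min_breakpoints_oracle <- function(lab, chrom) {
  total <- 0L
  for (ch in unique(chrom)) {
    s <- lab[chrom == ch]
    free <- is.na(s) | s == "U"
    k <- sum(free)
    if (all(free) || length(s) < 2) next
    if (k == 0) {
      total <- total + sum(s[-1] != s[-length(s)])
      next
    }
    best <- Inf
    grid <- expand.grid(rep(list(c("A", "B")), k), stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      s2 <- s
      s2[free] <- unlist(grid[g, ])
      best <- min(best, sum(s2[-1] != s2[-length(s2)]))
    }
    total <- total + best
  }
  total
}

# deterministic selfing-regime simulation fixture (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_stands = 8, L = 120, t = 0.08, mating_kernel_sigma = 2,
        seed_dispersal_sigma = 0.5, founders_per_stand = 4,
        generations = 15, capacity = 30, migration_rate = 0.02, seed = 99
      )
      cache <<- simulate_stands(cfg)
    }
    cache
  }
})
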