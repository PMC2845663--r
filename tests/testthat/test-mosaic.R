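test_that("pairwise profiles classify marker statuses symmetrically", {
  map <- tiny_map(6)
  g1 <- c(0L, 0L, 2L, 1L, NA, 2L)
  g2 <- c(0L, 2L, 2L, 0L, 0L, 1L)
  p <- pairwise_profile(g1, g2, map)
  expect_equal(p$status, c("identical", "divergent", "identical",
    "het_involved", "missing", "het_involved"))
  p2 <- pairwise_profile(g2, g1, map)
  expect_identical(p$status, p2$status)
  # identical homozygotes / opposite homozygotes everywhere
  expect_true(all(pairwise_profile(rep(0L, 6), rep(0L, 6), map)$status == "identical"))
  expect_true(all(pairwise_profile(rep(0L, 6), rep(2L, 6), map)$status == "divergent"))
})

test_that("block segmentation tiles chromosomes and honours min_run", {
  map <- tiny_map(30)
  g1 <- rep(0L, 30)
  g2 <- c(rep(0L, 10), rep(2L, 10), rep(0L, 10))
  p <- pairwise_profile(g1, g2, map)
  b <- segment_blocks(p, min_run = 5)
  expect_equal(nrow(b), 3L)
  expect_equal(b$state, c("identity", "divergence", "identity"))
  expect_equal(b$start_idx, c(0L, 10L, 20L))
  expect_equal(b$end_idx, c(9L, 19L, 29L))
  # blocks tile: consecutive, non-overlapping
  expect_true(all(b$start_idx[-1] == b$end_idx[-3] + 1L))

  # a short interior run is merged into its flanks
  g3 <- g1; g3[15] <- 2L
  b2 <- segment_blocks(pairwise_profile(g1, g3, map), min_run = 5)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$state, "identity")

  # min_run = 1 is lossless: restores the exact informative state sequence
  set.seed(23)
  for (r in 1:10) {
    gg <- sample(c(0L, 2L), 30, replace = TRUE)
    pr <- pairwise_profile(rep(0L, 30), gg, map)
    bl <- segment_blocks(pr, min_run = 1)
    reconstructed <- character(30)
    for (k in seq_len(nrow(bl))) {
      reconstructed[(bl$start_idx[k] + 1L):(bl$end_idx[k] + 1L)] <- bl$state[k]
    }
    want <- ifelse(pr$status == "identical", "identity", "divergence")
    expect_identical(reconstructed, want)
  }

  # chromosome with too few informative markers is a single flagged block
  mapc <- tiny_map(4)
  ph <- pairwise_profile(c(1L, 1L, 1L, 0L), c(0L, 0L, 0L, 0L), mapc)
  bf <- segment_blocks(ph, min_run = 3)
  expect_equal(nrow(bf), 1L)
  expect_true(bf$flagged)
})

test_that("block boundaries localise simulated crossovers to a marker interval", {
  # construct a recombinant directly: founder A (all 0), founder B (all 2),
  # two crossovers at known positions on one chromosome
  map <- tiny_map(40, chroms = 1, spacing = 1e5)
  cuts <- c(12.5e5, 27.5e5)    # between markers 12/13 and 27/28
  seg <- findInterval(map$pos, cuts)
  child <- ifelse(seg == 1L, 2L, 0L)
  p <- pairwise_profile(rep(0L, 40), as.integer(child), map)
  b <- segment_blocks(p, min_run = 3)
  expect_equal(nrow(b), 3L)
  # boundaries within one marker interval of the true cuts
  expect_equal(b$end_idx[1], 11L)   # marker index 11 = 12th marker
  expect_equal(b$start_idx[2], 12L)
  expect_equal(b$end_idx[2], 26L)
  expect_equal(b$start_idx[3], 27L)
})

test_that("heterozygous stretch detection obeys min_run and interrupts", {
  map <- tiny_map(20)
  # fully homozygous: none
  expect_equal(nrow(detect_het_stretches(rep(0L, 20), map)), 0L)
  # fully heterozygous: one stretch spanning the chromosome
  hs <- detect_het_stretches(rep(1L, 20), map)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_het, 20L)
  expect_equal(attr(hs, "het_fraction"), 1)
  # a single interruption is tolerated, two break the run
  g <- rep(1L, 20); g[10] <- 0L
  expect_equal(nrow(detect_het_stretches(g, map, min_run = 3, max_interrupt = 1)), 1L)
  g2 <- rep(1L, 20); g2[10:11] <- 0L
  expect_equal(nrow(detect_het_stretches(g2, map, min_run = 3, max_interrupt = 1)), 2L)
  # missing calls are neutral
  g3 <- rep(1L, 20); g3[c(5, 6, 7)] <- NA_integer_
  expect_equal(nrow(detect_het_stretches(g3, map, min_run = 3, max_interrupt = 0)), 1L)
  # runs below min_run are dropped
  g4 <- rep(0L, 20); g4[3:4] <- 1L
  expect_equal(nrow(detect_het_stretches(g4, map, min_run = 3)), 0L)
})

test_that("an F1 after one selfed generation keeps about half its het markers", {
  set.seed(44)
  map <- tiny_map(200, chroms = 5)
  fracs <- replicate(30, {
    # selfing meiosis on a fully heterozygous F1: each chromosome segment
    # segregates; count residual het markers in the selfed offspring
    child <- unlist(lapply(split(seq_len(200), map$chrom), function(idx) {
      # one crossover on average: simulate two gametes with the package's
      # recombination model via independent segment inheritance
      n <- length(idx)
      br <- sort(runif(rpois(1, 1), 0, max(map$pos[idx])))
      seg <- findInterval(map$pos[idx], br) + 1
      h1 <- (seg + rbinom(1, 1, 0.5)) %% 2
      br2 <- sort(runif(rpois(1, 1), 0, max(map$pos[idx])))
      seg2 <- findInterval(map$pos[idx], br2) + 1
      h2 <- (seg2 + rbinom(1, 1, 0.5)) %% 2
      h1 + h2   # dosage: 1 = still heterozygous
    }))
    mean(child == 1)
  })
  # Mendelian expectation: half the markers stay heterozygous
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.5), 4 * se + 0.02)
})

test_that("F1 parent assignment recovers constructed parent pairs", {
  map <- tiny_map(10)
  A <- rep(0L, 10)
  B <- c(rep(0L, 6), rep(2L, 4))      # differs from A at 4 markers
  C <- rep(2L, 10)
  cands <- rbind(A = A, B = B, C = C)
  # child heterozygous at exactly the A/B differentiating markers
  child <- c(rep(0L, 6), rep(1L, 4))
  call <- assign_f1_parents(child, cands)
  expect_equal(call$verdict, "first_generation")
  expect_equal(call$parents, c("A", "B"))
  expect_equal(call$n_differentiating, 4L)
  expect_equal(call$fraction_het, 1)
  # child identical to a candidate: self-descendant, no F1 call
  expect_equal(assign_f1_parents(A, cands)$verdict, "none")
  # child het at half the differentiating markers: later generation
  child2 <- c(rep(0L, 6), 1L, 1L, 2L, 2L)
  call2 <- assign_f1_parents(child2, cands)
  expect_equal(call2$verdict, "later_generation_or_recombinant")
  # heterozygous candidates are not eligible parents
  expect_error(assign_f1_parents(child, rbind(X = rep(1L, 10), Y = rep(1L, 10))),
    "homozygous")
})

test_that("simulator-logged F1s with sampled homozygous parents are recovered", {
  cfg <- sim_config(
    n_stands = 4, L = 100, t = 0.25, mating_kernel_sigma = Inf,
    founders_per_stand = 6, generations = 8, capacity = 30,
    migration_rate = 0, seed = 13
  )
  ds <- simulate_stands(cfg)
  fin_gen <- ds$config$generations
  ped <- ds$pedigree
  fin <- ped[ped$gen == fin_gen & !ped$selfed, ]
  par_pop <- ds$parents
  par_ids <- unlist(lapply(par_pop, function(s) s$ids))
  par_calls <- do.call(rbind, lapply(par_pop, function(s) s$hapA + s$hapB))
  rownames(par_calls) <- par_ids
  pop_ids <- unlist(lapply(ds$pop, function(s) s$ids))
  pop_calls <- do.call(rbind, lapply(ds$pop, function(s) s$hapA + s$hapB))
  rownames(pop_calls) <- pop_ids
  checked <- 0
  for (k in seq_len(nrow(fin))) {
    mo <- par_calls[fin$mother_id[k], ]
    fa <- par_calls[fin$father_id[k], ]
    if (any(mo == 1L) || any(fa == 1L) || all(mo == fa)) next
    # parents homozygous and distinct: child must be het exactly at their
    # differentiating markers
    child <- pop_calls[fin$id[k], ]
    diffm <- mo != fa
    expect_true(all(child[diffm] == 1L))
    expect_true(all(child[!diffm] == mo[!diffm]))
    cands <- rbind(mo, fa, extra = 2L - mo)   # add a decoy candidate
    rownames(cands) <- c("mother", "father", "decoy")
    cands <- cands[rowSums(cands == 1L) == 0, , drop = FALSE]
    call <- assign_f1_parents(child, cands)
    expect_equal(call$verdict, "first_generation")
    expect_setequal(call$parents, c("mother", "father"))
    checked <- checked + 1
  }
  expect_gt(checked, 0)
})

test_that("RIL reconstruction paints constructed mosaics exactly", {
  map <- tiny_map(6)
  A <- rep(0L, 6); B <- rep(2L, 6)
  rec <- c(0L, 0L, 0L, 2L, 2L, 2L)
  res <- reconstruct_ril(rbind(A = A, B = B, rec = rec), map)
  expect_setequal(res$founders, c("A", "B"))
  expect_equal(unname(res$painting["rec", ]), c("A", "A", "A", "B", "B", "B"))
  expect_equal(unname(res$breakpoints["rec"]), 1L)
  expect_equal(sum(res$unexplained), 0)
  # a genotype heterozygous across the differentiating region matches
  # neither homozygous founder there: all 10 markers unexplained
  map2 <- tiny_map(20)
  A2 <- rep(0L, 20)
  B2 <- c(rep(0L, 10), rep(2L, 10))    # founders differ at markers 11..20
  other <- c(rep(0L, 10), rep(1L, 10))
  res2 <- reconstruct_ril(rbind(A = A2, B = B2,
    rec = c(rep(0L, 15), rep(2L, 5)), other = other), map2)
  expect_equal(unname(res2$unexplained["other"]), 10)
  # identical MLGs leave nothing to reconstruct
  expect_error(reconstruct_ril(rbind(A = A, B = A, C = A), tiny_map(6)), "at least 3")
})

test_that("greedy breakpoint counts equal the exhaustive minimum on small instances", {
  set.seed(55)
  for (r in 1:20) {
    L <- sample(8:12, 1)
    map <- tiny_map(L, chroms = 2)
    A <- rep(0L, L); B <- rep(2L, L)
    # random recombinants + occasional het (unexplained) markers
    recs <- t(replicate(4, {
      g <- ifelse(runif(L) < 0.5, 0L, 2L)
      g[runif(L) < 0.1] <- 1L
      g
    }))
    mat <- rbind(A = A, B = B, recs)
    rownames(mat) <- c("A", "B", paste0("r", 1:4))
    hom_mat <- mat[rowSums(mat == 1L) == 0, , drop = FALSE]
    if (nrow(unique(hom_mat)) < 3) next
    res <- reconstruct_ril(hom_mat, map)
    for (id in rownames(res$painting)) {
      expect_equal(
        unname(res$breakpoints[id]),
        min_breakpoints_oracle(res$painting[id, ], map$chrom[res$diff_idx + 1L])
      )
    }
  }
})

test_that("simulated two-founder stands reconstruct with zero unexplained markers", {
  cfg <- sim_config(
    n_stands = 2, L = 100, t = 0.15, founders_per_stand = 2,
    mating_kernel_sigma = Inf, generations = 12, capacity = 25,
    migration_rate = 0, seed = 77
  )
  ds <- simulate_stands(cfg)
  tab <- sample_survey(ds, seed = 9)
  found <- 0
  for (st in ds$stands$stand_id) {
    sub <- subset_table(tab, stands = st)
    m <- identify_mlgs(sub)
    hom <- m$mlg_calls[rowSums(m$mlg_calls == 1L, na.rm = TRUE) == 0, , drop = FALSE]
    if (nrow(unique(hom)) < 3) next
    res <- reconstruct_ril(hom, ds$map)
    expect_equal(sum(res$unexplained), 0)
    found <- found + 1
  }
  expect_gt(found, 0)
})

test_that("BED export writes half-open intervals", {
  map <- tiny_map(10)
  p <- pairwise_profile(rep(0L, 10), c(rep(0L, 5), rep(2L, 5)), map)
  b <- segment_blocks(p, min_run = 2)
  f <- tempfile(fileext = ".bed")
  write_blocks_bed(b, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(nrow(bed), nrow(b))
  expect_true(all(bed$V2 == b$start_bp - 1L))
  expect_true(all(bed$V3 == b$end_bp))
})
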