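#' Configuration for the selfing-metapopulation simulator
#'
#' Defaults emulate a survey of a predominantly selfing annual plant in a
#' ~20 x 20 km landscape: 77 stands, 436 intermediate-frequency biallelic
#' SNPs over 5 chromosomes, discrete non-overlapping generations at fixed
#' per-stand carrying capacity, rare whole-seed migration, Gaussian pollen
#' and seed dispersal kernels within stands, and no mutation (negligible
#' relative to even low outcrossing at SNP markers).
#'
#' @param n_stands number of stands.
#' @param L number of markers.
#' @param maf_range interval in (0, 0.5] for founder minor-allele
#'   frequencies (markers are ascertained at intermediate frequency).
#' @param founders_per_stand founding haplotypes per stand.
#' @param t outcrossing probability per ovule, scalar or one value per
#'   stand.
#' @param mating_kernel_sigma scale (m) of the Gaussian pollen kernel over
#'   stand-mates; \code{Inf} gives uniform random-partner mating.
#' @param seed_dispersal_sigma scale (m) of seed movement from the mother.
#' @param migration_rate per-stand per-generation probability of one
#'   immigrant seed from another stand.
#' @param generations number of generations to iterate.
#' @param recomb_rate expected crossovers per chromosome per meiosis.
#' @param capacity per-stand carrying capacity, scalar or one per stand.
#' @param stand_extent side (m) of the square patch a stand occupies.
#' @param chrom_lengths bp lengths of the chromosomes (default the five
#'   A. thaliana chromosomes: 30.4, 19.7, 23.5, 18.6, 27.0 Mb).
#' @param landscape_size side (m) of the square region stands are
#'   scattered over.
#' @param site_type per-stand "rural"/"urban" labels, or NULL to draw
#'   them evenly.
#' @param seed RNG seed for the whole simulation.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_stands = 77, L = 436, maf_range = c(0.2, 0.5),
                       founders_per_stand = 2, t = 0.02,
                       mating_kernel_sigma = 1, seed_dispersal_sigma = 0.5,
                       migration_rate = 0.005, generations = 40,
                       recomb_rate = 1, capacity = 30, stand_extent = 20,
                       chrom_lengths = c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 27.0e6),
                       landscape_size = 20000, site_type = NULL, seed = 1) {
  if (L < 1) stop("L must be >= 1")
  if (generations < 1) stop("generations must be >= 1")
  if (diff(range(maf_range)) < 0 || maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be within (0, 0.5]")
  }
  probs <- c(t, migration_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!length(t) %in% c(1L, n_stands)) stop("t must be scalar or one value per stand")
  if (!length(capacity) %in% c(1L, n_stands)) stop("capacity must be scalar or one value per stand")
  structure(list(
    n_stands = n_stands, L = L, maf_range = maf_range,
    founders_per_stand = founders_per_stand,
    t = rep_len(t, n_stands), mating_kernel_sigma = mating_kernel_sigma,
    seed_dispersal_sigma = seed_dispersal_sigma,
    migration_rate = migration_rate, generations = generations,
    recomb_rate = recomb_rate, capacity = rep_len(as.integer(capacity), n_stands),
    stand_extent = stand_extent, chrom_lengths = chrom_lengths,
    landscape_size = landscape_size, site_type = site_type, seed = seed
  ), class = "sim_config")
}

#' Generate founder haplotypes and a marker map
#'
#' Places L biallelic markers uniformly at random over the configured
#' chromosomes (probability proportional to length) and draws one founder
#' haplotype pool: per marker an allele-b frequency q ~ U(maf_range), per
#' haplotype allele b with probability q. Uses the current RNG state;
#' \code{\link{simulate_stands}} seeds it from the config.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{map} (a \code{\link{marker_map}}), \code{haplotypes}
#'   (pool matrix, n_stands * founders_per_stand rows), \code{q} (founder
#'   allele-b frequencies in map order).
#' @export
generate_founders <- function(config) {
  cl <- config$chrom_lengths
  chrom <- sample.int(length(cl), config$L, replace = TRUE, prob = cl)
  pos <- floor(stats::runif(config$L, 1, cl[chrom])) + 0
  # regenerate duplicate positions within a chromosome until unique
  repeat {
    dup <- duplicated(paste(chrom, pos))
    if (!any(dup)) break
    pos[dup] <- floor(stats::runif(sum(dup), 1, cl[chrom[dup]]))
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  map <- marker_map(sprintf("M%04d", seq_len(config$L)), chrom, pos)
  q <- stats::runif(config$L, config$maf_range[1], config$maf_range[2])
  n_haps <- config$n_stands * config$founders_per_stand
  haplotypes <- matrix(
    stats::rbinom(n_haps * config$L, 1L, rep(q, each = n_haps)),
    nrow = n_haps, ncol = config$L
  )
  storage.mode(haplotypes) <- "integer"
  list(map = map, haplotypes = haplotypes, q = q)
}

# one gamete from a diploid parent: Poisson crossovers per chromosome,
# uniform positions, random starting haplotype per chromosome. Returns
# list(hap, xo). Fully homozygous parents short-circuit (no crossover
# draw; distributionally identical).
make_gamete <- function(hapA, hapB, map_chrom, map_pos, chrom_lengths, recomb_rate) {
  if (all(hapA == hapB)) return(list(hap = hapA, xo = NULL))
  hap <- hapA
  xo <- vector("list", length(chrom_lengths))
  for (ch in seq_along(chrom_lengths)) {
    sel <- map_chrom == ch
    if (!any(sel)) next
    nx <- stats::rpois(1, recomb_rate)
    br <- if (nx > 0) sort(stats::runif(nx, 0, chrom_lengths[ch])) else numeric(0)
    xo[[ch]] <- br
    start <- sample.int(2L, 1L) - 1L
    parity <- (start + findInterval(map_pos[sel], br)) %% 2L
    hap[sel] <- ifelse(parity == 0L, hapA[sel], hapB[sel])
  }
  list(hap = hap, xo = xo)
}

#' Run the forward-in-time selfing metapopulation simulation
#'
#' Discrete non-overlapping generations at fixed carrying capacity. Each
#' offspring draws its ovule parent uniformly from the stand; with
#' probability t the pollen parent is a stand-mate (excluding the mother)
#' weighted by a Gaussian kernel of the configured scale, otherwise the
#' ovule self-fertilises. Meiosis applies Poisson crossovers per
#' chromosome; offspring are placed near the mother; with probability
#' \code{migration_rate} per stand per generation one immigrant offspring
#' from a random other stand replaces a random resident. Pedigree and
#' event logs record every parentage, outcross and migration; crossover
#' positions are logged for the final generation.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{sim_dataset}: map, stands
#'   (\code{\link{stand_table}}), pop (final-generation individuals:
#'   per-stand haplotype matrices, ids, coordinates), parents (previous
#'   generation, same layout), pedigree (data.frame id, gen, stand_id,
#'   mother_id, father_id, selfed, immigrant), events (outcross and
#'   migration logs), crossovers (final generation), founders, config.
#' @export
simulate_stands <- function(config) {
  set.seed(config$seed)
  fd <- generate_founders(config)
  map <- fd$map
  n_st <- config$n_stands
  ext <- config$stand_extent

  site_type <- config$site_type
  if (is.null(site_type)) {
    site_type <- rep_len(c("rural", "urban"), n_st)[sample.int(n_st)]
  }
  centers <- matrix(stats::runif(2 * n_st, 0, config$landscape_size), ncol = 2)
  stands <- stand_table(
    sprintf("S%02d", seq_len(n_st)), site_type,
    centers[, 1], centers[, 2], config$capacity
  )

  # initial population: capacity individuals per stand, doubled founder
  # haplotypes clustered around per-founder patch centres
  pop <- vector("list", n_st)
  pedigree <- list()
  for (s in seq_len(n_st)) {
    K <- config$capacity[s]
    f_rows <- ((s - 1L) * config$founders_per_stand + 1L):(s * config$founders_per_stand)
    pick <- sample(rep_len(seq_along(f_rows), K))
    centres_f <- matrix(stats::runif(2 * length(f_rows), 0, ext), ncol = 2)
    hap <- fd$haplotypes[f_rows[pick], , drop = FALSE]
    ids <- sprintf("g0_s%02d_%03d", s, seq_len(K))
    pop[[s]] <- list(
      hapA = hap, hapB = hap, ids = ids,
      x = centres_f[pick, 1] + stats::rnorm(K, 0, config$seed_dispersal_sigma),
      y = centres_f[pick, 2] + stats::rnorm(K, 0, config$seed_dispersal_sigma),
      founder = f_rows[pick]
    )
    pedigree[[length(pedigree) + 1L]] <- data.frame(
      id = ids, gen = 0L, stand_id = stands$stand_id[s],
      mother_id = sprintf("F%03d", f_rows[pick]),
      father_id = sprintf("F%03d", f_rows[pick]),
      selfed = TRUE, immigrant = FALSE, stringsAsFactors = FALSE
    )
  }

  outcross_log <- list()
  migration_log <- list()
  crossovers <- list()
  parents <- NULL

  for (gen in seq_len(config$generations)) {
    final <- gen == config$generations
    newpop <- vector("list", n_st)
    for (s in seq_len(n_st)) {
      K <- config$capacity[s]
      cur <- pop[[s]]
      n_cur <- nrow(cur$hapA)
      hapA <- matrix(0L, K, config$L)
      hapB <- matrix(0L, K, config$L)
      xs <- ys <- numeric(K)
      ids <- sprintf("g%d_s%02d_%03d", gen, s, seq_len(K))
      mo_id <- fa_id <- character(K)
      selfed <- logical(K)
      mothers <- sample.int(n_cur, K, replace = TRUE)
      outx <- stats::runif(K) < config$t[s]
      for (k in seq_len(K)) {
        m <- mothers[k]
        f <- m
        if (outx[k] && n_cur > 1L) {
          if (is.infinite(config$mating_kernel_sigma)) {
            f <- sample(setdiff(seq_len(n_cur), m), 1L)
          } else {
            d2 <- (cur$x - cur$x[m])^2 + (cur$y - cur$y[m])^2
            w <- exp(-d2 / (2 * config$mating_kernel_sigma^2))
            w[m] <- 0
            if (sum(w) <= 0) w[-m] <- 1
            f <- sample.int(n_cur, 1L, prob = w)
          }
        }
        g1 <- make_gamete(cur$hapA[m, ], cur$hapB[m, ], map$chrom, map$pos,
          config$chrom_lengths, config$recomb_rate)
        g2 <- make_gamete(cur$hapA[f, ], cur$hapB[f, ], map$chrom, map$pos,
          config$chrom_lengths, config$recomb_rate)
        hapA[k, ] <- g1$hap
        hapB[k, ] <- g2$hap
        xs[k] <- cur$x[m] + stats::rnorm(1, 0, config$seed_dispersal_sigma)
        ys[k] <- cur$y[m] + stats::rnorm(1, 0, config$seed_dispersal_sigma)
        mo_id[k] <- cur$ids[m]; fa_id[k] <- cur$ids[f]
        selfed[k] <- f == m
        if (final) {
          crossovers[[ids[k]]] <- list(maternal = g1$xo, paternal = g2$xo)
        }
        if (!selfed[k]) {
          outcross_log[[length(outcross_log) + 1L]] <- data.frame(
            gen = gen, stand_id = stands$stand_id[s], child = ids[k],
            mother = mo_id[k], father = fa_id[k], stringsAsFactors = FALSE
          )
        }
      }
      newpop[[s]] <- list(hapA = hapA, hapB = hapB, ids = ids, x = xs, y = ys)
      pedigree[[length(pedigree) + 1L]] <- data.frame(
        id = ids, gen = gen, stand_id = stands$stand_id[s],
        mother_id = mo_id, father_id = fa_id, selfed = selfed,
        immigrant = FALSE, stringsAsFactors = FALSE
      )
    }
    # whole-seed migration between stands
    if (config$migration_rate > 0 && n_st > 1L) {
      for (s in seq_len(n_st)) {
        if (stats::runif(1) >= config$migration_rate) next
        src <- sample(setdiff(seq_len(n_st), s), 1L)
        donor <- sample.int(nrow(newpop[[src]]$hapA), 1L)
        slot <- sample.int(nrow(newpop[[s]]$hapA), 1L)
        mig_id <- sprintf("g%d_s%02d_m%03d", gen, s, slot)
        old_id <- newpop[[s]]$ids[slot]
        newpop[[s]]$hapA[slot, ] <- newpop[[src]]$hapA[donor, ]
        newpop[[s]]$hapB[slot, ] <- newpop[[src]]$hapB[donor, ]
        newpop[[s]]$ids[slot] <- mig_id
        newpop[[s]]$x[slot] <- stats::runif(1, 0, ext)
        newpop[[s]]$y[slot] <- stats::runif(1, 0, ext)
        donor_id <- newpop[[src]]$ids[donor]
        ped_tail <- pedigree[[length(pedigree) - n_st + s]]
        drop_row <- ped_tail$id == old_id
        src_ped <- pedigree[[length(pedigree) - n_st + src]]
        src_row <- src_ped[src_ped$id == donor_id, ]
        src_row$id <- mig_id
        src_row$stand_id <- stands$stand_id[s]
        src_row$immigrant <- TRUE
        ped_tail <- rbind(ped_tail[!drop_row, ], src_row)
        pedigree[[length(pedigree) - n_st + s]] <- ped_tail
        if (final) {
          crossovers[[mig_id]] <- crossovers[[donor_id]]
          crossovers[[old_id]] <- NULL
        }
        migration_log[[length(migration_log) + 1L]] <- data.frame(
          gen = gen, from = stands$stand_id[src], to = stands$stand_id[s],
          child = mig_id, source_individual = donor_id, stringsAsFactors = FALSE
        )
      }
    }
    parents <- pop
    pop <- newpop
  }

  structure(list(
    map = map, stands = stands, pop = pop, parents = parents,
    pedigree = do.call(rbind, pedigree),
    events = list(
      outcross = if (length(outcross_log)) do.call(rbind, outcross_log) else NULL,
      migration = if (length(migration_log)) do.call(rbind, migration_log) else NULL
    ),
    crossovers = crossovers, founders = fd, config = config
  ), class = "sim_dataset")
}

#' Survey sampling of a simulated metapopulation
#'
#' Mirrors the field design: stands of 20 plants or fewer are sampled
#' completely; larger stands contribute a uniform random 20 to
#' \code{per_stand_cap} individuals. Transect order is the within-stand
#' x-coordinate rank of the sampled plants.
#'
#' @param dataset a \code{\link{simulate_stands}} result.
#' @param per_stand_cap maximum sample per stand (default 30).
#' @param seed optional RNG seed (sampling only).
#' @param year value recorded in the sample metadata (default the final
#'   generation number).
#' @return A \code{\link{genotype_table}} whose sample ids are the
#'   simulator individual ids (so truth can be joined).
#' @export
sample_survey <- function(dataset, per_stand_cap = 30, seed = NULL, year = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(year)) year <- dataset$config$generations
  rows <- list(); calls <- list()
  for (s in seq_along(dataset$pop)) {
    st <- dataset$pop[[s]]
    n <- nrow(st$hapA)
    take <- if (n <= 20L) seq_len(n) else {
      hi <- min(per_stand_cap, n)
      m <- if (hi > 20L) sample(20L:hi, 1L) else 20L
      sort(sample.int(n, m))
    }
    tr <- rank(st$x[take], ties.method = "first") - 1L
    rows[[s]] <- data.frame(
      sample_id = st$ids[take],
      stand_id = dataset$stands$stand_id[s],
      year = year, transect_index = as.integer(tr),
      stringsAsFactors = FALSE
    )
    calls[[s]] <- st$hapA[take, , drop = FALSE] + st$hapB[take, , drop = FALSE]
  }
  genotype_table(do.call(rbind, calls), do.call(rbind, rows), dataset$map)
}
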