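#' Configuration for a full desk-scale analysis run
#'
#' Bundles the input (a simulation config, or paths to genotype, marker
#' map and stand tables), analysis thresholds and seeds. All stochastic
#' stages derive their own seed from \code{master_seed} plus a fixed
#' offset, so stages can be rerun independently with identical results.
#'
#' @param sim a \code{\link{sim_config}}, or NULL when reading files.
#' @param genotype_path,map_path,stands_path input TSVs (used when
#'   \code{sim} is NULL).
#' @param min_n minimum stand size for diversity statistics (default 10).
#' @param subsample_size,n_reps,bootstrap_reps subsampling settings.
#' @param classes a \code{\link{distance_classes}} spec for correlograms.
#' @param n_perms permutations for spatial tests (default 500).
#' @param k_max,gap_B gap-statistic settings.
#' @param master_seed seed from which stage seeds are derived.
#' @param out_dir optional directory; when given, all report tables are
#'   written there as TSV plus a JSON manifest.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, genotype_path = NULL, map_path = NULL,
                       stands_path = NULL, min_n = 10, subsample_size = 10,
                       n_reps = 100, bootstrap_reps = 1000,
                       classes = distance_classes(10, 3.84), n_perms = 500,
                       k_max = 8, gap_B = 100, master_seed = 1,
                       out_dir = NULL) {
  if (is.null(sim) && (is.null(genotype_path) || is.null(map_path) || is.null(stands_path))) {
    stop("provide either a sim_config or all three input paths")
  }
  structure(list(
    sim = sim, genotype_path = genotype_path, map_path = map_path,
    stands_path = stands_path, min_n = min_n, subsample_size = subsample_size,
    n_reps = n_reps, bootstrap_reps = bootstrap_reps, classes = classes,
    n_perms = n_perms, k_max = k_max, gap_B = gap_B,
    master_seed = master_seed, out_dir = out_dir
  ), class = "run_config")
}

# stage seeds derived from the master seed; kept well below 2^31
stage_seed <- function(config, offset) (config$master_seed * 1000L + offset) %% 2147483647L

#' Run the complete analysis pipeline
#'
#' Simulates (or ingests) a stand-structured genotype dataset, then runs
#' the genotype census, size-corrected diversity and outcrossing
#' estimation, pairwise differentiation, spatial structure, transect
#' clustering and nonparametric clustering stages, returning a bundle of
#' report tables. Each stage is logged with its parameters and seed.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress stage messages (default TRUE).
#' @return list of class \code{report_bundle}: \code{stand_summary}
#'   (per-stand census), \code{mlg_frequencies}, \code{diversity}
#'   (subsample-corrected per-stand statistics with OC), \code{excluded}
#'   (stands below min_n), \code{shared_mlgs}, \code{fst} (mean pairwise
#'   theta and the matrix), \code{mantel}, \code{morans},
#'   \code{distogram}, \code{aggregation}, \code{transect},
#'   \code{regression}, \code{site_comparison} (He and F_IS),
#'   \code{within_between}, \code{clustering} (newick + gap), and
#'   \code{manifest} (stage log).
#' @export
run_all <- function(config, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  manifest <- list(master_seed = config$master_seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  say("stage: input")
  if (!is.null(config$sim)) {
    ds <- stage("simulate", simulate_stands(config$sim))
    table <- stage("survey", sample_survey(ds, seed = stage_seed(config, 1L)))
    stands <- ds$stands
    log_stage("simulate", seed = config$sim$seed, n_stands = config$sim$n_stands)
  } else {
    map <- stage("input", read_marker_map(config$map_path))
    table <- stage("input", read_genotype_table(config$genotype_path, map))
    stands <- stage("input", read_stand_table(config$stands_path))
    ds <- NULL
  }

  say("stage: census")
  mlgs <- stage("mlg", identify_mlgs(table))
  census <- stage("census", stand_census(table, mlgs))
  census <- merge(census, as.data.frame(stands)[, c("stand_id", "site_type", "x", "y")],
    by = "stand_id", sort = TRUE)
  log_stage("census", n_mlg = mlgs$n_mlg)

  say("stage: diversity")
  div_seed <- stage_seed(config, 2L)
  diversity <- stage("diversity", subsampled_stand_stats(
    table, subsample_size = config$subsample_size, n_reps = config$n_reps,
    bootstrap_reps = config$bootstrap_reps, min_n = config$min_n,
    seed = div_seed
  ))
  diversity <- merge(diversity, as.data.frame(stands)[, c("stand_id", "site_type")],
    by = "stand_id", sort = TRUE)
  excluded <- setdiff(census$stand_id, diversity$stand_id)
  log_stage("diversity", seed = div_seed, subsample = config$subsample_size,
    reps = config$n_reps, boot = config$bootstrap_reps, min_n = config$min_n)

  say("stage: differentiation")
  fst_mat <- stage("fst", pairwise_fst(table, min_n = config$min_n))
  mean_fst <- mean(fst_mat[lower.tri(fst_mat)], na.rm = TRUE)
  shared <- stage("shared_mlgs", shared_mlgs_between_stands(mlgs, stands))

  say("stage: spatial")
  sp_seed <- stage_seed(config, 3L)
  used <- rownames(fst_mat)
  geo <- as.matrix(stats::dist(as.data.frame(stands)[match(used, stands$stand_id), c("x", "y")]))
  dimnames(geo) <- dimnames(fst_mat)
  mantel <- stage("mantel", tryCatch(
    mantel_test(fst_mat, geo, n_perms = config$n_perms, seed = sp_seed),
    error = function(e) NULL
  ))
  coords <- as.data.frame(stands)[match(table$samples$stand_id, stands$stand_id), c("x", "y")]
  morans <- stage("morans", morans_i_correlogram(table, coords, config$classes,
    n_perms = config$n_perms, seed = sp_seed + 1L))
  distog <- stage("distogram", dg_distogram(table, coords, config$classes,
    n_perms = config$n_perms, seed = sp_seed + 2L))
  aggr <- stage("aggregation", aggregation_index(unique(as.matrix(coords)),
    seed = sp_seed + 3L))
  log_stage("spatial", seed = sp_seed, perms = config$n_perms)

  say("stage: transect")
  tstats <- stage("transect", transect_stats(table, mlgs))
  regression <- stage("regression", tryCatch(
    cluster_vs_fis_regression(tstats, diversity),
    error = function(e) NULL
  ))

  say("stage: site comparison")
  site_cmp <- stage("site_comparison", tryCatch(list(
    He = compare_site_types(diversity, stands, stat = "He"),
    F_IS = compare_site_types(diversity, stands, stat = "F_IS")
  ), error = function(e) NULL))

  say("stage: clustering")
  cl_seed <- stage_seed(config, 4L)
  nr <- stage("clustering", nonredundant_mlgs(table, mlgs))
  D <- stage("clustering", genetic_distance_matrix(nr))
  wb <- stage("within_between", within_between_distributions(
    D, sub("\\..*$", "", rownames(D))
  ))
  hc <- stage("clustering", cluster_genotypes(D))
  k_max <- min(config$k_max, nrow(nr) - 1L)
  gap <- stage("gap", if (k_max >= 2) {
    gap_statistic(nr, k_max = k_max, B = config$gap_B, seed = cl_seed)
  } else NULL)
  log_stage("clustering", seed = cl_seed, k_max = k_max, B = config$gap_B)

  bundle <- structure(list(
    stand_summary = census,
    mlg_frequencies = mlgs$freq,
    diversity = diversity,
    excluded = excluded,
    shared_mlgs = shared,
    fst = list(mean_pairwise = mean_fst, matrix = fst_mat),
    mantel = mantel,
    morans = morans,
    distogram = distog,
    aggregation = aggr,
    transect = tstats,
    regression = regression,
    site_comparison = site_cmp,
    within_between = wb,
    clustering = list(newick = as_newick(hc), gap = gap),
    manifest = manifest,
    truth = if (!is.null(ds)) list(
      pedigree = ds$pedigree, events = ds$events
    ) else NULL
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to a directory of TSV/Newick/JSON files
#'
#' @param bundle a \code{\link{run_all}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) utils::write.table(df, file.path(dir, name),
    sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bundle$stand_summary, "stand_summary.tsv")
  wt(bundle$mlg_frequencies, "mlg_frequencies.tsv")
  wt(bundle$diversity, "diversity.tsv")
  wt(bundle$shared_mlgs, "shared_mlgs.tsv")
  wt(as.data.frame(bundle$morans), "morans_correlogram.tsv")
  wt(as.data.frame(bundle$distogram), "dg_distogram.tsv")
  wt(bundle$transect, "transect_stats.tsv")
  if (!is.null(bundle$regression)) wt(bundle$regression, "cluster_fis_regression.tsv")
  writeLines(bundle$clustering$newick, file.path(dir, "genotypes.nwk"))
  utils::write.table(bundle$fst$matrix, file.path(dir, "pairwise_fst.tsv"),
    sep = "\t", quote = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Simulation scenario at the scale of the original survey design
#'
#' Returns a \code{\link{sim_config}} for 77 stands and 436 markers with
#' heterogeneous per-stand outcrossing (urban stands near zero, rural
#' stands up to ~15% per ovule), small urban and larger rural carrying
#' capacities, rare migration and tight within-stand dispersal kernels —
#' the regime of mostly monotypic-or-simple urban stands, diverse rural
#' stands, and strong stand differentiation.
#'
#' @param seed RNG seed (also used to draw the per-stand rates).
#' @param generations generations to iterate (default 40).
#' @return A \code{\link{sim_config}}.
#' @export
survey_scale_scenario <- function(seed = 1, generations = 40) {
  set.seed(seed %% 2147483647)
  n_stands <- 77
  site_type <- rep_len(c("rural", "urban"), n_stands)[sample.int(n_stands)]
  t <- ifelse(site_type == "rural",
    stats::runif(n_stands, 0, 0.15),
    stats::runif(n_stands, 0, 0.01)
  )
  capacity <- ifelse(site_type == "rural",
    sample(15:40, n_stands, replace = TRUE),
    sample(3:25, n_stands, replace = TRUE)
  )
  sim_config(
    n_stands = n_stands, L = 436, founders_per_stand = 3, t = t,
    mating_kernel_sigma = 1, seed_dispersal_sigma = 0.5,
    migration_rate = 0.005, generations = generations, capacity = capacity,
    site_type = site_type, seed = seed
  )
}
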