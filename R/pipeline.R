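#' Configuration for a full factorial simulation experiment
#'
#' One experiment crosses ILS conditions (target gene-tree discordance
#' fractions) with locus counts, simulating `n_replicates` trait datasets per
#' cell and running the downstream analyses: summary moments, BM rate and
#' lambda estimation (>= 4 species), the pair-versus-rest phylogenetic ANOVA
#' screen and the threshold-trait classification (5 species).
#'
#' @param tree A `"species_tree"`, `"phylo"`, Newick string, or path to a
#'   Newick file.
#' @param targets Target discordance fractions, e.g. `c(0, .2, .4, .6, .8)`.
#' @param locus_counts Numbers of loci controlling the trait.
#' @param n_replicates Replicates per (condition, locus count) cell (>= 2).
#' @param theta Population mutation parameter per locus.
#' @param sigma_M2 Total per-mutation effect variance (scaled by 1/L per
#'   locus).
#' @param alpha ANOVA significance level.
#' @param n_null_sims Null simulations per ANOVA grouping.
#' @param calib_n_sims Gene trees per Monte-Carlo calibration step.
#' @param seed Root seed; everything downstream is derived from it.
#' @param fast If `TRUE`, a reduced profile for quick runs: caps
#'   `n_replicates` at 200, `n_null_sims` at 500 and `calib_n_sims` at 4000.
#' @return An `"experiment_config"` list.
#' @export
experiment_config <- function(tree, targets, locus_counts,
                              n_replicates = 1000L, theta = 4, sigma_M2 = 1,
                              alpha = 0.05, n_null_sims = 1000L,
                              calib_n_sims = 10000L, seed = 1L,
                              fast = FALSE) {
  if (is.character(tree) && length(tree) == 1L && file.exists(tree))
    tree <- readLines(tree, warn = FALSE)[1L]
  st <- as_species_tree(tree)
  stopifnot(length(targets) >= 1L, length(locus_counts) >= 1L,
            n_replicates >= 2L, theta > 0, sigma_M2 > 0,
            alpha > 0, alpha < 1, n_null_sims >= 1L)
  if (fast) {
    n_replicates <- min(n_replicates, 200L)
    n_null_sims <- min(n_null_sims, 500L)
    calib_n_sims <- min(calib_n_sims, 4000L)
  }
  structure(list(tree = st, targets = as.numeric(targets),
                 locus_counts = as.integer(locus_counts),
                 n_replicates = as.integer(n_replicates),
                 theta = theta, sigma_M2 = sigma_M2, alpha = alpha,
                 n_null_sims = as.integer(n_null_sims),
                 calib_n_sims = as.integer(calib_n_sims),
                 seed = as.integer(seed), fast = fast),
            class = "experiment_config")
}

#' Run the factorial discordance experiment
#'
#' Calibrates one ancestral multiplier per target discordance level (shared
#' across locus counts), simulates each (condition, locus count) cell, and
#' tabulates: across-replicate trait moments, realized discordance, mean ML
#' rate and lambda estimates (with and without lambda), the mean number of
#' significant pair-versus-rest ANOVA tests per replicate, and the threshold
#' incongruence frequency. Deterministic given the config seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory: writes `moments.csv`, `fits.csv`,
#'   `anova.csv`, `threshold.csv` and `manifest.json`.
#' @return (Invisibly) a list of data frames `moments`, `fits`, `anova`,
#'   `threshold`, plus `conditions`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  st <- config$tree
  nt <- length(st$phy$tip.label)
  tips <- st$phy$tip.label
  seeds <- with_seed(config$seed, spawn_seeds(2L +
    length(config$targets) * length(config$locus_counts) * 2L))
  conditions <- calibrate_conditions(st, config$targets,
                                     n_sims = config$calib_n_sims,
                                     seed = seeds[1L])
  moments <- fits <- anova_tab <- thr_tab <- list()
  si <- 2L
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    for (L in config$locus_counts) {
      si <- si + 2L
      cell <- sprintf("target=%g,L=%d", cond$target, L)
      res <- tryCatch({
        ds <- simulate_trait_dataset(
          st, cond, n_loci = L,
          model = mutation_model(config$theta, config$sigma_M2),
          n_replicates = config$n_replicates, seed = seeds[si - 1L])
        mom <- summary_moments(ds)
        S <- mom$vcv
        pairs <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
        ## fourth-moment standard error of each sample moment
        ctr <- scale(ds$values, center = TRUE, scale = FALSE)
        mse <- apply(pairs, 1L, function(ij)
          stats::sd(ctr[, ij[1L]] * ctr[, ij[2L]]) / sqrt(nrow(ctr)))
        mrow <- data.frame(
          target = cond$target, multiplier = cond$multiplier, n_loci = L,
          discordance = empirical_discordance(ds),
          species_i = tips[pairs[, 1L]], species_j = tips[pairs[, 2L]],
          moment = S[pairs], moment_se = mse,
          normalized = (S / S[1L, 1L])[pairs],
          stringsAsFactors = FALSE)
        frow <- arow <- trow <- NULL
        if (nt >= 4L) {
          f0 <- apply(ds$values, 1L, function(z)
            fit_sigma2(st, stats::setNames(z, tips))$sigma2)
          fl <- apply(ds$values, 1L, function(z) {
            ft <- fit_lambda_sigma2(st, stats::setNames(z, tips))
            c(ft$sigma2, ft$lambda)
          })
          frow <- data.frame(
            target = cond$target, multiplier = cond$multiplier, n_loci = L,
            mean_sigma2 = mean(f0), mean_lambda = mean(fl[2L, ]),
            mean_sigma2_with_lambda = mean(fl[1L, ]))
        }
        if (nt == 5L) {
          scr <- count_significant_groupings(
            st, ds, alpha = config$alpha,
            n_null_sims = config$n_null_sims, seed = seeds[si])
          arow <- data.frame(
            target = cond$target, multiplier = cond$multiplier, n_loci = L,
            mean_significant = scr$mean_count, alpha = config$alpha,
            n_null_sims = config$n_null_sims)
          pt <- discretize(ds, compute_threshold(ds), st)
          trow <- data.frame(
            target = cond$target, multiplier = cond$multiplier, n_loci = L,
            cutoff = pt$cutoff,
            incongruence = incongruence_frequency(pt),
            n_informative_21 = sum(pt$table$count[
              pt$table$n_derived == 2L & pt$table$class != "uninformative"]))
        }
        list(mrow = mrow, frow = frow, arow = arow, trow = trow)
      }, error = function(e) {
        warning("cell ", cell, " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(res)) next
      moments[[cell]] <- res$mrow
      fits[[cell]] <- res$frow
      anova_tab[[cell]] <- res$arow
      thr_tab[[cell]] <- res$trow
    }
  }
  out <- list(moments = do.call(rbind, c(moments, make.row.names = FALSE)),
              fits = if (length(Filter(Negate(is.null), fits)))
                do.call(rbind, c(fits, make.row.names = FALSE)) else NULL,
              anova = if (length(Filter(Negate(is.null), anova_tab)))
                do.call(rbind, c(anova_tab, make.row.names = FALSE)) else NULL,
              threshold = if (length(Filter(Negate(is.null), thr_tab)))
                do.call(rbind, c(thr_tab, make.row.names = FALSE)) else NULL,
              conditions = conditions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nmf in c("moments", "fits", "anova", "threshold"))
      if (!is.null(out[[nmf]]))
        utils::write.csv(out[[nmf]], file.path(out_dir, paste0(nmf, ".csv")),
                         row.names = FALSE)
    manifest <- list(
      package = "mscquant",
      version = as.character(utils::packageVersion("mscquant")),
      tree = write_newick(st$phy),
      targets = config$targets,
      multipliers = vapply(conditions, `[[`, 0, "multiplier"),
      locus_counts = config$locus_counts,
      n_replicates = config$n_replicates, theta = config$theta,
      sigma_M2 = config$sigma_M2, alpha = config$alpha,
      n_null_sims = config$n_null_sims, calib_n_sims = config$calib_n_sims,
      seed = config$seed, fast = config$fast)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Covariances normalized by the first species' variance
#'
#' @param moments Output of [summary_moments()] (or a covariance matrix).
#' @return Matrix of `Cov(i, j) / Var(A)` where A is the first species.
#' @export
normalized_covariances <- function(moments) {
  S <- if (is.list(moments)) moments$vcv else moments
  if (!is.matrix(S)) stop("expected a covariance matrix", call. = FALSE)
  if (S[1L, 1L] <= 0)
    stop("Var of the first species is zero: normalization undefined",
         call. = FALSE)
  S / S[1L, 1L]
}
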