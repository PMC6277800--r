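## End-to-end orchestration: simulate/load -> motion exclusion -> FC
## features + PCA -> wavelet entropy (with optional r0 grid) -> coupling
## model -> statistics, with a machine-readable report.

#' Build a run configuration
#'
#' Defaults mirror the analysis' stated parameters: FD threshold 0.3 mm,
#' >10% flagged frames exclusion, 0.01-0.10 Hz band, r0 = 0.2 (or
#' `"auto"` for grid selection over 0.10-0.30 by 0.05), template length
#' m = 1, 10-fold CV over a 21-point alpha grid.
#'
#' @param cohort_dir directory with an on-disk cohort (`manifest.tsv`,
#'   `roi_map.tsv`, ...), or `NULL` to simulate.
#' @param simulate a [sim_config()] used when `cohort_dir` is `NULL`.
#' @param out_dir where stage outputs and `report.json` are written
#'   (`NULL`: in-memory only).
#' @param fd_threshold,max_flag_fraction motion exclusion parameters.
#' @param band,r0,wavelet,m entropy parameters; `r0 = "auto"` runs the
#'   grid `seq(0.10, 0.30, 0.05)`.
#' @param alpha_grid,n_folds elastic-net search parameters.
#' @param seed root seed; stage seeds are derived as `seed + offset`
#'   (simulation +0, CV folds +1).
#' @return list of class `rsnec_config`.
#' @export
run_config <- function(cohort_dir = NULL, simulate = sim_config(),
                       out_dir = NULL,
                       fd_threshold = 0.3, max_flag_fraction = 0.10,
                       band = c(0.01, 0.10), r0 = 0.2, wavelet = "sym8",
                       m = 1L, alpha_grid = seq(0, 1, by = 0.05),
                       n_folds = 10L, seed = 1L) {
  structure(list(cohort_dir = cohort_dir, simulate = simulate,
                 out_dir = out_dir, fd_threshold = fd_threshold,
                 max_flag_fraction = max_flag_fraction, band = band,
                 r0 = r0, wavelet = wavelet, m = as.integer(m),
                 alpha_grid = alpha_grid, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "rsnec_config")
}

stage_msg <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full coupling analysis
#'
#' Stages, in order: simulate (or load), validate + motion exclusion,
#' FC features + PCA, wavelet entropy (grid r0 selection if requested),
#' elastic-net coupling model, statistics (rank-sum on c1 and c1H,
#' group-by-c1H interaction, severity correlations with c1H and c1).
#' Re-running with an identical config and seed reproduces the report
#' exactly. Any stage failure aborts with the stage name in the error.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress (default `TRUE`).
#' @return list of class `rsnec_run`: `report` (plain list, also written
#'   to `out_dir/report.json`), `cohort`, `features`, `pca`, `entropy`,
#'   `model`, `stats`, `truth` (when simulated).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "rsnec_config"))
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  truth <- NULL
  cohort <- with_stage("cohort", {
    if (is.null(config$cohort_dir)) {
      sim <- config$simulate
      sim$seed <- config$seed
      stage_msg(verbose, "cohort", "simulating %d + %d subjects",
                sim$n_control, sim$n_case)
      gen <- generate_cohort(sim,
                             dir = if (is.null(config$out_dir)) NULL
                                   else file.path(config$out_dir, "cohort"))
      truth <- gen$truth
      gen$cohort
    } else {
      stage_msg(verbose, "cohort", "reading %s", config$cohort_dir)
      read_cohort(file.path(config$cohort_dir, "manifest.tsv"),
                  file.path(config$cohort_dir, "roi_map.tsv"))
    }
  })
  n_before <- nrow(cohort$manifest)
  cohort <- with_stage("exclusion",
    apply_exclusions(cohort, config$fd_threshold, config$max_flag_fraction))
  n_after <- nrow(cohort$manifest)
  stage_msg(verbose, "exclusion", "%d of %d subjects retained",
            n_after, n_before)
  if (n_after < 3) stop("stage 'exclusion' failed: fewer than 3 subjects",
                        call. = FALSE)

  features <- with_stage("fc", cohort_features(cohort))
  pca <- with_stage("fc", compile_and_pca(features))
  stage_msg(verbose, "fc", "c1 explains %.1f%% of feature variance",
            100 * pca$variance_explained[1])

  r0_grid <- seq(0.10, 0.30, by = 0.05)
  ent <- with_stage("entropy", {
    if (identical(config$r0, "auto")) {
      stage_msg(verbose, "entropy", "r0 grid %s",
                paste(r0_grid, collapse = "/"))
      grids <- cohort_entropy(cohort, r0 = r0_grid, m = config$m,
                              band = config$band, wavelet = config$wavelet)
      sel <- select_r0(grids)
      list(profile = grids[[format(sel$r0, trim = TRUE)]],
           r0 = sel$r0, ranges = sel$ranges)
    } else {
      list(profile = cohort_entropy(cohort, r0 = config$r0, m = config$m,
                                    band = config$band,
                                    wavelet = config$wavelet),
           r0 = config$r0, ranges = NULL)
    }
  })
  stage_msg(verbose, "entropy", "r0 = %.2f", ent$r0)

  X_H <- ent$profile
  complete <- stats::complete.cases(X_H)
  dropped <- rownames(X_H)[!complete]
  if (length(dropped))
    stage_msg(verbose, "model", "dropping %d subject(s) with missing network entropy",
              length(dropped))
  X_H <- X_H[complete, , drop = FALSE]
  c1 <- pca$c1[complete]
  groups <- cohort$manifest$group[complete]
  severity <- cohort$manifest$severity[complete]

  model <- with_stage("model",
    fit_elastic_net(X_H, c1, alpha_grid = config$alpha_grid,
                    n_folds = config$n_folds, seed = config$seed + 1L))
  stage_msg(verbose, "model", "alpha = %.2f, lambda = %.4g, CV MSE = %.4g",
            model$alpha, model$lambda, model$cv_mse["mean"])

  stats_out <- with_stage("stats", {
    rs_c1 <- rank_sum_test(c1, groups)
    rs_c1h <- rank_sum_test(model$c1H, groups)
    inter <- interaction_regression(c1, model$c1H, groups)
    sev_c1h <- if (sum(is.finite(severity)) >= 5)
      severity_correlation(model$c1H, severity) else NULL
    sev_c1 <- if (sum(is.finite(severity)) >= 5)
      severity_correlation(c1, severity) else NULL
    list(ranksum_c1 = rs_c1, ranksum_c1H = rs_c1h, interaction = inter,
         severity_c1H = sev_c1h, severity_c1 = sev_c1)
  })

  report <- list(
    parameters = list(
      fd_threshold = config$fd_threshold,
      max_flag_fraction = config$max_flag_fraction,
      band = config$band, r0 = ent$r0, r0_mode = config$r0,
      wavelet = config$wavelet, m = config$m,
      alpha_grid = config$alpha_grid, n_folds = config$n_folds,
      seed = config$seed),
    subjects = list(before_exclusion = n_before,
                    after_exclusion = n_after,
                    modeled = nrow(X_H),
                    dropped_missing_entropy = dropped),
    pca = list(variance_explained_c1 = unname(pca$variance_explained[1]),
               n_features = ncol(features)),
    entropy = list(r0 = ent$r0, ranges = as.list(ent$ranges)),
    model = list(alpha = model$alpha, lambda = model$lambda,
                 cv_mse = unname(model$cv_mse["mean"]),
                 cv_mse_sd = unname(model$cv_mse["sd"]),
                 beta = as.list(model$beta),
                 intercept = model$intercept),
    stats = list(
      ranksum_c1 = stats_out$ranksum_c1[c("W", "U", "p")],
      ranksum_c1H = stats_out$ranksum_c1H[c("W", "U", "p")],
      gamma3 = stats_out$interaction$gamma3,
      gamma3_p = stats_out$interaction$gamma3_p,
      severity_c1H = stats_out$severity_c1H[c("r", "p", "n")],
      severity_c1 = stats_out$severity_c1[c("r", "p", "n")]))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(data.frame(subject_id = rownames(features), features,
                         check.names = FALSE),
              file.path(config$out_dir, "features.tsv"))
    write_tsv(data.frame(subject_id = rownames(X_H),
                         c1 = c1, c1H = model$c1H, group = groups,
                         check.names = FALSE),
              file.path(config$out_dir, "scores.tsv"))
    write_tsv(data.frame(subject_id = rownames(ent$profile), ent$profile,
                         check.names = FALSE),
              file.path(config$out_dir, "entropy.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  structure(list(report = report, cohort = cohort, features = features,
                 pca = pca, entropy = ent, model = model,
                 stats = stats_out, truth = truth),
            class = "rsnec_run")
}

#' @export
print.rsnec_run <- function(x, ...) {
  r <- x$report
  cat("rsnec pipeline run\n")
  cat(sprintf("  subjects: %d -> %d after motion exclusion (%d modeled)\n",
              r$subjects$before_exclusion, r$subjects$after_exclusion,
              r$subjects$modeled))
  cat(sprintf("  c1 variance explained: %.1f%%; r0 = %.2f; alpha = %.2f\n",
              100 * r$pca$variance_explained_c1, r$entropy$r0,
              r$model$alpha))
  cat(sprintf("  rank-sum p (c1) = %.3g, (c1H) = %.3g; gamma3 = %.3g (p = %.3g)\n",
              r$stats$ranksum_c1$p, r$stats$ranksum_c1H$p,
              r$stats$gamma3, r$stats$gamma3_p))
  if (!is.null(r$stats$severity_c1H))
    cat(sprintf("  severity vs c1H: r = %.3g (p = %.3g)\n",
                r$stats$severity_c1H$r, r$stats$severity_c1H$p))
  invisible(x)
}
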