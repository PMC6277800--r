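## Synthetic cohort generator: block-structured FC over 11 RSNs,
## AR(1) temporal regularity coupled to a latent per-subject FC score,
## motion flags, and an ADOS-like severity model for cases.

default_rois_per_network <- function() {
  ## plausible split of the 264-ROI functional atlas over the 11 RSNs
  c("SM" = 30, "SM-lat" = 5, "VIS" = 31, "AUD" = 13, "DAN" = 11,
    "VAN" = 9, "CO" = 14, "DMN" = 58, "SAL" = 18, "FP" = 25, "SUB" = 50)
}

#' Default signed network contrast over the 66 feature slots
#'
#' Built from per-network signs (+1 sensory-type, -1 cognitive-type,
#' matching the direction of the primary connectivity component reported
#' for this kind of cohort): slot weight for networks (k, l) is
#' `(s_k + s_l) / 2`.
#'
#' @param networks network labels (default canonical 11).
#' @param positive networks given sign +1; all others get -1.
#' @return Named numeric vector over [slot_names()].
#' @export
default_contrast <- function(networks = canonical_networks(),
                             positive = c("SM", "SM-lat", "VIS", "AUD",
                                          "DAN", "VAN", "CO")) {
  s <- ifelse(networks %in% positive, 1, -1)
  idx <- slot_index(networks)
  w <- (s[idx$k] + s[idx$l]) / 2
  names(w) <- slot_names(networks)
  w
}

#' Simulation configuration
#'
#' Defaults follow the cohort the method was designed for: 163 controls
#' and 85 cases, 264 ROIs over 11 RSNs, TR = 2 s. Unstated quantities
#' (correlation levels, AR(1) bases, coupling strengths) are fixed
#' documented choices, not tuning knobs.
#'
#' @param n_control,n_case subject counts.
#' @param n_frames frames per subject.
#' @param tr_s repetition time, seconds.
#' @param rois_per_network named integer vector (one entry per network).
#' @param intra_corr,inter_corr baseline within-/between-network
#'   correlation.
#' @param contrast 66-slot signed weight vector `w` (default
#'   [default_contrast()]).
#' @param group_fc_shift FC shift along `w` applied to cases (negative:
#'   cases move against the sensory-positive contrast).
#' @param latent_sd sd of the per-subject latent FC score, in
#'   correlation units.
#' @param entropy_base named per-network AR(1) coefficient phi_k in
#'   [0, 1).
#' @param coupling_control,coupling_case strength with which the
#'   (standardized) latent score modulates network AR(1) coefficients;
#'   the default preset has `coupling_case <= coupling_control`.
#' @param entropy_noise_sd sd of per-network modulation noise.
#' @param severity_intercept,severity_slope,severity_noise_sd generative
#'   ADOS-like model for cases: `intercept + slope * entropy_score +
#'   noise`, truncated at 0; `severity_slope < 0` by default. The
#'   defaults are calibrated so that, at the default case coupling
#'   (entropy-score sd 0.08), severity is distributed ~10.1 +/- 5.4 with
#'   an entropy-severity correlation near -0.31 — the regime this kind
#'   of cohort exhibits.
#' @param flag_rate per-frame motion-flag probability.
#' @param fd_threshold framewise displacement threshold (mm) the flags
#'   are realized against.
#' @param band_limit length-2 Hz band the generated series are filtered
#'   into (default `c(0.01, 0.10)`, emulating preprocessed band-passed
#'   BOLD); `NULL` disables filtering (raw AR output).
#' @param seed RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_control = 163L, n_case = 85L,
                       n_frames = 150L, tr_s = 2,
                       rois_per_network = default_rois_per_network(),
                       intra_corr = 0.30, inter_corr = 0.05,
                       contrast = NULL,
                       group_fc_shift = -0.08, latent_sd = 0.04,
                       entropy_base = NULL,
                       coupling_control = 0.25, coupling_case = 0.08,
                       entropy_noise_sd = 0.03,
                       severity_intercept = 10.1, severity_slope = -21,
                       severity_noise_sd = 5.1,
                       flag_rate = 0.02, fd_threshold = 0.3,
                       band_limit = c(0.01, 0.10),
                       seed = 1L) {
  networks <- names(rois_per_network)
  if (is.null(networks)) {
    networks <- canonical_networks()[seq_along(rois_per_network)]
    names(rois_per_network) <- networks
  }
  if (any(rois_per_network < 2))
    stop("every network needs at least 2 ROIs", call. = FALSE)
  if (is.null(contrast)) {
    pos_def <- c("SM", "SM-lat", "VIS", "AUD", "DAN", "VAN", "CO")
    contrast <- default_contrast(networks,
                                 positive = intersect(pos_def, networks))
  }
  if (length(contrast) != n_slots(length(networks)))
    stop("contrast length must equal the number of feature slots",
         call. = FALSE)
  if (is.null(entropy_base))
    entropy_base <- setNames(rep(0.45, length(networks)), networks)
  if (any(entropy_base < 0 | entropy_base >= 1))
    stop("entropy_base (AR(1) phi) must lie in [0, 1)", call. = FALSE)
  cfg <- list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    n_frames = as.integer(n_frames), tr_s = tr_s,
    rois_per_network = rois_per_network, networks = networks,
    intra_corr = intra_corr, inter_corr = inter_corr,
    contrast = contrast, group_fc_shift = group_fc_shift,
    latent_sd = latent_sd, entropy_base = entropy_base,
    coupling_control = coupling_control, coupling_case = coupling_case,
    entropy_noise_sd = entropy_noise_sd,
    severity_intercept = severity_intercept,
    severity_slope = severity_slope,
    severity_noise_sd = severity_noise_sd,
    flag_rate = flag_rate, fd_threshold = fd_threshold,
    band_limit = band_limit,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  ## reject configs whose baseline target cannot be a correlation matrix
  tgt <- build_block_covariance(cfg, subject_latent = 0, group = 0L)
  ev <- min(eigen(tgt, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("baseline correlation target is not positive semidefinite",
         call. = FALSE)
  cfg
}

#' Block-structured ROI correlation target for one subject
#'
#' Within-network blocks sit at `intra_corr + shift`, between-network
#' blocks at `inter_corr + shift`, with
#' `shift = (group_fc_shift * group + subject_latent) * w_slot`.
#' Entries are clipped into `[-0.95, 0.95]` and the matrix projected to
#' the nearest positive-semidefinite correlation matrix (eigenvalue
#' clipping at 1e-8, then renormalization to unit diagonal).
#'
#' @param config a [sim_config()].
#' @param subject_latent latent FC score in correlation units.
#' @param group 0 = control, 1 = case.
#' @return R x R correlation matrix.
#' @export
build_block_covariance <- function(config, subject_latent = 0, group = 0L) {
  nets <- config$networks
  sizes <- config$rois_per_network
  membership <- rep(seq_along(nets), sizes)
  R <- length(membership)
  idx <- slot_index(nets)
  amp <- config$group_fc_shift * as.numeric(group) + subject_latent
  base <- ifelse(idx$k == idx$l, config$intra_corr, config$inter_corr)
  slot_val <- pmin(pmax(base + amp * config$contrast, -0.95), 0.95)
  ## scatter slot values into the R x R matrix
  slot_mat <- matrix(NA_real_, length(nets), length(nets))
  for (s in seq_len(nrow(idx))) {
    slot_mat[idx$k[s], idx$l[s]] <- slot_val[s]
    slot_mat[idx$l[s], idx$k[s]] <- slot_val[s]
  }
  tgt <- slot_mat[membership, membership]
  diag(tgt) <- 1
  psd_correlation(tgt)
}

## nearest-PSD repair: clip eigenvalues at eps, renormalize diagonal
psd_correlation <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  if (min(e$values) >= -eps) {
    vals <- pmax(e$values, eps)
  } else {
    vals <- pmax(e$values, eps)
  }
  m2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / outer(d, d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

## ideal (FFT brick-wall) band-pass of each column, band in Hz; the
## identical filter on every ROI leaves lag-0 cross-correlations intact
## when ROIs share an AR coefficient
bandpass_columns <- function(x, tr_s, band) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)   # two-sided frequency magnitude
  keep <- f >= band[1] & f <= band[2]
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

#' Simulate one subject's ROI series and motion record
#'
#' Each ROI in network k follows an AR(1) process with coefficient
#' `phi_k` reduced by that network's entropy modulation (higher
#' modulation -> lower phi -> less repetitive signal), with innovations
#' drawn jointly through the Cholesky factor of `cov_target` so that,
#' for matched phi within a comparison, stationary cross-correlations
#' approximate the target. Series are standardized per ROI. The FD
#' series is drawn so that the flag rate matches `flag_rate` in
#' expectation.
#'
#' @param cov_target R x R PSD correlation target.
#' @param config a [sim_config()].
#' @param entropy_modulation named per-network modulation (phi units).
#' @return list with `series` (T x R, band-limited per
#'   `config$band_limit` and standardized) and `motion` (data.frame
#'   `fd_mm`, `flag`).
#' @export
generate_subject_series <- function(cov_target, config,
                                    entropy_modulation = NULL) {
  nets <- config$networks
  sizes <- config$rois_per_network
  membership <- rep(seq_along(nets), sizes)
  R <- length(membership)
  Tn <- config$n_frames
  if (is.null(entropy_modulation))
    entropy_modulation <- setNames(rep(0, length(nets)), nets)
  phi <- pmin(pmax(config$entropy_base[membership] -
                     entropy_modulation[nets][membership], 0), 0.97)
  L <- t(chol(cov_target + diag(1e-10, R)))
  burn <- 100L
  z <- matrix(rnorm((Tn + burn) * R), nrow = Tn + burn)
  innov <- z %*% t(L)
  x <- matrix(0, Tn + burn, R)
  x[1, ] <- innov[1, ] / sqrt(pmax(1 - phi^2, 1e-6))
  for (t in 2:(Tn + burn)) x[t, ] <- phi * x[t - 1, ] + innov[t, ]
  x <- x[(burn + 1):(burn + Tn), , drop = FALSE]
  if (!is.null(config$band_limit))
    x <- bandpass_columns(x, config$tr_s, config$band_limit)
  x <- scale(x)
  attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  ## FD: lognormal bulk below threshold, exceedances with prob flag_rate
  fd <- exp(rnorm(Tn, mean = log(0.06), sd = 0.35))
  fd <- pmin(fd, config$fd_threshold * 0.95)
  hot <- runif(Tn) < config$flag_rate
  fd[hot] <- config$fd_threshold * (1.1 + rexp(sum(hot), rate = 4))
  list(series = x,
       motion = data.frame(fd_mm = fd, flag = as.integer(hot)))
}

#' Plant the cohort-level ground truth (no time series)
#'
#' Draws the latent FC score, per-network entropy modulation, and (for
#' cases) the ADOS-like severity for every subject. Used by
#' [generate_cohort()] and directly by recovery tests that do not need
#' the signals themselves.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list: `subjects` data.frame (subject_id, group, latent_z,
#'   subject_latent, entropy_score, severity), `modulation` (N x K
#'   matrix), `coupling` (named control/case), `severity_model`,
#'   `contrast`, `group_fc_shift`.
#' @export
plant_ground_truth <- function(config, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  N <- config$n_control + config$n_case
  group <- c(rep(0L, config$n_control), rep(1L, config$n_case))
  ids <- sprintf("sub%03d", seq_len(N))
  z <- rnorm(N)
  coupling <- ifelse(group == 1L, config$coupling_case,
                     config$coupling_control)
  nets <- config$networks
  sgn <- sign(config$contrast[seq_along(nets)])  # intra-slot signs
  ## modulation: coupling * z along the network sign pattern, plus noise
  mod <- outer(coupling * z, sgn) +
    matrix(rnorm(N * length(nets), sd = config$entropy_noise_sd),
           N, length(nets))
  colnames(mod) <- nets
  entropy_score <- coupling * z
  severity <- rep(NA_real_, N)
  case_idx <- which(group == 1L)
  severity[case_idx] <- pmax(0, config$severity_intercept +
    config$severity_slope * entropy_score[case_idx] +
    rnorm(length(case_idx), sd = config$severity_noise_sd))
  list(
    subjects = data.frame(subject_id = ids, group = group, latent_z = z,
                          subject_latent = config$latent_sd * z,
                          entropy_score = entropy_score,
                          severity = severity, stringsAsFactors = FALSE),
    modulation = mod,
    coupling = c(control = config$coupling_control,
                 case = config$coupling_case),
    severity_model = c(intercept = config$severity_intercept,
                       slope = config$severity_slope,
                       noise_sd = config$severity_noise_sd),
    contrast = config$contrast,
    group_fc_shift = config$group_fc_shift)
}

#' Generate a full synthetic cohort on disk
#'
#' Deterministic given `config$seed`: writes the TSV cohort layout
#' ([write_cohort()]) plus `ground_truth.json`, and returns the cohort
#' and ground truth.
#'
#' @param config a [sim_config()].
#' @param dir output directory; `NULL` keeps the cohort in memory only.
#' @return list `cohort` (an `rsnec_cohort`), `truth`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  truth <- plant_ground_truth(config)
  subj <- truth$subjects
  nets <- config$networks
  sizes <- config$rois_per_network
  roi_id <- seq_len(sum(sizes))
  map <- network_map(roi_id, rep(nets, sizes),
                     strict = identical(nets, canonical_networks()))
  series <- list(); motion <- list()
  for (i in seq_len(nrow(subj))) {
    tgt <- build_block_covariance(config, subj$subject_latent[i],
                                  subj$group[i])
    out <- generate_subject_series(tgt, config,
                                   setNames(truth$modulation[i, ], nets))
    colnames(out$series) <- as.character(roi_id)
    series[[subj$subject_id[i]]] <- out$series
    motion[[subj$subject_id[i]]] <- out$motion
  }
  man <- data.frame(
    subject_id = subj$subject_id, group = subj$group,
    severity = subj$severity, tr_s = config$tr_s,
    n_frames = config$n_frames,
    timeseries_path = paste0("ts_", subj$subject_id, ".tsv"),
    motion_path = paste0("motion_", subj$subject_id, ".tsv"),
    stringsAsFactors = FALSE)
  cohort <- structure(
    list(manifest = man, map = map, series = series, motion = motion),
    rejected = data.frame(subject_id = character(0), reason = character(0)),
    class = "rsnec_cohort")
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(cohort = cohort, truth = truth)
}
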