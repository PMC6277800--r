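## Shared fixtures, built in code. Cohort sizes, ROI counts and frame
## counts are scaled well below the full 248 x 264 design for runtime;
## every planted effect is the generator's, not the test's.

## eleven canonical networks, k ROIs each
nets11 <- function(k = 2L) {
  stats::setNames(rep(as.integer(k), 11L), canonical_networks())
}

## small fully-deterministic cohort for io/fc plumbing tests
tiny_cohort <- function(n_control = 3L, n_case = 2L, n_frames = 96L,
                        rois = 2L, seed = 42L, ...) {
  generate_cohort(sim_config(n_control = n_control, n_case = n_case,
                             n_frames = n_frames,
                             rois_per_network = nets11(rois),
                             seed = seed, ...))
}

## strong-effect preset for model recovery (frozen; see methods vignette)
strong_model_sim <- function(seed) {
  sim_config(n_control = 60L, n_case = 30L,
             coupling_control = 0.5, coupling_case = 0.3,
             entropy_noise_sd = 0.10, seed = seed)
}

## entropy-profile proxy from planted ground truth: baseline + planted
## modulation + measurement noise (sd 0.02), response = latent + noise
strong_model_xy <- function(seed) {
  cfg <- strong_model_sim(seed)
  truth <- plant_ground_truth(cfg)
  z <- truth$subjects$latent_z
  N <- length(z)
  set.seed(seed + 7L)
  X_H <- 1.9 + truth$modulation + matrix(rnorm(N * 11, sd = 0.02), N, 11)
  colnames(X_H) <- canonical_networks()
  list(X_H = X_H, c1 = z + rnorm(N, sd = 0.2),
       sgn = sign(truth$contrast[1:11]), truth = truth)
}

## naive O(N^2) double-loop sample-entropy oracle (independent of the
## package's chunked implementation)
brute_sample_entropy <- function(pm, pm1, r) {
  count <- function(P) {
    n <- nrow(P); tot <- 0L
    for (p in seq_len(n)) for (q in seq_len(n)) {
      if (p != q && max(abs(P[p, ] - P[q, ])) < r) tot <- tot + 1L
    }
    tot
  }
  n_m <- nrow(pm); n_m1 <- nrow(pm1)
  cm <- count(pm) / (n_m * (n_m - 1))
  cm1 <- count(pm1) / (n_m1 * (n_m1 - 1))
  list(Cm = cm, Cm1 = cm1,
       H = if (cm > 0 && cm1 > 0) -log(cm1 / cm) else NA_real_)
}

## AR(1) series (burned in), optionally band-limited like the generator
ar1_series <- function(n, phi, tr_s = 2, band = NULL) {
  x <- as.numeric(stats::filter(rnorm(n + 200), phi, "recursive"))
  x <- x[(201):(200 + n)]
  if (!is.null(band)) {
    f <- (seq_len(n) - 1) / (n * tr_s)
    f <- pmin(f, 1 / tr_s - f)
    X <- stats::fft(x)
    X[f < band[1] | f > band[2]] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  as.numeric(scale(x))
}
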