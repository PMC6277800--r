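## Elastic-net coupling model (network entropies -> primary FC
## component) and the cohort-level statistics: rank-sum group tests,
## group-by-prediction interaction, severity correlation.

#' Fit the entropy-connectivity elastic-net model
#'
#' Models the primary FC component score `c1` from the N x K matrix of
#' network entropies, pooled over the whole cohort (group labels are
#' never seen by the model). For every mixing value in `alpha_grid` a
#' lambda path is fit by coordinate descent (glmnet convention:
#' `(1/2N)RSS + lambda[(1-alpha)||b||^2/2 + alpha||b||_1]`) and
#' `n_folds`-fold cross-validated MSE computed with a seeded fold
#' assignment shared across the grid; the (alpha, lambda) pair with the
#' smallest mean CV MSE is selected and refit on all data. Predictors
#' are standardized internally (inside glmnet, per training fold during
#' CV); coefficients are reported on the original scale.
#'
#' @param X_H N x K numeric matrix of network entropies (no missing
#'   values; columns named by network).
#' @param c1 numeric response of length N.
#' @param alpha_grid mixing-parameter grid (default `seq(0, 1, 0.05)`).
#' @param n_folds folds for cross validation (default 10).
#' @param seed seed for the fold assignment (default 1).
#' @param lambda optional fixed lambda sequence (mainly for oracle
#'   tests); default lets glmnet build a 100-value path per alpha.
#' @param standardize standardize predictors internally (default
#'   `TRUE`).
#' @param thresh coordinate-descent convergence threshold.
#' @return Object of class `rsnec_enet`: `beta` (named K-vector),
#'   `intercept`, `alpha`, `lambda`, `cv_mse` (mean, sd), `c1H` (fitted
#'   scores), `residuals`, `cv_grid` (per-alpha summary), `path_lambda`,
#'   `path_l1` (L1 norms along the selected alpha's path), `glmnet_fit`.
#' @export
fit_elastic_net <- function(X_H, c1, alpha_grid = seq(0, 1, by = 0.05),
                            n_folds = 10L, seed = 1L, lambda = NULL,
                            standardize = TRUE, thresh = 1e-10) {
  X_H <- as.matrix(X_H)
  N <- nrow(X_H)
  stopifnot(length(c1) == N)
  if (N <= n_folds)
    stop("need more subjects than folds", call. = FALSE)
  cvars <- apply(X_H, 2, var)
  if (any(cvars == 0))
    stop("constant predictor column(s): ",
         paste(colnames(X_H)[cvars == 0], collapse = ", "), call. = FALSE)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = N))
  if (min(tabulate(foldid, n_folds)) <= 1L)
    stop("degenerate fold with <= 1 subject", call. = FALSE)
  cv_rows <- list()
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(X_H, c1, alpha = a, foldid = foldid,
                            lambda = lambda, standardize = standardize,
                            family = "gaussian", thresh = thresh)
    i <- which.min(cv$cvm)
    cv_rows[[length(cv_rows) + 1L]] <- data.frame(
      alpha = a, lambda = cv$lambda[i], cv_mse = cv$cvm[i],
      cv_mse_sd = cv$cvsd[i])
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(alpha = a, lambda = cv$lambda[i], cvm = cv$cvm[i],
                   cvsd = cv$cvsd[i], lambda_seq = cv$lambda)
    }
  }
  fit <- glmnet::glmnet(X_H, c1, alpha = best$alpha,
                        lambda = best$lambda_seq, standardize = standardize,
                        family = "gaussian", thresh = thresh)
  cf <- as.numeric(coef(fit, s = best$lambda))
  beta <- setNames(cf[-1L], colnames(X_H))
  intercept <- cf[1L]
  c1H <- as.numeric(X_H %*% beta + intercept)
  bmat <- as.matrix(fit$beta)
  structure(list(
    beta = beta, intercept = intercept,
    alpha = best$alpha, lambda = best$lambda,
    cv_mse = c(mean = best$cvm, sd = best$cvsd),
    c1H = c1H, residuals = c1 - c1H,
    cv_grid = do.call(rbind, cv_rows),
    path_lambda = fit$lambda, path_l1 = colSums(abs(bmat)),
    n_folds = n_folds, seed = seed, glmnet_fit = fit),
    class = "rsnec_enet")
}

#' @export
print.rsnec_enet <- function(x, ...) {
  cat(sprintf("rsnec elastic net: alpha = %.2f, lambda = %.4g, CV MSE = %.4g (sd %.4g)\n",
              x$alpha, x$lambda, x$cv_mse["mean"], x$cv_mse["sd"]))
  cat(sprintf("  %d/%d nonzero coefficients\n", sum(x$beta != 0),
              length(x$beta)))
  invisible(x)
}

#' Predict coupling-model scores for new entropy profiles
#'
#' @param fit an `rsnec_enet`.
#' @param X_H N x K matrix with the same columns as the training matrix.
#' @return Numeric vector `c1H = X_H beta + intercept`.
#' @export
predict_scores <- function(fit, X_H) {
  X_H <- as.matrix(X_H)
  if (ncol(X_H) != length(fit$beta))
    stop(sprintf("X_H has %d columns, model has %d coefficients",
                 ncol(X_H), length(fit$beta)), call. = FALSE)
  if (!is.null(colnames(X_H)) && !is.null(names(fit$beta)) &&
      !identical(colnames(X_H), names(fit$beta)))
    stop("X_H column names do not match model coefficients", call. = FALSE)
  as.numeric(X_H %*% fit$beta + fit$intercept)
}

## exact null counts of the Mann-Whitney U for sample sizes (n1, n2):
## table[[a+1]][[b+1]] built by the standard two-sample recursion
ranksum_exact_counts <- function(n1, n2) {
  prev <- list()   # counts for (a, b-?) — fill full (a,b) grid
  tab <- vector("list", n1 + 1L)
  for (a in 0:n1) tab[[a + 1L]] <- vector("list", n2 + 1L)
  for (a in 0:n1) for (b in 0:n2) {
    if (a == 0L || b == 0L) {
      tab[[a + 1L]][[b + 1L]] <- 1   # only u = 0
    } else {
      u_max <- a * b
      v <- numeric(u_max + 1L)
      left <- tab[[a - 1L + 1L]][[b + 1L]]   # largest group1 elt is max: u gains b
      right <- tab[[a + 1L]][[b - 1L + 1L]]  # largest elt in group2: u unchanged
      v[(b + 1L):(u_max + 1L)] <- v[(b + 1L):(u_max + 1L)] +
        left[seq_len(min(length(left), u_max - b + 1L))]
      v[seq_along(right)] <- v[seq_along(right)] + right
      tab[[a + 1L]][[b + 1L]] <- v
    }
  }
  tab[[n1 + 1L]][[n2 + 1L]]
}

#' Two-sided Wilcoxon rank-sum / Mann-Whitney test
#'
#' Mid-ranks for ties. With both group sizes at most 20 and no ties the
#' two-sided p comes from exact enumeration of the null distribution of
#' U (dynamic programming over group assignments); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Both conventions of the statistic are reported: `W` (sum of
#' mid-ranks of group 1, the convention behind cohort-scale values like
#' W = 5,846) and `U = W - n1(n1+1)/2`.
#'
#' @param values numeric vector.
#' @param groups binary labels (0/1 or two-level factor); "group 1" is
#'   the higher level.
#' @return list of class `rsnec_ranksum`: `W`, `U`, `p`, `n1`, `n2`,
#'   `method` ("exact" or "normal").
#' @export
rank_sum_test <- function(values, groups) {
  g <- as.integer(factor(groups))
  if (length(unique(g[!is.na(g)])) != 2L)
    stop("groups must contain exactly two levels", call. = FALSE)
  ok <- is.finite(values) & !is.na(g)
  values <- values[ok]; g <- g[ok]
  g1 <- g == 2L   # higher factor level = "group 1"
  n1 <- sum(g1); n2 <- sum(!g1); N <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty", call. = FALSE)
  rk <- rank(values)   # mid-ranks
  W <- sum(rk[g1])
  U <- W - n1 * (n1 + 1) / 2
  ties <- table(values)
  has_ties <- any(ties > 1)
  if (all(ties == N)) {   # every value identical
    return(structure(list(W = W, U = U, p = 1, n1 = n1, n2 = n2,
                          method = "degenerate"), class = "rsnec_ranksum"))
  }
  if (!has_ties && n1 <= 20L && n2 <= 20L) {
    cnt <- ranksum_exact_counts(n1, n2)
    prob <- cnt / sum(cnt)
    u <- as.integer(round(U))
    p_le <- sum(prob[seq_len(u + 1L)])
    p_ge <- sum(prob[(u + 1L):length(prob)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  structure(list(W = W, U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "rsnec_ranksum")
}

#' @export
print.rsnec_ranksum <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): W = %g, U = %g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$W, x$U, x$p, x$n1, x$n2))
  invisible(x)
}

#' Group-by-prediction interaction regression
#'
#' Ordinary least squares for
#' `c1 = g0 + g1 G + g2 c1H + g3 G * c1H + e`; the interaction
#' coefficient `g3` measures how much the entropy-model slope differs
#' between groups (a negative planted coupling difference for cases
#' shows up as a nonzero g3).
#'
#' @param c1 primary component scores.
#' @param c1H entropy-model predictions.
#' @param groups binary group labels (0 = control, 1 = case).
#' @return list of class `rsnec_interaction`: `coefficients` (4 x 4
#'   table: estimate, se, t, p), `gamma3`, `gamma3_p`, `residuals`,
#'   `fit` (the `lm` object).
#' @export
interaction_regression <- function(c1, c1H, groups) {
  G <- as.numeric(groups)
  if (length(unique(G)) < 2)
    stop("both groups must be present", call. = FALSE)
  N <- length(c1)
  stopifnot(length(c1H) == N, length(G) == N)
  if (N < 8) stop("need at least 8 subjects", call. = FALSE)
  df <- data.frame(c1 = c1, G = G, c1H = c1H)
  mm <- stats::model.matrix(~ G * c1H, df)
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    piv <- qr(mm)$pivot
    bad <- colnames(mm)[piv[(qr_rank + 1):ncol(mm)]]
    stop("collinear design; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm(c1 ~ G * c1H, data = df)
  ct <- summary(fit)$coefficients
  rownames(ct) <- c("gamma0", "gamma1", "gamma2", "gamma3")
  colnames(ct) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = ct,
                 gamma3 = ct["gamma3", "estimate"],
                 gamma3_p = ct["gamma3", "p"],
                 residuals = stats::residuals(fit), fit = fit),
            class = "rsnec_interaction")
}

#' @export
print.rsnec_interaction <- function(x, ...) {
  cat("group x entropy-model interaction (OLS)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Pearson correlation of model scores with symptom severity
#'
#' Computed over subjects with a severity score only; two-sided t-based
#' p-value. Zero-variance input yields an undefined (flagged) result
#' rather than an error.
#'
#' @param scores numeric vector (e.g. `c1H` or `c1`).
#' @param severity numeric vector with `NA` for unscored subjects.
#' @param min_n minimum scored subjects (default 5).
#' @return list: `r`, `p`, `n`, `defined`.
#' @export
severity_correlation <- function(scores, severity, min_n = 5L) {
  ok <- is.finite(scores) & is.finite(severity)
  x <- scores[ok]; y <- severity[ok]
  n <- length(x)
  if (n < min_n)
    stop(sprintf("only %d scored subjects (< %d)", n, min_n), call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n, defined = TRUE)
}
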