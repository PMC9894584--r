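# Successor-representation, co-occurrence and null models of
# partial-sequence activity profiles, their fitting, and RMSE/BIC comparison.

SEQ_LABELS <- c("A", "B", "C", "D")

#' Transition matrix of the learned sequence
#'
#' 4x4 one-step transition matrix over the sequence states A-B-C-D:
#' T\[A,B\] = T\[B,C\] = T\[C,D\] = 1, all else 0. D is terminal (row of
#' zeros) by default; `cyclic = TRUE` adds D -> A.
#'
#' @param spec A `sequence_spec` (the matrix is over sequence positions, so
#'   any valid 4-item spec gives the same chain). May be `NULL`.
#' @param cyclic Wrap the sequence D -> A (off by default).
#' @return 4x4 numeric matrix with dimnames A-D.
#' @export
build_transition_matrix <- function(spec = NULL, cyclic = FALSE) {
  T_ <- matrix(0, 4, 4, dimnames = list(SEQ_LABELS, SEQ_LABELS))
  T_[cbind(1:3, 2:4)] <- 1
  if (cyclic) T_[4, 1] <- 1
  T_
}

#' Successor representation matrix
#'
#' The discounted predictive map M = (I - gamma T)^{-1}: entry (i, j) is the
#' discounted expected future occupancy of state j starting from state i.
#' For the terminal 4-chain this equals gamma^(j-i) for j >= i and 0 below
#' the diagonal.
#'
#' @param T_ Transition matrix from [build_transition_matrix()].
#' @param gamma Discount factor in \[0, 1\].
#' @return 4x4 successor matrix.
#' @export
successor_matrix <- function(T_, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1)
    stop("`gamma` must be a single value in [0, 1]")
  solve(diag(nrow(T_)) - gamma * T_)
}

#' Model prediction for partial-sequence trials
#'
#' Predicted 4x4 activity matrix (rows: partial-trial type, i.e. which item
#' was shown; columns: sequence location probed). The diagonal carries the
#' bottom-up response to the shown dot in all models; off-diagonal cells are
#' the model's anticipatory activity:
#' * SR: row s is `a` times row s of M(gamma) — discounted successors only;
#' * CO: all off-diagonal cells equal `a * omega` (non-directional);
#' * H0: off-diagonal all zero.
#'
#' @param model_id One of "SR", "CO", "H0".
#' @param params Named list: `a` (scale, all models), `gamma` (SR),
#'   `omega` (CO).
#' @param T_ Transition matrix (SR only).
#' @return 4x4 prediction matrix.
#' @export
predict_partial <- function(model_id, params,
                            T_ = build_transition_matrix()) {
  a <- if (is.null(params$a)) 1 else params$a
  pred <- switch(model_id,
    SR = {
      if (is.null(params$gamma)) stop("SR prediction needs `gamma`")
      a * successor_matrix(T_, params$gamma)
    },
    CO = {
      if (is.null(params$omega)) stop("CO prediction needs `omega`")
      m <- matrix(a * params$omega, 4, 4)
      diag(m) <- a
      m
    },
    H0 = a * diag(4),
    stop("unknown model_id: ", model_id)
  )
  dimnames(pred) <- list(SEQ_LABELS, SEQ_LABELS)
  pred
}

#' Root-mean-square error between two matrices
#'
#' @param predicted,observed Matrices of equal shape.
#' @return sqrt(mean of squared cell-wise differences).
#' @export
rmse <- function(predicted, observed) {
  if (!all(dim(predicted) == dim(observed)))
    stop("`predicted` and `observed` must have the same shape")
  sqrt(mean((predicted - observed)^2))
}

#' Bayesian information criterion for a Gaussian-error least-squares fit
#'
#' `n * log(rss / n) + k * log(n)`, up to the additive constant shared by
#' all models on the same data.
#'
#' @param rss Residual sum of squares.
#' @param n Number of fitted points.
#' @param k Number of free parameters.
#' @return BIC value; `-Inf` with a warning for a perfect fit (rss = 0).
#' @export
bic <- function(rss, n, k) {
  if (n <= k || k < 0) stop("need n > k >= 0")
  if (rss <= 0) {
    warning("zero residual sum of squares: BIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + k * log(n)
}

# closed-form non-negative scale minimizing ||y - a p||^2
ls_scale <- function(p, y) {
  denom <- sum(p * p)
  if (denom == 0) return(0)
  max(0, sum(p * y) / denom)
}

#' Fit a predictive model to an activity profile
#'
#' Least-squares fit over all 16 cells of the partial-trial x location
#' profile. SR: deterministic grid on gamma (step 0.01) with the scale `a`
#' solved in closed form at each grid point, then local refinement with
#' [stats::optimize()]. CO and H0 have closed-form least-squares solutions
#' (diagonal and off-diagonal cell means). `a` is constrained >= 0; `omega`
#' may be negative (predecessor suppression is meaningful).
#'
#' @param profile 4x4 observed activity profile (shown item x location).
#' @param model_id One of "SR", "CO", "H0".
#' @param T_ Transition matrix for the SR model.
#' @return A `model_fit` list: `model_id`, `params`, `rmse`, `rss`, `bic`,
#'   `n_points` (16), `k_params` (SR 2, CO 2, H0 1), `predicted`.
#' @export
fit_model <- function(profile, model_id = c("SR", "CO", "H0"),
                      T_ = build_transition_matrix()) {
  model_id <- match.arg(model_id)
  profile <- as.matrix(profile)
  if (!all(dim(profile) == c(4, 4)) || any(!is.finite(profile)))
    stop("`profile` must be a complete, finite 4x4 matrix")
  n <- 16
  off <- row(profile) != col(profile)

  if (model_id == "H0") {
    a <- max(0, mean(diag(profile)))
    params <- list(a = a)
    k <- 1
  } else if (model_id == "CO") {
    a <- max(0, mean(diag(profile)))
    m_off <- mean(profile[off])
    omega <- if (a > 0) m_off / a else 0
    params <- list(a = a, omega = omega)
    k <- 2
  } else {
    sse_at <- function(g) {
      p <- successor_matrix(T_, g)
      a <- ls_scale(p, profile)
      sum((profile - a * p)^2)
    }
    grid <- seq(0, 1, by = 0.01)
    sse <- vapply(grid, sse_at, numeric(1))
    g0 <- grid[which.min(sse)]
    lo <- max(0, g0 - 0.01); hi <- min(1, g0 + 0.01)
    opt <- stats::optimize(sse_at, lower = lo, upper = hi, tol = 1e-10)
    gamma <- if (opt$objective <= min(sse)) opt$minimum else g0
    p <- successor_matrix(T_, gamma)
    params <- list(a = ls_scale(p, profile), gamma = gamma)
    k <- 2
  }
  pred <- predict_partial(model_id, params, T_ = T_)
  rss <- sum((profile - pred)^2)
  list(
    model_id = model_id, params = params,
    rmse = sqrt(rss / n), rss = rss,
    bic = suppressWarnings(bic(max(rss, 0), n, k)),
    n_points = n, k_params = k, predicted = pred
  )
}

#' Exponential decay fit to a successor-lag profile
#'
#' Least squares fit of `a * gamma^lag` to mean activity at lags 1, 2, ...,
#' with gamma constrained to \[0, 1\]: a grid on gamma (step 1e-3) with `a`
#' solved in closed form, refined locally. Values of gamma near 0 indicate a
#' steep decay; gamma = 1 indicates no decay.
#'
#' @param lag_profile Numeric vector of mean activity at lags 1..L (L >= 2).
#' @param lags Lag values (default `seq_along(lag_profile)`).
#' @return List with `gamma`, `a`, `rss`.
#' @export
fit_gamma_decay <- function(lag_profile, lags = seq_along(lag_profile)) {
  y <- as.numeric(lag_profile)
  if (length(y) < 2) stop("need at least 2 lag values")
  if (all(y == 0)) stop("all-zero profile: gamma undefined")
  sse_at <- function(g) {
    p <- g^lags
    a <- ls_scale(p, y)
    sum((y - a * p)^2)
  }
  grid <- seq(0, 1, by = 1e-3)
  sse <- vapply(grid, sse_at, numeric(1))
  g0 <- grid[which.min(sse)]
  opt <- stats::optimize(sse_at, lower = max(0, g0 - 1e-3),
                         upper = min(1, g0 + 1e-3), tol = 1e-10)
  gamma <- if (opt$objective <= min(sse)) opt$minimum else g0
  p <- gamma^lags
  a <- ls_scale(p, y)
  list(gamma = gamma, a = a, rss = sum((y - a * p)^2))
}

#' Group-level model comparison
#'
#' Fits SR, CO and H0 to each subject's activity profile, compares RMSEs
#' across subjects with paired t tests, and selects the winner by lowest
#' group-mean BIC.
#'
#' @param profiles List of per-subject 4x4 activity profiles.
#' @param T_ Transition matrix.
#' @return List: `fits` data frame (subject, model, gamma, omega, scale,
#'   rmse, bic), `mean_bic`, `mean_rmse`, `winner`, `tests` (pairwise paired
#'   t tests on RMSE).
#' @export
model_comparison <- function(profiles, T_ = build_transition_matrix()) {
  if (length(profiles) < 2) stop("need at least 2 subjects")
  models <- c("SR", "CO", "H0")
  rows <- list()
  for (s in seq_along(profiles)) {
    for (m in models) {
      f <- fit_model(profiles[[s]], m, T_ = T_)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, model = m,
        gamma = if (is.null(f$params$gamma)) NA_real_ else f$params$gamma,
        omega = if (is.null(f$params$omega)) NA_real_ else f$params$omega,
        scale = f$params$a, rmse = f$rmse, bic = f$bic
      )
    }
  }
  fits <- do.call(rbind, rows)
  mean_bic <- tapply(fits$bic, fits$model, mean)[models]
  mean_rmse <- tapply(fits$rmse, fits$model, mean)[models]
  pairs <- utils::combn(models, 2, simplify = FALSE)
  tests <- lapply(pairs, function(pr) {
    x <- fits$rmse[fits$model == pr[1]]
    y <- fits$rmse[fits$model == pr[2]]
    c(list(comparison = paste(pr, collapse = " vs ")), safe_paired_t(x, y))
  })
  list(
    fits = fits, mean_bic = mean_bic, mean_rmse = mean_rmse,
    winner = models[which.min(mean_bic)], tests = tests
  )
}
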