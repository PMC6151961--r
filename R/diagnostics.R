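#' Leverage of query compounds
#'
#' Hat-matrix leverage in the model's scaled descriptor space with the
#' intercept convention: `h = 1/n + x' (Xc' Xc)^-1 x` where `Xc` is the
#' centered, unit-variance training block.  Training-row leverages then lie
#' in (0, 1] and sum to `k + 1` for `k` descriptors.  High leverage flags a
#' compound structurally distant from the training set.
#'
#' @param X_train raw-unit training descriptor matrix (or a `pls_model`,
#'   in which case its stored scaling and training scores are unused and
#'   leverage is computed in its scaled X space).
#' @param X_query raw-unit query matrix; defaults to the training block.
#' @return numeric vector of leverages, one per query row.
#' @export
leverage <- function(X_train, X_query = NULL) {
  X_train <- as.matrix(X_train)
  if (is.null(X_query)) X_query <- X_train
  X_query <- as.matrix(X_query)
  if (ncol(X_query) != ncol(X_train))
    stop("descriptor mismatch between training and query")
  sc <- autoscale(X_train, X_query)
  XtX <- crossprod(sc$train)
  inv <- tryCatch(solve(XtX), error = function(e) {
    warning("X'X singular; using pseudo-inverse")
    pseudo_inverse(XtX)
  })
  1 / nrow(X_train) + rowSums((sc$apply_to %*% inv) * sc$apply_to)
}

pseudo_inverse <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Leverage warning threshold
#'
#' The conventional applicability-domain cutoff `h* = 3 (k + 1) / n` for a
#' model with `k` descriptors fitted on `n` training compounds.
#'
#' @param k number of descriptors in the model.
#' @param n number of training compounds.
#' @return `h*`.
#' @export
leverage_threshold <- function(k, n) {
  if (k < 0 || n <= 0) stop("k must be >= 0 and n > 0")
  if (n <= k + 1) stop("n must exceed k + 1")
  3 * (k + 1) / n
}

#' Hotelling T-squared of score vectors
#'
#' Mahalanobis-type distance of PLS scores from the training centroid,
#' `T2 = t' S^-1 t` with `S` the training score covariance.
#'
#' @param model a `pls_model`.
#' @param scores n x A score matrix (e.g. from [predict.pls_model()]);
#'   defaults to the training scores.
#' @return numeric vector of T2 values.
#' @export
hotelling_t2 <- function(model, scores = model$training_scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  S <- model$score_cov
  inv <- tryCatch(solve(S), error = function(e)
    stop("singular training score covariance"))
  rowSums((scores %*% inv) * scores)
}

#' F-based critical limit for Hotelling T-squared
#'
#' `T2_crit = A (n - 1) / (n - A) * F_{1-alpha}(A, n - A)` for a model with
#' `A` latent variables and `n` training compounds.
#'
#' @param A number of latent variables.
#' @param n number of training compounds, `n > A`.
#' @param alpha significance level (default 0.05).
#' @return the critical limit.
#' @export
t2_critical <- function(A, n, alpha = 0.05) {
  if (A < 1 || n <= A) stop("need n > A >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
}

#' Distance to the model in X space (DModX)
#'
#' Normalized residual distance of each row from the A-dimensional PLS
#' subspace: with residual `e = x_s - P t` (scaled units),
#' `DModX = sqrt(sum(e^2) / (p - A)) / s0`, where the pooled training
#' residual standard deviation is
#' `s0 = sqrt(sum(E_train^2) / ((n - A - 1)(p - A)))`.  Training rows then
#' average about 1; values far above 1 flag compounds the model cannot
#' reconstruct.
#'
#' @param model a `pls_model`.
#' @param X_query raw-unit query matrix (pass the training block for
#'   training-row DModX; NIPALS scores satisfy `t = Xs Rstar`, so the
#'   projection residual equals the deflation residual there).
#' @param scaled set TRUE if `X_query` is already scaled.
#' @return numeric vector of DModX values.
#' @export
dmodx <- function(model, X_query, scaled = FALSE) {
  p <- model$p; A <- model$A; n <- model$n_train
  if (p <= A) stop("DModX undefined: p <= A")
  s0 <- sqrt(model$ssx_residual / ((n - A - 1) * (p - A)))
  E <- residual_matrix(model, X_query, scaled = scaled)
  d <- sqrt(rowSums(E^2) / (p - A))
  # an exactly low-rank training block has s0 = 0; report unnormalized
  # residual distances rather than 0/0
  if (s0 > 1e-12) d <- d / s0
  d
}

# scaled-space reconstruction residuals e = x_s - P t
residual_matrix <- function(model, X_query, scaled = FALSE) {
  if (is.null(dim(X_query))) X_query <- matrix(X_query, nrow = 1)
  Xs <- if (scaled) as.matrix(X_query)
        else apply_scaling(as.matrix(X_query), model$x_scaling)
  Tn <- Xs %*% model$Rstar
  Xs - tcrossprod(Tn, model$P)
}

#' F-based critical limit for DModX
#'
#' `sqrt(F_{1-alpha}(p - A, (n - A - 1)(p - A)))` under the normalization
#' of [dmodx()].
#'
#' @param model a `pls_model` (or supply `p`, `A`, `n` directly).
#' @param alpha significance level (default 0.05).
#' @param p,A,n model dimensions, read from `model` when given.
#' @return the critical DModX.
#' @export
dmodx_critical <- function(model = NULL, alpha = 0.05,
                           p = model$p, A = model$A, n = model$n_train) {
  if (p <= A) stop("p must exceed A")
  sqrt(stats::qf(1 - alpha, p - A, (n - A - 1) * (p - A)))
}

#' Applicability-domain report
#'
#' Combines the Williams-plot rule (|standardized residual| <= 3 and
#' leverage h <= h*) with Hotelling T-squared and DModX statistics for a
#' set of compounds.  Standardized residuals are raw-unit residuals divided
#' by the per-response training RMSEE.
#'
#' @param model a `pls_model`.
#' @param X_train,Y_train the training data the model was fitted on.
#' @param X_query,Y_query compounds to diagnose (default: training set);
#'   `Y_query` may be NULL, in which case residual-based columns are NA.
#' @param alpha significance level for the T2 and DModX limits.
#' @param sd_limit standardized-residual warning limit (default 3).
#' @return object of class `diagnostics_report`: a data.frame with columns
#'   `compound_id`, `h`, `std_resid_logkw`, `std_resid_logKi`, `t2`,
#'   `dmodx`, `in_domain`, plus attributes `h_star`, `t2_crit`,
#'   `dmodx_crit`.
#' @export
diagnose <- function(model, X_train, Y_train, X_query = NULL,
                     Y_query = NULL, alpha = 0.05, sd_limit = 3) {
  if (inherits(Y_train, "property_table")) Y_train <- property_matrix(Y_train)
  if (inherits(Y_query, "property_table")) Y_query <- property_matrix(Y_query)
  if (is.null(X_query)) { X_query <- X_train; Y_query <- Y_train }
  X_query <- as.matrix(X_query)
  h <- leverage(X_train, X_query)
  h_star <- leverage_threshold(ncol(X_train), nrow(X_train))
  pr <- predict(model, X_query)
  t2 <- hotelling_t2(model, pr$scores)
  t2c <- t2_critical(model$A, model$n_train, alpha)
  dx <- dmodx(model, X_query)
  dxc <- dmodx_critical(model, alpha)
  rmsee <- sqrt(colMeans((predict(model, X_train)$predictions - Y_train)^2))
  if (!is.null(Y_query)) {
    res <- pr$predictions - Y_query
    sr1 <- res[, 1] / rmsee[1]
    sr2 <- res[, 2] / rmsee[2]
    in_domain <- abs(sr1) <= sd_limit & abs(sr2) <= sd_limit & h <= h_star
  } else {
    sr1 <- sr2 <- rep(NA_real_, nrow(X_query))
    in_domain <- h <= h_star
  }
  out <- data.frame(
    compound_id = rownames(X_query) %||% paste0("q", seq_len(nrow(X_query))),
    h = h, std_resid_logkw = sr1, std_resid_logKi = sr2,
    t2 = t2, dmodx = dx, in_domain = in_domain,
    stringsAsFactors = FALSE)
  attr(out, "h_star") <- h_star
  attr(out, "t2_crit") <- t2c
  attr(out, "dmodx_crit") <- dxc
  class(out) <- c("diagnostics_report", "data.frame")
  out
}
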