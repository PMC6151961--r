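#' Fit a two-response PLS model (NIPALS)
#'
#' PLS2 regression of the two drug properties on a descriptor block.  X and
#' Y are autoscaled internally (centering + unit variance); components are
#' extracted by NIPALS with deflation of X only, Y loadings recomputed per
#' component against the orthogonal scores.  The fitted object stores the
#' weights W, X-loadings P, Y-loadings C, the transformed weights
#' `Rstar = W (P'W)^-1` used for direct score prediction, the training
#' scores and their sample covariance (needed by the Hotelling T-squared
#' constraint of the model inversion), and both scaling parameter sets.
#'
#' @param X numeric matrix (n x p), raw units.
#' @param Y numeric matrix (n x 2) or `property_table`, raw units.
#' @param A number of latent variables, `1 <= A <= min(n - 1, p)`.
#' @param max_iter,tol NIPALS inner-loop controls.
#' @param truncate_on_null when the residual X/Y covariance vanishes before
#'   `A` components (exactly low-rank data), keep the components extracted
#'   so far instead of raising an error.
#' @return object of class `pls_model`.
#' @export
fit_pls <- function(X, Y, A, max_iter = 500, tol = 1e-10,
                    truncate_on_null = FALSE) {
  if (inherits(Y, "property_table")) Y <- property_matrix(Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y row counts differ")
  if (A < 1 || A > min(n - 1, p))
    stop("A must lie in [1, min(n-1, p)] = [1, ", min(n - 1, p), "]")
  xs <- autoscale(X)
  ys <- autoscale(Y)
  E <- xs$train            # deflated X residuals
  Ys <- ys$train           # Y stays fixed; scores are orthogonal
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); C <- matrix(0, ncol(Y), A)
  ssx0 <- sum(E^2); ssy0 <- sum(Ys^2)
  r2x_cum <- numeric(A)
  for (a in seq_len(A)) {
    # the NIPALS inner loop (w <- E'u; t <- Ew; c <- Y't; u <- Yc) is a
    # power iteration whose fixed point is the dominant eigenvector of the
    # small q x q matrix (E'Y)'(E'Y); solve it exactly instead of iterating
    Z <- crossprod(E, Ys)                      # p x q
    q <- eigen(crossprod(Z), symmetric = TRUE)$vectors[, 1]
    w <- Z %*% q
    nw <- sqrt(sum(w^2))
    if (a == 1) nw1 <- max(nw, .Machine$double.eps)
    if (nw < 1e-8 * nw1) {
      if (truncate_on_null && a > 1) { A <- a - 1L; break }
      stop("NIPALS failed: no residual X/Y covariance at component ", a)
    }
    w <- w / nw
    tt <- E %*% w
    cc <- crossprod(Ys, tt) / sum(tt^2)
    pp <- crossprod(E, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; C[, a] <- cc
    E <- E - tcrossprod(tt, pp)
    r2x_cum[a] <- 1 - sum(E^2) / ssx0
  }
  A <- as.integer(A)
  W <- W[, seq_len(A), drop = FALSE]; P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]; C <- C[, seq_len(A), drop = FALSE]
  # regress Y on the (orthogonal) scores for the final Y-loadings
  for (a in seq_len(A)) C[, a] <- crossprod(Ys, Tm[, a]) / sum(Tm[, a]^2)
  Rstar <- W %*% solve(crossprod(P, W))
  fitted_scaled <- Tm %*% t(C)
  r2y <- 1 - sum((Ys - fitted_scaled)^2) / ssy0
  structure(list(
    A = A, W = W, P = P, C = C, Rstar = Rstar,
    training_scores = Tm,
    score_cov = stats::cov(Tm),
    x_scaling = xs$scaling, y_scaling = ys$scaling,
    descriptor_names = colnames(X),
    response_names = colnames(Y) %||% c("logkw", "logKi"),
    n_train = as.integer(n), p = as.integer(p),
    r2x = r2x_cum[A], r2y = r2y,
    ssx_residual = sum(E^2)),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("pls_model:", x$p, "descriptors,", x$A, "latent variables,",
      x$n_train, "training compounds\n")
  cat(sprintf("  R2X = %.4f, R2Y = %.4f\n", x$r2x, x$r2y))
  invisible(x)
}

#' Predict drug properties with a fitted PLS model
#'
#' Applies the stored X scaling, computes scores `t = Rstar' x`, predictions
#' `y = C t` in scaled units, and back-transforms to raw property units.
#'
#' @param object a `pls_model`.
#' @param X_new matrix (or single row) in raw descriptor units; columns must
#'   match the training descriptors.
#' @param scaled set TRUE if `X_new` is already in the model's scaled space.
#' @param ... unused.
#' @return list with `predictions` (n x 2, raw units) and `scores` (n x A).
#' @export
predict.pls_model <- function(object, X_new, scaled = FALSE, ...) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$p)
    stop("X_new has ", ncol(X_new), " columns; model expects ", object$p)
  if (!is.null(colnames(X_new)) && !is.null(object$descriptor_names) &&
      !identical(colnames(X_new), object$descriptor_names))
    stop("descriptor columns do not match the training set")
  Xs <- if (scaled) X_new else apply_scaling(X_new, object$x_scaling)
  Tn <- Xs %*% object$Rstar
  Yhat_s <- Tn %*% t(object$C)
  Yhat <- invert_scaling(Yhat_s, object$y_scaling)
  colnames(Yhat) <- object$response_names
  list(predictions = Yhat, scores = Tn)
}

#' Cross-validate the number of latent variables
#'
#' k-fold cross-validation with folds formed as contiguous blocks after a
#' seeded shuffle.  For each candidate A the root-mean-square CV error is
#' computed per response (raw units) and summed over the two responses; the
#' chosen A minimizes that sum (smallest A on ties).  Scaling is refit
#' inside every fold.
#'
#' @param X,Y training matrices in raw units.
#' @param A_max largest number of latent variables to consider.
#' @param k number of folds (default 7).
#' @param seed integer seed controlling the shuffle.
#' @return list with `cv_table` (A, rmsecv per response, total) and
#'   `A_chosen`.
#' @export
cross_validate <- function(X, Y, A_max, k = 7, seed = 1) {
  if (inherits(Y, "property_table")) Y <- property_matrix(Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of samples")
  folds <- local_seed(seed, {
    ord <- sample.int(n)
    split(ord, cut(seq_len(n), breaks = k, labels = FALSE))
  })
  sizes <- lengths(folds)
  if (any(n - sizes < 2))
    stop("a fold leaves fewer than 2 training samples")
  A_max <- min(A_max, min(n - sizes) - 1, ncol(X))
  if (A_max < 1) stop("no admissible number of latent variables")
  press <- matrix(0, A_max, ncol(Y))
  for (f in folds) {
    Xtr <- X[-f, , drop = FALSE]; Ytr <- Y[-f, , drop = FALSE]
    Xte <- X[f, , drop = FALSE]
    # guard: drop columns constant within this fold's training part
    keep <- apply(Xtr, 2, stats::sd) > 0
    m <- fit_pls(Xtr[, keep, drop = FALSE], Ytr,
                 A = min(A_max, sum(keep), nrow(Xtr) - 1),
                 truncate_on_null = TRUE)
    for (a in seq_len(A_max)) {
      pr <- predict_with_A(m, Xte[, keep, drop = FALSE], min(a, m$A))
      press[a, ] <- press[a, ] + colSums((pr - Y[f, , drop = FALSE])^2)
    }
  }
  rmsecv <- sqrt(press / n)
  total <- rowSums(rmsecv)
  cv_table <- data.frame(A = seq_len(A_max), rmsecv_logkw = rmsecv[, 1],
                         rmsecv_logKi = rmsecv[, 2], total = total)
  list(cv_table = cv_table, A_chosen = which.min(total))
}

# predictions truncated to the first a components of a fitted model
predict_with_A <- function(model, X_new, a) {
  Xs <- apply_scaling(as.matrix(X_new), model$x_scaling)
  Rstar_a <- model$W[, seq_len(a), drop = FALSE] %*%
    solve(crossprod(model$P[, seq_len(a), drop = FALSE],
                    model$W[, seq_len(a), drop = FALSE]))
  Tn <- Xs %*% Rstar_a
  invert_scaling(Tn %*% t(model$C[, seq_len(a), drop = FALSE]),
                 model$y_scaling)
}

#' Error metrics of a fitted model
#'
#' RMSEE (training) and RMSEP (external test) per response as
#' `sqrt(sum((pred - obsd)^2) / n)`, plus the mean relative error
#' `MRE = mean(|pred - obsd| / |obsd|) * 100` in percent and the cumulative
#' explained variances R2X / R2Y.  Compounds with observed value exactly 0
#' make MRE undefined and are excluded from it with a warning.
#'
#' @param model a `pls_model`.
#' @param X_train,Y_train training data in raw units.
#' @param X_test,Y_test optional external test data.
#' @return object of class `model_metrics` with per-response `rmsee`,
#'   `rmsep`, `mre_train_pct`, `mre_test_pct`, and `r2x`, `r2y`.
#' @export
pls_metrics <- function(model, X_train, Y_train,
                        X_test = NULL, Y_test = NULL) {
  if (inherits(Y_train, "property_table")) Y_train <- property_matrix(Y_train)
  if (inherits(Y_test, "property_table")) Y_test <- property_matrix(Y_test)
  pr_tr <- predict(model, X_train)$predictions
  rmsee <- sqrt(colMeans((pr_tr - Y_train)^2))
  mre_tr <- mre_pct(pr_tr, Y_train)
  rmsep <- mre_te <- NULL
  if (!is.null(X_test)) {
    pr_te <- predict(model, X_test)$predictions
    rmsep <- sqrt(colMeans((pr_te - Y_test)^2))
    mre_te <- mre_pct(pr_te, Y_test)
  }
  structure(list(rmsee = rmsee, rmsep = rmsep,
                 mre_train_pct = mre_tr, mre_test_pct = mre_te,
                 r2x = model$r2x, r2y = model$r2y),
            class = "model_metrics")
}

mre_pct <- function(pred, obsd) {
  out <- numeric(ncol(obsd))
  for (j in seq_len(ncol(obsd))) {
    zero <- obsd[, j] == 0
    if (any(zero))
      warning(sum(zero), " observed value(s) equal to 0 excluded from MRE")
    out[j] <- 100 * mean(abs(pred[!zero, j] - obsd[!zero, j]) /
                           abs(obsd[!zero, j]))
  }
  names(out) <- colnames(obsd)
  out
}

#' Serialize a PLS model to JSON
#' @param model a `pls_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  doc <- list(schema = "plsinvert/pls_model/1",
              A = model$A, n_train = model$n_train, p = model$p,
              W = model$W, P = model$P, C = model$C, Rstar = model$Rstar,
              training_scores = model$training_scores,
              score_cov = model$score_cov,
              x_center = model$x_scaling$center,
              x_scale = model$x_scaling$scale,
              y_center = model$y_scaling$center,
              y_scale = model$y_scaling$scale,
              descriptor_names = model$descriptor_names,
              response_names = model$response_names,
              r2x = model$r2x, r2y = model$r2y,
              ssx_residual = model$ssx_residual)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PLS model from JSON
#' @param path path written by [write_pls_model()].
#' @return a `pls_model`.
#' @export
read_pls_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "plsinvert/pls_model/1"))
    stop("unrecognized model schema: ", doc$schema)
  structure(list(
    A = as.integer(doc$A), W = as.matrix(doc$W), P = as.matrix(doc$P),
    C = as.matrix(doc$C), Rstar = as.matrix(doc$Rstar),
    training_scores = as.matrix(doc$training_scores),
    score_cov = as.matrix(doc$score_cov),
    x_scaling = list(center = stats::setNames(doc$x_center,
                                              doc$descriptor_names),
                     scale = stats::setNames(doc$x_scale,
                                             doc$descriptor_names)),
    y_scaling = list(center = stats::setNames(doc$y_center,
                                              doc$response_names),
                     scale = stats::setNames(doc$y_scale,
                                             doc$response_names)),
    descriptor_names = doc$descriptor_names,
    response_names = doc$response_names,
    n_train = as.integer(doc$n_train), p = as.integer(doc$p),
    r2x = doc$r2x, r2y = doc$r2y, ssx_residual = doc$ssx_residual),
    class = "pls_model")
}

# evaluate expr under a temporary RNG state; the caller's stream is restored
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
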