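#' Relative standard deviation filter
#'
#' Removes near-constant descriptors: those whose relative standard deviation
#' `100 * sd / |mean|` (sample sd) falls below `threshold_pct`.  All-zero
#' columns (mean 0, sd 0) are removed; columns with mean 0 but positive sd
#' have an undefined RSD and are retained.  Set `invert = TRUE` to remove
#' high-RSD descriptors instead.
#'
#' @param desc a `descriptor_table` with at least two compounds.
#' @param threshold_pct RSD threshold in percent (default 5).
#' @param invert remove descriptors above the threshold instead of below.
#' @return list with `removed` and `surviving` descriptor-name vectors and
#'   the numeric `rsd` per descriptor (NA where undefined).
#' @export
rsd_filter <- function(desc, threshold_pct = 5, invert = FALSE) {
  if (length(desc$compound_ids) < 2)
    stop("RSD filter needs at least 2 compounds")
  v <- desc$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  rsd <- ifelse(mu == 0, NA_real_, 100 * sdv / abs(mu))
  zero_col <- mu == 0 & sdv == 0
  low <- !is.na(rsd) & if (invert) rsd > threshold_pct else rsd < threshold_pct
  removed <- desc$descriptor_names[low | zero_col]
  list(removed = removed,
       surviving = setdiff(desc$descriptor_names, removed),
       rsd = stats::setNames(rsd, desc$descriptor_names))
}

#' Pairwise-correlation redundancy filter
#'
#' For every descriptor pair with `|Pearson r| > threshold`, drops the member
#' whose maximum absolute correlation against the two responses is lower.
#' Pairs are processed in descending `|r|`; a pair is skipped if either
#' member was already removed.  Ties in response correlation keep the
#' descriptor earlier in column order.  Zero-variance descriptors are
#' treated as uncorrelated (r = 0) and can never be removed here.
#'
#' @param desc a `descriptor_table`.
#' @param props an aligned `property_table`.
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return list with `removed` and `surviving` descriptor-name vectors.
#' @export
correlation_filter <- function(desc, props, threshold = 0.8) {
  if (!identical(desc$compound_ids, props$compound_ids))
    stop("descriptor and property tables are not aligned")
  X <- desc$values
  Y <- property_matrix(props)
  p <- ncol(X)
  if (p < 2)
    return(list(removed = character(0), surviving = desc$descriptor_names))
  sdx <- apply(X, 2, stats::sd)
  ok <- sdx > 0
  R <- matrix(0, p, p)
  if (sum(ok) >= 2)
    R[ok, ok] <- suppressWarnings(stats::cor(X[, ok, drop = FALSE]))
  diag(R) <- 0
  # max |r| of each descriptor against the two responses
  ry <- rep(0, p)
  if (any(ok)) {
    cy <- suppressWarnings(stats::cor(X[, ok, drop = FALSE], Y))
    ry[ok] <- apply(abs(cy), 1, max)
  }
  pairs <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
  removed <- logical(p)
  if (nrow(pairs)) {
    ord <- order(-abs(R[pairs]), pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (removed[i] || removed[j]) next
      # drop the one less correlated with Y; tie keeps the earlier column
      if (ry[i] < ry[j]) removed[i] <- TRUE else removed[j] <- TRUE
    }
  }
  list(removed = desc$descriptor_names[removed],
       surviving = desc$descriptor_names[!removed])
}

#' Zero-value filter
#'
#' Removes continuous descriptors containing any exact zero entry; binary
#' and integer descriptors, where zeros are meaningful values, are exempt.
#'
#' @param desc a `descriptor_table` with kinds.
#' @return list with `removed` and `surviving` descriptor-name vectors.
#' @export
zero_filter <- function(desc) {
  has_zero <- apply(desc$values == 0, 2, any)
  removed <- desc$descriptor_names[has_zero & desc$kinds == "continuous"]
  list(removed = removed,
       surviving = setdiff(desc$descriptor_names, removed))
}

#' Apply the full pre-selection filter chain
#'
#' Runs the three statistical pre-selection filters in order: RSD,
#' pairwise correlation, zero-value.  The four fate lists in the returned
#' report partition the input descriptor names exactly.
#'
#' @param desc a `descriptor_table`.
#' @param props an aligned `property_table`.
#' @param rsd_pct RSD threshold in percent.
#' @param corr_threshold pairwise-correlation cutoff.
#' @return object of class `filter_report` with fields `removed_by_rsd`,
#'   `removed_by_correlation`, `removed_by_zero`, `surviving`, and the
#'   filtered `desc`.
#' @export
filter_descriptors <- function(desc, props, rsd_pct = 5,
                               corr_threshold = 0.8) {
  r1 <- rsd_filter(desc, rsd_pct)
  d1 <- subset_descriptors(desc, descriptors = r1$surviving)
  r2 <- correlation_filter(d1, props, corr_threshold)
  d2 <- subset_descriptors(d1, descriptors = r2$surviving)
  r3 <- zero_filter(d2)
  d3 <- subset_descriptors(d2, descriptors = r3$surviving)
  if (!length(r3$surviving)) stop("all descriptors removed by filters")
  structure(list(removed_by_rsd = r1$removed,
                 removed_by_correlation = r2$removed,
                 removed_by_zero = r3$removed,
                 surviving = r3$surviving,
                 desc = d3),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", length(x$removed_by_rsd), "removed by RSD,",
      length(x$removed_by_correlation), "by correlation,",
      length(x$removed_by_zero), "by zero rule;",
      length(x$surviving), "surviving\n")
  invisible(x)
}

#' Write a filter report as a (descriptor, fate) CSV
#' @param report a `filter_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  fate_df <- function(nms, fate)
    data.frame(descriptor = nms, fate = rep(fate, length(nms)))
  df <- rbind(
    fate_df(report$removed_by_rsd, "removed_by_rsd"),
    fate_df(report$removed_by_correlation, "removed_by_correlation"),
    fate_df(report$removed_by_zero, "removed_by_zero"),
    fate_df(report$surviving, "surviving"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Autoscale to training mean and unit variance
#'
#' Columns are centered to the training mean and divided by the training
#' (sample) standard deviation; the same parameters transform `apply_to`.
#' Unit-variance scaling is the pretreatment assumed by the PLS, leverage
#' and distance-to-model diagnostics throughout the package.
#'
#' @param train numeric matrix with at least two rows.
#' @param apply_to optional matrix with the same columns to transform with
#'   the training parameters.
#' @return list with `train`, `apply_to` (or NULL), and `scaling`
#'   (`center`, `scale` vectors).
#' @export
autoscale <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("autoscale needs at least 2 training rows")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  zero <- which(scl == 0)
  if (length(zero))
    stop("zero-variance column(s): ",
         paste(colnames(train)[zero] %||% zero, collapse = ", "))
  ts <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  as_ <- NULL
  if (!is.null(apply_to)) {
    apply_to <- as.matrix(apply_to)
    if (ncol(apply_to) != ncol(train)) stop("column mismatch in apply_to")
    as_ <- sweep(sweep(apply_to, 2, ctr), 2, scl, "/")
  }
  list(train = ts, apply_to = as_,
       scaling = list(center = ctr, scale = scl))
}

#' Apply stored scaling parameters
#' @param x matrix or vector in raw units.
#' @param scaling list with `center` and `scale`.
#' @return scaled matrix.
#' @export
apply_scaling <- function(x, scaling) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(sweep(as.matrix(x), 2, scaling$center), 2, scaling$scale, "/")
}

#' Invert stored scaling parameters
#' @param x scaled matrix or vector.
#' @param scaling list with `center` and `scale`.
#' @return matrix in raw units.
#' @export
invert_scaling <- function(x, scaling) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sweep(sweep(as.matrix(x), 2, scaling$scale, "*"), 2, scaling$center, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kennard-Stone train/test split
#'
#' Classic max-min coverage design: seed with the pair of compounds at
#' maximum Euclidean distance (autoscaled descriptors), then repeatedly add
#' the compound whose minimum distance to the selected set is largest, until
#' `n_train` compounds are selected.  Deterministic; ties are broken by the
#' lowest row index.
#'
#' @param desc a `descriptor_table`.
#' @param n_train number of training compounds, `1 < n_train <= n`.
#' @param scale autoscale descriptors before computing distances
#'   (default TRUE).
#' @return object of class `split_result` with `train_ids` (in selection
#'   order) and `test_ids` (original order).
#' @export
kennard_stone_split <- function(desc, n_train, scale = TRUE) {
  n <- length(desc$compound_ids)
  if (n_train <= 1 || n_train > n)
    stop("n_train must satisfy 1 < n_train <= n_compounds")
  X <- desc$values
  if (scale) {
    sdv <- apply(X, 2, stats::sd)
    keep <- sdv > 0
    X <- sweep(sweep(X[, keep, drop = FALSE], 2, colMeans(X[, keep,
                drop = FALSE])), 2, sdv[keep], "/")
  }
  D <- as.matrix(stats::dist(X))
  sel <- integer(0)
  # seed: global maximum-distance pair, lowest indices on ties
  idx <- which(D == max(D), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sel <- c(idx[1, 1], idx[1, 2])
  while (length(sel) < n_train) {
    remaining <- setdiff(seq_len(n), sel)
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)]  # which.max takes the first on ties
    sel <- c(sel, pick)
  }
  sel <- sel[seq_len(n_train)]
  structure(list(train_ids = desc$compound_ids[sel],
                 test_ids = desc$compound_ids[setdiff(seq_len(n), sel)]),
            class = "split_result")
}

#' Fit the linear lipophilicity extrapolation
#'
#' Ordinary least squares of `log k` on the organic-modifier fraction phi:
#' `log k = log kw + S * phi`.  `logkw`, the intercept at phi = 0, is the
#' chromatographic lipophilicity; `S` is the (negative) solvent-strength
#' slope.
#'
#' @param series a [retention_series()].
#' @return object of class `lipophilicity_fit` with `logkw`, `S`,
#'   `residual_sse`.
#' @export
fit_logkw <- function(series) {
  if (length(unique(series$phi)) < 2)
    stop("cannot fit: all phi values are equal")
  fit <- stats::lm(logk ~ phi, data = data.frame(phi = series$phi,
                                                 logk = series$logk))
  co <- stats::coef(fit)
  structure(list(logkw = unname(co[1]), S = unname(co[2]),
                 residual_sse = sum(stats::residuals(fit)^2)),
            class = "lipophilicity_fit")
}
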