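test_that("RSD filter removes near-constant and all-zero descriptors", {
  m <- cbind(const = rep(7, 3),        # RSD 0 -> removed
             spread = c(1, 2, 3),      # RSD 50% -> kept at threshold 5
             zero = rep(0, 3),         # all-zero -> removed
             centered = c(-1, 0, 1))   # mean 0, sd > 0 -> kept (undefined)
  dt <- descriptor_table(m)
  r <- rsd_filter(dt, threshold_pct = 5)
  expect_setequal(r$removed, c("const", "zero"))
  expect_setequal(r$surviving, c("spread", "centered"))
  expect_equal(unname(r$rsd["spread"]), 50)
  expect_error(rsd_filter(descriptor_table(m[1, , drop = FALSE])), "2")
  # inverted mode removes the high-RSD column instead
  expect_true("spread" %in% rsd_filter(dt, 5, invert = TRUE)$removed)
})

test_that("correlation filter drops the member less correlated with Y", {
  set.seed(5)
  base <- rnorm(20)
  y1 <- base + rnorm(20, sd = 0.1)
  m <- cbind(strong = base, clone = base, indep = rnorm(20))
  dt <- descriptor_table(m)
  pt <- property_table(dt$compound_ids, y1, rnorm(20))
  r <- correlation_filter(dt, pt, threshold = 0.8)
  expect_identical(r$removed, "clone")  # identical columns: tie -> keep first
  # orthogonal columns: nothing removed
  m2 <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  dt2 <- descriptor_table(m2)
  pt2 <- property_table(dt2$compound_ids, rnorm(4), rnorm(4))
  expect_length(correlation_filter(dt2, pt2)$removed, 0)
})

test_that("correlation filter matches brute-force rule application", {
  # independent oracle: walk pairs in descending |r|, drop lower-|rY| member
  oracle <- function(X, Y, thr) {
    R <- cor(X); diag(R) <- 0
    ry <- apply(abs(cor(X, Y)), 1, max)
    removed <- rep(FALSE, ncol(X))
    prs <- which(upper.tri(R) & abs(R) > thr, arr.ind = TRUE)
    prs <- prs[order(-abs(R[prs])), , drop = FALSE]
    for (k in seq_len(nrow(prs))) {
      i <- prs[k, 1]; j <- prs[k, 2]
      if (removed[i] || removed[j]) next
      if (ry[i] < ry[j]) removed[i] <- TRUE else removed[j] <- TRUE
    }
    colnames(X)[!removed]
  }
  for (seed in 1:5) {
    set.seed(seed)
    b <- rnorm(15)
    X <- cbind(d1 = b + rnorm(15, sd = 0.05),
               d2 = b + rnorm(15, sd = 0.05),
               d3 = -b + rnorm(15, sd = 0.05),
               d4 = rnorm(15))
    Y <- cbind(b + rnorm(15, sd = 0.3), rnorm(15))
    dt <- descriptor_table(X)
    pt <- property_table(dt$compound_ids, Y[, 1], Y[, 2])
    expect_identical(correlation_filter(dt, pt, 0.8)$surviving,
                     oracle(X, Y, 0.8))
  }
})

test_that("zero filter exempts binary and integer descriptors", {
  m <- cbind(cz = c(0, 1.2, 3.4), bin = c(0, 1, 0),
             int = c(0, 2, 5), pos = c(0.1, 1.2, 3.4))
  dt <- descriptor_table(m)
  r <- zero_filter(dt)
  expect_identical(r$removed, "cz")
  expect_setequal(r$surviving, c("bin", "int", "pos"))
})

test_that("filter chain partitions the descriptor names exactly", {
  ds <- toy_tables(n = 30, p = 20, seed = 3)
  rep_ <- filter_descriptors(ds$desc, ds$props)
  all_names <- sort(c(rep_$removed_by_rsd, rep_$removed_by_correlation,
                      rep_$removed_by_zero, rep_$surviving))
  expect_identical(all_names, sort(ds$desc$descriptor_names))
  f <- withr::local_tempfile(fileext = ".csv")
  write_filter_report(rep_, f)
  fates <- utils::read.csv(f)
  expect_identical(sort(fates$descriptor), all_names)
})

test_that("autoscale centers, scales, round-trips, and flags constants", {
  set.seed(2)
  X <- matrix(rnorm(40, mean = 5, sd = 3), 10, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  sc <- autoscale(X)
  expect_equal(unname(colMeans(sc$train)), rep(0, 4))
  expect_equal(unname(apply(sc$train, 2, sd)), rep(1, 4))
  expect_equal(invert_scaling(sc$train, sc$scaling), X, ignore_attr = TRUE)
  # a row at the training mean maps to zeros
  sc2 <- autoscale(X, apply_to = matrix(colMeans(X), 1))
  expect_equal(unname(drop(sc2$apply_to)), rep(0, 4))
  X[, 2] <- 1
  expect_error(autoscale(X), "c2")
})

test_that("Kennard-Stone matches brute-force max-min selection", {
  # exhaustive oracle over candidate picks
  ks_oracle <- function(X, n_train) {
    D <- as.matrix(dist(scale(X)))
    pair <- which(D == max(D), arr.ind = TRUE)
    pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
    pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
    sel <- c(pair[1, 1], pair[1, 2])
    while (length(sel) < n_train) {
      rem <- setdiff(seq_len(nrow(X)), sel)
      best <- rem[1]; bestd <- -Inf
      for (i in rem) {
        mind <- min(D[i, sel])
        if (mind > bestd) { bestd <- mind; best <- i }
      }
      sel <- c(sel, best)
    }
    sel
  }
  # line case, unscaled geometry preserved by scaling (single column)
  pts <- matrix(c(0, 1, 2, 7, 10), dimnames = list(paste0("P", 1:5), "x"))
  dt <- descriptor_table(pts)
  sp <- kennard_stone_split(dt, 3)
  expect_identical(sp$train_ids, paste0("P", ks_oracle(pts, 3)))
  # random sets up to 8 points
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(sprintf("c%02d", 1:n), paste0("d", 1:3)))
    sp <- kennard_stone_split(descriptor_table(X), n - 2)
    expect_identical(sp$train_ids,
                     sprintf("c%02d", ks_oracle(X, n - 2)))
  }
})

test_that("Kennard-Stone split sizes and equivariance", {
  ds <- toy_tables(n = 45, p = 8, seed = 9)
  sp <- kennard_stone_split(ds$desc, 33)
  expect_length(sp$train_ids, 33)
  expect_length(sp$test_ids, 12)
  expect_setequal(c(sp$train_ids, sp$test_ids), ds$desc$compound_ids)
  # relabeling rows permutes the output accordingly
  perm <- rev(ds$desc$compound_ids)
  sp2 <- kennard_stone_split(subset_descriptors(ds$desc, compounds = perm),
                             33)
  expect_setequal(sp2$train_ids, sp$train_ids)
  expect_error(kennard_stone_split(ds$desc, 1), "n_train")
  # n = 2 degenerate case: both compounds are the training set
  two <- subset_descriptors(ds$desc, compounds = ds$desc$compound_ids[1:2])
  expect_setequal(kennard_stone_split(two, 2)$train_ids,
                  two$compound_ids)
})

test_that("lipophilicity fit recovers the retention line", {
  # two points force the line: logkw 4, S -5
  f <- fit_logkw(retention_series(c(0.2, 0.4), c(3, 2)))
  expect_equal(f$logkw, 4)
  expect_equal(f$S, -5)
  expect_equal(f$residual_sse, 0)
  # noisy series equals the closed-form least-squares oracle
  set.seed(8)
  phi <- seq(0.1, 0.5, length.out = 5)
  logk <- 3.7 - 4.2 * phi + rnorm(5, sd = 0.05)
  f2 <- fit_logkw(retention_series(phi, logk))
  Xd <- cbind(1, phi)
  beta <- solve(crossprod(Xd), crossprod(Xd, logk))
  expect_equal(f2$logkw, beta[1], tolerance = 1e-12)
  expect_equal(f2$S, beta[2], tolerance = 1e-12)
  expect_error(retention_series(c(0.3, 0.3), c(1, 2)), "distinct")
})
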