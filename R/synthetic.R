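#' Specification of a synthetic descriptor/property dataset
#'
#' Describes a dataset with planted low-rank latent structure,
#' `X = T P' + E`, `Y = T C' + F`: a block of informative descriptors
#' driven by `latent_dim` latent scores, the remainder independent noise,
#' and the two responses labelled `logkw`/`logKi` generated from the same
#' scores.  A subset of the informative columns is dichotomized at its
#' median to emulate binary fingerprint descriptors.  The default shape
#' mirrors a small sulphonamide QSPR campaign: 45 compounds, a few hundred
#' candidate descriptors, two correlated drug properties.
#'
#' @param n_compounds,n_descriptors dataset shape (defaults 45 x 300).
#' @param latent_dim number of latent factors (default 4).
#' @param n_informative descriptors carrying latent signal (default 10).
#' @param n_binary informative descriptors dichotomized at the median
#'   (default 3, matching the typical share of fingerprint bits in a
#'   selected descriptor set).
#' @param noise_sd_x,noise_sd_y noise standard deviations (defaults 0.1).
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 45, n_descriptors = 300,
                           latent_dim = 4, n_informative = 10,
                           n_binary = 3, noise_sd_x = 0.1,
                           noise_sd_y = 0.1, seed = 1) {
  stopifnot(n_informative <= n_descriptors, latent_dim <= n_informative,
            n_binary <= n_informative, noise_sd_x >= 0, noise_sd_y >= 0,
            n_compounds >= 4)
  structure(list(n_compounds = n_compounds, n_descriptors = n_descriptors,
                 latent_dim = latent_dim, n_informative = n_informative,
                 n_binary = n_binary, noise_sd_x = noise_sd_x,
                 noise_sd_y = noise_sd_y, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with known truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `desc` (a `descriptor_table`), `props` (a
#'   `property_table`), and `truth` (class `synthetic_truth`: `P_true`,
#'   `C_true`, `informative_names`, `scores`, `Y_noiseless`,
#'   `binary_names`).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(spec$seed, {
    n <- spec$n_compounds; p <- spec$n_descriptors
    a <- spec$latent_dim; pi_ <- spec$n_informative
    Tm <- matrix(stats::rnorm(n * a), n, a)
    # planted loadings built from a randomly rotated harmonic tight frame:
    # columns orthogonal (every latent factor identifiable, condition
    # number <= 1.5) and row norms equal (every informative descriptor
    # carries the same signal strength, so none degenerates into a
    # noise-dominated column after autoscaling)
    rot <- if (a > 1) qr.Q(qr(matrix(stats::rnorm(a * a), a, a))) else
      matrix(1, 1, 1)
    P_true <- harmonic_frame(pi_, a) %*% rot %*%
      diag(sqrt(pi_ / a) * stats::runif(a, 0.8, 1.2), a)
    C_true <- if (a >= 2) {
      # orthogonal response loadings: both properties are stably
      # determined by the latent scores (a near-singular C would leave
      # one score direction unidentified by Y)
      diag(stats::runif(2, 0.8, 1.2), 2) %*%
        t(qr.Q(qr(matrix(stats::rnorm(a * 2), a, 2))))
    } else {
      matrix(stats::runif(2, 0.8, 1.2) *
               sample(c(-1, 1), 2, replace = TRUE), 2, 1)
    }
    X <- matrix(stats::rnorm(n * p), n, p)       # uninformative background
    X[, seq_len(pi_)] <- Tm %*% t(P_true) +
      stats::rnorm(n * pi_, sd = spec$noise_sd_x)
    ids <- sprintf("S%03d", seq_len(n))
    nms <- sprintf("D%03d", seq_len(p))
    binary_names <- character(0)
    if (spec$n_binary > 0) {
      bcols <- seq(pi_ - spec$n_binary + 1, pi_)
      for (j in bcols) X[, j] <- as.numeric(X[, j] > stats::median(X[, j]))
      binary_names <- nms[bcols]
    }
    Y0 <- Tm %*% t(C_true)
    Y <- Y0 + stats::rnorm(n * 2, sd = spec$noise_sd_y)
    dimnames(X) <- list(ids, nms)
    desc <- descriptor_table(X, compound_ids = ids, descriptor_names = nms)
    props <- property_table(ids, Y[, 1], Y[, 2])
    truth <- structure(list(P_true = P_true, C_true = C_true,
                            informative_names = nms[seq_len(pi_)],
                            binary_names = binary_names,
                            scores = Tm, Y_noiseless = Y0,
                            spec = spec),
                       class = "synthetic_truth")
    list(desc = desc, props = props, truth = truth)
  })
}

# m x a real Fourier basis subset with orthonormal columns and exactly
# equal row norms (sqrt(a/m)): the constant column, complete cos/sin
# frequency pairs, and (when needed) the Nyquist column
harmonic_frame <- function(m, a) {
  stopifnot(a <= m)
  j <- 0:(m - 1)
  use_dc <- a %% 2 == 1
  pairs <- (a - use_dc) / 2
  use_nyq <- FALSE
  if (pairs > floor((m - 1) / 2)) {   # only when a = m with m even
    use_dc <- TRUE; use_nyq <- TRUE
    pairs <- (a - 2) / 2
  }
  cols <- list()
  if (use_dc) cols <- c(cols, list(rep(1 / sqrt(m), m)))
  for (f in seq_len(pairs)) {
    cols <- c(cols, list(sqrt(2 / m) * cos(2 * pi * f * j / m)),
              list(sqrt(2 / m) * sin(2 * pi * f * j / m)))
  }
  if (use_nyq) cols <- c(cols, list((-1)^j / sqrt(m)))
  do.call(cbind, cols)
}

#' Reference properties from a synthetic compound
#'
#' Returns the noiseless properties (and descriptor row) of a chosen
#' compound, for inversion round-trip experiments that mirror inverting a
#' model toward the properties of a known reference ligand.
#'
#' @param dataset output of [generate_synthetic()].
#' @param compound_index row index of the reference compound.
#' @return list with `reference` (a [reference_properties()]),
#'   `descriptors` (named raw-unit vector), `compound_id`.
#' @export
make_reference <- function(dataset, compound_index) {
  truth <- dataset$truth
  n <- nrow(truth$scores)
  if (compound_index < 1 || compound_index > n)
    stop("compound_index out of range [1, ", n, "]")
  list(reference = reference_properties(
         truth$Y_noiseless[compound_index, 1],
         truth$Y_noiseless[compound_index, 2]),
       descriptors = dataset$desc$values[compound_index, ],
       compound_id = dataset$desc$compound_ids[compound_index])
}
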