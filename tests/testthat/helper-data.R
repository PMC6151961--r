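# shared fixtures, all generated in code

# small descriptor/property pair with named structure
toy_tables <- function(n = 12, p = 6, seed = 11) {
  ds <- generate_synthetic(synthetic_spec(
    n_compounds = n, n_descriptors = p, latent_dim = 2,
    n_informative = min(4, p), n_binary = 0,
    noise_sd_x = 0.2, noise_sd_y = 0.2, seed = seed))
  ds
}

# a fitted model plus its training data on a clean latent structure
fitted_fixture <- function(n = 40, p = 10, latent = 3, noise = 0.1,
                           A = latent, seed = 21) {
  ds <- generate_synthetic(synthetic_spec(
    n_compounds = n, n_descriptors = p, latent_dim = latent,
    n_informative = p, n_binary = 0,
    noise_sd_x = noise, noise_sd_y = noise, seed = seed))
  X <- ds$desc$values
  Y <- property_matrix(ds$props)
  rownames(Y) <- ds$props$compound_ids
  list(model = fit_pls(X, Y, A = A), X = X, Y = Y, ds = ds)
}

# published worked-example fixtures bundled with the package
example_path <- function(file) {
  system.file("extdata", "caix_example", file, package = "plsinvert",
              mustWork = TRUE)
}
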