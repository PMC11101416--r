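# shared fixtures, all built in code at test time

tiny_cohort <- function(n = 60, dims = c(a = 12, b = 30), seed = 1, ...) {
  generate_cohort(cohort_spec(n_samples = n, assay_dims = dims, latent_dim = 3,
                              noise_sd = 0.05, seed = seed, ...))
}

# one scaled, imputed assay ready for the autoencoder
scaled_assay <- function(cohort, assay = names(cohort$assays)[1]) {
  minmax_scale(impute_missing(cohort$assays[[assay]])$data)$data
}

# a small trained autoencoder for attribution tests
small_model <- function(d = 8, latent = 2, n = 80, seed = 5, epochs = 3) {
  co <- tiny_cohort(n = n, dims = setNames(d, "a"), seed = seed)
  m <- scaled_assay(co)
  train_autoencoder(m, build_encoder_spec(d, latent),
                    train_hyper(epochs = epochs, seed = seed))
}

# hand-built single-layer linear encoder g(x) = w'x + b for closed-form checks
linear_encoder <- function(w, b = 0) {
  d <- length(w)
  structure(list(
    spec = structure(list(input_dim = d, hidden_widths = integer(0),
                          latent_dim = 1L, hidden_activation = "relu",
                          final_activation = "sigmoid"),
                     class = "encoder_spec"),
    layers = list(list(W = matrix(w, d, 1), b = b, act = "linear"),
                  list(W = matrix(1, 1, d), b = rep(0, d), act = "sigmoid")),
    feature_names = paste0("f", seq_len(d)),
    n_encoder = 1L, assay = "linear", history = NULL),
    class = "trained_autoencoder")
}

# latent tibble of a given width, deterministic values
dummy_latent <- function(n, width, assay, offset = 0) {
  V <- matrix(seq_len(n * width) + offset, n, width)
  tensoromics:::new_omics_tbl(V, sprintf("S%03d", seq_len(n)),
                              paste0("latent_", seq_len(width)), assay)
}
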