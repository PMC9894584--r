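# shared fixtures, built in code

default_layout <- build_layout()
default_spec <- enumerate_sequences(default_layout)[[1]]

# well-separated 8-class samples: class means on a scaled identity basis
make_separable_samples <- function(n_per_class = 8, n_features = 16,
                                   sep = 5, noise = 0, seed = 1) {
  set.seed(seed)
  means <- matrix(0, 8, n_features)
  means[cbind(1:8, 1:8)] <- sep
  labels <- rep(1:8, each = n_per_class)
  feats <- means[labels, ] +
    matrix(rnorm(length(labels) * n_features, sd = noise),
           length(labels), n_features)
  structure(list(features = feats, labels = labels, window = c(3, 13.5)),
            class = "trial_samples")
}

# small noiseless subject: quick end-to-end fixture
make_noiseless_subject <- function(gamma = 0.4, model = "SR", seed = 7) {
  truth <- ground_truth(generative_model = model, gamma = gamma,
                        noise_sd = 0, hippocampus_noise_sd = 0)
  design <- build_session(default_spec, seed = seed)
  simulate_subject(design, truth, default_layout, seed = seed + 1)
}

# profile-level cohort: SR/CO/H0 prediction plus iid cell noise, for fast
# model-comparison tests that do not need the fMRI round trip
make_profile_cohort <- function(n = 35, model = "SR", gamma = 0.3,
                                omega = 0.2, a = 1, cell_sd = 0.05,
                                seed = 1) {
  set.seed(seed)
  base <- predict_partial(model, list(a = a, gamma = gamma, omega = omega))
  lapply(seq_len(n), function(i) base + matrix(rnorm(16, sd = cell_sd), 4, 4))
}
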