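# Shared fixtures: tiny designs and gaze matrices built in code.

# A design consisting only of test trials (no objects, no cues), useful
# for isolating the baseline/Dirichlet part of the model.
test_only_design <- function(n, sounds = rep(1L, n)) {
  trials <- lapply(seq_len(n), function(t)
    trial_spec(t, t, "test", sounds[t], integer(5), integer(5)))
  experiment_design("no_cue", trials, n_blocks = n, n_train_per_block = 0L)
}

uniform_gaze <- function(n, id = "u") {
  gaze_matrix(id, matrix(rep(0.2, 5 * n), n, 5))
}

# Random simplex rows.
random_gaze <- function(n, id = "r") {
  g <- matrix(rgamma(5 * n, shape = 1), n, 5)
  gaze_matrix(id, g / rowSums(g))
}

# A small single-table cluster state over flat parameter vectors.
simple_state <- function(n_infants, D = 2L) {
  theta <- stats::setNames(numeric(7 + 2 * D), gazelink:::param_names(D))
  cluster_state(rep(1L, n_infants), list(theta), kappa = 1,
                sparsity_scales = matrix(1, 1, 2 + 2 * D))
}
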