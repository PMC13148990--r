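# Shared simulated populations, built lazily once per run and cached so the
# expensive ones are reused across test files.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, envir = .fx_cache)) assign(name, make(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# small switching population (K = 12) for fast unit tests
fx_small <- function() cached("small", function() {
  ss <- make_stimulus_set(60, 60, D = 12, seed = 7)
  tr <- make_switching_truth(K = 12, n_cells = 20, flip_dims = 3, new_dims = 9,
                             seed = 8)
  pop <- simulate_population(ss, tr, time_ms = -50:249, n_repeats = 20, seed = 9)
  space <- fit_feature_space(ss$embeddings, K = 12)
  list(stimuli = ss, truth = tr, pop = pop, space = space,
       features = project_features(space, ss$embeddings),
       split = train_test_split(pop$category, seed = 10))
})

# matched noiseless no-switch population on the same stimuli
fx_stationary <- function() cached("stationary", function() {
  ss <- fx_small()$stimuli
  tr <- make_no_switch_truth(K = 12, n_cells = 20, flip_dims = 3, seed = 8)
  pop <- simulate_population(ss, tr, time_ms = -50:249, n_repeats = 1,
                             noise_override = "none", seed = 9)
  list(stimuli = ss, truth = tr, pop = pop,
       features = fx_small()$features, split = fx_small()$split)
})

# study-scale switching population (K = 60, 100 cells) shared by the
# acceptance suite
fx_big <- function() cached("big", function() {
  ss <- make_stimulus_set(250, 250, D = 60, seed = 1)
  tr <- make_switching_truth(K = 60, n_cells = 100, seed = 2)
  pop <- simulate_population(ss, tr, n_repeats = 10, seed = 3)
  space <- fit_feature_space(ss$embeddings, K = 60)
  features <- project_features(space, ss$embeddings)
  split <- train_test_split(pop$category, seed = 4)
  list(stimuli = ss, truth = tr, pop = pop, space = space,
       features = features, split = split)
})

fx_big_axes <- function() cached("big_axes", function() {
  fx <- fx_big()
  list(face = sliding_axes(fx$pop, fx$features, "face", split = fx$split),
       object = sliding_axes(fx$pop, fx$features, "object", split = fx$split))
})

# independent noise replicate of the big population (for debiased identity PSI)
fx_big_replicate <- function() cached("big_rep", function() {
  fx <- fx_big()
  simulate_population(fx$stimuli, fx$truth, n_repeats = 10, seed = 103)
})

# explicit pseudoinverse-with-intercept axis fit: the independent oracle for
# the closed-form QR solve
oracle_axis <- function(r, F, train_idx) {
  X <- cbind(1, F[train_idx, , drop = FALSE])
  beta <- solve(t(X) %*% X) %*% t(X) %*% r[train_idx]
  as.vector(beta[-1])
}
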