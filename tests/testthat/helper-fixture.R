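# Shared trained fixture for the behavioural and acceptance tests. Built
# once per test run on first use: a 5-layer network trained on the full
# 9-orientation x 5-color grating factorial at 64 px, with binary, color
# and softmax readouts, tuning and category-gradient tables.
.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_env$model)) {
    pop <- make_grating_population(size = 64, reps = 4, seed = 1)
    model <- train_fixture_network(pop, seed = 1)
    model <- attach_binary_readouts(model, default_orientations(), pop)
    model <- attach_color_readout(model, pop)
    clean <- make_grating_population(size = 64, reps = 1, seed = 11,
                                     degrade = FALSE)
    model <- compute_layer_means(model, clean$items)
    record <- activity_record(model, pop$items, pop$orientation)
    .fixture_env$model <- model
    .fixture_env$pop <- pop
    .fixture_env$clean <- clean
    .fixture_env$record <- record
    .fixture_env$tuning <- compute_tuning_values(record)
    .fixture_env$grads <- category_gradient_table(model, pop)
  }
  as.list(.fixture_env)
}

# Balanced two-grating test set for one condition, shared seed scheme.
fixture_test_set <- function(condition, n = 30, seed_base = 100) {
  build_balanced_detection_set(
    condition, n, two_grating_recipe(condition, canvas_size = 64),
    seed = seed_base + condition)
}
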