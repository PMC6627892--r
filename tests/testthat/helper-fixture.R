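# Shared fixtures, built once per test run. The default-configuration
# trained model is expensive (~2 min) and is shared by the acceptance
# criteria; the small model trains in seconds for unit tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.fixture_cache$dataset))
    .fixture_cache$dataset <- generate_dataset(generator_config())
  .fixture_cache$dataset
}

fixture_model <- function() {
  if (is.null(.fixture_cache$fit))
    .fixture_cache$fit <- train_fixture_model(fixture_dataset(),
                                              seed = 1L, epochs = 30L)
  .fixture_cache$fit
}

small_config <- function(seed = 7L) {
  generator_config(images_per_class = c(train = 6L, val = 2L, test = 2L),
                   seed = seed)
}

small_dataset <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- generate_dataset(small_config())
  .fixture_cache$small
}
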