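# Shared fixtures, built in code. The "micro" configuration is deliberately
# small (16 px images, width 16) so structural and gradient tests run in
# milliseconds; training-behavior tests use the tiny preset instead.

micro_config <- function(dropout = 0) {
  model_config("tiny", image_size = 16L, patch_size = 8L, embed_dim = 16L,
               depth = 2L, n_heads = 2L, ffn_dim = 24L, sfl_heads = 2L,
               sfl_ffn_dims = c(16L, 20L, 12L), dropout = dropout)
}

rand_image <- function(size, seed = 1) {
  stagevit:::with_seed(seed, array(stats::runif(size * size * 3), c(size, size, 3)))
}

# A handful of records per class from the default generator, cached per session.
micro_records <- local({
  cache <- NULL
  function(n_per_class = 2, image_size = 32, seed = 5) {
    key <- paste(n_per_class, image_size, seed)
    if (is.null(cache[[key]])) {
      ds <- generate_dataset(severity_params(n_per_class = n_per_class,
                                             image_size = image_size,
                                             seed = seed))
      cache[[key]] <<- ds
    }
    cache[[key]]
  }
})

# Micro records resized to 16 px for micro_config() training smoke tests.
micro_training_set <- function(n_per_class = 2, seed = 5) {
  ds <- micro_records(n_per_class, 32, seed)
  lapply(ds$records, function(r) {
    r$pixels <- preprocess(r$pixels, 16)
    r$mask <- NULL
    r
  })
}
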