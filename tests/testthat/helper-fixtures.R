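# Shared fixtures: small configs and random inputs built in code.

# 3x3 embedding grid, 4 channels, single head: the smallest configuration
# exercising every shape constraint (input/grid = 16).
tiny3_config <- function(embed_dim = 4L, n_heads = 1L) {
  backbone_config("tiny", input_size = 48L, grid_size = 3L,
                  embed_dim = embed_dim, n_heads = n_heads)
}

rand_tokens <- function(n, C) matrix(stats::rnorm(n * C), n, C)

rand_grid <- function(g, C) array(stats::rnorm(g * g * C), c(g, g, C))

# Internal accessors used across tests.
sf_ns <- asNamespace("segfuse")

# A tiny model whose backbone is frozen without pre-training (sufficient
# for contract tests that do not need segmentation quality).
frozen_toy_model <- function(seed = 1L, ...) {
  freeze(model_init(backbone_config("tiny", ...), seed = seed))
}

# Small phantom dataset for plumbing tests.
toy_dataset <- function(seed = 5L, n_cases = 10L, slices_per_case = 2L) {
  generate_dataset(phantom_spec(seed = seed), n_cases, slices_per_case)
}
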