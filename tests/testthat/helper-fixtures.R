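# shared builders for small test objects

tiny_schema <- function(codes) {
  df <- data.frame(code = codes,
                   component = icf_component(codes),
                   description = paste("cat", codes),
                   chapter = "test")
  class(df) <- c("icf_schema", "data.frame")
  df
}

# p independent-noise categories
noise_spec <- function(n, p, seed = 1, noise_sd = 1) {
  codes <- sprintf("d%03d", 100 + seq_len(p))
  synthetic_spec(n, tiny_schema(codes), noise_sd = noise_sd, seed = seed)
}

# directed chain over the given codes with one weight per step
chain_spec <- function(n, codes, weights, seed = 1, noise_sd = 0.5) {
  edges <- data.frame(source = codes[-length(codes)], target = codes[-1L],
                      weight = weights)
  synthetic_spec(n, tiny_schema(codes), edges, noise_sd = noise_sd,
                 seed = seed)
}

# dependence matrix of a cohort with small-grid settings for speed
quick_config <- function(...) {
  estimation_config(lambda_grid_size = 50L, ...)
}
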