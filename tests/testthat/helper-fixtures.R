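# benchmark bundles are deterministic; build each once per test session
.bench_cache <- new.env(parent = emptyenv())
get_bench <- function(name, seed = 1L) {
  key <- paste0(name, "_", seed)
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- make_benchmark(name, seed = seed)
  .bench_cache[[key]]
}

# small random zero-mean density grid
random_grid <- function(seed, n = 8L, a = 10) {
  set.seed(seed)
  v <- stats::rnorm(n^3)
  density_grid(unit_cell(a, grid = n), v - mean(v))
}

# the three-cosine P set: (100),(010),(001), unit amplitude, phase 0
p_cosine_set <- function(n = 16L, a = 1) {
  reflection_set(unit_cell(a, grid = n),
                 rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 rep(1, 3), rep(0, 3))
}
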