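# tiny local utilities for tests
axis_coords_test <- function(n, step) (seq_len(n) - 0.5) * step

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}
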