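# Shared helpers for building small test instances.

bits_from_strings <- function(strings) {
  t(vapply(strsplit(strings, ""), as.integer, integer(nchar(strings[1]))))
}

# random mixed-period attractor set in the small regime used for
# solver-vs-oracle comparisons
random_small_set <- function() {
  m <- sample(2:6, 1)
  n <- sample(6:16, 1)
  periods <- sample(1:3, m, replace = TRUE)
  random_attractor_set(n, m, periods)
}

# identity network on n nodes (every state is a fixed point)
identity_network <- function(n) {
  boolean_network(paste0("v", seq_len(n)),
                  inputs = as.list(seq_len(n)),
                  tables = rep(list(c(0L, 1L)), n))
}
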