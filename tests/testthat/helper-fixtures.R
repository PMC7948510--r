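# Small fixture builders shared across test files.

# A compact field: fewer, smaller nuclei than the defaults so unit tests are
# fast. Forward any generator argument.
small_field <- function(n_nuclei = 20, frac_positive = 0.5, seed = 1, ...) {
  simulate_nuclei_field(n_nuclei = n_nuclei, frac_positive = frac_positive,
                        width = 256, height = 256, nucleus_radius = 6,
                        seed = seed, ...)
}

small_control <- function(n_nuclei = 20, seed = 99, ...) {
  simulate_control_field(n_nuclei = n_nuclei, width = 256, height = 256,
                         nucleus_radius = 6, seed = seed, ...)
}

# A noiseless single-disk image with known geometry.
one_disk <- function(level = 30000, radius = 8, size = 64) {
  img <- matrix(0, size, size)
  ctr <- size / 2
  for (r in seq_len(size)) for (c in seq_len(size)) {
    if ((r - ctr)^2 + (c - ctr)^2 <= radius^2) img[r, c] <- level
  }
  img
}

# Exhaustive right-tail hypergeometric oracle: sum the point masses
# C(K, j) * C(N - K, n - j) / C(N, n) over j >= k by direct enumeration.
hyper_tail_oracle <- function(k, K, n, N) {
  js <- seq(max(k, 0), min(K, n))
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up written from its definition: sort, take
# p_(i) * m / i, enforce monotonicity from the largest p downwards.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
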