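# Shared fixtures, all built in code.

two_pop <- function() example_network()

# a small random dissipative network drawn from the study generator
random_net <- function(S, seed) {
  cfg <- generator_config(S = S, replicates = 1, seed = seed)
  generate_ensemble(cfg)[[1]]
}

# random bounded polytope: unit box cut by k random half-planes through
# the box interior (always contains a neighborhood of the box center)
random_box_cut <- function(d, k = 3, seed = 1) {
  set.seed(seed)
  A <- rbind(-diag(d), diag(d))
  b <- c(rep(0, d), rep(1, d))
  for (i in seq_len(k)) {
    a <- stats::rnorm(d)
    a <- a / sqrt(sum(a^2))
    x <- stats::runif(d, 0.25, 0.75)
    A <- rbind(A, a)
    b <- c(b, sum(a * x))
  }
  hpolytope(A, b)
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
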