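# Independent brute-force oracles and fixture builders used across tests.

# Exact two-sided Mann-Whitney p by full enumeration of all choose(n1+n2, n1)
# rank assignments (tie-free data only).  Independent of wilcox.test: works
# directly on the symmetric permutation distribution of U.
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ranks <- seq_len(n1 + n2)
  subsets <- utils::combn(ranks, n1)
  u_all <- colSums(subsets) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all 2^n sign
# vectors over the observed absolute-difference ranks.
wsr_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

# A random valid segment profile drawn from realistic clinical ranges; uses
# the caller's RNG stream.
random_profile <- function() {
  segment_profile(
    level = sample(segment_levels(), 1),
    linear_translation = runif(1, 0, 12),
    sagittal_angulation = runif(1, 0, 15),
    facet_angle = runif(1, 20, 130),
    tropism_present = sample(c(TRUE, FALSE, NA), 1),
    pfirrmann = sample(1:5, 1),
    fujiwara = sample(1:4, 1),
    adc = runif(1, 300, 2000),
    ivd_height = runif(1, 3, 14),
    height_loss_fraction = runif(1, 0.34, 0.66),
    general_lordosis = runif(1, 20, 60))
}

# The TDR-favourable nominal profile used in boundary probing.
tdr_nominal <- function() {
  segment_profile(linear_translation = 2, sagittal_angulation = 4,
                  facet_angle = 50, pfirrmann = "II", fujiwara = "I",
                  adc = 1540, height_loss_fraction = 0.5)
}
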