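# shared fixtures: small DVHs and random-DVH factory used across test files

uniform_dvh <- function(dose, organ = "lung", n = 1L)
  dvh(organ, dose, 1, n_fractions = n)

# random multi-bin differential DVH with a zero-dose bin
random_dvh <- function(organ = "lung", n_bins = 8, max_dose = 60, n_fx = 25L) {
  doses <- sort(stats::runif(n_bins, 0.1, max_dose))
  vols <- stats::runif(n_bins + 1)
  dvh(organ, c(0, doses), vols, n_fractions = n_fx)
}

lung_pars <- function() organ_params(dasu_default_params(), "lung")
lung_schneider <- function() organ_params(schneider_default_params(), "lung")

# independent closed-form evaluation of the competition-model per-voxel term,
# written against the formula, not the package internals
hand_dasu <- function(D, v, n, a1, a2, ab) {
  v <- v / sum(v)
  100 * sum(v * (a1 * D + (a1 / ab) * D^2 / n) *
              exp(-(a2 * D + (a2 / ab) * D^2 / n)))
}

hand_oed <- function(D, v, alpha) {
  v <- v / sum(v)
  sum(v * D * exp(-alpha * D))
}

# brute-force two-tailed signed-rank p over all 2^n sign assignments
brute_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  Vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  # two-tailed: doubled smaller tail, as for the exact distribution
  min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
}
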