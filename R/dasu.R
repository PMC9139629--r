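#' Secondary-malignancy risk from the linear-quadratic competition model
#'
#' The competition model balances induction of carcinogenic mutations
#' against killing of the mutated cells, giving a dose-response that rises
#' at low dose and decays at high dose. For a differential DVH with bin
#' doses \eqn{D_i}, volume fractions \eqn{v_i} and \eqn{n} fractions, the
#' risk is
#' \deqn{R = \frac{1}{\sum_i v_i} \sum_i v_i\,(\alpha_1 D_i + \beta_1 D_i^2/n)\,
#'       e^{-(\alpha_2 D_i + \beta_2 D_i^2/n)}}
#' with \eqn{\beta_k = \alpha_k / (\alpha/\beta)}. The quadratic terms carry
#' the per-fraction LQ correction \eqn{D_i d_i = D_i^2/n} with dose per
#' fraction \eqn{d_i = D_i/n}. `risk_type` selects the induction
#' coefficient: `"total"` (any secondary cancer) or `"fatal"` (fatal
#' secondary cancers only). The result is reported in percent.
#'
#' @param dvh A differential [dvh] (normalised; carries `n_fractions`).
#' @param params One-row parameter frame for the organ (see
#'   [dasu_default_params()], [organ_params()]), or a full registry from
#'   which the DVH's organ is looked up.
#' @param risk_type `"total"` or `"fatal"`.
#' @return Risk in percent (non-negative scalar).
#' @examples
#' d <- dvh("lung", bin_dose = 2, bin_volume_fraction = 1)
#' dasu_risk(d, dasu_default_params(), "total")
#' @export
dasu_risk <- function(dvh, params = dasu_default_params(),
                      risk_type = c("total", "fatal")) {
  risk_type <- match.arg(risk_type)
  stopifnot(inherits(dvh, "dvh"))
  if (!identical(dvh$form, "differential"))
    stop("'dvh' must be in differential form", call. = FALSE)
  if (nrow(params) > 1L) params <- organ_params(params, dvh$organ)
  tot <- sum(dvh$bin_volume_fraction)
  if (abs(tot - 1) > 1e-9)
    stop("DVH volume fractions must sum to 1 (got ", format(tot), ")",
         call. = FALSE)
  a1 <- if (risk_type == "total") params$alpha1_total else params$alpha1_fatal
  100 * sum(dvh$bin_volume_fraction *
              .dasu_term(dvh$bin_dose, dvh$n_fractions, a1,
                         params$alpha2, params$alpha_beta_ratio)) / tot
}

# per-voxel risk (probability, not percent) at total dose D in n fractions
.dasu_term <- function(D, n, alpha1, alpha2, ab) {
  beta1 <- alpha1 / ab
  beta2 <- alpha2 / ab
  (alpha1 * D + beta1 * D^2 / n) * exp(-(alpha2 * D + beta2 * D^2 / n))
}

#' Uniform-dose risk profile of the competition model
#'
#' Evaluates the competition-model risk for a series of uniform organ doses
#' (single-bin DVHs), e.g. to plot the rise-peak-decay dose-response.
#'
#' @param dose_grid Non-negative total doses in Gy.
#' @param params One-row organ parameter frame.
#' @param n_fractions Fraction count applied to every grid dose.
#' @param risk_type `"total"` or `"fatal"`.
#' @return Numeric vector of risks in percent, one per grid dose.
#' @export
dasu_risk_profile <- function(dose_grid, params, n_fractions = 1L,
                              risk_type = c("total", "fatal")) {
  risk_type <- match.arg(risk_type)
  dose_grid <- as.numeric(dose_grid)
  if (any(dose_grid < 0) || anyNA(dose_grid))
    stop("'dose_grid' must be non-negative", call. = FALSE)
  stopifnot(nrow(params) == 1L)
  a1 <- if (risk_type == "total") params$alpha1_total else params$alpha1_fatal
  100 * .dasu_term(dose_grid, as.integer(n_fractions), a1,
                   params$alpha2, params$alpha_beta_ratio)
}
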