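#' Default Dasu competition-model parameters
#'
#' Organ-specific coefficients for the linear-quadratic competition model:
#' the induction coefficient alpha1 (separately for total and fatal risk,
#' ICRP 103 risk coefficients per Gy), the cell-kill coefficient alpha2, and
#' the alpha/beta ratio from which the quadratic coefficients are derived
#' (`beta_k = alpha_k / alpha_beta_ratio`, never stored independently).
#'
#' alpha2 is not organ-specific in the shipped registry: 0.25 Gy^-1, the
#' value used in the competition-model literature, applies to every organ
#' and is an explicit, overridable column so that no run depends on a buried
#' constant. Left and right breast are distinct registry entries sharing the
#' breast coefficients, and thyroid shares them too (0.0028 fatal / 0.0144
#' total); each organ remains a separate row so lookup stays explicit.
#'
#' @return Data frame with columns `organ`, `alpha1_total`, `alpha1_fatal`,
#'   `alpha2` (all Gy^-1) and `alpha_beta_ratio` (Gy).
#' @export
dasu_default_params <- function() {
  data.frame(
    organ        = c("lung", "breast_left", "breast_right", "esophagus", "thyroid"),
    alpha1_total = c(0.0144, 0.0144, 0.0144, 0.0015, 0.0144),
    alpha1_fatal = c(0.0101, 0.0028, 0.0028, 0.0014, 0.0028),
    alpha2       = rep(0.25, 5L),
    alpha_beta_ratio = rep(3, 5L),
    stringsAsFactors = FALSE
  )
}

#' Default Schneider organ-equivalent-dose model parameters
#'
#' Organ-specific cancer incidence rate `I0` (per 10,000 patients per year
#' per Gy, as labelled in the source tables) and sterilization parameter
#' `alpha_org` (Gy^-1) governing the linear-exponential dose-response
#' `D * exp(-alpha_org * D)`.
#'
#' @return Data frame with columns `organ`, `I0`, `alpha_org`.
#' @export
schneider_default_params <- function() {
  data.frame(
    organ     = c("lung", "breast_left", "breast_right", "esophagus", "thyroid"),
    I0        = c(1.68, 0.78, 0.78, 0.61, 0.75),
    alpha_org = c(0.129, 0.08, 0.08, 0.274, 0.033),
    stringsAsFactors = FALSE
  )
}

#' Look up one organ's parameters in a registry
#'
#' @param params Parameter data frame with an `organ` column.
#' @param organ Organ name.
#' @return One-row data frame.
#' @export
organ_params <- function(params, organ) {
  stopifnot(is.data.frame(params), "organ" %in% names(params))
  i <- match(organ, params$organ)
  if (is.na(i))
    stop("organ '", organ, "' not found in parameter registry (have: ",
         paste(params$organ, collapse = ", "), ")", call. = FALSE)
  params[i, , drop = FALSE]
}

#' Read or write a parameter registry as YAML
#'
#' Registries are stored as a YAML mapping organ -> named coefficients,
#' the format shipped in `inst/extdata/`. Any coefficient column set is
#' supported; `read_params` reassembles the data frame.
#'
#' @param path YAML file path.
#' @return `read_params`: a data frame with an `organ` column.
#' @export
read_params <- function(path) {
  lst <- yaml::read_yaml(path)
  if (length(lst) == 0L) stop("empty parameter registry: ", path, call. = FALSE)
  rows <- lapply(names(lst), function(org)
    cbind(data.frame(organ = org, stringsAsFactors = FALSE),
          as.data.frame(lst[[org]])))
  do.call(rbind, rows)
}

#' @rdname read_params
#' @param params Parameter data frame.
#' @export
write_params <- function(params, path) {
  stopifnot(is.data.frame(params), "organ" %in% names(params))
  lst <- lapply(seq_len(nrow(params)), function(i)
    as.list(params[i, setdiff(names(params), "organ"), drop = FALSE]))
  names(lst) <- params$organ
  yaml::write_yaml(lst, path)
  invisible(path)
}
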