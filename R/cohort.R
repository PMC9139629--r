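#' Modality/organ DVH profiles for the synthetic cohort generator
#'
#' Each profile describes the qualitative shape of one organ's DVH under one
#' treatment modality as a three-component mixture:
#' \itemize{
#'   \item a spared component: a zero-dose bin whose volume fraction is
#'     drawn uniformly from `spared` (the organ volume the beams miss
#'     entirely). The upper end may exceed 1: draws at or above 1 are
#'     clamped and mean the organ is wholly outside the field (all risk
#'     metrics exactly 0), so the excess is the probability of complete
#'     sparing;
#'   \item a low/intermediate-dose bath: a beta-distributed dose plateau
#'     whose mean level, as a fraction of the prescription, is drawn from
#'     `bath`;
#'   \item a near-prescription component of volume fraction drawn from
#'     `high`, concentrated just below the prescription dose.
#' }
#' `concentration` is the beta concentration of the bath component (smaller
#' means a wider dose spread among the exposed volume).
#'
#' The shipped defaults are synthetic calibration, not measured data: they
#' encode the geometry of anterior-mediastinum irradiation — anterior proton
#' beams spare posterior organs (lungs, esophagus) and lateral breast tissue
#' far more than either photon technique, photon plans carry a low-dose
#' bath (larger for IMRT, at a lower level), and the thyroid profile is
#' identical across modalities, so any apparent modality difference for
#' thyroid is noise.
#'
#' @return Nested list `profiles[[modality]][[organ]]`, each element a list
#'   with `spared`, `bath`, `high` (length-2 ranges in `[0,1]`) and
#'   `concentration`.
#' @export
default_modality_profiles <- function() {
  prof <- function(spared, bath, high, concentration = 4)
    list(spared = spared, bath = bath, high = high,
         concentration = concentration)
  # thyroid sits at the field edge: in a sizeable share of patients it is
  # wholly outside the beams (spared draw clamped at 1, risk exactly 0),
  # and when exposed its dose is highly variable — same profile for all
  # three modalities, so any modality difference is noise
  thyroid <- prof(spared = c(0.55, 1.25), bath = c(0.05, 0.55),
                  high = c(0.00, 0.06), concentration = 2)
  list(
    `3DCRT` = list(
      lung         = prof(c(0.28, 0.45), c(0.10, 0.22), c(0.04, 0.09)),
      breast_left  = prof(c(0.15, 0.35), c(0.20, 0.40), c(0.02, 0.06)),
      breast_right = prof(c(0.15, 0.35), c(0.20, 0.40), c(0.02, 0.06)),
      esophagus    = prof(c(0.10, 0.28), c(0.18, 0.35), c(0.05, 0.12)),
      thyroid      = thyroid
    ),
    IMRT = list(
      lung         = prof(c(0.18, 0.36), c(0.08, 0.18), c(0.04, 0.09)),
      breast_left  = prof(c(0.22, 0.42), c(0.14, 0.30), c(0.02, 0.06)),
      breast_right = prof(c(0.22, 0.42), c(0.14, 0.30), c(0.02, 0.06)),
      esophagus    = prof(c(0.10, 0.28), c(0.17, 0.34), c(0.05, 0.12)),
      thyroid      = thyroid
    ),
    PBS = list(
      lung         = prof(c(0.58, 0.80), c(0.08, 0.20), c(0.04, 0.09)),
      breast_left  = prof(c(0.68, 0.90), c(0.05, 0.14), c(0.01, 0.04)),
      breast_right = prof(c(0.70, 0.92), c(0.04, 0.12), c(0.01, 0.03)),
      esophagus    = prof(c(0.45, 0.72), c(0.10, 0.24), c(0.03, 0.10)),
      thyroid      = thyroid
    )
  )
}

#' Read a modality/organ profile registry from YAML
#'
#' The YAML mirrors the structure of [default_modality_profiles()]
#' (modality -> organ -> spared/bath/high/concentration); a copy of the
#' shipped defaults lives at
#' `system.file("extdata", "modality_profiles.yaml", package = "smrisk")`.
#'
#' @param path YAML file path.
#' @return Nested profile list.
#' @export
read_modality_profiles <- function(path) {
  prof <- yaml::read_yaml(path)
  for (m in names(prof))
    for (org in names(prof[[m]])) {
      p <- prof[[m]][[org]]
      if (!all(c("spared", "bath", "high") %in% names(p)))
        stop("profile ", m, "/", org, " lacks spared/bath/high ranges",
             call. = FALSE)
      for (k in c("spared", "bath", "high")) {
        hi <- if (k == "spared") 2 else 1   # spared may clamp above 1
        if (length(p[[k]]) != 2L || any(p[[k]] < 0) || any(p[[k]] > hi))
          stop("profile ", m, "/", org, ": '", k,
               "' must be a length-2 range in [0,", hi, "]", call. = FALSE)
      }
    }
  prof
}

#' Prescription table of the modelled cohort
#'
#' The empirical (total dose, fractions) pairs the generator samples from:
#' 45–66 Gy in 25–33 fractions, median 54 Gy. One row per patient of the
#' modelled 17-patient cohort.
#'
#' @return Data frame with columns `dose_gy`, `fractions`.
#' @export
cohort_prescriptions <- function() {
  data.frame(
    dose_gy   = c(50, 50, 50, 54, 50, 50, 50, 54, 66, 66, 54, 54, 54, 45, 54, 54, 54),
    fractions = c(25, 25, 25, 27, 25, 25, 25, 27, 33, 33, 30, 30, 30, 25, 30, 30, 30)
  )
}

#' Specification of a synthetic cohort
#'
#' @param n_patients Number of patients (>= 2). Default 17, the size of the
#'   modelled cohort.
#' @param organs Organ names; must all be covered by the profile registry.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param prescriptions Data frame of candidate `(dose_gy, fractions)`
#'   pairs sampled per patient. Default [cohort_prescriptions()].
#' @param patient_sd Standard deviation of the shared per-patient anatomy
#'   random effect (logit/log scale). Default 0.5.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 17L,
                        organs = c("lung", "breast_left", "breast_right",
                                   "esophagus", "thyroid"),
                        seed = 1L,
                        prescriptions = cohort_prescriptions(),
                        patient_sd = 0.5) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L)
    stop("'n_patients' must be at least 2", call. = FALSE)
  stopifnot(is.data.frame(prescriptions),
            all(c("dose_gy", "fractions") %in% names(prescriptions)))
  structure(list(n_patients = n_patients, organs = organs,
                 seed = as.integer(seed), prescriptions = prescriptions,
                 patient_sd = patient_sd),
            class = "cohort_spec")
}

# deterministic 31-bit stream seed from the base seed and a label, so each
# (patient, modality, organ) draws from its own substream and adding an
# organ does not perturb the others
.stream_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483647)
}

#' Generate one synthetic DVH
#'
#' Draws a differential DVH on a 0.5 Gy bin grid spanning 0 to 1.1 times
#' the prescription: a zero-dose bin of the drawn spared fraction, a beta
#' bath component at the drawn mean level, and a near-prescription beta
#' component (concentration 60) of the drawn high-dose volume fraction.
#' `patient_effect` shifts the drawn spared fraction (negatively, so larger
#' effects mean more exposed volume) before the complete-sparing clamp and
#' scales the bath level multiplicatively; sharing it across a patient's
#' modalities creates the paired structure the cohort comparison relies
#' on, including patient-correlated complete sparing of edge organs.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param profile One profile entry (see [default_modality_profiles()]).
#' @param organ Organ name stored in the DVH.
#' @param prescription Prescription dose in Gy (> 0).
#' @param n_fractions Fraction count.
#' @param patient_effect Shared anatomy random effect (scalar, default 0).
#' @return A differential [dvh].
#' @export
generate_dvh <- function(profile, organ, prescription, n_fractions,
                         patient_effect = 0) {
  if (is.null(profile) || !all(c("spared", "bath", "high") %in% names(profile)))
    stop("invalid or missing modality/organ profile", call. = FALSE)
  if (prescription <= 0) stop("'prescription' must be > 0", call. = FALSE)
  dmax <- 1.1 * prescription
  edges <- seq(0, dmax, by = 0.5)
  if (edges[length(edges)] < dmax) edges <- c(edges, dmax)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2

  s0 <- stats::runif(1, profile$spared[1], profile$spared[2])
  if (profile$spared[2] >= 1 && s0 - 0.5 * patient_effect >= 1) {
    # edge organ wholly outside this patient's fields: the patient anatomy
    # term shifts the draw before the clamp, so complete sparing is
    # correlated across one patient's modality plans
    return(dvh(organ, 0, 1, n_fractions, prescription))
  }
  # interior sparing: patient effect acts on the logit scale (negated, so
  # larger effects mean more exposed volume)
  s0 <- min(max(s0, 1e-9), 1 - 1e-9)
  s <- stats::plogis(stats::qlogis(s0) - patient_effect)
  h <- min(stats::runif(1, profile$high[1], profile$high[2]), 1 - s)
  b <- 1 - s - h
  bath_level <- stats::runif(1, profile$bath[1], profile$bath[2]) *
    exp(0.25 * patient_effect)
  bath_mu <- min(max(bath_level * prescription / dmax, 0.01), 0.95)
  kap <- profile$concentration %||% 4
  bath_mass <- diff(stats::pbeta(edges / dmax, bath_mu * kap, (1 - bath_mu) * kap))
  high_mu <- prescription / dmax
  high_mass <- diff(stats::pbeta(edges / dmax, high_mu * 60, (1 - high_mu) * 60))
  vol <- c(s, b * bath_mass + h * high_mass)
  dvh(organ, c(0, mids), vol, n_fractions, prescription)
}

#' Generate a paired synthetic cohort
#'
#' For each patient, one prescription and one anatomy random effect are
#' drawn once and shared across that patient's three modality plans (the
#' within-patient pairing a signed-rank comparison needs); the modality
#' profiles then shape each plan's DVHs. Every random draw flows from
#' `spec$seed` through named substreams keyed by patient, modality and
#' organ, so the same spec always reproduces the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param profiles Profile registry covering every (modality, organ) pair;
#'   default [default_modality_profiles()].
#' @return A `cohort_plan_set`: list with `patients` (ids), `plans`
#'   (`plans[[patient]][[modality]][[organ]]` = [dvh]), and `meta`
#'   (`meta[[patient]][[modality]]` = list with `patient_id`, `modality`,
#'   `prescription_dose`, `n_fractions`).
#' @export
generate_cohort <- function(spec, profiles = default_modality_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  modalities <- names(profiles)
  for (m in modalities)
    for (org in spec$organs)
      if (is.null(profiles[[m]][[org]]))
        stop("no profile for modality '", m, "', organ '", org, "'",
             call. = FALSE)

  ids <- sprintf("P%02d", seq_len(spec$n_patients))
  plans <- stats::setNames(vector("list", length(ids)), ids)
  meta <- stats::setNames(vector("list", length(ids)), ids)

  for (i in seq_along(ids)) {
    pid <- ids[[i]]
    set.seed(.stream_seed(spec$seed, paste0("patient/", pid)))
    rx_row <- spec$prescriptions[sample.int(nrow(spec$prescriptions), 1L), ]
    u <- stats::rnorm(1, 0, spec$patient_sd)
    plans[[pid]] <- stats::setNames(vector("list", length(modalities)), modalities)
    meta[[pid]] <- stats::setNames(vector("list", length(modalities)), modalities)
    for (m in modalities) {
      meta[[pid]][[m]] <- list(patient_id = pid, modality = m,
                               prescription_dose = rx_row$dose_gy,
                               n_fractions = as.integer(rx_row$fractions))
      organ_dvhs <- stats::setNames(vector("list", length(spec$organs)), spec$organs)
      for (org in spec$organs) {
        set.seed(.stream_seed(spec$seed, paste(pid, m, org, sep = "/")))
        organ_dvhs[[org]] <- generate_dvh(profiles[[m]][[org]], org,
                                          rx_row$dose_gy,
                                          as.integer(rx_row$fractions),
                                          patient_effect = u)
      }
      plans[[pid]][[m]] <- organ_dvhs
    }
  }
  structure(list(patients = ids, plans = plans, meta = meta),
            class = "cohort_plan_set")
}

#' @export
print.cohort_plan_set <- function(x, ...) {
  orgs <- names(x$plans[[1]][[1]])
  cat(sprintf("<cohort_plan_set> %d patients x %d modalities (%s) x %d organs (%s)\n",
              length(x$patients), length(x$plans[[1]]),
              paste(names(x$plans[[1]]), collapse = ", "),
              length(orgs), paste(orgs, collapse = ", ")))
  invisible(x)
}

#' Write a cohort to DVH table files plus a manifest
#'
#' One DVH table file per (patient, modality, organ) in the [load_dvh_table()]
#' format, and a JSON manifest mapping patient -> modality -> organ ->
#' relative file path, with plan metadata alongside.
#'
#' @param cohort A `cohort_plan_set`.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_plan_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(patients = list())
  for (pid in cohort$patients) {
    pm <- list()
    for (m in names(cohort$plans[[pid]])) {
      files <- list()
      for (org in names(cohort$plans[[pid]][[m]])) {
        rel <- file.path("dvh", sprintf("%s_%s_%s.csv", pid, m, org))
        dir.create(file.path(dir, "dvh"), showWarnings = FALSE)
        write_dvh_table(cohort$plans[[pid]][[m]][[org]], file.path(dir, rel))
        files[[org]] <- rel
      }
      pm[[m]] <- list(meta = cohort$meta[[pid]][[m]], dvh = files)
    }
    manifest$patients[[pid]] <- pm
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort from a manifest written by [write_cohort()]
#'
#' @param manifest_path Path to `manifest.json`; DVH paths are resolved
#'   relative to its directory.
#' @return A `cohort_plan_set`.
#' @export
read_cohort <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  ids <- names(man$patients)
  plans <- stats::setNames(vector("list", length(ids)), ids)
  meta <- stats::setNames(vector("list", length(ids)), ids)
  for (pid in ids) {
    plans[[pid]] <- list()
    meta[[pid]] <- list()
    for (m in names(man$patients[[pid]])) {
      entry <- man$patients[[pid]][[m]]
      meta[[pid]][[m]] <- entry$meta
      plans[[pid]][[m]] <- lapply(entry$dvh, function(rel)
        load_dvh_table(file.path(base, rel)))
    }
  }
  structure(list(patients = ids, plans = plans, meta = meta),
            class = "cohort_plan_set")
}
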