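test_that("generated DVHs validate and full sparing yields zero risk", {
  profiles <- default_modality_profiles()
  set.seed(1)
  d <- generate_dvh(profiles$PBS$lung, "lung", 54, 27L)
  expect_s3_class(d, "dvh")
  expect_equal(sum(d$bin_volume_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(d$bin_dose) > 0))
  expect_identical(d$n_fractions, 27L)

  # profile forcing complete sparing: single zero-dose bin, all metrics 0
  full <- list(spared = c(1.0, 1.0), bath = c(0.1, 0.2), high = c(0, 0.05),
               concentration = 4)
  set.seed(2)
  z <- generate_dvh(full, "esophagus", 54, 27L)
  expect_identical(z$bin_dose, 0)
  expect_identical(dasu_risk(z, dasu_default_params(), "total"), 0)
  expect_identical(oed(z, schneider_default_params()), 0)

  expect_error(generate_dvh(NULL, "lung", 54, 27L), "profile")
  expect_error(generate_dvh(profiles$PBS$lung, "lung", -5, 27L), "> 0")
})

test_that("the same seed reproduces DVHs and whole cohorts exactly", {
  profiles <- default_modality_profiles()
  set.seed(99)
  a <- generate_dvh(profiles$IMRT$breast_left, "breast_left", 50, 25L)
  set.seed(99)
  b <- generate_dvh(profiles$IMRT$breast_left, "breast_left", 50, 25L)
  expect_identical(a, b)

  c1 <- generate_cohort(cohort_spec(n_patients = 4L, seed = 3L))
  c2 <- generate_cohort(cohort_spec(n_patients = 4L, seed = 3L))
  expect_identical(c1, c2)
})

test_that("mean dose over many draws matches the mixture expectation", {
  # lung 3DCRT profile, fixed prescription, no patient effect: the
  # expected mean dose of the mixture is
  #   E[1 - s - h] * E[bath_level] * Rx + E[h] * Rx
  prof <- default_modality_profiles()$`3DCRT`$lung
  rx <- 54
  n_rep <- 3000
  set.seed(17)
  means <- replicate(n_rep, mean_dose(generate_dvh(prof, "lung", rx, 27L)))
  es <- mean(prof$spared)
  eh <- mean(prof$high)
  eb <- mean(prof$bath)
  expected <- (1 - es - eh) * eb * rx + eh * rx
  se <- sd(means) / sqrt(n_rep)
  expect_lt(abs(mean(means) - expected), 3 * se + 0.02)
})

test_that("cohort has the paired cardinality and shared prescriptions", {
  spec <- cohort_spec(n_patients = 17L, seed = 1L)
  co <- generate_cohort(spec)
  expect_length(co$patients, 17)
  expect_equal(sum(lengths(lapply(unlist(co$plans, recursive = FALSE),
                                  names))), 17 * 3 * 5)
  for (pid in co$patients) {
    rx <- sapply(co$meta[[pid]], function(m) m$prescription_dose)
    fx <- sapply(co$meta[[pid]], function(m) m$n_fractions)
    expect_length(unique(rx), 1)
    expect_length(unique(fx), 1)
    # prescriptions come only from the tabulated support
    expect_true(any(cohort_prescriptions()$dose_gy == rx[1] &
                      cohort_prescriptions()$fractions == fx[1]))
    for (m in names(co$plans[[pid]]))
      for (org in names(co$plans[[pid]][[m]]))
        expect_equal(sum(co$plans[[pid]][[m]][[org]]$bin_volume_fraction), 1,
                     tolerance = 1e-9)
  }
})

test_that("patient anatomy effect induces positive cross-modality correlation", {
  co <- generate_cohort(cohort_spec(n_patients = 17L, seed = 4L))
  md <- sapply(c("3DCRT", "IMRT", "PBS"), function(m)
    sapply(co$patients, function(p) mean_dose(co$plans[[p]][[m]]$lung)))
  expect_gt(cor(md[, "3DCRT"], md[, "IMRT"], method = "spearman"), 0)
  expect_gt(cor(md[, "3DCRT"], md[, "PBS"], method = "spearman"), 0)
})

test_that("median lung risk orders PBS below both photon techniques", {
  pars <- dasu_default_params()
  for (s in 1:10) {
    co <- generate_cohort(cohort_spec(seed = s, organs = "lung"))
    risk <- sapply(c("3DCRT", "IMRT", "PBS"), function(m)
      stats::median(sapply(co$patients, function(p)
        dasu_risk(co$plans[[p]][[m]]$lung, pars, "total"))))
    expect_lt(risk["PBS"], risk["3DCRT"])
    expect_lt(risk["PBS"], risk["IMRT"])
  }
})

test_that("thyroid profile is the same object for all three modalities", {
  profiles <- default_modality_profiles()
  expect_identical(profiles$`3DCRT`$thyroid, profiles$IMRT$thyroid)
  expect_identical(profiles$`3DCRT`$thyroid, profiles$PBS$thyroid)
})

test_that("cohorts round-trip through manifest and DVH files", {
  co <- generate_cohort(cohort_spec(n_patients = 3L, seed = 8L,
                                    organs = c("lung", "thyroid")))
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(man))
  co2 <- read_cohort(man)
  expect_identical(co2$patients, co$patients)
  for (pid in co$patients)
    for (m in names(co$plans[[pid]]))
      for (org in names(co$plans[[pid]][[m]])) {
        expect_equal(co2$plans[[pid]][[m]][[org]]$bin_dose,
                     co$plans[[pid]][[m]][[org]]$bin_dose, tolerance = 1e-9)
        expect_equal(co2$plans[[pid]][[m]][[org]]$bin_volume_fraction,
                     co$plans[[pid]][[m]][[org]]$bin_volume_fraction,
                     tolerance = 1e-9)
      }
})

test_that("profile registry files validate on read", {
  path <- system.file("extdata", "modality_profiles.yaml", package = "smrisk")
  prof <- read_modality_profiles(path)
  expect_setequal(names(prof), c("3DCRT", "IMRT", "PBS"))
  expect_equal(prof$PBS$lung$spared, default_modality_profiles()$PBS$lung$spared)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(PBS = list(lung = list(spared = c(0, 0.5)))), bad)
  expect_error(read_modality_profiles(bad), "lacks")
})
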