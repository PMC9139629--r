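test_that("signed-rank p-values match brute-force enumeration for n <= 12", {
  set.seed(13)
  for (n in 2:12) {
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    if (length(d) < 2) next
    x <- cumsum(abs(d)) + 10   # arbitrary paired baseline
    y <- x - d
    got <- wilcoxon_paired(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p.value, brute_signrank_p(d), tolerance = 1e-12,
                 label = sprintf("n=%d", n))
  }
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_paired(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("classic small-sample cases come out exactly", {
  # five all-positive differences: two-tailed p = 2/2^5
  w <- wilcoxon_paired(6:10, 5:9 - c(0, 1, 2, 3, 4))
  expect_equal(w$p.value, 0.0625, tolerance = 1e-15)

  # identical vectors: defined result, not an error
  w0 <- wilcoxon_paired(1:5, 1:5)
  expect_identical(w0$p.value, 1)
  expect_true(w0$all_zero)

  # n = 17 with a constant shift is decisive
  set.seed(3)
  x <- rnorm(17)
  expect_lt(wilcoxon_paired(x + 5, x)$p.value, 0.001)

  expect_error(wilcoxon_paired(1:3, 1:2), "equal length")
})

test_that("two-tailed p is antisymmetric and zeros are dropped", {
  set.seed(37)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_paired(x, y)$p.value,
               wilcoxon_paired(y, x)$p.value, tolerance = 1e-15)

  # zero differences reduce the effective n
  x2 <- c(x, 1, 2); y2 <- c(y, 1, 2)
  expect_identical(wilcoxon_paired(x2, y2)$n, 10L)
  expect_equal(wilcoxon_paired(x2, y2)$p.value,
               wilcoxon_paired(x, y)$p.value, tolerance = 1e-15)
})

test_that("ties and large n switch to the corrected normal approximation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(2, 1, 5, 2, 7, 3, 10, 4)   # tied |differences|
  w <- wilcoxon_paired(x, y)
  expect_identical(w$method, "approximate")
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE, correct = FALSE))
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-9)

  set.seed(41)
  x <- rnorm(40); y <- rnorm(40)
  expect_identical(wilcoxon_paired(x, y)$method, "approximate")
  expect_identical(wilcoxon_paired(x, y, exact_threshold = 40L)$method, "exact")
})

test_that("per-patient metrics equal direct single-DVH calls", {
  co <- generate_cohort(cohort_spec(n_patients = 2L, seed = 5L,
                                    organs = c("lung", "esophagus")))
  m <- evaluate_cohort(co)
  expect_identical(nrow(m), 2L * 3L * 2L)
  i <- which(m$patient_id == "P02" & m$modality == "IMRT" & m$organ == "lung")
  d <- co$plans$P02$IMRT$lung
  expect_equal(m$dasu_total[i], dasu_risk(d, dasu_default_params(), "total"),
               tolerance = 1e-15)
  expect_equal(m$dasu_fatal[i], dasu_risk(d, dasu_default_params(), "fatal"),
               tolerance = 1e-15)
  expect_equal(m$oed[i], oed(d, schneider_default_params()), tolerance = 1e-15)

  # missing organ in one modality is a pairing error naming the patient
  co$plans$P01$PBS$lung <- NULL
  expect_error(evaluate_cohort(co), "P01")
})

test_that("comparison table reports medians, ranges and raw p-values", {
  co <- generate_cohort(cohort_spec(seed = 1L))
  m <- evaluate_cohort(co)
  tab <- build_comparison_table(m)
  expect_identical(nrow(tab), 5L * 3L)
  expect_true(all(tab$p_pbs_vs_3dcrt >= 0 & tab$p_pbs_vs_3dcrt <= 1))

  # medians equal an independent sort-based median of the column
  v <- m$dasu_total[m$organ == "lung" & m$modality == "PBS"]
  sorted <- sort(v)
  expect_length(v, 17)
  expect_equal(tab$median_pbs[tab$organ == "lung" & tab$metric == "dasu_total"],
               sorted[9], tolerance = 1e-15)
  expect_equal(tab$min_pbs[tab$organ == "lung" & tab$metric == "dasu_total"],
               min(v), tolerance = 1e-15)

  # lung sparing by protons is significant against both photon plans
  lung <- tab[tab$organ == "lung" & tab$metric == "dasu_total", ]
  expect_lte(lung$p_pbs_vs_3dcrt, 0.05)
  expect_lte(lung$p_pbs_vs_imrt, 0.05)
  expect_true(lung$sig_pbs_vs_3dcrt)

  # markdown rendering carries one row per table row
  md <- format_comparison_markdown(tab)
  expect_length(md, nrow(tab) + 2)
  expect_match(md[1], "PBS vs 3DCRT")
})

test_that("identical plans across modalities give p = 1 and equal medians", {
  co <- generate_cohort(cohort_spec(n_patients = 5L, seed = 9L, organs = "lung"))
  for (pid in co$patients) {
    co$plans[[pid]]$IMRT <- co$plans[[pid]]$`3DCRT`
    co$plans[[pid]]$PBS <- co$plans[[pid]]$`3DCRT`
  }
  tab <- build_comparison_table(evaluate_cohort(co))
  expect_true(all(tab$p_pbs_vs_3dcrt == 1))
  expect_true(all(tab$median_pbs == tab$median_x3dcrt))
})

test_that("null cohorts with identical profiles keep type-I error near nominal", {
  # all three modalities share one profile -> exchangeable paired values
  profiles <- default_modality_profiles()
  null_prof <- profiles
  for (m in names(null_prof)) null_prof[[m]]$lung <- profiles$`3DCRT`$lung
  rej <- 0; n_sim <- 300
  for (s in seq_len(n_sim)) {
    co <- generate_cohort(cohort_spec(seed = 50000 + s, organs = "lung"),
                          profiles = null_prof)
    m <- evaluate_cohort(co)
    p <- wilcoxon_paired(m$dasu_total[m$modality == "PBS"],
                         m$dasu_total[m$modality == "3DCRT"])$p.value
    rej <- rej + (p <= 0.05)
  }
  # 3 standard errors around 0.05 for 300 simulations
  expect_lt(abs(rej / n_sim - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})
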