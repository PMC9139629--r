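#' Per-patient risk metrics for a whole cohort
#'
#' Runs both risk models over every (patient, modality, organ) DVH: the
#' competition-model total and fatal risks (percent), the organ equivalent
#' dose (Gy) and the incidence rate derived from it.
#'
#' @param cohort A `cohort_plan_set` (see [generate_cohort()],
#'   [read_cohort()]).
#' @param dasu_params Competition-model registry; default
#'   [dasu_default_params()].
#' @param schneider_params OED-model registry; default
#'   [schneider_default_params()].
#' @param incidence_form Passed to [schneider_incidence()].
#' @return Data frame with one row per (patient, modality, organ) and
#'   columns `patient_id`, `modality`, `organ`, `dasu_total`, `dasu_fatal`,
#'   `oed`, `schneider_incidence`.
#' @export
evaluate_cohort <- function(cohort,
                            dasu_params = dasu_default_params(),
                            schneider_params = schneider_default_params(),
                            incidence_form = c("as_printed", "linear_in_oed")) {
  stopifnot(inherits(cohort, "cohort_plan_set"))
  incidence_form <- match.arg(incidence_form)
  organs <- names(cohort$plans[[cohort$patients[[1]]]][[1]])
  rows <- list()
  for (pid in cohort$patients) {
    for (m in names(cohort$plans[[pid]])) {
      have <- names(cohort$plans[[pid]][[m]])
      missing <- setdiff(organs, have)
      if (length(missing))
        stop("patient ", pid, ", modality ", m, ": missing organ(s) ",
             paste(missing, collapse = ", "), call. = FALSE)
      for (org in organs) {
        d <- cohort$plans[[pid]][[m]][[org]]
        sp <- organ_params(schneider_params, org)
        o <- oed(d, sp)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, modality = m, organ = org,
          dasu_total = dasu_risk(d, organ_params(dasu_params, org), "total"),
          dasu_fatal = dasu_risk(d, organ_params(dasu_params, org), "fatal"),
          oed = o,
          schneider_incidence = schneider_incidence(o, sp, incidence_form),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test on within-patient differences. Zero
#' differences are dropped before ranking (the classical convention;
#' `zero_method = "pratt"` instead ranks them and then discards their
#' ranks). With no ties among the non-zero absolute differences and a
#' post-drop sample size at most `exact_threshold`, the exact null
#' distribution of the positive-rank sum is used; otherwise a normal
#' approximation with tie-corrected variance. If every difference is zero
#' the test is undefined and `p = 1` is returned with `all_zero = TRUE`
#' rather than an error, so degenerate cohort cells stay reportable.
#'
#' @param x,y Paired numeric vectors (same patients, same order), length
#'   >= 2.
#' @param zero_method `"drop"` (default) or `"pratt"`.
#' @param exact_threshold Largest post-drop n for which the exact null
#'   distribution is used (default 25, covering the 17-patient design).
#' @return List with `statistic` (positive-rank sum V), `n` (post-drop
#'   pairs), `p.value` (two-tailed), `method` (`"exact"` or
#'   `"approximate"`), `all_zero`.
#' @export
wilcoxon_paired <- function(x, y, zero_method = c("drop", "pratt"),
                            exact_threshold = 25L) {
  zero_method <- match.arg(zero_method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    stop("'x' and 'y' must be paired vectors of equal length >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data", call. = FALSE)
  d <- x - y
  if (all(d == 0))
    return(list(statistic = 0, n = 0L, p.value = 1,
                method = "degenerate", all_zero = TRUE))

  if (zero_method == "drop") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))          # zeros share the lowest ranks ...
    r <- r[d != 0]             # ... then their ranks are discarded
    d <- d[d != 0]
  }
  n <- length(d)
  V <- sum(r[d > 0])
  ties <- any(duplicated(r))

  if (!ties && n <= exact_threshold) {
    # exact null distribution of the positive-rank sum over 2^n signings
    p <- 2 * min(stats::psignrank(V, n), 1 - stats::psignrank(V - 1, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approximate"
  }
  list(statistic = V, n = n, p.value = min(p, 1),
       method = method, all_zero = FALSE)
}

#' Cohort-level paired comparison table
#'
#' Summarises a per-patient metric table (from [evaluate_cohort()]) per
#' (organ, metric): the median and range of the per-patient values under
#' each modality, plus the three pairwise signed-rank p-values
#' (PBS vs 3DCRT, PBS vs IMRT, IMRT vs 3DCRT). No multiple-testing
#' correction is applied across organs, metrics or pairs: every p-value is
#' reported raw, per cell, and flagged against the two-tailed significance
#' level `alpha`.
#'
#' @param metrics Per-patient metric data frame from [evaluate_cohort()].
#' @param metric_cols Metric columns to summarise.
#' @param alpha Two-tailed significance level for the `sig_*` flags
#'   (default 0.05).
#' @param ... Passed to [wilcoxon_paired()].
#' @return Data frame of class `comparison_table`: one row per
#'   (organ, metric) with `median_`, `min_`, `max_` columns per modality,
#'   three `p_` columns and matching `sig_` logical flags.
#' @export
build_comparison_table <- function(metrics,
                                   metric_cols = c("dasu_total", "dasu_fatal",
                                                   "schneider_incidence"),
                                   alpha = 0.05, ...) {
  stopifnot(is.data.frame(metrics),
            all(c("patient_id", "modality", "organ") %in% names(metrics)),
            all(metric_cols %in% names(metrics)))
  modalities <- c("3DCRT", "IMRT", "PBS")
  if (!all(modalities %in% unique(metrics$modality)))
    stop("metrics must cover modalities ", paste(modalities, collapse = ", "),
         call. = FALSE)
  pairs <- list(p_pbs_vs_3dcrt = c("PBS", "3DCRT"),
                p_pbs_vs_imrt  = c("PBS", "IMRT"),
                p_imrt_vs_3dcrt = c("IMRT", "3DCRT"))
  organs <- unique(metrics$organ)
  pts <- sort(unique(metrics$patient_id))

  rows <- list()
  for (org in organs) {
    sub <- metrics[metrics$organ == org, , drop = FALSE]
    # per-modality patient-aligned value matrix per metric
    for (mc in metric_cols) {
      vals <- sapply(modalities, function(m) {
        v <- sub[sub$modality == m, , drop = FALSE]
        idx <- match(pts, v$patient_id)
        if (anyNA(idx))
          stop("incomplete pairing for organ ", org, ", modality ", m,
               ": missing patients ", paste(pts[is.na(idx)], collapse = ", "),
               call. = FALSE)
        v[[mc]][idx]
      })
      row <- data.frame(organ = org, metric = mc, stringsAsFactors = FALSE)
      for (m in modalities) {
        key <- tolower(gsub("3DCRT", "x3dcrt", m))
        row[[paste0("median_", key)]] <- stats::median(vals[, m])
        row[[paste0("min_", key)]] <- min(vals[, m])
        row[[paste0("max_", key)]] <- max(vals[, m])
      }
      for (pn in names(pairs)) {
        w <- wilcoxon_paired(vals[, pairs[[pn]][1]], vals[, pairs[[pn]][2]], ...)
        row[[pn]] <- w$p.value
      }
      row$sig_pbs_vs_3dcrt <- row$p_pbs_vs_3dcrt <= alpha
      row$sig_pbs_vs_imrt <- row$p_pbs_vs_imrt <= alpha
      row$sig_imrt_vs_3dcrt <- row$p_imrt_vs_3dcrt <= alpha
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", class(out))
  out
}

#' Render a comparison table as markdown
#'
#' Human-readable twin of the CSV output: one `median (min-max)` cell per
#' modality and the three pairwise p-values, in the column order
#' 3DCRT, IMRT, PBS, PBS vs 3DCRT, PBS vs IMRT, IMRT vs 3DCRT.
#'
#' @param tab A `comparison_table`.
#' @param digits Significant digits for medians/ranges.
#' @return Character vector of markdown lines.
#' @export
format_comparison_markdown <- function(tab, digits = 3) {
  stopifnot(inherits(tab, "comparison_table"))
  fm <- function(x) formatC(x, digits = digits, format = "g")
  fp <- function(p) ifelse(p < 0.001, "p < 0.001", sprintf("p = %.3f", p))
  cell <- function(key) sprintf("%s (%s-%s)",
                                fm(tab[[paste0("median_", key)]]),
                                fm(tab[[paste0("min_", key)]]),
                                fm(tab[[paste0("max_", key)]]))
  c("| Organ | Metric | 3DCRT | IMRT | PBS | PBS vs 3DCRT | PBS vs IMRT | IMRT vs 3DCRT |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s | %s | %s | %s |",
            tab$organ, tab$metric,
            cell("x3dcrt"), cell("imrt"), cell("pbs"),
            fp(tab$p_pbs_vs_3dcrt), fp(tab$p_pbs_vs_imrt),
            fp(tab$p_imrt_vs_3dcrt)))
}
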