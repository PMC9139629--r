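#' Construct a dose-volume histogram object
#'
#' A `dvh` is the canonical input to both risk models: a differential
#' histogram of the dose an organ receives, stored as bin-centre doses (Gy)
#' and the fraction of organ volume in each bin, together with the
#' fractionation context of the plan. Unirradiated volume is carried
#' explicitly as a zero-dose bin so that volume-weighted sums run over the
#' whole organ.
#'
#' @param organ Organ name (single string).
#' @param bin_dose Numeric vector of bin-centre doses in Gy, strictly
#'   increasing, all non-negative.
#' @param bin_volume_fraction Numeric vector of non-negative relative
#'   volumes, same length as `bin_dose`. For `form = "differential"` these
#'   are renormalised to sum to 1.
#' @param n_fractions Number of fractions the total dose is delivered in
#'   (positive integer). Default 1.
#' @param prescription_dose Prescription dose in Gy (optional metadata).
#' @param form `"differential"` (default) or `"cumulative"`. Cumulative
#'   input is converted with [cumulative_to_differential()] so the stored
#'   object is always differential.
#' @return An object of class `dvh`.
#' @examples
#' d <- dvh("lung", bin_dose = c(0, 10, 20),
#'          bin_volume_fraction = c(0.5, 0.3, 0.2), n_fractions = 25)
#' mean_dose(d)
#' @export
dvh <- function(organ, bin_dose, bin_volume_fraction, n_fractions = 1L,
                prescription_dose = NA_real_, form = c("differential", "cumulative")) {
  form <- match.arg(form)
  if (!is.character(organ) || length(organ) != 1L || !nzchar(organ))
    stop("'organ' must be a non-empty string", call. = FALSE)
  bin_dose <- as.numeric(bin_dose)
  bin_volume_fraction <- as.numeric(bin_volume_fraction)
  if (length(bin_dose) == 0L)
    stop("empty DVH: at least one bin is required", call. = FALSE)
  if (length(bin_dose) != length(bin_volume_fraction))
    stop("'bin_dose' and 'bin_volume_fraction' must have the same length", call. = FALSE)
  if (anyNA(bin_dose) || anyNA(bin_volume_fraction))
    stop("DVH bins must not contain NA", call. = FALSE)
  if (any(bin_dose < 0))
    stop("doses must be non-negative", call. = FALSE)
  if (is.unsorted(bin_dose, strictly = TRUE))
    stop("'bin_dose' must be strictly increasing", call. = FALSE)
  if (any(bin_volume_fraction < 0))
    stop("volumes must be non-negative", call. = FALSE)
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L)
    stop("'n_fractions' must be a positive integer", call. = FALSE)

  if (form == "cumulative") {
    return(cumulative_to_differential(
      structure(list(organ = organ, bin_dose = bin_dose,
                     bin_volume_fraction = bin_volume_fraction,
                     n_fractions = n_fractions,
                     prescription_dose = prescription_dose,
                     form = "cumulative"),
                class = "dvh")))
  }

  total <- sum(bin_volume_fraction)
  if (total <= 0)
    stop("total volume must be positive", call. = FALSE)
  structure(list(organ = organ,
                 bin_dose = bin_dose,
                 bin_volume_fraction = bin_volume_fraction / total,
                 n_fractions = n_fractions,
                 prescription_dose = prescription_dose,
                 form = "differential"),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> organ=%s, %d bins, mean dose %.3f Gy, %d fx%s\n",
              x$organ, length(x$bin_dose), mean_dose(x), x$n_fractions,
              if (is.na(x$prescription_dose)) ""
              else sprintf(", Rx %.1f Gy", x$prescription_dose)))
  invisible(x)
}

#' Volume-weighted mean dose of a DVH
#'
#' @param dvh A [dvh] object (differential).
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dvh) {
  stopifnot(inherits(dvh, "dvh"))
  sum(dvh$bin_dose * dvh$bin_volume_fraction) / sum(dvh$bin_volume_fraction)
}

#' Convert a cumulative DVH to differential form
#'
#' A cumulative DVH tabulates the volume receiving at least each dose; its
#' successive differences give the volume in each dose interval. The
#' differential bin dose is taken at the interval midpoint (second-order
#' accurate); volume remaining beyond the last tabulated dose is assumed
#' zero. Total volume is conserved: the differential volumes sum to the
#' cumulative value at the lowest dose.
#'
#' @param dvh A `dvh` whose `form` is `"cumulative"`: `bin_volume_fraction`
#'   non-increasing in dose.
#' @return A differential [dvh].
#' @export
cumulative_to_differential <- function(dvh) {
  stopifnot(inherits(dvh, "dvh"))
  if (!identical(dvh$form, "cumulative"))
    stop("'dvh' is not in cumulative form", call. = FALSE)
  v <- dvh$bin_volume_fraction
  d <- dvh$bin_dose
  if (any(diff(v) > 1e-12))
    stop("cumulative volume must be non-increasing in dose", call. = FALSE)
  if (length(d) == 1L) {
    # single point: all tabulated volume sits at that dose
    return(dvh(dvh$organ, d, v, dvh$n_fractions, dvh$prescription_dose))
  }
  dv <- -diff(v)                      # volume lost across each interval
  mids <- (d[-length(d)] + d[-1L]) / 2
  tail_v <- v[length(v)]              # volume at/above the last dose point
  if (tail_v > 0) {
    mids <- c(mids, d[length(d)])
    dv <- c(dv, tail_v)
  }
  keep <- dv > 0 | seq_along(dv) == 1L  # keep first bin even if empty
  # collapse duplicate midpoints is unnecessary: mids strictly increasing
  dvh(dvh$organ, mids[keep], dv[keep], dvh$n_fractions, dvh$prescription_dose)
}

#' Re-accumulate a differential DVH
#'
#' Inverse of [cumulative_to_differential()] up to the binning: returns the
#' cumulative volume fraction at each differential bin dose (volume
#' receiving at least that bin's dose).
#'
#' @param dvh A differential [dvh].
#' @return Data frame with columns `dose_gy` and `cum_volume_fraction`.
#' @export
differential_to_cumulative <- function(dvh) {
  stopifnot(inherits(dvh, "dvh"), identical(dvh$form, "differential"))
  v <- dvh$bin_volume_fraction
  data.frame(dose_gy = dvh$bin_dose,
             cum_volume_fraction = rev(cumsum(rev(v))))
}

#' Split every DVH bin into equal-volume sub-bins
#'
#' Each bin's volume is divided among `factor` sub-bins at the same dose.
#' Because both risk models are volume-weighted sums of per-dose terms, any
#' metric computed before and after rebinning is identical to floating-point
#' precision; the operation exists to test that invariance.
#'
#' @param dvh A differential [dvh].
#' @param factor Positive integer; `1` returns the DVH unchanged.
#' @return A [dvh] with `factor` times as many bins.
#' @export
rebin <- function(dvh, factor) {
  stopifnot(inherits(dvh, "dvh"), identical(dvh$form, "differential"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("'factor' must be a positive integer", call. = FALSE)
  if (factor == 1L) return(dvh)
  # sub-bins repeat the parent dose; built directly since the constructor
  # requires strictly increasing doses for tabulated input
  out <- dvh
  out$bin_dose <- rep(dvh$bin_dose, each = factor)
  out$bin_volume_fraction <- rep(dvh$bin_volume_fraction / factor, each = factor)
  out
}

#' Read a DVH table file
#'
#' The interchange format is a two-column delimited text table (`dose_gy`,
#' `volume`), comma- or tab-separated (autodetected), with an optional
#' `#`-prefixed header carrying `organ=`, `form=`, `volume_mode=`,
#' `n_fractions=` and `prescription_gy=` keys. Doses are in Gy; a
#' `dose_scale` argument rescales if the source used other units (no silent
#' unit guessing). Absolute volumes are normalised by their total;
#' cumulative tables are converted to differential form.
#'
#' @param path Path to the table file.
#' @param form `"differential"` or `"cumulative"`; a `form=` header key
#'   takes precedence when `form` is `NULL`.
#' @param volume_mode `"relative"` or `"absolute"`; header key
#'   `volume_mode=` takes precedence when `NULL`.
#' @param organ Organ name; header key `organ=` used when `NULL`.
#' @param n_fractions Fractions; header key used when `NULL`; default 1.
#' @param dose_scale Multiplier applied to the dose column (e.g. `0.01` for
#'   a table in cGy). Default 1.
#' @return A differential [dvh].
#' @seealso [write_dvh_table()]
#' @export
load_dvh_table <- function(path, form = NULL, volume_mode = NULL,
                           organ = NULL, n_fractions = NULL, dose_scale = 1) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L)
    stop("empty DVH table: ", path, call. = FALSE)

  keys <- .parse_header_keys(hdr)
  if (is.null(organ)) organ <- keys[["organ"]] %||% "unknown"
  if (is.null(form)) form <- keys[["form"]] %||% "differential"
  if (is.null(volume_mode)) volume_mode <- keys[["volume_mode"]] %||% "relative"
  if (is.null(n_fractions))
    n_fractions <- as.integer(keys[["n_fractions"]] %||% "1")
  prescription <- as.numeric(keys[["prescription_gy"]] %||% NA)
  form <- match.arg(form, c("differential", "cumulative"))
  volume_mode <- match.arg(volume_mode, c("relative", "absolute"))

  sep <- if (grepl("\t", body[[1]])) "\t" else ","
  # drop a non-numeric header row if present
  first <- strsplit(body[[1]], sep, fixed = TRUE)[[1]]
  if (suppressWarnings(is.na(as.numeric(trimws(first[[1]])))))
    body <- body[-1L]
  if (length(body) == 0L)
    stop("empty DVH table: ", path, call. = FALSE)
  parts <- strsplit(body, sep, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("malformed DVH table row in ", path, call. = FALSE)
  dose <- suppressWarnings(as.numeric(vapply(parts, function(p) trimws(p[[1]]), "")))
  vol <- suppressWarnings(as.numeric(vapply(parts, function(p) trimws(p[[2]]), "")))
  if (anyNA(dose) || anyNA(vol))
    stop("non-numeric entries in DVH table ", path, call. = FALSE)
  dose <- dose * dose_scale
  if (is.unsorted(dose, strictly = TRUE))
    stop("dose column must be strictly increasing in ", path, call. = FALSE)
  if (any(vol < 0))
    stop("negative volume in DVH table ", path, call. = FALSE)
  # relative-vs-absolute only changes the normalising constant, which the
  # constructor applies for differential form; cumulative keeps its scale
  if (form == "cumulative" && volume_mode == "absolute" && max(vol) > 0)
    vol <- vol / max(vol)
  dvh(organ, dose, vol, n_fractions, prescription, form = form)
}

#' Write a DVH to the interchange table format
#'
#' @param dvh A differential [dvh].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [load_dvh_table()]
#' @export
write_dvh_table <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh"), identical(dvh$form, "differential"))
  hdr <- c(sprintf("# organ=%s", dvh$organ),
           "# form=differential",
           "# volume_mode=relative",
           sprintf("# n_fractions=%d", dvh$n_fractions),
           if (!is.na(dvh$prescription_dose))
             sprintf("# prescription_gy=%.6g", dvh$prescription_dose),
           "dose_gy,volume")
  rows <- sprintf("%.12g,%.12g", dvh$bin_dose, dvh$bin_volume_fraction)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

.parse_header_keys <- function(hdr) {
  out <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    for (kv in strsplit(h, "\\s+")[[1]]) {
      if (grepl("=", kv, fixed = TRUE)) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        out[[p[[1]]]] <- p[[2]]
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
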