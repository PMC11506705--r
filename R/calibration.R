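# Calibration curves, detection/quantification limits and single-point
# quantification for stable-isotope-dilution assays.

#' Fit a light/heavy calibration curve
#'
#' Ordinary least squares of the observed light/heavy ratio (LH) on the spiked
#' light amount, via [stats::lm()]. Reports the adjusted r-squared, the
#' residual standard error s_yx = sqrt(SSres / (n - 2)) (set only when n >= 3),
#' and, when the slope is positive and s_yx is available, the detection and
#' quantification limits via [lod_loq()].
#'
#' @param points data.frame with columns `amount` (>= 0) and `lh` (>= 0), one
#'   row per replicate injection; a `replicate` column is allowed and ignored.
#' @param peptide Optional peptide identifier stored on the curve.
#' @return A `calibration_curve` object: list with `peptide`, `slope`,
#'   `intercept`, `r2` (adjusted), `s_yx`, `lod`, `loq`, `n_points`.
#' @export
fit_calibration <- function(points, peptide = NA_character_) {
  stopifnot(is.data.frame(points), all(c("amount", "lh") %in% names(points)))
  if (any(points$amount < 0) || any(points$lh < 0)) {
    stop("amounts and LH ratios must be non-negative", call. = FALSE)
  }
  n <- nrow(points)
  if (n < 2L || length(unique(points$amount)) < 2L) {
    stop("calibration requires at least 2 distinct amounts", call. = FALSE)
  }
  fit <- stats::lm(lh ~ amount, data = points)
  # summary.lm warns on zero-residual fits; exact lines are legitimate here
  sm <- suppressWarnings(summary(fit))
  s_yx <- if (n >= 3L) sm$sigma else NA_real_
  curve <- structure(list(
    peptide = peptide,
    slope = unname(stats::coef(fit)[["amount"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r2 = sm$adj.r.squared,
    s_yx = s_yx,
    lod = NA_real_, loq = NA_real_,
    n_points = n), class = "calibration_curve")
  if (!is.na(s_yx) && curve$slope > 0) {
    lim <- lod_loq(curve)
    curve$lod <- lim[["lod"]]
    curve$loq <- lim[["loq"]]
  }
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve%s: LH = %.5g * amount + %.5g\n  adj r2 = %.5g, s_yx = %.4g, n = %d\n  LOD = %.4g, LOQ = %.4g\n",
    if (is.na(x$peptide)) "" else paste0(" [", x$peptide, "]"),
    x$slope, x$intercept, x$r2, x$s_yx, x$n_points, x$lod, x$loq))
  invisible(x)
}

#' Detection and quantification limits from a calibration curve
#'
#' The calibration-curve method: LOD = 3.3 * s_yx / slope and
#' LOQ = 10 * s_yx / slope, where s_yx is the residual standard error of the
#' fitted line. The LOQ/LOD ratio is 10/3.3 by construction. An alternative
#' blank-based sigma can be supplied in place of the curve's own residual
#' scatter.
#'
#' @param curve A `calibration_curve` from [fit_calibration()].
#' @param sigma Optional dispersion estimate overriding `curve$s_yx` (e.g. the
#'   standard deviation of blank responses).
#' @return Named numeric vector `c(lod = , loq = )`, in amount units.
#' @export
lod_loq <- function(curve, sigma = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  s <- if (is.null(sigma)) curve$s_yx else sigma
  if (is.na(s)) stop("no residual standard error available (n < 3)", call. = FALSE)
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("LOD/LOQ require a positive slope", call. = FALSE)
  }
  c(lod = 3.3 * s / curve$slope, loq = 10 * s / curve$slope)
}

#' Single-point quantification
#'
#' Quantifies a sample from one observed LH ratio. In `"proportional"` mode
#' (the default) the response is assumed proportional to amount through one
#' reference point: amount = lh * reference_amount / reference_lh. In
#' `"curve"` mode the fitted line is inverted:
#' amount = (lh - intercept) / slope; a negative result is reported as 0 with
#' a warning.
#'
#' @param lh Observed light/heavy ratio (>= 0).
#' @param reference List or data.frame row with `amount` and `lh` of the
#'   reference calibration point (proportional mode).
#' @param mode `"proportional"` or `"curve"`.
#' @param curve A `calibration_curve` (curve mode).
#' @return Estimated amount, in the reference/curve amount units.
#' @export
single_point_quantify <- function(lh, reference = NULL,
                                  mode = c("proportional", "curve"),
                                  curve = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(lh), length(lh) == 1L, lh >= 0)
  if (mode == "proportional") {
    if (is.null(reference) || is.null(reference$amount) || is.null(reference$lh)) {
      stop("proportional mode needs a reference point with amount and lh",
           call. = FALSE)
    }
    if (reference$lh <= 0) stop("reference LH must be positive", call. = FALSE)
    lh * reference$amount / reference$lh
  } else {
    if (!inherits(curve, "calibration_curve")) {
      stop("curve mode needs a calibration_curve", call. = FALSE)
    }
    amount <- (lh - curve$intercept) / curve$slope
    if (amount < 0) {
      warning("computed amount below zero; reported as 0", call. = FALSE)
      amount <- 0
    }
    amount
  }
}

#' Total amount across peptide forms with per-form external curves
#'
#' When a peptide is detected as several digestion forms (fully cleaved plus
#' missed-cleavage species), each form is quantified against its own
#' calibration curve (for blood samples, an external curve built from light
#' synthetic missed-cleavage peptides) and the amounts are summed. A form
#' whose estimate falls below its curve's LOD contributes 0 and is flagged.
#'
#' @param forms List of lists, each with `form` (label), `signal` (LH ratio or
#'   area, matching what its curve was fitted on), and `curve`
#'   (a `calibration_curve`).
#' @return List with `total` and `per_form` (data.frame: `form`, `amount`,
#'   `below_lod`).
#' @export
external_curve_correct <- function(forms) {
  if (length(forms) < 1L) stop("at least one form is required", call. = FALSE)
  rows <- lapply(forms, function(f) {
    if (is.null(f$form)) stop("each form needs a 'form' label", call. = FALSE)
    if (!inherits(f$curve, "calibration_curve")) {
      stop(sprintf("form '%s' has no calibration curve", f$form), call. = FALSE)
    }
    amount <- (f$signal - f$curve$intercept) / f$curve$slope
    amount <- max(amount, 0)
    below <- !is.na(f$curve$lod) && amount < f$curve$lod
    data.frame(form = f$form,
               amount = if (below) 0 else amount,
               below_lod = below, stringsAsFactors = FALSE)
  })
  per_form <- do.call(rbind, rows)
  list(total = sum(per_form$amount), per_form = per_form)
}
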