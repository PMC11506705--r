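# From transition-level peak areas to absolute subtype amounts and
# H1-complement (percentage) profiles.

#' Light/heavy ratio from transition peak areas
#'
#' Sums light areas over the fragments observed in *both* labels and divides
#' by the matched heavy sum (intersection rule: a fragment present in only
#' one label is ignored, so the ratio always compares like with like).
#'
#' @param records data.frame for one peptide / sample / replicate with columns
#'   `label` (`"light"`/`"heavy"`), `fragment`, `area` (>= 0).
#' @return The LH ratio (numeric scalar).
#' @export
lh_ratio <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("label", "fragment", "area") %in% names(records)))
  if (any(records$area < 0)) stop("areas must be non-negative", call. = FALSE)
  light <- records[records$label == "light", , drop = FALSE]
  heavy <- records[records$label == "heavy", , drop = FALSE]
  shared <- intersect(unique(light$fragment), unique(heavy$fragment))
  if (length(shared) == 0L) {
    stop("no fragment observed in both light and heavy labels", call. = FALSE)
  }
  num <- sum(light$area[light$fragment %in% shared])
  den <- sum(heavy$area[heavy$fragment %in% shared])
  if (den == 0) stop("heavy area sum is zero", call. = FALSE)
  num / den
}

#' LH ratio with oxidation correction
#'
#' For methionine-containing peptides the oxidized and canonical forms are
#' summed at the area level, per label and fragment, before ratioing:
#' (L_canonical + L_oxidized) / (H_canonical + H_oxidized). An oxidized form
#' observed in only one label still contributes to that label's sum. With no
#' oxidized rows present this reduces exactly to [lh_ratio()].
#'
#' @param records data.frame as in [lh_ratio()] plus a `form` column
#'   containing `"canonical"` and/or `"oxidized"`.
#' @return The oxidation-corrected LH ratio.
#' @export
combine_oxidized <- function(records) {
  stopifnot(is.data.frame(records), "form" %in% names(records))
  keep <- records[records$form %in% c("canonical", "oxidized"), , drop = FALSE]
  if (nrow(keep) == 0L) stop("no canonical or oxidized rows", call. = FALSE)
  agg <- stats::aggregate(area ~ label + fragment, data = keep, FUN = sum)
  lh_ratio(agg)
}

#' Convert a peptide amount to a normalized subtype amount
#'
#' Assumes 1:1 peptide:protein stoichiometry. Molar amounts (fmol) are
#' converted to mass (ng) through the subtype's molar mass
#' (ng = fmol * g/mol * 1e-6), then divided by the normalizer: micrograms of
#' protein extract or millilitres of peripheral blood processed.
#'
#' @param amount Peptide amount (>= 0).
#' @param unit_in `"ng"` or `"fmol"`.
#' @param molar_mass Subtype molar mass in g/mol (required for fmol input);
#'   compute it from the sequence with [average_mass()].
#' @param normalizer `"ug_extract"` or `"ml_blood"`.
#' @param normalizer_value Amount of extract (ug) or blood (mL) the sample
#'   represents; must be positive.
#' @return Normalized amount: ng per ug extract, or ng per mL blood.
#' @export
to_absolute <- function(amount, unit_in = c("ng", "fmol"), molar_mass = NULL,
                        normalizer = c("ug_extract", "ml_blood"),
                        normalizer_value = 1) {
  unit_in <- match.arg(unit_in)
  normalizer <- match.arg(normalizer)
  stopifnot(is.numeric(amount), amount >= 0)
  if (normalizer_value <= 0) stop("normalizer must be positive", call. = FALSE)
  ng <- if (unit_in == "fmol") {
    if (is.null(molar_mass)) stop("fmol input needs a molar mass", call. = FALSE)
    amount * molar_mass * 1e-6
  } else amount
  ng / normalizer_value
}

#' Complement profile: subtype percentages of total
#'
#' Expresses each quantifiable subtype as a percentage of the summed amount.
#' Subtypes flagged below the quantification limit are excluded and the
#' remaining percentages renormalized to 100 (they are reported in
#' `excluded`).
#'
#' @param quants data.frame with columns `subtype`, `amount` and optionally
#'   `below_loq` (logical).
#' @param sample Optional sample id carried through.
#' @return List with `sample`, `percent` (named vector summing to 100),
#'   `total` (sum of included amounts) and `excluded` (character vector).
#' @export
complement_profile <- function(quants, sample = NA_character_) {
  stopifnot(is.data.frame(quants),
            all(c("subtype", "amount") %in% names(quants)))
  below <- if (is.null(quants$below_loq)) rep(FALSE, nrow(quants)) else
    isTRUE_vec(quants$below_loq)
  keep <- quants[!below, , drop = FALSE]
  if (nrow(keep) == 0L) stop("all subtypes are below LOQ", call. = FALSE)
  total <- sum(keep$amount)
  if (total <= 0) stop("total quantified amount is zero", call. = FALSE)
  list(sample = sample,
       percent = stats::setNames(100 * keep$amount / total, keep$subtype),
       total = total,
       excluded = quants$subtype[below])
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Gel-band composition model
#'
#' Maps electrophoretic bands of a linker-histone acid extract to the subtypes
#' they contain. The default reflects an SDS-PAGE separation into three bands:
#' high molecular weight (H1.3, H1.4, H1.5), intermediate (H1.1, H1.2) and low
#' (H1.0); H1X runs outside these bands and is handled by renormalization in
#' [expected_band_percentages()].
#'
#' @param bands Named list of character vectors; bands must be disjoint.
#' @return A `band_model` list.
#' @export
band_model <- function(bands = list(high = c("H1.3", "H1.4", "H1.5"),
                                    intermediate = c("H1.1", "H1.2"),
                                    low = "H1.0")) {
  if (length(bands) == 0L) stop("band model is empty", call. = FALSE)
  all_members <- unlist(bands, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("bands must be disjoint", call. = FALSE)
  }
  structure(bands, class = "band_model")
}

#' Expected gel-band percentages from a complement profile
#'
#' Subtypes not assigned to any band (e.g. H1X) are removed and the remaining
#' percentages renormalized to 100 before summation per band, giving the
#' percentages expected in each electrophoretic band for comparison with
#' densitometry.
#'
#' @param profile Output of [complement_profile()].
#' @param model A [band_model()].
#' @return Named numeric vector of band percentages (summing to 100).
#' @export
expected_band_percentages <- function(profile, model = band_model()) {
  stopifnot(inherits(model, "band_model"))
  pct <- profile$percent
  in_band <- names(pct) %in% unlist(model, use.names = FALSE)
  pct <- pct[in_band]
  if (length(pct) == 0L || sum(pct) == 0) {
    stop("no banded subtype with positive percentage", call. = FALSE)
  }
  pct <- 100 * pct / sum(pct)
  vapply(model, function(members) sum(pct[names(pct) %in% members]),
         numeric(1))
}

#' Coefficient of variation across replicates
#'
#' 100 * sd / mean with the sample (n - 1) standard deviation.
#'
#' @param amounts Numeric vector of per-replicate amounts (length >= 2).
#' @return CV in percent.
#' @export
replicate_cv <- function(amounts) {
  if (length(amounts) < 2L) stop("CV needs at least 2 replicates", call. = FALSE)
  m <- mean(amounts)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  100 * stats::sd(amounts) / m
}

#' Quantify subtype amounts from a transition-level peak-area report
#'
#' The full per-sample quantification path: for every assay peptide, the LH
#' ratio is computed per replicate (with area-level oxidation correction when
#' oxidized rows are present), converted to an amount by single-point
#' calibration against the known heavy spike, and averaged across replicates.
#' Missed-cleavage forms, which have no heavy counterpart, are quantified from
#' their light areas against per-form external curves and added at the amount
#' level. Subtypes whose mean amount falls below a supplied LOQ are flagged.
#'
#' @param report Peak-area data.frame (see [read_peak_report()]).
#' @param assay Assay definition data.frame with at least `subtype` and
#'   `peptide` columns (see [read_assay()]).
#' @param heavy_spike_ng Named vector (by peptide) or scalar: spiked heavy
#'   amount per injection, in ng.
#' @param sample Sample id to quantify (default: the only one present).
#' @param external_curves Optional named list (by `form` string) of
#'   `calibration_curve` objects fitted on *light area* vs amount, used for
#'   missed-cleavage forms.
#' @param loq Optional named vector (by subtype) of quantification limits in
#'   ng; means below it set `below_loq`.
#' @return data.frame with one row per subtype: `subtype`, `amount` (ng),
#'   `cv` (percent, `NA` for a single replicate), `below_loq`,
#'   `n_replicates`.
#' @export
quantify_report <- function(report, assay, heavy_spike_ng, sample = NULL,
                            external_curves = NULL, loq = NULL) {
  stopifnot(is.data.frame(report), is.data.frame(assay))
  if (is.null(sample)) {
    sample <- unique(report$sample)
    if (length(sample) != 1L) {
      stop("report contains several samples; pick one with 'sample='",
           call. = FALSE)
    }
  }
  rep_s <- report[report$sample == sample, , drop = FALSE]
  if (nrow(rep_s) == 0L) stop("sample not found in report", call. = FALSE)
  rows <- lapply(seq_len(nrow(assay)), function(i) {
    pep <- assay$peptide[i]
    spike <- if (length(heavy_spike_ng) == 1L && is.null(names(heavy_spike_ng)))
      heavy_spike_ng else unname(heavy_spike_ng[[pep]])
    recs <- rep_s[rep_s$peptide == pep, , drop = FALSE]
    if (nrow(recs) == 0L) return(NULL)
    reps <- sort(unique(recs$replicate))
    amounts <- vapply(reps, function(r) {
      rr <- recs[recs$replicate == r, , drop = FALSE]
      main <- rr[rr$form %in% c("canonical", "oxidized"), , drop = FALSE]
      amt <- if (nrow(main) > 0L) {
        ratio <- if (any(main$form == "oxidized")) combine_oxidized(main)
                 else lh_ratio(main)
        single_point_quantify(ratio, reference = list(amount = spike, lh = 1))
      } else 0
      mc <- rr[startsWith(rr$form, "miscleaved"), , drop = FALSE]
      if (nrow(mc) > 0L) {
        if (is.null(external_curves)) {
          stop(sprintf("missed-cleavage form(s) of %s present but no external curves supplied", pep),
               call. = FALSE)
        }
        for (form in unique(mc$form)) {
          cv <- external_curves[[form]]
          if (is.null(cv)) {
            stop(sprintf("no external curve for form '%s'", form), call. = FALSE)
          }
          sig <- sum(mc$area[mc$form == form & mc$label == "light"])
          amt <- amt + external_curve_correct(
            list(list(form = form, signal = sig, curve = cv)))$total
        }
      }
      amt
    }, numeric(1))
    mean_amt <- mean(amounts)
    lim <- if (!is.null(loq)) unname(loq[[assay$subtype[i]]]) else NA_real_
    data.frame(subtype = assay$subtype[i],
               amount = mean_amt,
               cv = if (length(amounts) >= 2L && mean_amt > 0)
                 replicate_cv(amounts) else NA_real_,
               below_loq = !is.na(lim) && mean_amt < lim,
               n_replicates = length(amounts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("no assay peptide found in the report", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
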