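# Ground-truth-known simulators for calibration reports, sample peak-area
# reports and patient cohorts. Every generator is deterministic under a fixed
# seed and emits the same CSV dialects the readers consume.

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Mean-one multiplicative log-normal noise with coefficient of variation cv.
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Reference PRM assay definition for the H1 family
#'
#' The machine-readable assay developed for the seven somatic H1 subtypes:
#' one quantification peptide per subtype with its producing enzyme, position
#' in the subtype sequence, heavy-label site (Lys +8, Leu +7 or Ala +4),
#' precursor charge and the reported detection/quantification limits
#' (ng per ug of acid extract). The H1.1 peptide is a one-missed-cleavage
#' tryptic species; the H1.2/H1.4 pair is isobaric (identical composition)
#' and distinguished by sequence, never by mass.
#'
#' @return data.frame with one row per subtype.
#' @export
h1_assay <- function() {
  data.frame(
    subtype = c("H1.0", "H1.1", "H1.2", "H1.3", "H1.4", "H1.5", "H1X"),
    peptide = c("YSDMIVAAIQAEK", "KKPAGPSVSELIVQAASSSK", "TAPAAPAAAPPAE",
                "TAPLAPTIPAPAE", "TAPAAPAAPAPAE", "ATGPPVSELITK",
                "ALVQNDTLLQVK"),
    enzyme = c("trypsin", "trypsin", "glu_c", "glu_c", "glu_c", "trypsin",
               "trypsin"),
    start = c(28L, 37L, 4L, 4L, 4L, 38L, 95L),
    end = c(40L, 56L, 16L, 16L, 16L, 49L, 106L),
    missed_cleavages = c(0L, 1L, 0L, 0L, 0L, 0L, 0L),
    labeled_residue = c("K", "K", "A", "L", "A", "K", "K"),
    labeled_position = c(13L, 20L, 12L, 4L, 12L, 12L, 12L),
    precursor_charge = c(2L, 3L, 2L, 2L, 2L, 2L, 2L),
    met_containing = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    lod_ng = c(0.055, 0.037, 0.026, 0.02, 0.032, 0.046, 0.027),
    loq_ng = c(0.168, 0.111, 0.08, 0.06, 0.098, 0.14, 0.066),
    stringsAsFactors = FALSE)
}

#' Synthetic H1-like protein family
#'
#' A seven-member protein family for tests and examples: each subtype's real
#' quantification peptide (see [h1_assay()]) is embedded at its catalogued
#' position inside *synthetic* H1-like flanking sequence (lysine/alanine/
#' proline-rich, generated deterministically). The flanks are not the
#' canonical UniProt sequences; accessions are prefixed `SYN` to make this
#' unmistakable. Digestion context is valid: each tryptic peptide is preceded
#' by K/R and each Glu-C peptide by E.
#'
#' @return data.frame with columns `id`, `accession`, `sequence`.
#' @export
synthetic_h1_family <- function() {
  assay <- h1_assay()
  lens <- c(H1.0 = 194L, H1.1 = 215L, H1.2 = 213L, H1.3 = 221L,
            H1.4 = 219L, H1.5 = 226L, H1X = 213L)
  # H1-like residue usage for the synthetic flanks (no Met/Cys/Trp)
  res <- c("A", "K", "P", "S", "T", "G", "V", "E", "L", "I", "Q", "N", "D", "R")
  wts <- c(.24, .22, .13, .08, .07, .06, .06, .04, .03, .02, .02, .015, .015, .01)
  with_seed(20240927L, {
    seqs <- vapply(seq_len(nrow(assay)), function(i) {
      n <- lens[[assay$subtype[i]]]
      chars <- sample(res, n, replace = TRUE, prob = wts)
      pep <- strsplit(assay$peptide[i], "")[[1L]]
      st <- assay$start[i]; en <- assay$end[i]
      chars[st:en] <- pep
      if (assay$enzyme[i] == "trypsin") {
        chars[st - 1L] <- if (assay$peptide[i] == "KKPAGPSVSELIVQAASSSK") "R" else "K"
      } else {
        chars[seq_len(st - 1L)] <- strsplit("MSE", "")[[1L]][seq_len(st - 1L)]
      }
      if (en < n) chars[en + 1L] <- "A"
      paste(chars, collapse = "")
    }, character(1))
    data.frame(id = assay$subtype,
               accession = paste0("SYN", sub(".", "", assay$subtype, fixed = TRUE)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Simulation configuration
#'
#' Defines the generating conditions for the peak-area simulators: the assay,
#' ground-truth subtype amounts, the heavy spike, per-transition noise, and
#' the fractions of the light signal carried by missed-cleavage and (for
#' methionine peptides) oxidized forms.
#'
#' @param seed Integer RNG seed; identical seed + config gives identical
#'   output.
#' @param assay Assay data.frame (default [h1_assay()]).
#' @param true_amounts_ng Named vector of light amounts per subtype, in ng on
#'   column. The default is a cell-line-like complement with H1.4/H1.5
#'   dominant and one subtype (H1.3) near the detection floor.
#' @param heavy_spike_ng Heavy (SIS) amount spiked per peptide, ng.
#' @param noise_cv Per-transition multiplicative log-normal noise CV
#'   (fraction, e.g. 0.10).
#' @param miscleavage_fraction Fraction of each peptide's light signal carried
#'   by its missed-cleavage form, in \[0, 1); scalar or named by peptide.
#' @param oxidation_fraction Fraction of a methionine peptide's light signal
#'   carried by the oxidized form, in \[0, 1).
#' @param n_replicates Injection replicates per sample or level.
#' @param calibration_levels_ng Light amounts of the calibration series, ng.
#' @param response Base detector response (area units per ng per unit
#'   transition weight).
#' @param response_ratio Light/heavy response asymmetry rho; the generating
#'   calibration slope is rho / heavy_spike_ng. Scalar or named by peptide.
#' @param transitions Fragment labels monitored per peptide.
#' @param transition_weights Relative intensity of each transition (sums
#'   to 1).
#' @param sample_id Sample name used in sample reports.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              assay = h1_assay(),
                              true_amounts_ng = c(H1.0 = 0.45, H1.1 = 0.9,
                                                  H1.2 = 1.6, H1.3 = 0.04,
                                                  H1.4 = 2.8, H1.5 = 2.4,
                                                  H1X = 0.35),
                              heavy_spike_ng = 1,
                              noise_cv = 0.10,
                              miscleavage_fraction = 0,
                              oxidation_fraction = 0.2,
                              n_replicates = 3L,
                              calibration_levels_ng = c(0.05, 0.1, 0.25, 0.5,
                                                        1, 2, 5),
                              response = 1e5,
                              response_ratio = 1,
                              transitions = c("y4", "y5", "y6"),
                              transition_weights = c(0.5, 0.3, 0.2),
                              sample_id = "sample_1") {
  stopifnot(noise_cv >= 0,
            all(miscleavage_fraction >= 0), all(miscleavage_fraction < 1),
            all(oxidation_fraction >= 0), all(oxidation_fraction < 1),
            heavy_spike_ng > 0, n_replicates >= 1,
            length(transitions) == length(transition_weights),
            abs(sum(transition_weights) - 1) < 1e-9)
  if (!all(names(true_amounts_ng) %in% assay$subtype)) {
    stop("true_amounts_ng names must be assay subtypes", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), assay = assay,
                 true_amounts_ng = true_amounts_ng,
                 heavy_spike_ng = heavy_spike_ng, noise_cv = noise_cv,
                 miscleavage_fraction = miscleavage_fraction,
                 oxidation_fraction = oxidation_fraction,
                 n_replicates = as.integer(n_replicates),
                 calibration_levels_ng = calibration_levels_ng,
                 response = response, response_ratio = response_ratio,
                 transitions = transitions,
                 transition_weights = transition_weights,
                 sample_id = sample_id),
            class = "simulation_config")
}

.per_peptide <- function(x, peptide, default = NULL) {
  if (!is.null(names(x))) {
    if (peptide %in% names(x)) return(unname(x[[peptide]]))
    if (!is.null(default)) return(default)
    stop(sprintf("no value for peptide %s", peptide), call. = FALSE)
  }
  x
}

#' Simulate a calibration series
#'
#' Emits a transition-level peak-area report for a dilution series of light
#' peptide at a fixed heavy spike, with multiplicative log-normal noise per
#' transition. The truth record carries the generating line per peptide:
#' slope = response_ratio / heavy_spike_ng, intercept 0, so at zero noise a
#' fitted curve recovers it exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `report` (peak-area data.frame), `design` (peptide,
#'   level, amount, replicate) and `truth` (generating slope per peptide).
#' @export
simulate_calibration <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  a <- config$assay; tr <- config$transitions; w <- config$transition_weights
  with_seed(config$seed, {
    rows <- list(); des <- list()
    for (i in seq_len(nrow(a))) {
      pep <- a$peptide[i]
      rho <- .per_peptide(config$response_ratio, pep, 1)
      for (lv in seq_along(config$calibration_levels_ng)) {
        amt <- config$calibration_levels_ng[lv]
        for (r in seq_len(config$n_replicates)) {
          light <- config$response * w * rho * amt *
            .lognoise(length(w), config$noise_cv)
          heavy <- config$response * w * config$heavy_spike_ng *
            .lognoise(length(w), config$noise_cv)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sprintf("cal_L%02d", lv), replicate = r, peptide = pep,
            form = "canonical",
            label = rep(c("light", "heavy"), each = length(tr)),
            fragment = rep(tr, 2L), area = c(light, heavy),
            stringsAsFactors = FALSE)
          des[[length(des) + 1L]] <- data.frame(
            peptide = pep, level = lv, amount = amt, replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
    slopes <- vapply(a$peptide, function(p)
      .per_peptide(config$response_ratio, p, 1) / config$heavy_spike_ng,
      numeric(1))
    list(report = do.call(rbind, rows), design = do.call(rbind, des),
         truth = list(slope = slopes, intercept = 0,
                      heavy_spike_ng = config$heavy_spike_ng))
  })
}

#' Simulate a sample peak-area report
#'
#' Light areas are proportional to the true subtype amount, split between the
#' canonical form, a missed-cleavage form (light-only rows, matching an
#' external-curve workflow) and, for methionine peptides, an oxidized form;
#' heavy areas come from the spiked SIS peptide in the canonical form.
#'
#' @param config A [simulation_config()].
#' @return List with `report` and `truth` (per-subtype amounts, per-form
#'   amounts and the true complement percentages).
#' @export
simulate_sample_report <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  a <- config$assay; tr <- config$transitions; w <- config$transition_weights
  amounts <- config$true_amounts_ng
  a <- a[a$subtype %in% names(amounts), , drop = FALSE]
  with_seed(config$seed + 1L, {
    rows <- list(); forms <- list()
    for (i in seq_len(nrow(a))) {
      pep <- a$peptide[i]; sub <- a$subtype[i]
      amt <- unname(amounts[[sub]])
      rho <- .per_peptide(config$response_ratio, pep, 1)
      f_mc <- .per_peptide(config$miscleavage_fraction, pep, 0)
      f_ox <- if (isTRUE(a$met_containing[i])) config$oxidation_fraction else 0
      amt_main <- amt * (1 - f_mc)
      forms[[sub]] <- c(canonical = amt_main * (1 - f_ox),
                        oxidized = amt_main * f_ox,
                        miscleaved = amt * f_mc)
      for (r in seq_len(config$n_replicates)) {
        emit <- function(form, label, scale) {
          areas <- config$response * w * scale * .lognoise(length(w), config$noise_cv)
          data.frame(sample = config$sample_id, replicate = r, peptide = pep,
                     form = form, label = label, fragment = tr, area = areas,
                     stringsAsFactors = FALSE)
        }
        out <- list(emit("canonical", "light", rho * amt_main * (1 - f_ox)),
                    emit("canonical", "heavy", config$heavy_spike_ng))
        if (f_ox > 0) {
          out <- c(out, list(emit("oxidized", "light", rho * amt_main * f_ox)))
        }
        if (f_mc > 0) {
          out <- c(out, list(emit(paste0("miscleaved:", pep), "light",
                                  rho * amt * f_mc)))
        }
        rows[[length(rows) + 1L]] <- do.call(rbind, out)
      }
    }
    pos <- amounts[amounts > 0]
    list(report = do.call(rbind, rows),
         truth = list(amounts_ng = amounts,
                      per_form = forms,
                      percent = 100 * amounts / sum(amounts),
                      percent_detected = 100 * pos / sum(pos)))
  })
}

#' Simulate an external light-peptide calibration curve
#'
#' Builds the light-area-versus-amount series used to quantify forms that
#' have no heavy counterpart (missed-cleavage species): the signal is the
#' summed light area over the monitored transitions. Returns a fitted
#' `calibration_curve` per requested form plus the raw points.
#'
#' @param config A [simulation_config()].
#' @param forms Character vector of form labels, e.g.
#'   `"miscleaved:<peptide>"`; the corresponding peptide's response ratio is
#'   used.
#' @param levels_ng Amounts of the external series (default: the config's
#'   calibration levels).
#' @return Named list (by form) of `calibration_curve` objects with a
#'   `points` attribute.
#' @export
simulate_external_curves <- function(config, forms,
                                     levels_ng = config$calibration_levels_ng) {
  stopifnot(inherits(config, "simulation_config"))
  w <- config$transition_weights
  with_seed(config$seed + 2L, {
    out <- lapply(forms, function(form) {
      pep <- sub("^miscleaved:", "", form)
      rho <- .per_peptide(config$response_ratio, pep, 1)
      pts <- do.call(rbind, lapply(levels_ng, function(amt) {
        data.frame(amount = amt,
                   lh = vapply(seq_len(config$n_replicates), function(r) {
                     sum(config$response * w * rho * amt *
                           .lognoise(length(w), config$noise_cv))
                   }, numeric(1)))
      }))
      cv <- fit_calibration(pts, peptide = form)
      attr(cv, "points") <- pts
      cv
    })
    stats::setNames(out, forms)
  })
}

#' Simulate a responder / non-responder cohort
#'
#' Total H1 per mL of blood is drawn per group from a normal model
#' (non-responders shifted upward by `effect`), and subtype percentages from
#' group-specific Dirichlet distributions in which non-responders carry lower
#' H1.0, H1.1 and H1X proportions.
#'
#' @param n_responders,n_nonresponders Group sizes (>= 1).
#' @param effect Difference in mean total H1 (ng/mL) between non-responders
#'   and responders.
#' @param sd Within-group standard deviation of total H1.
#' @param mean_responder Mean total H1 of responders, ng/mL.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `group`, `total_h1_ng_ml` and
#'   `pct_<subtype>`; the generating parameters are attached as attribute
#'   `truth`.
#' @export
simulate_cohort <- function(n_responders = 6L, n_nonresponders = 2L,
                            effect = 60, sd = 20, mean_responder = 60,
                            seed = 1L) {
  if (n_responders < 1L || n_nonresponders < 1L) {
    stop("both group sizes must be >= 1", call. = FALSE)
  }
  subtypes <- c("H1.0", "H1.1", "H1.2", "H1.3", "H1.4", "H1.5", "H1X")
  alpha_r <- c(H1.0 = 8, H1.1 = 3, H1.2 = 1, H1.3 = 6, H1.4 = 12, H1.5 = 12,
               H1X = 3)
  alpha_n <- c(H1.0 = 1, H1.1 = 0.5, H1.2 = 1, H1.3 = 8, H1.4 = 14,
               H1.5 = 16, H1X = 0.5)
  rdirichlet <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
                byrow = TRUE)
    g / rowSums(g)
  }
  with_seed(seed, {
    tot_r <- pmax(stats::rnorm(n_responders, mean_responder, sd), 1)
    tot_n <- pmax(stats::rnorm(n_nonresponders, mean_responder + effect, sd), 1)
    pct <- rbind(100 * rdirichlet(n_responders, alpha_r),
                 100 * rdirichlet(n_nonresponders, alpha_n))
    colnames(pct) <- paste0("pct_", subtypes)
    out <- data.frame(
      subject = c(sprintf("R%d", seq_len(n_responders)),
                  sprintf("NR%d", seq_len(n_nonresponders))),
      group = c(rep("responder", n_responders),
                rep("non_responder", n_nonresponders)),
      total_h1_ng_ml = c(tot_r, tot_n), stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(pct))
    attr(out, "truth") <- list(effect = effect, sd = sd,
                               mean_responder = mean_responder,
                               alpha_responder = alpha_r,
                               alpha_nonresponder = alpha_n)
    out
  })
}
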