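# Mass arithmetic for peptides, stable-isotope labels and b/y fragment ions.

# Monoisotopic residue (not free amino acid) masses in Da, standard 20 residues.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da), used for protein molar masses (g/mol).
.AA_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.WATER_MONO <- 18.010565
.WATER_AVG <- 18.01528
.PROTON <- 1.007276

# Single-substitution isotope mass shifts.
.C13_SHIFT <- 1.003355
.N15_SHIFT <- 0.997035

#' Residue mass table
#'
#' The monoisotopic (default) or average masses of the 20 standard amino acid
#' residues, plus the water and proton masses used throughout the package.
#'
#' @param type `"monoisotopic"` or `"average"`.
#' @return Named list with elements `residues` (named numeric vector),
#'   `water` and `proton` (Da).
#' @export
residue_masses <- function(type = c("monoisotopic", "average")) {
  type <- match.arg(type)
  if (type == "monoisotopic") {
    list(residues = .AA_MONO, water = .WATER_MONO, proton = .PROTON)
  } else {
    list(residues = .AA_AVG, water = .WATER_AVG, proton = .PROTON)
  }
}

#' Validate a peptide or protein sequence
#'
#' Checks that the sequence is a non-empty uppercase string over the 20
#' standard residues. The error names the offending character and its
#' position so malformed FASTA records are easy to locate.
#'
#' @param sequence Amino-acid string.
#' @param what Label used in error messages (e.g. a record id).
#' @return The sequence, invisibly, if valid.
#' @export
validate_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(.AA_MONO))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], what), call. = FALSE)
  }
  invisible(sequence)
}

#' Heavy-label scheme
#'
#' Mass shifts of fully substituted stable-isotope-labelled residues used in
#' SIS (stable-isotope standard) peptides: Lys +8 (6x13C, 2x15N), Leu/Ile +7
#' (6x13C, 1x15N) and Ala +4 (3x13C, 1x15N). The nominal +8/+7/+4 names map
#' to exact shifts of 8.0142, 7.017165 and 4.0071 Da.
#'
#' @return Named numeric vector of residue mass deltas (Da).
#' @export
label_scheme <- function() {
  c(K = 6 * .C13_SHIFT + 2 * .N15_SHIFT,
    L = 6 * .C13_SHIFT + 1 * .N15_SHIFT,
    I = 6 * .C13_SHIFT + 1 * .N15_SHIFT,
    A = 3 * .C13_SHIFT + 1 * .N15_SHIFT)
}

#' Define a (positional) modification
#'
#' @param name Modification name, e.g. `"oxidation"`.
#' @param delta Mass delta in Da (finite).
#' @param position 1-based residue position the modification sits on, or `NA`
#'   for a composition-only modification (mass arithmetic only, no fragment
#'   localisation).
#' @param target Optional residue letter the modification is restricted to;
#'   checked against the sequence when a position is given.
#' @return A `prm_mod` list.
#' @export
modification <- function(name, delta, position = NA_integer_, target = NULL) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  structure(list(name = name, delta = delta,
                 position = as.integer(position), target = target),
            class = "prm_mod")
}

#' @rdname modification
#' @export
mod_oxidation <- function(position = NA_integer_) {
  modification("oxidation", 15.994915, position, target = "M")
}

#' @rdname modification
#' @export
mod_carbamidomethyl <- function(position = NA_integer_) {
  modification("carbamidomethyl", 57.021464, position, target = "C")
}

.check_mods <- function(peptide, mods) {
  if (is.null(mods)) return(list())
  if (inherits(mods, "prm_mod")) mods <- list(mods)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  pos_seen <- integer(0)
  for (m in mods) {
    if (!inherits(m, "prm_mod")) stop("mods must be created with modification()", call. = FALSE)
    if (!is.na(m$position)) {
      if (m$position < 1L || m$position > length(chars)) {
        stop(sprintf("modification '%s' position %d outside peptide", m$name, m$position),
             call. = FALSE)
      }
      if (m$position %in% pos_seen) {
        stop(sprintf("more than one modification at position %d", m$position), call. = FALSE)
      }
      pos_seen <- c(pos_seen, m$position)
      if (!is.null(m$target) && chars[m$position] != m$target) {
        stop(sprintf("modification '%s' targets %s but position %d holds %s",
                     m$name, m$target, m$position, chars[m$position]), call. = FALSE)
      }
    }
  }
  mods
}

#' Monoisotopic mass of a peptide
#'
#' Neutral monoisotopic mass: sum of residue masses plus one water, plus any
#' modification deltas. Order-independent in the residues, so peptides with
#' identical composition (such as the H1.2 and H1.4 proteotypic peptides) are
#' exactly isobaric.
#'
#' @param peptide Peptide string (uppercase, standard residues).
#' @param mods Optional list of [modification()] objects.
#' @return Neutral mass in Da.
#' @export
monoisotopic_mass <- function(peptide, mods = NULL) {
  validate_sequence(peptide, "peptide")
  mods <- .check_mods(peptide, mods)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  sum(.AA_MONO[chars]) + .WATER_MONO + sum(vapply(mods, `[[`, numeric(1), "delta"))
}

#' Average (chemical) mass of a protein or peptide
#'
#' Used to convert molar amounts (fmol) of a subtype into mass amounts (ng)
#' via the molar mass of the full-length protein computed from its sequence.
#'
#' @inheritParams monoisotopic_mass
#' @return Average mass in Da (numerically equal to g/mol).
#' @export
average_mass <- function(peptide) {
  validate_sequence(peptide, "peptide")
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  sum(.AA_AVG[chars]) + .WATER_AVG
}

#' Heavy (labelled) peptide mass
#'
#' Mass of the SIS form: light mass plus the label-scheme delta at each
#' labelled position.
#'
#' @inheritParams monoisotopic_mass
#' @param scheme Named vector of residue deltas, default [label_scheme()].
#' @param labeled_positions Integer vector of 1-based positions carrying a
#'   label; each position's residue must be present in `scheme`.
#' @return Neutral heavy mass in Da.
#' @export
heavy_mass <- function(peptide, labeled_positions, scheme = label_scheme(),
                       mods = NULL) {
  light <- monoisotopic_mass(peptide, mods)
  if (length(labeled_positions) == 0L) {
    stop("at least one labeled position is required", call. = FALSE)
  }
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  labeled_positions <- as.integer(labeled_positions)
  for (p in labeled_positions) {
    if (p < 1L || p > length(chars)) {
      stop(sprintf("labeled position %d outside peptide", p), call. = FALSE)
    }
    if (!chars[p] %in% names(scheme)) {
      stop(sprintf("residue %s at position %d has no heavy label in the scheme",
                   chars[p], p), call. = FALSE)
    }
  }
  light + sum(scheme[chars[labeled_positions]])
}

#' Precursor m/z
#'
#' @param mass Neutral mass in Da.
#' @param charge Positive integer charge.
#' @return m/z = (mass + charge * proton) / charge.
#' @export
precursor_mz <- function(mass, charge) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge)) {
    stop("charge must be an integer >= 1", call. = FALSE)
  }
  (mass + charge * .PROTON) / charge
}

#' Fragment ion m/z (b and y series)
#'
#' b_i covers the first i residues (no water); y_i covers the last i residues
#' plus water. Positional modifications are applied when their residue falls
#' inside the fragment. For any split point,
#' b_i(1+) + y_(n-i)(1+) equals the precursor mass plus two protons.
#'
#' @inheritParams monoisotopic_mass
#' @param series `"b"` or `"y"`.
#' @param index Fragment length, 1..(n-1) for informative ions (`index = n`
#'   is allowed for the y-series, where it equals the singly protonated
#'   precursor).
#' @param charge Positive integer fragment charge.
#' @return m/z value.
#' @export
fragment_mz <- function(peptide, series = c("b", "y"), index, charge = 1L,
                        mods = NULL) {
  series <- match.arg(series)
  validate_sequence(peptide, "peptide")
  mods <- .check_mods(peptide, mods)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  max_ok <- if (series == "y") n else n - 1L
  if (!is.numeric(index) || length(index) != 1L || index < 1L || index > max_ok) {
    stop(sprintf("%s-ion index must be in 1..%d for a %d-residue peptide",
                 series, max_ok, n), call. = FALSE)
  }
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1) {
    stop("charge must be an integer >= 1", call. = FALSE)
  }
  covered <- if (series == "b") seq_len(index) else seq.int(n - index + 1L, n)
  neutral <- sum(.AA_MONO[chars[covered]]) + if (series == "y") .WATER_MONO else 0
  for (m in mods) {
    if (!is.na(m$position) && m$position %in% covered) neutral <- neutral + m$delta
  }
  (neutral + charge * .PROTON) / charge
}
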