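# In-silico digestion and proteotypic candidate selection for a protein family.

#' Digestion parameters
#'
#' Cleavage and filter settings for in-silico digestion. Trypsin cleaves
#' C-terminal to K or R; Glu-C cleaves C-terminal to E (`E_only`, the
#' ammonium-bicarbonate specificity) or to E and D (`E_and_D`, the phosphate
#' buffer specificity). The proline rule suppresses cleavage when the next
#' residue is proline and defaults to on for trypsin only.
#'
#' @param enzyme `"trypsin"` or `"glu_c"`.
#' @param glu_c_mode `"E_only"` or `"E_and_D"` (ignored for trypsin).
#' @param max_missed_cleavages Non-negative integer.
#' @param min_mass_da Minimum neutral monoisotopic mass retained by
#'   [enumerate_candidates()] (default 600 Da).
#' @param max_length Maximum peptide length retained (default 24, i.e.
#'   "shorter than 25 residues").
#' @param proline_rule Logical; default `TRUE` for trypsin, `FALSE` for Glu-C.
#' @return A `digestion_params` list.
#' @export
digestion_params <- function(enzyme = c("trypsin", "glu_c"),
                             glu_c_mode = c("E_only", "E_and_D"),
                             max_missed_cleavages = 0L,
                             min_mass_da = 600,
                             max_length = 24L,
                             proline_rule = NULL) {
  enzyme <- match.arg(enzyme)
  glu_c_mode <- match.arg(glu_c_mode)
  if (is.null(proline_rule)) proline_rule <- enzyme == "trypsin"
  stopifnot(max_missed_cleavages >= 0, max_length >= 1, min_mass_da >= 0)
  structure(list(enzyme = enzyme, glu_c_mode = glu_c_mode,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_mass_da = min_mass_da, max_length = as.integer(max_length),
                 proline_rule = isTRUE(proline_rule)),
            class = "digestion_params")
}

.cleavage_residues <- function(params) {
  switch(params$enzyme,
         trypsin = c("K", "R"),
         glu_c = if (params$glu_c_mode == "E_and_D") c("E", "D") else "E")
}

#' In-silico digestion of one sequence
#'
#' Enumerates all peptides with up to `max_missed_cleavages` retained internal
#' sites. Every peptide with k missed cleavages is the concatenation of k + 1
#' adjacent fully cleaved fragments; positions are 1-based inclusive. No mass
#' or length filtering is applied here.
#'
#' @param sequence Protein sequence (uppercase, standard residues).
#' @param params A [digestion_params()] object.
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, `enzyme`.
#' @export
digest <- function(sequence, params = digestion_params()) {
  validate_sequence(sequence, "sequence")
  stopifnot(inherits(params, "digestion_params"))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  targets <- .cleavage_residues(params)
  sites <- which(chars[-n] %in% targets)          # cleave after these positions
  if (params$proline_rule && length(sites) > 0L) {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  starts0 <- c(1L, sites + 1L)
  ends0 <- c(sites, n)
  nfrag <- length(starts0)
  out <- vector("list", params$max_missed_cleavages + 1L)
  for (k in 0:params$max_missed_cleavages) {
    if (nfrag - k < 1L) break
    i <- seq_len(nfrag - k)
    st <- starts0[i]
    en <- ends0[i + k]
    out[[k + 1L]] <- data.frame(
      sequence = substring(sequence, st, en),
      start = st, end = en, missed_cleavages = k,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res$enzyme <- params$enzyme
  rownames(res) <- NULL
  res
}

#' Enumerate unique (proteotypic) peptide candidates for a protein family
#'
#' Digests every family member with both a trypsin and a Glu-C parameter set,
#' keeps peptides passing the length and monoisotopic-mass filters, and flags
#' uniqueness: a peptide is proteotypic when its sequence occurs (as an exact
#' substring, I/L distinct) in exactly one family member's full sequence.
#' By default only unique peptides are returned.
#'
#' @param family data.frame with columns `id`, `accession`, `sequence` (one
#'   row per subtype), e.g. from [read_fasta()].
#' @param params_trypsin,params_gluc [digestion_params()] for the two enzymes.
#' @param keep_shared If `TRUE`, non-unique peptides are retained (flagged
#'   `unique = FALSE`) instead of dropped.
#' @return data.frame of candidates sorted by (subtype, start) with columns
#'   `subtype`, `accession`, `enzyme`, `sequence`, `start`, `end`,
#'   `missed_cleavages`, `mono_mass`, `unique`, `ess`, `n_observations`.
#' @export
enumerate_candidates <- function(family,
                                 params_trypsin = digestion_params("trypsin"),
                                 params_gluc = digestion_params("glu_c"),
                                 keep_shared = FALSE) {
  stopifnot(is.data.frame(family),
            all(c("id", "sequence") %in% names(family)),
            nrow(family) >= 1L)
  if (anyDuplicated(family$id)) {
    stop("duplicate subtype ids in family: ",
         paste(unique(family$id[duplicated(family$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(family$accession)) family$accession <- family$id
  for (i in seq_len(nrow(family))) {
    validate_sequence(family$sequence[i], paste0("sequence of ", family$id[i]))
  }
  pieces <- lapply(seq_len(nrow(family)), function(i) {
    per_enzyme <- lapply(list(params_trypsin, params_gluc), function(p) {
      d <- digest(family$sequence[i], p)
      d$max_length <- p$max_length
      d$min_mass <- p$min_mass_da
      d
    })
    d <- do.call(rbind, per_enzyme)
    d$subtype <- family$id[i]
    d$accession <- family$accession[i]
    d
  })
  cand <- do.call(rbind, pieces)
  cand <- cand[nchar(cand$sequence) <= cand$max_length, , drop = FALSE]
  cand$mono_mass <- vapply(cand$sequence, monoisotopic_mass, numeric(1),
                           USE.NAMES = FALSE)
  cand <- cand[cand$mono_mass >= cand$min_mass, , drop = FALSE]
  # uniqueness within the supplied family: substring of exactly one member
  n_members <- vapply(cand$sequence, function(p) {
    sum(vapply(family$sequence, function(s) grepl(p, s, fixed = TRUE),
               logical(1)))
  }, numeric(1), USE.NAMES = FALSE)
  cand$unique <- n_members == 1L
  if (!keep_shared) cand <- cand[cand$unique, , drop = FALSE]
  cand$ess <- rep(NA_real_, nrow(cand))
  cand$n_observations <- rep(NA_integer_, nrow(cand))
  cand <- cand[order(cand$subtype, cand$start, cand$end, cand$enzyme), ,
               drop = FALSE]
  rownames(cand) <- NULL
  cand[, c("subtype", "accession", "enzyme", "sequence", "start", "end",
           "missed_cleavages", "mono_mass", "unique", "ess", "n_observations")]
}

#' Candidate counts per subtype
#'
#' Number of distinct unique peptide sequences per subtype plus the family
#' total, the summary used to benchmark an assay design.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @return Named list with `per_subtype` (named integer vector) and `total`.
#' @export
candidate_counts <- function(candidates) {
  u <- candidates[candidates$unique, , drop = FALSE]
  key <- !duplicated(paste(u$subtype, u$sequence, sep = "\r"))
  u <- u[key, , drop = FALSE]
  per <- table(u$subtype)
  list(per_subtype = stats::setNames(as.integer(per), names(per)),
       total = nrow(u))
}

#' Annotate candidates with empirical suitability scores
#'
#' Attaches an ESS (empirical suitability score, in \[0,1\]) and observation
#' count to each candidate found in the annotation table; candidates absent
#' from the table are left unset.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param ess_table data.frame with columns `peptide`, `ess`, and optionally
#'   `n_observations`.
#' @return `candidates` with `ess` and `n_observations` filled in.
#' @export
annotate_ess <- function(candidates, ess_table) {
  stopifnot(is.data.frame(ess_table),
            all(c("peptide", "ess") %in% names(ess_table)))
  if (any(!is.na(ess_table$ess) & (ess_table$ess < 0 | ess_table$ess > 1))) {
    stop("ess values must lie in [0, 1]", call. = FALSE)
  }
  idx <- match(candidates$sequence, ess_table$peptide)
  hit <- !is.na(idx)
  candidates$ess[hit] <- ess_table$ess[idx[hit]]
  if (!is.null(ess_table$n_observations)) {
    candidates$n_observations[hit] <-
      as.integer(ess_table$n_observations[idx[hit]])
  }
  candidates
}

#' Rank candidates by ESS within each subtype
#'
#' Orders candidates by decreasing ESS inside each subtype (unscored
#' candidates last), the order used to pick the quantification peptide.
#'
#' @param candidates Annotated candidates from [annotate_ess()].
#' @return The same data.frame, reordered.
#' @export
rank_by_ess <- function(candidates) {
  ess <- candidates$ess
  ess[is.na(ess)] <- -Inf
  candidates[order(candidates$subtype, -ess, candidates$start), , drop = FALSE]
}
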