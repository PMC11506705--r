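# Readers and writers for the toolkit's file formats: FASTA protein families,
# transition-level peak-area reports (CSV), candidate tables (TSV), assay and
# configuration files (YAML) and result bundles (JSON).

#' Read a protein family from FASTA
#'
#' Headers are parsed for an accession: UniProt-style `db|ACC|NAME` headers
#' yield the middle token, otherwise the first whitespace-delimited word is
#' used. Sequences are uppercased, whitespace/gap characters stripped, and
#' validated against the 20 standard residues (the error names the record and
#' offending position).
#'
#' @param path FASTA file.
#' @param subtype_map Optional named character vector mapping accession to a
#'   subtype label used as `id`; unmapped records keep their accession.
#' @return data.frame with columns `id`, `accession`, `sequence`, in file
#'   order.
#' @export
read_fasta <- function(path, subtype_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  accession <- vapply(headers, function(h) {
    first <- strsplit(h, "\\s+")[[1L]][1L]
    parts <- strsplit(first, "|", fixed = TRUE)[[1L]]
    if (length(parts) >= 2L) parts[2L] else parts[1L]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(gsub("[-. *\t]", "", as.character(set)))
  for (i in seq_along(seqs)) {
    validate_sequence(seqs[i], paste0("record ", accession[i]))
  }
  id <- accession
  if (!is.null(subtype_map)) {
    hit <- accession %in% names(subtype_map)
    id[hit] <- unname(subtype_map[accession[hit]])
  }
  data.frame(id = id, accession = accession, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein family as FASTA
#'
#' @param family data.frame with `id`, `accession`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(family, path) {
  lines <- unlist(lapply(seq_len(nrow(family)), function(i) {
    c(sprintf(">syn|%s|%s", family$accession[i], family$id[i]),
      family$sequence[i])
  }))
  writeLines(lines, path)
  invisible(path)
}

.PEAK_COLS <- c("sample", "replicate", "peptide", "form", "label", "fragment",
                "area")

#' Read a transition-level peak-area report
#'
#' Comma-separated with a header containing at least the columns `sample`,
#' `replicate`, `peptide`, `form`, `label`, `fragment`, `area` (optionally
#' `retention_time`); unknown columns are preserved. Validation is strict:
#' missing columns, labels other than light/heavy, negative areas and
#' duplicate (sample, replicate, peptide, form, label, fragment) keys are all
#' rejected with named errors.
#'
#' @param path CSV file.
#' @return data.frame of typed records.
#' @export
read_peak_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.PEAK_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("peak report lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$area)) stop("'area' must be numeric", call. = FALSE)
  if (any(is.na(df$area)) || any(df$area < 0)) {
    stop("negative or missing area(s) in peak report", call. = FALSE)
  }
  bad_label <- setdiff(unique(df$label), c("light", "heavy"))
  if (length(bad_label) > 0L) {
    stop("label must be light or heavy; found: ",
         paste(bad_label, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(df[, c("sample", "replicate", "peptide", "form",
                                 "label", "fragment")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (sample, replicate, peptide, form, label, fragment) row(s)",
         call. = FALSE)
  }
  df
}

#' Write a peak-area report
#'
#' @param report Peak-area data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESS annotation table
#'
#' Tab-separated with columns `peptide`, `ess` and optionally
#' `n_observations`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ess_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "ess") %in% names(df))) {
    stop("ESS table needs columns peptide, ess", call. = FALSE)
  }
  df
}

#' Read a calibration design table
#'
#' Comma-separated with columns `peptide`, `level`, `amount`, `replicate`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_calibration_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide", "level", "amount", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("design lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(df$amount < 0)) stop("amounts must be non-negative", call. = FALSE)
  df
}

#' Write a candidate table as TSV
#'
#' @param candidates Output of [enumerate_candidates()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write an assay definition (YAML)
#'
#' The assay file is the machine-readable form of the PRM method: one entry
#' per subtype with peptide, enzyme, positions, label site, precursor charge
#' and reference limits.
#'
#' @param path YAML file.
#' @return data.frame (one row per subtype).
#' @export
read_assay <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  entries <- yaml::read_yaml(path)
  do.call(rbind, lapply(entries, function(e) {
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
}

#' @rdname read_assay
#' @param assay Assay data.frame, e.g. [h1_assay()].
#' @export
write_assay <- function(assay, path) {
  entries <- lapply(seq_len(nrow(assay)), function(i) as.list(assay[i, ]))
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; identical configurations hash
#' identically across sessions.
#'
#' @param config Any JSON-serializable object.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble a result bundle
#'
#' Collects run metadata and the per-stage outputs into a single serializable
#' object. Absent stages are stored as explicit nulls so the JSON schema is
#' stable.
#'
#' @param config Configuration list used for the run (hashed into metadata).
#' @param seed Seed used for any randomness.
#' @param candidates,curves,quants,profiles,stats Stage outputs or `NULL`.
#' @return A `result_bundle` list.
#' @export
result_bundle <- function(config = list(), seed = NA_integer_,
                          candidates = NULL, curves = NULL, quants = NULL,
                          profiles = NULL, stats = NULL) {
  bundle <- list(
    meta = list(toolkit = "h1prm",
                version = as.character(utils::packageVersion("h1prm")),
                seed = seed,
                config_hash = config_hash(config)),
    config = config)
  # assign via [ so NULL stages stay present as explicit entries
  for (nm in c("candidates", "curves", "quants", "profiles", "stats")) {
    bundle[nm] <- list(get(nm))
  }
  structure(bundle, class = "result_bundle")
}

#' Write / read a result bundle (JSON)
#'
#' `write_results()` serializes the bundle (explicit nulls retained) and
#' `read_results()` restores it; a write/read round trip reproduces the
#' bundle's content.
#'
#' @param bundle A [result_bundle()].
#' @param path Output JSON path.
#' @return `path` invisibly; `read_results()` returns the bundle list.
#' @export
write_results <- function(bundle, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE,
                       always_decimal = FALSE, force = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "result_bundle")
}
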