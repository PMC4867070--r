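# Peptide handling: FASTA IO, hydrophobic percentage, reference subpeptide
# anchoring, and the HPP window filter.

#' Read peptide records from a FASTA file
#'
#' Headers follow a pipe-delimited dialect `seq_id|bagel_id|species`; only
#' `seq_id` is mandatory and missing trailing fields are tolerated. Sequences
#' are uppercased and whitespace-stripped, then validated against the
#' 20-letter standard alphabet ([AMINO_ACIDS]). Records are returned in file
#' order.
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `seq_id`, `bagel_id`, `species`,
#'   `sequence`, one row per FASTA entry.
#' @seealso [write_peptide_fasta()], [validate_peptides()]
#' @export
read_peptide_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  if (is.null(headers)) headers <- rep("", length(aa))
  fields <- strsplit(headers, "|", fixed = TRUE)
  take <- function(i) {
    vapply(fields, function(f) {
      if (length(f) >= i && nzchar(trimws(f[[i]]))) trimws(f[[i]])
      else NA_character_
    }, character(1))
  }
  records <- data.frame(
    seq_id = take(1),
    bagel_id = take(2),
    species = take(3),
    sequence = toupper(gsub("[[:space:]]", "", as.character(aa))),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  validate_peptides(records)
  records
}

#' Write peptide records to a FASTA file
#'
#' Inverse of [read_peptide_fasta()]: headers are rebuilt as
#' `seq_id|bagel_id|species`, dropping trailing missing fields.
#'
#' @param records peptide record data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(records, path) {
  validate_peptides(records)
  hdr <- vapply(seq_len(nrow(records)), function(i) {
    f <- c(records$seq_id[i],
           if ("bagel_id" %in% names(records)) records$bagel_id[i] else NA,
           if ("species" %in% names(records)) records$species[i] else NA)
    while (length(f) > 1 && is.na(f[length(f)])) f <- f[-length(f)]
    f[is.na(f)] <- ""
    paste(f, collapse = "|")
  }, character(1))
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Validate a peptide record collection
#'
#' Checks the record invariants: non-empty unique `seq_id`, non-empty
#' sequences, and sequences drawn only from the 20 standard residues. Errors
#' name the offending record and character.
#'
#' @param records data frame with at least `seq_id` and `sequence` columns.
#' @return the records, invisibly, if valid.
#' @export
validate_peptides <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("seq_id", "sequence") %in% names(records))) {
    stop("peptide records must be a data frame with 'seq_id' and 'sequence'")
  }
  if (nrow(records) == 0) {
    return(invisible(records))
  }
  if (anyNA(records$seq_id) || any(!nzchar(records$seq_id))) {
    stop("every peptide record needs a non-empty seq_id")
  }
  dup <- unique(records$seq_id[duplicated(records$seq_id)])
  if (length(dup) > 0) {
    stop("duplicate seq_id: ", paste(dup, collapse = ", "))
  }
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    if (is.na(s) || !nzchar(s)) {
      stop("record '", records$seq_id[i], "' has an empty sequence")
    }
    bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), AMINO_ACIDS)
    if (length(bad) > 0) {
      stop("record '", records$seq_id[i],
           "' contains non-standard residue(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(records)
}

#' Hydrophobic percentage of peptide sequences
#'
#' Counts residues belonging to [HYDROPHOBIC_RESIDUES] and expresses the
#' count as a percentage of sequence length. The raw percentage is also
#' rounded half-up to the nearest integer (`hpp`), which is the value used
#' for window filtering and table reporting.
#'
#' @param sequence character vector of sequences (optionally named by id), or
#'   a peptide record data frame as returned by [read_peptide_fasta()].
#' @param seq_id optional character vector of ids overriding names.
#' @return data frame with columns `seq_id`, `length`, `hydrophobic_count`,
#'   `hpp_raw` (percent, exact) and `hpp` (percent, integer).
#' @examples
#' hydrophobic_percentage(c(p18 = "LSTAADMQGVVTDGMASG"))
#' @export
hydrophobic_percentage <- function(sequence, seq_id = NULL) {
  if (is.data.frame(sequence)) {
    if (is.null(seq_id)) seq_id <- sequence$seq_id
    sequence <- sequence$sequence
  }
  if (length(sequence) == 0) {
    return(data.frame(seq_id = character(), length = integer(),
                      hydrophobic_count = integer(), hpp_raw = numeric(),
                      hpp = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(seq_id)) {
    seq_id <- if (!is.null(names(sequence))) names(sequence)
              else paste0("seq", seq_along(sequence))
  }
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  validate_peptides(data.frame(seq_id = seq_id, sequence = sequence,
                               stringsAsFactors = FALSE))
  len <- nchar(sequence)
  count <- vapply(strsplit(sequence, "", fixed = TRUE),
                  function(ch) sum(ch %in% HYDROPHOBIC_RESIDUES), integer(1))
  hpp_raw <- 100 * count / len
  data.frame(seq_id = as.character(seq_id), length = len,
             hydrophobic_count = count, hpp_raw = hpp_raw,
             hpp = as.integer(round_half_up(hpp_raw)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Locate a documented subpeptide within a parent sequence
#'
#' Anchors a fragment such as p28 inside its parent (azurin) by exact
#' substring search rather than by hard-coded offsets, so precursor versus
#' mature numbering conventions (which differ by the signal peptide length)
#' cannot cause off-by-N errors. The match must be unique.
#'
#' @param parent parent amino-acid sequence.
#' @param documented_sub the documented fragment sequence.
#' @return list with `sequence` (the matched substring) and `start` (1-based
#'   position of the match in `parent`).
#' @examples
#' extract_reference_subpeptide("GAVLIM", "VLI")$start  # 3
#' @export
extract_reference_subpeptide <- function(parent, documented_sub) {
  stopifnot(is.character(parent), length(parent) == 1L,
            is.character(documented_sub), length(documented_sub) == 1L,
            nzchar(parent), nzchar(documented_sub))
  m <- gregexpr(documented_sub, parent, fixed = TRUE)[[1]]
  if (m[1] == -1L) {
    stop("subpeptide not found in parent sequence")
  }
  if (length(m) > 1L) {
    stop("subpeptide occurs ", length(m), " times in parent; ambiguous anchor")
  }
  list(sequence = documented_sub, start = as.integer(m[1]))
}

#' Derive a hydrophobic-percentage selection window
#'
#' The window spans from the smallest reference percentage minus the
#' tolerance to the largest plus the tolerance. With the azurin (49) and
#' p28-azurin (46) references and the default tolerance of 2 percentage
#' points this gives the 44-51 window.
#'
#' @param reference_hpps integer percentages of the reference peptides.
#' @param tolerance allowed deviation in percentage points (>= 0).
#' @return an object of class `hpp_window` with fields `low`, `high`,
#'   `tolerance` and `reference_hpps`.
#' @examples
#' derive_window(c(49, 46), 2)
#' @export
derive_window <- function(reference_hpps, tolerance = 2) {
  stopifnot(is.numeric(reference_hpps), length(reference_hpps) >= 1,
            !anyNA(reference_hpps), is.numeric(tolerance),
            length(tolerance) == 1, tolerance >= 0)
  structure(list(low = min(reference_hpps) - tolerance,
                 high = max(reference_hpps) + tolerance,
                 tolerance = tolerance,
                 reference_hpps = reference_hpps),
            class = "hpp_window")
}

#' @export
print.hpp_window <- function(x, ...) {
  cat(sprintf("HPP window [%g, %g] (references %s, tolerance %g)\n",
              x$low, x$high, paste(x$reference_hpps, collapse = "/"),
              x$tolerance))
  invisible(x)
}

#' Filter peptides by hydrophobic-percentage window
#'
#' A record is retained iff its integer-rounded hydrophobic percentage lies
#' inside the closed window. Filtering operates on the rounded value, not the
#' raw one: a raw value of 51.22 rounds to 51 and is retained by the 44-51
#' window. Input order is preserved and rejected records stay in the report.
#'
#' @param records peptide record data frame.
#' @param window an `hpp_window` from [derive_window()].
#' @return list with `report` (per-record HPP table plus `retained`,
#'   `window_low`, `window_high` columns) and `retained` (the retained subset
#'   of `records`).
#' @export
hpp_window_filter <- function(records, window) {
  stopifnot(inherits(window, "hpp_window"))
  validate_peptides(records)
  report <- hydrophobic_percentage(records)
  report$retained <- if (nrow(report)) {
    report$hpp >= window$low & report$hpp <= window$high
  } else logical(0)
  report$window_low <- rep(window$low, nrow(report))
  report$window_high <- rep(window$high, nrow(report))
  list(report = report,
       retained = records[report$retained, , drop = FALSE])
}

#' Write an HPP filter report as TSV
#'
#' @param report the `report` element of [hpp_window_filter()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hpp_report <- function(report, path) {
  cols <- c("seq_id", "length", "hydrophobic_count", "hpp_raw", "hpp",
            "retained", "window_low", "window_high")
  stopifnot(all(cols %in% names(report)))
  write_tsv(report[cols], path)
}
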