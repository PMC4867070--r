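# Functional-annotation odds tables and the azurin-similarity score.
#
# Annotation tables emulate ab initio function predictor output: for each
# sequence and each of three category groups -- cellular function (F),
# enzyme class (EZ) and gene-ontology category (GO) -- a probability and an
# odds number. The odds number is the predictor's confidence that the
# sequence belongs to the category, independent of the category's prior.

.ANNOTATION_GROUPS <- c("F", "EZ", "GO")
.ANNOTATION_COLUMNS <- c("seq_id", "group", "category", "probability", "odds")

#' Read a functional-annotation odds table
#'
#' Expects a TSV with header `seq_id`, `group`, `category`, `probability`,
#' `odds`. `group` must be one of `F` (cellular function), `EZ` (enzyme
#' class) or `GO` (gene ontology); probabilities must lie in `[0, 1]`, odds
#' must be non-negative, and `(seq_id, group, category)` must be unique.
#' Validation errors name the offending file line.
#'
#' @param path path to the TSV file.
#' @return data frame of class `annotation_set` with the five columns above.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) {
    stop("annotation table not found: ", path)
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(!is.na(nf) & nf != length(.ANNOTATION_COLUMNS))
  if (length(bad) > 0) {
    stop("line ", bad[1], ": expected ", length(.ANNOTATION_COLUMNS),
         " tab-separated fields, found ", nf[bad[1]])
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!identical(sort(names(df)), sort(.ANNOTATION_COLUMNS))) {
    stop("annotation table header must be: ",
         paste(.ANNOTATION_COLUMNS, collapse = ", "))
  }
  df <- df[.ANNOTATION_COLUMNS]
  df$probability <- suppressWarnings(as.numeric(df$probability))
  df$odds <- suppressWarnings(as.numeric(df$odds))
  validate_annotations(df, line_offset = 1L)
  class(df) <- c("annotation_set", class(df))
  df
}

#' Validate an annotation set
#'
#' Enforces the entry invariants described in [read_annotation_table()].
#' `line_offset` maps row numbers to file lines when the set was parsed from
#' a file with a header.
#'
#' @param annotations data frame with the annotation columns.
#' @param line_offset number to add to row indices in error messages.
#' @return the annotation set, invisibly, if valid.
#' @export
validate_annotations <- function(annotations, line_offset = 0L) {
  if (!is.data.frame(annotations) ||
      !all(.ANNOTATION_COLUMNS %in% names(annotations))) {
    stop("annotation set must have columns: ",
         paste(.ANNOTATION_COLUMNS, collapse = ", "))
  }
  where <- function(i) {
    if (line_offset > 0) paste0("line ", i + line_offset) else paste0("row ", i)
  }
  bad <- which(is.na(annotations$seq_id) | !nzchar(annotations$seq_id))
  if (length(bad)) stop(where(bad[1]), ": missing seq_id")
  bad <- which(!(annotations$group %in% .ANNOTATION_GROUPS))
  if (length(bad)) {
    stop(where(bad[1]), ": group must be one of ",
         paste(.ANNOTATION_GROUPS, collapse = ", "))
  }
  bad <- which(is.na(annotations$category) | !nzchar(annotations$category))
  if (length(bad)) stop(where(bad[1]), ": missing category")
  bad <- which(is.na(annotations$probability) | annotations$probability < 0 |
                 annotations$probability > 1)
  if (length(bad)) stop(where(bad[1]), ": probability must be in [0, 1]")
  bad <- which(is.na(annotations$odds) | annotations$odds < 0)
  if (length(bad)) stop(where(bad[1]), ": odds must be non-negative")
  key <- paste(annotations$seq_id, annotations$group, annotations$category,
               sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad)) {
    stop(where(bad[1]), ": duplicate (seq_id, group, category) entry")
  }
  invisible(annotations)
}

#' Top-odds categories of the control sequence
#'
#' For each of the three groups, picks the category in which the control
#' (azurin by default) attains its maximal odds. These become the reference
#' categories in which every candidate's odds are read off. Ties are broken
#' deterministically by lexicographic category name, with a warning.
#'
#' @param annotations an annotation set.
#' @param control_id id of the control sequence.
#' @return object of class `reference_categories`: a list with elements `F`,
#'   `EZ`, `GO` and `control_id`.
#' @export
reference_categories <- function(annotations, control_id = "azurin") {
  validate_annotations(annotations)
  ctl <- annotations[annotations$seq_id == control_id, , drop = FALSE]
  if (nrow(ctl) == 0) {
    stop("control sequence '", control_id, "' has no annotation entries")
  }
  pick <- function(g) {
    rows <- ctl[ctl$group == g, , drop = FALSE]
    if (nrow(rows) == 0) {
      stop("control '", control_id, "' lacks entries in group ", g)
    }
    top <- rows$category[rows$odds == max(rows$odds)]
    if (length(top) > 1) {
      top <- sort(top)
      warning("control '", control_id, "' has tied top odds in group ", g,
              "; using lexicographically first category '", top[1], "'")
      log_msg("WARN", "tie in group ", g, " resolved to '", top[1], "'")
    }
    top[1]
  }
  structure(list(F = pick("F"), EZ = pick("EZ"), GO = pick("GO"),
                 control_id = control_id),
            class = "reference_categories")
}

#' @export
print.reference_categories <- function(x, ...) {
  cat(sprintf("Reference categories of control '%s':\n", x$control_id))
  cat(sprintf("  F : %s\n  EZ: %s\n  GO: %s\n", x$F, x$EZ, x$GO))
  invisible(x)
}

.lookup_odds <- function(annotations, seq_id, group, category) {
  row <- annotations[annotations$seq_id == seq_id &
                       annotations$group == group &
                       annotations$category == category, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("sequence '", seq_id, "' has no ", group, " entry for category '",
         category, "'")
  }
  row[1, ]
}

#' Azurin-similarity score of one sequence
#'
#' The score is the base-10 logarithm of the product of the three odds the
#' sequence attains in the control's reference categories. The three odds
#' enter unweighted. A score above 0 means the odds product exceeds 1, i.e.
#' the predictor favours azurin-like membership in all three groups jointly;
#' the selection rule `score > 0` is invariant to the logarithm base. The
#' probability score is computed with the same formula over the probability
#' column. A zero constituent odds (or probability) yields a `-Inf` sentinel
#' score with a warning rather than an error, so one failed category does
#' not abort a batch; sentinel entries are never selected.
#'
#' @param annotations an annotation set.
#' @param refs reference categories from [reference_categories()].
#' @param seq_id id of the sequence to score.
#' @return one-row data frame with `seq_id`, `odds_product`, `score`
#'   (log10), `prob_product`, `prob_score`.
#' @export
azurin_similarity_score <- function(annotations, refs, seq_id) {
  stopifnot(inherits(refs, "reference_categories"),
            is.character(seq_id), length(seq_id) == 1)
  rows <- lapply(.ANNOTATION_GROUPS, function(g) {
    .lookup_odds(annotations, seq_id, g, refs[[g]])
  })
  odds <- vapply(rows, function(r) r$odds, numeric(1))
  prob <- vapply(rows, function(r) r$probability, numeric(1))
  odds_product <- prod(odds)
  prob_product <- prod(prob)
  if (any(odds == 0)) {
    warning("sequence '", seq_id, "' has zero odds in a reference category; ",
            "score set to -Inf")
    score <- -Inf
  } else {
    score <- log10(odds_product)
  }
  prob_score <- if (any(prob == 0)) -Inf else log10(prob_product)
  data.frame(seq_id = seq_id, odds_product = odds_product, score = score,
             prob_product = prob_product, prob_score = prob_score,
             stringsAsFactors = FALSE)
}

#' Score a batch of sequences against the control's categories
#'
#' @param annotations an annotation set.
#' @param refs reference categories from [reference_categories()].
#' @param seq_ids ids to score; defaults to every annotated id except the
#'   control.
#' @return data frame with one [azurin_similarity_score()] row per id.
#' @export
similarity_scores <- function(annotations, refs, seq_ids = NULL) {
  if (is.null(seq_ids)) {
    seq_ids <- setdiff(unique(annotations$seq_id), refs$control_id)
  }
  if (length(seq_ids) == 0) {
    return(data.frame(seq_id = character(), odds_product = numeric(),
                      score = numeric(), prob_product = numeric(),
                      prob_score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_ids, function(id) {
    azurin_similarity_score(annotations, refs, id)
  }))
}

#' Rank scored sequences and select the azurin-like subset
#'
#' Sorts by descending score with `-Inf` sentinels last and ties broken by
#' `seq_id`, then selects every sequence with score strictly greater than 0
#' (equivalently, odds product greater than 1).
#'
#' @param scores data frame from [similarity_scores()].
#' @return the scores with added `rank` and `selected` columns, in rank
#'   order.
#' @export
rank_and_select <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("seq_id", "score") %in% names(scores)))
  if (nrow(scores) == 0) {
    out <- scores
    out$rank <- integer(0)
    out$selected <- logical(0)
    return(out)
  }
  ord <- order(-scores$score, scores$seq_id)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$score > 0
  rownames(out) <- NULL
  out
}

#' Correlation between odds score and probability score
#'
#' Pearson correlation over all sequences with finite scores in both
#' coordinates (sentinel-scored sequences are excluded).
#'
#' @param scores data frame with `score` and `prob_score` columns.
#' @return object of class `correlation_result` with fields `r` and `n`.
#' @export
odds_probability_correlation <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("score", "prob_score") %in% names(scores)))
  keep <- is.finite(scores$score) & is.finite(scores$prob_score)
  x <- scores$score[keep]
  y <- scores$prob_score[keep]
  if (length(x) < 2) {
    stop("need at least 2 sequences with finite scores; have ", length(x))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one coordinate; correlation undefined")
  }
  structure(list(r = stats::cor(x, y), n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f over n = %d scored sequences\n", x$r, x$n))
  invisible(x)
}

#' Write a similarity-score report as TSV
#'
#' Columns: `seq_id`, `odds_product`, `score` (base-10 log), `prob_score`,
#' `rank`, `selected`.
#'
#' @param ranked data frame from [rank_and_select()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(ranked, path) {
  cols <- c("seq_id", "odds_product", "score", "prob_score", "rank",
            "selected")
  stopifnot(all(cols %in% names(ranked)))
  write_tsv(ranked[cols], path)
}
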