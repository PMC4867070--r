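#' Round half up
#'
#' Rounds to `digits` decimal places with halves rounding up (0.5 becomes 1),
#' unlike [round()]'s round-half-to-even. All reported percentages in the
#' package go through this rule so that integer hydrophobic percentages and
#' two-decimal interface percentages match conventional table formatting.
#'
#' @param x numeric vector; package uses are non-negative.
#' @param digits number of decimal places to keep.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_up(51.22)        # 51
#' round_half_up(100 * 16 / 30, 2)  # 53.33
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# leveled logging to stderr; reports are never mixed into this stream
.log_levels <- c(DEBUG = 10, INFO = 20, WARN = 30, ERROR = 40)

log_threshold <- function() {
  lev <- getOption("azurscreen.log_level", "INFO")
  .log_levels[[match.arg(lev, names(.log_levels))]]
}

log_msg <- function(level, ...) {
  if (.log_levels[[level]] < log_threshold()) {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s azurscreen: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level,
                  paste0(..., collapse = "")))
  invisible(NULL)
}

# TSV conventions shared by every report writer
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "")
}

ext_file <- function(name) {
  system.file("extdata", name, package = "azurscreen", mustWork = TRUE)
}

# evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators never perturb global randomness
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
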