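## Amplicon panel: the primer table. One row per amplicon with the forward
## primer, the reverse primer and the insert length (bases between the two
## primer 3' ends, primers excluded).

#' Construct an amplicon panel
#'
#' Validates and assembles a panel from its columns. Most users will call
#' [read_primer_table()] instead.
#'
#' @param forward,reverse Uppercase DNA primer sequences (`A/C/G/T/N`).
#' @param insert_len Non-negative integer insert lengths (primer-exclusive:
#'   the number of bases between the forward and reverse primers).
#' @param amplicon_id Unique identifiers; defaults to `AMP1`, `AMP2`, ...
#' @return A data frame of class `amplicon_panel` with columns
#'   `amplicon_id`, `forward`, `reverse`, `insert_len` and attribute
#'   `max_primer_len`.
#' @export
amplicon_panel <- function(forward, reverse, insert_len,
                           amplicon_id = paste0("AMP", seq_along(forward))) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  .check_dna(forward, "forward primer")
  .check_dna(reverse, "reverse primer")
  if (any(!nzchar(forward)) || any(!nzchar(reverse)))
    stop("primers must be non-empty", call. = FALSE)
  insert_len <- as.integer(insert_len)
  if (anyNA(insert_len) || any(insert_len < 0L))
    stop("insert_len must be a non-negative integer", call. = FALSE)
  if (anyDuplicated(amplicon_id))
    stop("duplicate amplicon_id: ",
         amplicon_id[duplicated(amplicon_id)][1L], call. = FALSE)
  stopifnot(length(forward) == length(reverse),
            length(forward) == length(insert_len),
            length(forward) == length(amplicon_id))
  panel <- data.frame(amplicon_id = as.character(amplicon_id),
                      forward = forward, reverse = reverse,
                      insert_len = insert_len,
                      stringsAsFactors = FALSE)
  attr(panel, "max_primer_len") <- max(nchar(panel$forward),
                                       nchar(panel$reverse))
  class(panel) <- c("amplicon_panel", "data.frame")
  panel
}

#' Read a tab-delimited primer table
#'
#' One line per amplicon with three required tab-separated fields —
#' forward primer, reverse primer, insert length — and an optional fourth
#' identifier field. Lines starting with `#` are skipped. Sequences are
#' uppercased; insert length excludes the primers.
#'
#' @param path Path to the primer table.
#' @return An [amplicon_panel()].
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path))
    stop("primer table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("primer table has no data lines: ", path, call. = FALSE)
  fwd <- rev_ <- id <- character(length(idx))
  ins <- integer(length(idx))
  for (j in seq_along(idx)) {
    ln <- idx[j]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("line ", ln, ": expected >= 3 tab-separated fields, got ",
           length(fields), call. = FALSE)
    f <- toupper(trimws(fields[1L]))
    r <- toupper(trimws(fields[2L]))
    if (!grepl("^[ACGTN]+$", f) || !grepl("^[ACGTN]+$", r))
      stop("line ", ln, ": primer contains illegal characters", call. = FALSE)
    il <- suppressWarnings(as.integer(trimws(fields[3L])))
    if (is.na(il) || il < 0L)
      stop("line ", ln, ": insert length is not a non-negative integer: '",
           fields[3L], "'", call. = FALSE)
    fwd[j] <- f; rev_[j] <- r; ins[j] <- il
    id[j] <- if (length(fields) >= 4L && nzchar(trimws(fields[4L])))
      trimws(fields[4L]) else paste0("AMP", ln)
  }
  amplicon_panel(fwd, rev_, ins, id)
}

#' Write a panel back to the tab-delimited table format
#'
#' @param panel An [amplicon_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(panel, path) {
  stopifnot(inherits(panel, "amplicon_panel"))
  lines <- c("#forward\treverse\tinsert_len\tamplicon_id",
             sprintf("%s\t%s\t%d\t%s", panel$forward, panel$reverse,
                     panel$insert_len, panel$amplicon_id))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d primer pairs, max primer length %d bp\n",
              nrow(x), attr(x, "max_primer_len")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more\n", sep = "")
  invisible(x)
}
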