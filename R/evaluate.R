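## Scoring trimmed output against simulator truth. Definitions:
##   TPR = any-trim rate on primer-bearing reads,
##   TNR = no-trim rate on primer-free reads,
##   ACC = exact-trim rate on primer-bearing reads (output byte-equal to
##         the true insert, already truncated at the read end for
##         normal-condition reads).

#' Evaluate trimmed reads against the ground truth
#'
#' @param trimmed Either a data frame with columns `id` and `seq` (as
#'   returned by [read_fastq()]; paired-end output should be
#'   concatenated with `rbind`), or a character vector of trimmed FASTQ
#'   paths to read.
#' @param truth Truth data frame from [simulate_reads()] /
#'   [read_truth_table()], or a truth-table path.
#' @return A list of class `trim_metrics`: `tpr`, `tnr`, `acc` (fractions
#'   in `[0, 1]`, `NA` when the corresponding class is empty), `n_pos`,
#'   `n_neg`.
#' @examples
#' \dontrun{
#' sim <- simulate_dataset(sim_config(seed = 1), tempfile())
#' trim_fastq(sim$fastq1, out1, sim$panel, sim$fastq2, out2)
#' evaluate_trimming(c(out1, out2), sim$truth)
#' }
#' @export
evaluate_trimming <- function(trimmed, truth) {
  if (is.character(trimmed))
    trimmed <- do.call(rbind, lapply(trimmed, read_fastq))
  if (is.character(truth) && length(truth) == 1L && file.exists(truth))
    truth <- read_truth_table(truth)
  stopifnot(is.data.frame(trimmed), is.data.frame(truth))
  idx <- match(truth$read_id, trimmed$id)
  if (anyNA(idx))
    stop("truth read absent from trimmed output: ",
         truth$read_id[is.na(idx)][1L],
         " (was it dropped by the quality filter?)", call. = FALSE)
  out_seq <- trimmed$seq[idx]
  any_trim <- nchar(out_seq) < truth$read_len
  pos <- truth$has_primer
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tpr <- if (n_pos > 0L) mean(any_trim[pos]) else NA_real_
  tnr <- if (n_neg > 0L) mean(!any_trim[!pos]) else NA_real_
  acc <- if (n_pos > 0L) mean(out_seq[pos] == truth$true_insert[pos])
         else NA_real_
  structure(list(tpr = tpr, tnr = tnr, acc = acc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "trim_metrics")
}

#' Write a one-row tab-separated metrics report
#'
#' @param metrics A `trim_metrics` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "trim_metrics"))
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.6f", x)
  writeLines(c("#tpr\ttnr\tacc\tn_pos\tn_neg",
               sprintf("%s\t%s\t%s\t%d\t%d", fmt(metrics$tpr),
                       fmt(metrics$tnr), fmt(metrics$acc),
                       metrics$n_pos, metrics$n_neg)), path)
  invisible(path)
}

#' @export
print.trim_metrics <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf(
    "TPR %s  TNR %s  ACC %s  (%d primer-bearing, %d primer-free reads)\n",
    pc(x$tpr), pc(x$tnr), pc(x$acc), x$n_pos, x$n_neg))
  invisible(x)
}
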