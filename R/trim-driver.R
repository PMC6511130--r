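## File-level trimming driver: streams one FASTQ (single-end) or two
## (paired-end) through the trim engine in chunks and accumulates a run
## summary.

.new_counts <- function(panel) {
  list(total = 0L, normal = 0L, readthrough = 0L, untrimmed = 0L,
       dropped = 0L,
       per_amplicon = stats::setNames(integer(nrow(panel)),
                                      panel$amplicon_id))
}

.count_result <- function(counts, res, amp_ids) {
  counts$total <- counts$total + 1L
  switch(res$status,
    TRIMMED_NORMAL = { counts$normal <- counts$normal + 1L },
    TRIMMED_READTHROUGH = { counts$readthrough <- counts$readthrough + 1L },
    UNTRIMMED = { counts$untrimmed <- counts$untrimmed + 1L },
    DROPPED_QUALITY = { counts$dropped <- counts$dropped + 1L })
  if (startsWith(res$status, "TRIMMED")) {
    a <- amp_ids[res$match$primer_index]
    counts$per_amplicon[a] <- counts$per_amplicon[a] + 1L
  }
  counts
}

#' Trim FASTQ file(s) against a primer panel
#'
#' Streams the input in chunks, trims every read with [trim_single()]
#' (paired-end: [process_pair()], which keeps mates synchronized), and
#' writes trimmed FASTQ plus an optional tab-separated stats file.
#' Untrimmed reads are written unless `keep_untrimmed = FALSE`; reads
#' dropped by the quality filter are never written. Trimming is fully
#' deterministic.
#'
#' @param read1 Input FASTQ (mate 1 for paired-end).
#' @param out1 Output FASTQ for `read1` (gzipped iff ending `.gz`).
#' @param panel An [amplicon_panel()] or a primer-table path.
#' @param read2,out2 Mate-2 input/output for paired-end; `NULL` for
#'   single-end.
#' @param params A [trim_params()] list.
#' @param stats_path Optional path for a tab-separated run summary.
#' @return A list of class `trim_summary`: `total_reads`,
#'   `trimmed_reads`, `readthrough_reads`, `untrimmed_reads`,
#'   `dropped_quality`, `per_amplicon`, `encoding`.
#' @export
trim_fastq <- function(read1, out1, panel, read2 = NULL, out2 = NULL,
                       params = trim_params(), stats_path = NULL) {
  if (is.character(panel)) panel <- read_primer_table(panel)
  stopifnot(inherits(panel, "amplicon_panel"))
  paired <- !is.null(read2)
  if (paired && is.null(out2))
    stop("paired-end trimming needs out2", call. = FALSE)
  index <- build_kmer_index(panel, params$match_params$k)

  scan <- prescan_fastq(c(read1, if (paired) read2), sample_size = 1000L)
  if (scan$record_count == 0L)
    warning("no records in input; writing empty output", call. = FALSE)
  enc <- scan$encoding

  con1 <- .open_fastq_out(out1)
  on.exit(close(con1), add = TRUE)
  if (paired) {
    con2 <- .open_fastq_out(out2)
    on.exit(close(con2), add = TRUE)
  }

  counts <- .new_counts(panel)
  ch1 <- .fastq_chunker(read1)
  on.exit(ch1$close(), add = TRUE)
  if (paired) {
    ch2 <- .fastq_chunker(read2)
    on.exit(ch2$close(), add = TRUE)
  }

  write_chunk <- function(con, recs) {
    if (length(recs) == 0L) return(invisible())
    lines <- unlist(lapply(recs, function(r)
      c(paste0("@", r$id), r$seq, "+", r$qual)), use.names = FALSE)
    writeLines(lines, con)
  }

  repeat {
    d1 <- ch1$read(2000L)
    d2 <- if (paired) ch2$read(if (is.null(d1)) 2000L else nrow(d1)) else NULL
    if (is.null(d1) && is.null(d2)) break
    if (paired && (is.null(d1) || is.null(d2) || nrow(d1) != nrow(d2)))
      stop("paired-end inputs are desynchronized (unequal record counts)",
           call. = FALSE)
    keep1 <- list(); keep2 <- list()
    for (i in seq_len(nrow(d1))) {
      r1 <- list(id = d1$id[i], seq = d1$seq[i], qual = d1$qual[i],
                 encoding = enc)
      if (paired) {
        r2 <- list(id = d2$id[i], seq = d2$seq[i], qual = d2$qual[i],
                   encoding = enc)
        res <- process_pair(r1, r2, index, panel, params)
        counts <- .count_result(counts, res[[1L]], panel$amplicon_id)
        counts <- .count_result(counts, res[[2L]], panel$amplicon_id)
        writable <- res[[1L]]$status != "DROPPED_QUALITY" &&
          (params$keep_untrimmed ||
             (res[[1L]]$status != "UNTRIMMED" &&
                res[[2L]]$status != "UNTRIMMED"))
        if (writable) {
          keep1[[length(keep1) + 1L]] <- res[[1L]]$read
          keep2[[length(keep2) + 1L]] <- res[[2L]]$read
        }
      } else {
        if (!passes_quality(r1$qual, params$min_qual, enc)) {
          res1 <- .trim_result(r1, "DROPPED_QUALITY")
        } else {
          res1 <- trim_single(r1, index, panel, params)
        }
        counts <- .count_result(counts, res1, panel$amplicon_id)
        if (res1$status != "DROPPED_QUALITY" &&
            (params$keep_untrimmed || res1$status != "UNTRIMMED")) {
          keep1[[length(keep1) + 1L]] <- res1$read
        }
      }
    }
    write_chunk(con1, keep1)
    if (paired) write_chunk(con2, keep2)
  }

  summary <- structure(list(
    total_reads = counts$total,
    trimmed_reads = counts$normal + counts$readthrough,
    readthrough_reads = counts$readthrough,
    untrimmed_reads = counts$untrimmed,
    dropped_quality = counts$dropped,
    per_amplicon = counts$per_amplicon,
    encoding = enc), class = "trim_summary")
  if (!is.null(stats_path)) write_trim_stats(summary, stats_path)
  summary
}

#' Write a run summary as a tab-separated stats file
#'
#' @param summary A `trim_summary` from [trim_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trim_stats <- function(summary, path) {
  stopifnot(inherits(summary, "trim_summary"))
  lines <- c(
    "#category\tcount",
    sprintf("total_reads\t%d", summary$total_reads),
    sprintf("trimmed_reads\t%d", summary$trimmed_reads),
    sprintf("readthrough_reads\t%d", summary$readthrough_reads),
    sprintf("untrimmed_reads\t%d", summary$untrimmed_reads),
    sprintf("dropped_quality\t%d", summary$dropped_quality),
    sprintf("amplicon:%s\t%d", names(summary$per_amplicon),
            summary$per_amplicon))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.trim_summary <- function(x, ...) {
  cat(sprintf(
    paste0("trim run: %d reads; %d trimmed (%d read-through), ",
           "%d untrimmed, %d dropped by quality [%s]\n"),
    x$total_reads, x$trimmed_reads, x$readthrough_reads,
    x$untrimmed_reads, x$dropped_quality, x$encoding))
  invisible(x)
}
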