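## Streaming FASTQ I/O on base R connections. gzip input is transparent
## (gzfile reads both plain and compressed); output is gzipped when the
## path ends in ".gz". Records travel as data frames with columns
## id / seq / qual, in chunks, so peak memory does not depend on file
## size.

.open_fastq_in <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gzfile(path, open = "rt")
}

.open_fastq_out <- function(path) {
  if (endsWith(path, ".gz")) gzfile(path, open = "w") else file(path, open = "w")
}

## chunk reader: returns a closure yielding data.frame(id, seq, qual) or
## NULL at EOF; validates record structure and normalizes bases.
.fastq_chunker <- function(path) {
  con <- .open_fastq_in(path)
  ordinal <- 0L
  warned_bases <- FALSE
  list(
    read = function(n = 2000L) {
      lines <- readLines(con, n = 4L * n, warn = FALSE)
      if (length(lines) == 0L) return(NULL)
      if (length(lines) %% 4L != 0L)
        stop("truncated FASTQ record ", ordinal + length(lines) %/% 4L + 1L,
             " in ", path, call. = FALSE)
      ids <- lines[seq(1L, length(lines), by = 4L)]
      seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
      plus <- lines[seq(3L, length(lines), by = 4L)]
      quals <- lines[seq(4L, length(lines), by = 4L)]
      bad_hdr <- !startsWith(ids, "@") | !startsWith(plus, "+")
      if (any(bad_hdr))
        stop("malformed FASTQ record ", ordinal + which(bad_hdr)[1L],
             " in ", path, call. = FALSE)
      mism <- nchar(seqs) != nchar(quals)
      if (any(mism))
        stop("sequence/quality length mismatch at record ",
             ordinal + which(mism)[1L], " in ", path, call. = FALSE)
      odd <- grepl("[^ACGTN]", seqs)
      if (any(odd)) {
        if (!warned_bases) {
          warning("non-ACGTN bases in ", path, " mapped to N", call. = FALSE)
          warned_bases <<- TRUE
        }
        seqs[odd] <- gsub("[^ACGTN]", "N", seqs[odd])
      }
      ordinal <<- ordinal + length(ids)
      data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
                 stringsAsFactors = FALSE)
    },
    close = function() close(con)
  )
}

#' Read an entire FASTQ file
#'
#' Convenience wrapper over the chunked reader; loads all records. Input
#' may be plain or gzip-compressed (auto-detected). Lowercase bases are
#' uppercased; bases outside `{A,C,G,T,N}` are mapped to `N` with a
#' one-time warning.
#'
#' @param path FASTQ path.
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ch <- .fastq_chunker(path)
  on.exit(ch$close())
  out <- list()
  repeat {
    d <- ch$read(10000L)
    if (is.null(d)) break
    out[[length(out) + 1L]] <- d
  }
  if (length(out) == 0L)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write FASTQ records
#'
#' Writes 4-line records; output is gzip-compressed iff `path` ends in
#' `".gz"`. Byte-stable for a fixed input.
#'
#' @param records Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  con <- .open_fastq_out(path)
  on.exit(close(con))
  if (nrow(records) > 0L) {
    lines <- as.vector(rbind(paste0("@", records$id), records$seq,
                             "+", records$qual))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Detect the quality-score encoding
#'
#' Community-convention heuristic: any ASCII code below 59 forces
#' `PHRED33` (such codes are illegal under Phred+64). `PHRED64` requires
#' every code to be at least 64 and some code above 74 (`'J'`, the
#' Phred+33 ceiling of modern Illumina data); anything else — including a
#' sample confined to `'@'..'J'`, which is ordinary high-quality Phred+33
#' — defaults to `PHRED33` (the modern-platform prior).
#'
#' @param quals Character vector of quality strings (non-empty).
#' @return `"PHRED33"` or `"PHRED64"`.
#' @export
detect_quality_encoding <- function(quals) {
  quals <- quals[nzchar(quals)]
  if (length(quals) == 0L)
    stop("cannot detect quality encoding from an empty sample", call. = FALSE)
  codes <- as.integer(charToRaw(paste(quals, collapse = "")))
  if (any(codes < 59L)) "PHRED33"
  else if (all(codes >= 64L) && any(codes > 74L)) "PHRED64"
  else "PHRED33"
}

#' Preprocessing scan of FASTQ input
#'
#' Single bounded streaming pass over the first `sample_size` records of
#' each file, recording the maximum read length and the quality encoding.
#' This sizes the 5' search window (longest primer plus buffer); an exact
#' global maximum read length is not required, so the scan is bounded
#' rather than a full pass.
#'
#' @param paths One (single-end) or two (paired-end) FASTQ paths.
#' @param sample_size Maximum records scanned per file (default 10000).
#' @return A list with `max_read_len`, `record_count` (records scanned)
#'   and `encoding`.
#' @export
prescan_fastq <- function(paths, sample_size = 10000L) {
  max_len <- 0L
  count <- 0L
  quals <- character(0L)
  for (path in paths) {
    ch <- .fastq_chunker(path)
    seen <- 0L
    while (seen < sample_size) {
      d <- ch$read(min(2000L, sample_size - seen))
      if (is.null(d)) break
      seen <- seen + nrow(d)
      max_len <- max(max_len, nchar(d$seq))
      quals <- c(quals, d$qual[1:min(50L, nrow(d))])
    }
    ch$close()
    count <- count + seen
  }
  list(max_read_len = max_len, record_count = count,
       encoding = if (count > 0L) detect_quality_encoding(quals) else "PHRED33")
}
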