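## The trimming engine: apply a located 5' primer match, then decide
## between the normal condition (amplicon longer than the read; only the
## 5' primer is present) and the read-through condition (insert shorter
## than the remaining read; the reverse complement of the partner primer
## is present near position insert_len and is removed together with
## everything 3' of it).

#' Trimming parameters
#'
#' @param match_params A [match_params()] list.
#' @param min_qual Mean-Phred quality threshold; reads (or pairs) below it
#'   are dropped. 0 (default) disables the filter.
#' @param keep_untrimmed Write reads in which no primer was found
#'   (default `TRUE`).
#' @param readthrough_slack Half-width (bases) of the window around the
#'   expected 3'-primer start position searched for the partner primer
#'   (default 5; absorbs small indels).
#' @return A list of class `trim_params`.
#' @export
trim_params <- function(match_params = amptrim::match_params(),
                        min_qual = 0, keep_untrimmed = TRUE,
                        readthrough_slack = 5L) {
  stopifnot(inherits(match_params, "match_params"),
            min_qual >= 0, readthrough_slack >= 0L)
  structure(list(match_params = match_params, min_qual = min_qual,
                 keep_untrimmed = isTRUE(keep_untrimmed),
                 readthrough_slack = as.integer(readthrough_slack)),
            class = "trim_params")
}

#' Find the 3' trim boundary under the read-through condition
#'
#' After the 5' primer has been removed, the reverse complement of the
#' partner primer is expected to start at position `insert_len`. It is
#' tested at every offset within `insert_len +/- readthrough_slack` by
#' Hamming distance over the overlapping portion (the primer may be
#' truncated by the read end; at least `k` overlapping bases are
#' required). Returns the offset with minimum distance if that distance is
#' within `max_mismatch`; ties prefer the offset closest to `insert_len`,
#' then the smaller offset.
#'
#' @param seq Read sequence after 5'-primer removal.
#' @param partner The partner primer sequence (as given in the panel; it
#'   is reverse-complemented internally).
#' @param insert_len Expected insert length of the matched amplicon.
#' @param params A [trim_params()] list.
#' @return Integer offset (number of insert bases to keep) or `NULL`.
#' @export
find_readthrough_end <- function(seq, partner, insert_len,
                                 params = trim_params()) {
  mp <- params$match_params
  rc <- charToRaw(reverse_complement(partner))
  s_raw <- charToRaw(seq)
  n <- length(s_raw)
  Lp <- length(rc)
  lo <- max(0L, insert_len - params$readthrough_slack)
  hi <- min(insert_len + params$readthrough_slack, n - mp$k)
  if (hi < lo) return(NULL)
  best_off <- NULL; best_cost <- Inf
  for (o in lo:hi) {
    ov <- min(Lp, n - o)
    if (ov < mp$k) next
    cost <- .ham_raw(rc[1:ov], s_raw[(o + 1L):(o + ov)])
    better <- cost < best_cost ||
      (cost == best_cost &&
         (abs(o - insert_len) < abs(best_off - insert_len)))
    if (better) { best_off <- o; best_cost <- cost }
  }
  if (!is.null(best_off) && best_cost <= mp$max_mismatch) best_off else NULL
}

#' Mean-quality filter
#'
#' @param qual Raw ASCII quality string.
#' @param min_qual Threshold on the mean Phred score; 0 disables.
#' @param encoding `"PHRED33"` or `"PHRED64"`.
#' @return `TRUE` if the read passes.
#' @export
passes_quality <- function(qual, min_qual = 0, encoding = "PHRED33") {
  if (min_qual <= 0) return(TRUE)
  offset <- if (encoding == "PHRED64") 64L else 33L
  mean(as.integer(charToRaw(qual)) - offset) >= min_qual
}

.trim_result <- function(read, status, match = NULL,
                         removed_5p = 0L, removed_3p = 0L) {
  structure(list(read = read, status = status, match = match,
                 bases_removed_5p = removed_5p,
                 bases_removed_3p = removed_3p),
            class = "trim_result")
}

#' Trim a single read
#'
#' Locates a primer at the 5' end ([locate_primer()], both 5' roles); if
#' found, removes everything up to the primer's end (leading junk bases
#' before a shifted placement are removed with it). If the remaining read
#' is longer than the matched amplicon's insert length, attempts
#' read-through removal of the partner primer's reverse complement at the
#' 3' end ([find_readthrough_end()]). The quality string is cut exactly as
#' the sequence.
#'
#' @param read A list with `id`, `seq`, `qual` (and optionally
#'   `encoding`).
#' @param index A [build_kmer_index()] result.
#' @param panel The [amplicon_panel()] the index was built from.
#' @param params A [trim_params()] list.
#' @return A `trim_result`: list with the (possibly shortened) `read`,
#'   `status` (`"TRIMMED_NORMAL"`, `"TRIMMED_READTHROUGH"`,
#'   `"UNTRIMMED"`), the `match`, and `bases_removed_5p` / `_3p`.
#' @export
trim_single <- function(read, index, panel, params = trim_params()) {
  m <- locate_primer(read$seq, index, params$match_params, .ROLES_5P)
  if (is.null(m)) return(.trim_result(read, "UNTRIMMED"))
  out_seq <- substring(read$seq, m$read_end + 1L)
  out_qual <- substring(read$qual, m$read_end + 1L)
  removed_5p <- m$read_end
  removed_3p <- 0L
  status <- "TRIMMED_NORMAL"
  ins <- panel$insert_len[m$primer_index]
  if (nchar(out_seq) > ins) {
    partner <- if (m$role == "FORWARD_5P") panel$reverse[m$primer_index]
               else panel$forward[m$primer_index]
    b <- find_readthrough_end(out_seq, partner, ins, params)
    if (!is.null(b)) {
      removed_3p <- nchar(out_seq) - b
      out_seq <- substr(out_seq, 1L, b)
      out_qual <- substr(out_qual, 1L, b)
      status <- "TRIMMED_READTHROUGH"
    }
  }
  read$seq <- out_seq
  read$qual <- out_qual
  .trim_result(read, status, m, removed_5p, removed_3p)
}

#' Trim a read pair
#'
#' Each mate is trimmed independently with [trim_single()]; if either
#' mate fails the quality filter, both are marked `DROPPED_QUALITY` so
#' the output files stay synchronized. A mate-id mismatch (ignoring a
#' trailing `/1` / `/2`) produces a warning, not an error.
#'
#' @param r1,r2 Reads as in [trim_single()].
#' @inheritParams trim_single
#' @return A list of two `trim_result`s.
#' @export
process_pair <- function(r1, r2, index, panel, params = trim_params()) {
  id1 <- sub("/[12]$", "", r1$id)
  id2 <- sub("/[12]$", "", r2$id)
  if (id1 != id2)
    warning("mate id mismatch: ", r1$id, " vs ", r2$id, call. = FALSE)
  enc1 <- if (is.null(r1$encoding)) "PHRED33" else r1$encoding
  enc2 <- if (is.null(r2$encoding)) "PHRED33" else r2$encoding
  if (!passes_quality(r1$qual, params$min_qual, enc1) ||
      !passes_quality(r2$qual, params$min_qual, enc2)) {
    return(list(.trim_result(r1, "DROPPED_QUALITY"),
                .trim_result(r2, "DROPPED_QUALITY")))
  }
  list(trim_single(r1, index, panel, params),
       trim_single(r2, index, panel, params))
}
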