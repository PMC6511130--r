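## Semi-global Needleman-Wunsch: the primer aligns end-to-end against a
## prefix of the text (anchored at text position 0; the text suffix past
## the alignment is free). Scoring 0 / -1 / -1 for match / mismatch / gap
## makes the score the negated edit distance to the best text prefix.

#' Semi-global Needleman-Wunsch alignment of a primer against text
#'
#' The whole primer must align; the alignment starts at text position 0
#' and may end anywhere (no penalty for the unaligned text suffix). With
#' the default scores (match 0, mismatch -1, gap -1; a single linear gap
#' penalty, no separate opening cost) the returned score equals minus the
#' Levenshtein distance between the primer and the best-matching text
#' prefix. Score ties are resolved toward the smallest `text_end`.
#' Primer-side `N` matches any text base (see [bases_match()]).
#'
#' @param primer,text Non-empty DNA strings.
#' @param match,mismatch,gap Alignment scores.
#' @return A list with `score` (integer) and `text_end` (number of text
#'   bases consumed; 0-based position just past the aligned region).
#' @examples
#' nw_align("ACGT", "ACGTTTTT")  # score 0, text_end 4
#' @export
nw_align <- function(primer, text, match = 0L, mismatch = -1L, gap = -1L) {
  p <- charToRaw(primer)
  t <- charToRaw(text)
  m <- length(p)
  n <- length(t)
  if (m == 0L || n == 0L)
    stop("nw_align() requires non-empty sequences", call. = FALSE)
  prev <- gap * (0:n)          # row 0: consuming text before any primer base
  for (i in seq_len(m)) {
    cur <- numeric(n + 1L)
    cur[1L] <- gap * i
    pi <- p[i]
    sub <- ifelse(pi == t | pi == .RAW_N, match, mismatch)
    for (j in seq_len(n)) {
      cur[j + 1L] <- max(prev[j] + sub[j],      # diagonal
                         prev[j + 1L] + gap,    # gap in text
                         cur[j] + gap)          # gap in primer
    }
    prev <- cur
  }
  best <- max(prev)
  list(score = as.integer(best),
       text_end = which(prev == best)[1L] - 1L)
}
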