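## Low-level DNA string utilities shared by every module. Sequences are
## plain uppercase character strings over {A,C,G,T,N}; hot paths work on
## raw vectors (one byte per base).

.RAW_N <- charToRaw("N")

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || anyNA(seq))
    stop(what, " must be a character vector without NA", call. = FALSE)
  bad <- !grepl("^[ACGTN]*$", seq)
  if (any(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         substr(seq[bad][1L], 1L, 40L), call. = FALSE)
  invisible(seq)
}

#' Reverse complement of DNA sequences
#'
#' Vectorised over its input. `N` complements to `N`. Input must be
#' uppercase `A/C/G/T/N`; anything else is an error.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AACG")  # "CGTT"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  vapply(chartr("ACGTN", "TGCAN", seq),
         function(s) rawToChar(rev(charToRaw(s))),
         character(1L), USE.NAMES = FALSE)
}

#' Single-base comparison with primer-side N wildcard
#'
#' `N` in the primer matches any read base; `N` in the read matches only an
#' `N` in the primer. This policy is applied consistently by
#' [hamming_distance()] and [nw_align()].
#'
#' @param primer_base,read_base Single characters in `{A,C,G,T,N}`
#'   (vectorised, recycled).
#' @return Logical vector.
#' @export
bases_match <- function(primer_base, read_base) {
  primer_base == read_base | primer_base == "N"
}

#' Hamming distance between a primer and an equal-length read segment
#'
#' Counts positions where [bases_match()] is false; the first argument is
#' the primer (its `N`s are wildcards).
#'
#' @param primer,segment Equal-length DNA strings.
#' @return Integer mismatch count.
#' @export
hamming_distance <- function(primer, segment) {
  if (length(primer) != 1L || length(segment) != 1L)
    stop("hamming_distance() takes single strings", call. = FALSE)
  p <- charToRaw(primer)
  t <- charToRaw(segment)
  if (length(p) != length(t))
    stop("hamming_distance() requires equal-length strings", call. = FALSE)
  .ham_raw(p, t)
}

## raw-vector core (no validation); p is the primer side
.ham_raw <- function(p, t) {
  sum(p != t & p != .RAW_N)
}

## uniform random DNA string(s)
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1L))
}
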