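# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain recursion / positional loops on tiny
# inputs.

# classic Levenshtein distance by exhaustive recursion (memoised on the
# index pair; each cell still derived from the recursive definition)
lev_recursive <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (av[i] == bv[j] || av[i] == "N") 0L else 1L
    v <- min(rec(i - 1L, j - 1L) + cost,
             rec(i - 1L, j) + 1L,
             rec(i, j - 1L) + 1L)
    memo[[key]] <- v
    v
  }
  rec(length(av), length(bv))
}

# oracle for the semi-global score: best (negated) edit distance over all
# text prefixes, ties to the shortest prefix
semiglobal_oracle <- function(primer, text) {
  n <- nchar(text)
  d <- vapply(0:n, function(e) {
    if (e == 0L) nchar(primer) else lev_recursive(primer, substr(text, 1, e))
  }, integer(1))
  best <- min(d)
  list(score = -best, text_end = which(d == best)[1] - 1L)
}

# positional brute-force Hamming with the primer-side N wildcard
hamming_oracle <- function(primer, segment) {
  pa <- strsplit(primer, "")[[1]]
  sa <- strsplit(segment, "")[[1]]
  sum(vapply(seq_along(pa),
             function(i) !(pa[i] == sa[i] || pa[i] == "N"), logical(1)))
}

# brute-force best primer placement in a read: try every start for every
# primer, whole-primer Hamming, minimum cost wins (ties: smaller primer
# index, then the scan cannot distinguish equal-cost starts -- return all)
placement_oracle <- function(seq, panel, roles = c("FORWARD_5P", "REVERSE_5P"),
                             max_mismatch = 3) {
  best <- NULL
  seqs <- list(FORWARD_5P = panel$forward, REVERSE_5P = panel$reverse)
  for (role in roles) {
    for (p in seq_along(seqs[[role]])) {
      primer <- seqs[[role]][p]
      L <- nchar(primer)
      for (rs in 0:(nchar(seq) - L)) {
        cost <- hamming_oracle(primer, substr(seq, rs + 1, rs + L))
        if (cost <= max_mismatch &&
            (is.null(best) || cost < best$cost ||
             (cost == best$cost && p < best$primer_index))) {
          best <- list(primer_index = p, role = role, read_start = rs,
                       read_end = rs + L, cost = cost)
        }
      }
    }
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small fixed panel used by several unit tests (two well-separated pairs)
tiny_panel <- function() {
  amplicon_panel(
    forward = c("ACGTTGCAGGTCAATCCGTA", "TTGACCGGATTCAGGCACTT"),
    reverse = c("GGATCCTTAGCACGTGATCC", "CCTAGGCATTGCAACGGTAA"),
    insert_len = c(110L, 30L))
}
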