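## Locating the best-matching primer at a read's 5' end. The k-mers model
## seeds with exact k-mer lookups at read offsets 0..buffer_len and
## verifies each implied placement with a whole-primer Hamming distance;
## the dynamic model ranks candidates by total k-mer hits over the read
## prefix and verifies the top candidate with Needleman-Wunsch.

#' Matching parameters
#'
#' @param k Seed k-mer length (default 8).
#' @param max_mismatch Mismatch/edit-distance allowance for an accepted
#'   match (default 3).
#' @param buffer_len Number of extra 5' read offsets tried when seeding,
#'   and extra bases of read prefix searched beyond the longest primer
#'   (default 12).
#' @param nw_match,nw_mismatch,nw_gap Needleman-Wunsch scores (defaults
#'   0 / -1 / -1; see [nw_align()]).
#' @return A list of class `match_params`.
#' @export
match_params <- function(k = 8L, max_mismatch = 3L, buffer_len = 12L,
                         nw_match = 0L, nw_mismatch = -1L, nw_gap = -1L) {
  k <- as.integer(k); max_mismatch <- as.integer(max_mismatch)
  buffer_len <- as.integer(buffer_len)
  stopifnot(k >= 4L, max_mismatch >= 0L, buffer_len >= 0L)
  structure(list(k = k, max_mismatch = max_mismatch, buffer_len = buffer_len,
                 nw_match = as.integer(nw_match),
                 nw_mismatch = as.integer(nw_mismatch),
                 nw_gap = as.integer(nw_gap)),
            class = "match_params")
}

.primer_match <- function(primer_index, role, read_start, read_end, cost,
                          model) {
  structure(list(primer_index = as.integer(unname(primer_index)),
                 role = unname(role),
                 read_start = as.integer(unname(read_start)),
                 read_end = as.integer(unname(read_end)),
                 cost = as.integer(unname(cost)), model = model),
            class = "primer_match")
}

#' @export
print.primer_match <- function(x, ...) {
  cat(sprintf("primer match: primer %d (%s), read [%d, %d), cost %d, %s model\n",
              x$primer_index, x$role, x$read_start, x$read_end, x$cost,
              x$model))
  invisible(x)
}

#' Locate a primer by exact k-mer seeding (the k-mers model)
#'
#' Extracts the k-mer at each read offset `0..buffer_len`, looks it up in
#' the hash index, and verifies every implied primer placement
#' (`read_start = offset_in_read - offset_in_primer`) by whole-primer
#' Hamming distance against the read segment it covers. Placements that
#' start before the read or run past its end are rejected. Returns the
#' minimum-cost candidate if its cost is within `max_mismatch`; cost ties
#' go to the smaller primer index. Stops early on a perfect hit.
#'
#' @param seq Read sequence (uppercase DNA string).
#' @param index A [build_kmer_index()] result.
#' @param params A [match_params()] list.
#' @param roles Index roles to search (default: both 5' roles).
#' @return A `primer_match` (list with `primer_index`, `role`,
#'   `read_start`, `read_end`, `cost`, `model`) or `NULL`.
#' @export
kmer_model_match <- function(seq, index, params = match_params(),
                             roles = .ROLES_5P) {
  k <- index$k
  n <- nchar(seq)
  if (n < k) return(NULL)
  codes <- .role_code(roles)
  seq_raw <- charToRaw(seq)
  best <- NULL
  seen <- character(0L)
  for (s in 0:min(params$buffer_len, n - k)) {
    m <- index$entries[[substr(seq, s + 1L, s + k)]]
    if (is.null(m)) next
    for (r in seq_len(nrow(m))) {
      role <- m[r, 2L]
      if (!(role %in% codes)) next
      p <- m[r, 1L]
      rs <- s - m[r, 3L]
      if (rs < 0L) next
      L <- index$role_len[[role]][p]
      if (rs + L > n) next                     # truncated placement
      key <- paste0(p, ".", role, ".", rs)
      if (key %in% seen) next
      seen <- c(seen, key)
      cost <- .ham_raw(index$role_raw[[role]][[p]],
                       seq_raw[(rs + 1L):(rs + L)])
      if (is.null(best) || cost < best$cost ||
          (cost == best$cost && p < best$primer_index)) {
        best <- .primer_match(p, .ROLES[role], rs, rs + L, cost, "KMERS")
      }
      if (best$cost == 0L) break
    }
    if (!is.null(best) && best$cost == 0L) break
  }
  if (!is.null(best) && best$cost <= params$max_mismatch) best else NULL
}

#' Locate a primer by k-mer hit ranking plus alignment (the dynamic model)
#'
#' Extracts every k-mer of the read prefix (longest primer plus
#' `buffer_len` bases), tallies hits per candidate (primer, role), and
#' aligns the top-scoring candidate against the prefix with [nw_align()].
#' Accepts iff the edit distance is within `max_mismatch`. Count ties go
#' to the smaller primer index, then to the role order. This is the
#' fallback that handles indels, which defeat exact seeding at a fixed
#' placement.
#'
#' @inheritParams kmer_model_match
#' @return A `primer_match` with `model = "DYNAMIC"` (always
#'   `read_start = 0`; `read_end` is the aligned prefix length) or `NULL`.
#' @export
dynamic_model_match <- function(seq, index, params = match_params(),
                                roles = .ROLES_5P) {
  k <- index$k
  n <- nchar(seq)
  if (n < k) return(NULL)
  codes <- .role_code(roles)
  prefix_len <- min(n, index$max_primer_len + params$buffer_len)
  counts <- matrix(0L, nrow = index$n_primers, ncol = length(.ROLES))
  total <- 0L
  for (s in 0:(prefix_len - k)) {
    m <- index$entries[[substr(seq, s + 1L, s + k)]]
    if (is.null(m)) next
    for (r in seq_len(nrow(m))) {
      if (m[r, 2L] %in% codes) {
        counts[m[r, 1L], m[r, 2L]] <- counts[m[r, 1L], m[r, 2L]] + 1L
        total <- total + 1L
      }
    }
  }
  if (total == 0L) return(NULL)
  ## top candidate: max hits, tie -> lowest primer index, then role order
  top <- which(counts == max(counts), arr.ind = TRUE)
  top <- top[order(top[, 1L], top[, 2L]), , drop = FALSE]
  p <- unname(top[1L, 1L]); role <- unname(top[1L, 2L])
  primer <- rawToChar(index$role_raw[[role]][[p]])
  aln <- nw_align(primer, substr(seq, 1L, prefix_len),
                  params$nw_match, params$nw_mismatch, params$nw_gap)
  cost <- -aln$score
  if (cost > params$max_mismatch || aln$text_end < 1L) return(NULL)
  .primer_match(p, .ROLES[role], 0L, aln$text_end, cost, "DYNAMIC")
}

#' Locate the best-matching primer at a read's 5' end
#'
#' Tries the k-mers model first; on failure falls back to the dynamic
#' model.
#'
#' @inheritParams kmer_model_match
#' @return A `primer_match` or `NULL` if neither model finds a primer
#'   within `max_mismatch`.
#' @export
locate_primer <- function(seq, index, params = match_params(),
                          roles = .ROLES_5P) {
  m <- kmer_model_match(seq, index, params, roles)
  if (!is.null(m)) return(m)
  dynamic_model_match(seq, index, params, roles)
}
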