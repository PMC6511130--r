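## The k-mer hash table: every 1-base-shift k-mer of every primer (and of
## the reverse complements needed for 3'-end search) maps to the primers
## and offsets it came from. Exact-match seeding only; k-mers containing N
## are not indexed (N handling is deferred to Hamming/NW verification).

## role codes, in deterministic order
.ROLES <- c("FORWARD_5P", "REVERSE_5P", "FORWARD_3P_RC", "REVERSE_3P_RC")
.ROLES_5P <- c("FORWARD_5P", "REVERSE_5P")

.role_code <- function(roles) {
  code <- match(roles, .ROLES)
  if (anyNA(code)) stop("unknown role: ", roles[is.na(code)][1L], call. = FALSE)
  code
}

#' Build the primer k-mer hash index
#'
#' Indexes, for every primer in the panel, all `L - k + 1` overlapping
#' k-mers of the primer itself (roles `FORWARD_5P` / `REVERSE_5P`) and of
#' its reverse complement (roles `FORWARD_3P_RC` / `REVERSE_3P_RC`, used
#' for 3'-end searches). Windows containing `N` are skipped.
#'
#' @param panel An [amplicon_panel()].
#' @param k K-mer length; default 8. Must satisfy `4 <= k <=` shortest
#'   primer length.
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(panel, k = 8L) {
  stopifnot(inherits(panel, "amplicon_panel"))
  k <- as.integer(k)
  if (is.na(k) || k < 4L)
    stop("k must be an integer >= 4", call. = FALSE)
  lens <- c(nchar(panel$forward), nchar(panel$reverse))
  if (k > min(lens)) {
    short <- which(pmin(nchar(panel$forward), nchar(panel$reverse)) == min(lens))[1L]
    stop("k = ", k, " exceeds the shortest primer (", min(lens),
         " bp, amplicon ", panel$amplicon_id[short], ")", call. = FALSE)
  }

  role_seqs <- list(panel$forward, panel$reverse,
                    reverse_complement(panel$forward),
                    reverse_complement(panel$reverse))

  env <- new.env(hash = TRUE, parent = emptyenv())
  n_entries <- 0L
  for (role in seq_along(role_seqs)) {
    seqs <- role_seqs[[role]]
    for (p in seq_along(seqs)) {
      s <- seqs[p]
      L <- nchar(s)
      for (o in 0:(L - k)) {
        km <- substr(s, o + 1L, o + k)
        if (grepl("N", km, fixed = TRUE)) next
        env[[km]] <- c(env[[km]], p, role, o)
        n_entries <- n_entries + 1L
      }
    }
  }
  ## finalize: 3-column integer matrices ordered by (primer, role, offset)
  for (km in ls(env, all.names = TRUE)) {
    m <- matrix(env[[km]], ncol = 3L, byrow = TRUE,
                dimnames = list(NULL, c("primer_index", "role", "offset")))
    env[[km]] <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
  }

  structure(list(
    k = k,
    entries = env,
    n_entries = n_entries,
    n_primers = nrow(panel),
    max_primer_len = attr(panel, "max_primer_len"),
    ## raw-vector forms of each role's sequences, for fast verification
    role_raw = lapply(role_seqs, lapply, charToRaw),
    role_len = lapply(role_seqs, nchar)
  ), class = "kmer_index")
}

#' Query the k-mer index
#'
#' @param index A [build_kmer_index()] result.
#' @param kmer A string of length exactly `index$k`.
#' @param roles Subset of `"FORWARD_5P"`, `"REVERSE_5P"`,
#'   `"FORWARD_3P_RC"`, `"REVERSE_3P_RC"` to report.
#' @return A data frame with columns `primer_index`, `role`, `offset`,
#'   ordered by primer index then offset; zero rows if the k-mer is absent.
#' @export
kmer_query <- function(index, kmer, roles = .ROLES) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(kmer) != index$k)
    stop("query k-mer must have length k = ", index$k, call. = FALSE)
  codes <- .role_code(roles)
  m <- index$entries[[kmer]]
  if (is.null(m)) m <- matrix(integer(), ncol = 3L)
  m <- m[m[, 2L] %in% codes, , drop = FALSE]
  data.frame(primer_index = m[, 1L],
             role = .ROLES[m[, 2L]],
             offset = m[, 3L],
             stringsAsFactors = FALSE)
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "k-mer index: k = %d, %d primers, %d indexed windows (%d distinct k-mers)\n",
    x$k, x$n_primers, x$n_entries, length(ls(x$entries, all.names = TRUE))))
  invisible(x)
}
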