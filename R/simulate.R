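## Seeded synthetic-data generator: random well-separated primer panels
## and amplicon read pairs with controlled primer-region errors, a
## configurable fraction of primer-free negative reads, and a ground-truth
## table. Insert bases are kept error-free so that the evaluation metrics
## isolate primer-matching behaviour.

#' Simulation configuration
#'
#' Defaults describe the benchmark conditions used throughout the
#' package's tests: a 50-amplicon panel with 18-25 bp primers, cfDNA-like
#' 80-100 bp inserts on 150 bp reads (so the 3' end reads through into
#' the partner primer), 100 read pairs per amplicon and 10% primer-free
#' reads.
#'
#' @param n_amplicons Number of primer pairs in the panel.
#' @param primer_len_range Min/max primer length (bases).
#' @param insert_len_range Min/max insert length (bases, primer-exclusive).
#' @param read_len Read length (bases).
#' @param depth Read pairs simulated per amplicon.
#' @param errors_in_primer Substitutions placed in each primer copy (0-5).
#' @param indel_prob Probability that one substitution is replaced by a
#'   1 bp indel.
#' @param negative_fraction Fraction of the total reads that are
#'   primer-free uniform-random sequence.
#' @param seed Integer RNG seed (`NULL` leaves the RNG state alone).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_amplicons = 50L, primer_len_range = c(18L, 25L),
                       insert_len_range = c(80L, 100L), read_len = 150L,
                       depth = 100L, errors_in_primer = 0L,
                       indel_prob = 0, negative_fraction = 0.1,
                       seed = NULL) {
  stopifnot(n_amplicons >= 1L, read_len >= 1L, depth >= 1L,
            length(primer_len_range) == 2L, length(insert_len_range) == 2L,
            all(primer_len_range >= 1L), all(insert_len_range >= 1L),
            primer_len_range[1L] <= primer_len_range[2L],
            insert_len_range[1L] <= insert_len_range[2L],
            errors_in_primer >= 0L, errors_in_primer <= 5L,
            indel_prob >= 0, indel_prob <= 1,
            negative_fraction >= 0, negative_fraction <= 1)
  structure(list(n_amplicons = as.integer(n_amplicons),
                 primer_len_range = as.integer(primer_len_range),
                 insert_len_range = as.integer(insert_len_range),
                 read_len = as.integer(read_len), depth = as.integer(depth),
                 errors_in_primer = as.integer(errors_in_primer),
                 indel_prob = indel_prob,
                 negative_fraction = negative_fraction,
                 seed = seed), class = "sim_config")
}

## minimum pairwise separation enforced between panel primers (and their
## reverse complements) when aligned at offset 0: greater than twice the
## largest mismatch allowance exercised in the benchmarks (5), so no read
## within allowance of its true primer can be within allowance of another.
.MIN_PRIMER_SEPARATION <- 11L

## uniform draw from an integer range given as c(min, max); safe when
## min == max (avoids sample()'s scalar expansion)
.sample_range <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

.prefix_ham <- function(a, b) {
  n <- min(length(a), length(b))
  sum(a[1:n] != b[1:n])
}

#' Simulate a well-separated primer panel
#'
#' Draws uniform-random primers and insert sequences. A candidate primer
#' is rejected and redrawn if its Hamming distance (aligned at offset 0,
#' over the shared prefix) to any primer already in the panel — or to any
#' reverse complement of one — is 10 or less (twice the largest mismatch
#' allowance exercised in the benchmarks), which guarantees unambiguous
#' ground truth up to 5 mismatches.
#'
#' @param config A [sim_config()]; its `seed` is applied if non-`NULL`.
#' @return A list with `panel` (an [amplicon_panel()]) and `inserts`
#'   (named character vector of reference insert sequences).
#' @export
simulate_panel <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  plr <- config$primer_len_range
  accepted <- list()
  accepted_raw <- list()
  n_needed <- 2L * config$n_amplicons
  tries <- 0L
  while (length(accepted) < n_needed) {
    len <- .sample_range(plr)
    cand <- .random_dna(1L, len)
    cand_raw <- charToRaw(cand)
    cand_rc_raw <- charToRaw(reverse_complement(cand))
    ok <- TRUE
    for (ex in accepted_raw) {
      if (.prefix_ham(cand_raw, ex) < .MIN_PRIMER_SEPARATION ||
          .prefix_ham(cand_rc_raw, ex) < .MIN_PRIMER_SEPARATION) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      accepted[[length(accepted) + 1L]] <- cand
      accepted_raw[[length(accepted_raw) + 1L]] <- cand_raw
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("cannot draw a well-separated primer after 1000 attempts; ",
             "use longer primers", call. = FALSE)
    }
  }
  fwd <- unlist(accepted[seq(1L, n_needed, by = 2L)])
  rv <- unlist(accepted[seq(2L, n_needed, by = 2L)])
  ins_len <- .sample_range(config$insert_len_range, config$n_amplicons)
  ids <- sprintf("AMP%03d", seq_len(config$n_amplicons))
  inserts <- stats::setNames(
    vapply(ins_len, function(l) .random_dna(1L, l), character(1L)), ids)
  list(panel = amplicon_panel(fwd, rv, ins_len, ids), inserts = inserts)
}

## place e substitutions (one possibly swapped for a 1 bp indel) in a
## primer copy; returns the mutated primer region string
.mutate_primer <- function(primer, e, indel_prob) {
  if (e == 0L) return(primer)
  bases <- strsplit(primer, "")[[1L]]
  L <- length(bases)
  pos <- sample.int(L, min(e, L))
  indel_at <- 0L
  if (stats::runif(1L) < indel_prob) {
    indel_at <- pos[1L]
    pos <- pos[-1L]
  }
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
  }
  if (indel_at > 0L) {
    if (stats::runif(1L) < 0.5) {
      bases <- bases[-indel_at]                      # deletion
    } else {
      bases <- append(bases, sample(c("A", "C", "G", "T"), 1L),
                      after = indel_at - 1L)         # insertion
    }
  }
  paste(bases, collapse = "")
}

## one simulated read: mutated primer region + insert + revcomp(partner)
## + random fill, truncated to read_len; returns read plus its truth row
.build_read <- function(primer, insert, partner, read_len, e, indel_prob) {
  region <- .mutate_primer(primer, e, indel_prob)
  body <- paste0(region, insert, reverse_complement(partner))
  if (nchar(body) < read_len)
    body <- paste0(body, .random_dna(1L, read_len - nchar(body)))
  read <- substr(body, 1L, read_len)
  p5_end <- nchar(region)
  ins_len <- nchar(insert)
  true_insert <- substr(read, p5_end + 1L, p5_end + ins_len)
  p3_start <- p5_end + ins_len
  has_p3 <- p3_start < read_len
  list(seq = read, p5_start = 0L, p5_end = p5_end,
       p3_start = if (has_p3) p3_start else NA_integer_,
       p3_end = if (has_p3) min(read_len, p3_start + nchar(partner))
                else NA_integer_,
       true_insert = true_insert)
}

#' Simulate amplicon reads with ground truth
#'
#' For each amplicon, emits `depth` read pairs: read 1 starts with a copy
#' of the forward primer carrying exactly `errors_in_primer` substitutions
#' (one of them replaced by a 1 bp indel with probability `indel_prob`),
#' followed by the error-free insert, the reverse complement of the
#' reverse primer and random fill, truncated to `read_len`; read 2
#' mirrors it from the reverse primer. Primer-free uniform-random read
#' pairs are added to reach `negative_fraction` of the total. Qualities
#' are uniform Q30.
#'
#' @param panel,inserts Output of [simulate_panel()].
#' @param config A [sim_config()]. When `config$seed` is set, the read
#'   stage reseeds with `seed + 1` so panel and reads are independently
#'   reproducible.
#' @param fastq1,fastq2,truth_path Output paths (`.gz` allowed for
#'   FASTQ).
#' @return Invisibly, a list with the three paths and the truth data
#'   frame (columns `read_id`, `mate`, `has_primer`, `amplicon_id`,
#'   `p5_start`, `p5_end`, `p3_start`, `p3_end`, `read_len`,
#'   `true_insert`).
#' @export
simulate_reads <- function(panel, inserts, config, fastq1, fastq2,
                           truth_path) {
  stopifnot(inherits(panel, "amplicon_panel"),
            inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  rl <- config$read_len
  rows <- list()
  r1 <- list(); r2 <- list()
  for (a in seq_len(nrow(panel))) {
    amp <- panel$amplicon_id[a]
    ins <- inserts[[amp]]
    for (d in seq_len(config$depth)) {
      base_id <- sprintf("%s_read%04d", amp, d)
      m1 <- .build_read(panel$forward[a], ins, panel$reverse[a], rl,
                        config$errors_in_primer, config$indel_prob)
      m2 <- .build_read(panel$reverse[a], reverse_complement(ins),
                        panel$forward[a], rl,
                        config$errors_in_primer, config$indel_prob)
      r1[[length(r1) + 1L]] <- c(paste0(base_id, "/1"), m1$seq)
      r2[[length(r2) + 1L]] <- c(paste0(base_id, "/2"), m2$seq)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = paste0(base_id, c("/1", "/2")), mate = 1:2,
        has_primer = TRUE, amplicon_id = amp,
        p5_start = c(m1$p5_start, m2$p5_start),
        p5_end = c(m1$p5_end, m2$p5_end),
        p3_start = c(m1$p3_start, m2$p3_start),
        p3_end = c(m1$p3_end, m2$p3_end),
        read_len = rl,
        true_insert = c(m1$true_insert, m2$true_insert),
        stringsAsFactors = FALSE)
    }
  }
  n_pos <- 2L * length(r1)
  f <- config$negative_fraction
  n_neg_pairs <- if (f > 0 && f < 1) round(n_pos * f / (1 - f) / 2)
                 else if (f >= 1) stop("negative_fraction must be < 1 when ",
                                       "positives are present", call. = FALSE)
                 else 0L
  for (j in seq_len(n_neg_pairs)) {
    base_id <- sprintf("NEG_read%05d", j)
    s1 <- .random_dna(1L, rl); s2 <- .random_dna(1L, rl)
    r1[[length(r1) + 1L]] <- c(paste0(base_id, "/1"), s1)
    r2[[length(r2) + 1L]] <- c(paste0(base_id, "/2"), s2)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = paste0(base_id, c("/1", "/2")), mate = 1:2,
      has_primer = FALSE, amplicon_id = NA_character_,
      p5_start = NA_integer_, p5_end = NA_integer_,
      p3_start = NA_integer_, p3_end = NA_integer_,
      read_len = rl, true_insert = NA_character_,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  qual <- strrep("?", rl)                      # Q30 under Phred+33
  to_df <- function(lst) {
    m <- do.call(rbind, lst)
    data.frame(id = m[, 1L], seq = m[, 2L],
               qual = vapply(nchar(m[, 2L]), function(n) substr(qual, 1L, n),
                             character(1L)),
               stringsAsFactors = FALSE)
  }
  write_fastq(to_df(r1), fastq1)
  write_fastq(to_df(r2), fastq2)
  write_truth_table(truth, truth_path)
  invisible(list(fastq1 = fastq1, fastq2 = fastq2, truth_path = truth_path,
                 truth = truth))
}

#' Write / read the simulator ground-truth table
#'
#' Tab-separated with a `#`-prefixed header line; `NA` fields are written
#' as `.`.
#'
#' @param truth Truth data frame (see [simulate_reads()]).
#' @param path File path.
#' @return `path` (write) or the truth data frame (read).
#' @export
write_truth_table <- function(truth, path) {
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- c(paste0("#", paste(names(truth), collapse = "\t")),
             do.call(paste, c(lapply(truth, fmt), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  lines <- readLines(path)
  header <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  d <- utils::read.table(text = lines[-1L], sep = "\t",
                         col.names = header, na.strings = ".",
                         colClasses = "character")
  for (col in c("mate", "p5_start", "p5_end", "p3_start", "p3_end",
                "read_len"))
    d[[col]] <- as.integer(d[[col]])
  d$has_primer <- d$has_primer == "TRUE"
  d
}

#' One-call simulation of a complete dataset
#'
#' Runs [simulate_panel()] and [simulate_reads()] and writes the primer
#' table, both FASTQ files and the truth table into `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ outputs.
#' @return A list with paths `primer_table`, `fastq1`, `fastq2`,
#'   `truth_path`, plus the in-memory `panel`, `inserts` and `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pan <- simulate_panel(config)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list(primer_table = file.path(dir, "primers.tsv"),
                fastq1 = file.path(dir, paste0("reads_R1", ext)),
                fastq2 = file.path(dir, paste0("reads_R2", ext)),
                truth_path = file.path(dir, "truth.tsv"))
  write_primer_table(pan$panel, paths$primer_table)
  sim <- simulate_reads(pan$panel, pan$inserts, config,
                        paths$fastq1, paths$fastq2, paths$truth_path)
  c(paths, list(panel = pan$panel, inserts = pan$inserts,
                truth = sim$truth))
}
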