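make_read <- function(seq, id = "r1") {
  list(id = id, seq = seq, qual = strrep("?", nchar(seq)),
       encoding = "PHRED33")
}

test_that("normal condition removes only the 5' primer", {
  set.seed(17)
  panel <- amplicon_panel(random_dna(20), random_dna(20), 140)
  idx <- build_kmer_index(panel, 8)
  insert <- random_dna(140)
  read <- make_read(substr(paste0(panel$forward, insert), 1, 150))
  res <- trim_single(read, idx, panel)
  expect_equal(res$status, "TRIMMED_NORMAL")
  expect_equal(nchar(res$read$seq), 130L)
  expect_equal(res$read$seq, substr(insert, 1, 130))
  expect_equal(res$bases_removed_5p, 20L)
  expect_equal(res$bases_removed_3p, 0L)
})

test_that("read-through condition removes both primers, leaving the insert", {
  set.seed(18)
  panel <- amplicon_panel(random_dna(20), random_dna(20), 110)
  idx <- build_kmer_index(panel, 8)
  insert <- random_dna(110)
  read <- make_read(paste0(panel$forward, insert,
                           reverse_complement(panel$reverse)))  # 150 bp
  res <- trim_single(read, idx, panel)
  expect_equal(res$status, "TRIMMED_READTHROUGH")
  expect_equal(res$read$seq, insert)
  expect_equal(res$bases_removed_5p + res$bases_removed_3p + 110L, 150L)
  expect_equal(nchar(res$read$qual), nchar(res$read$seq))
})

test_that("primer-free reads pass through untouched", {
  set.seed(19)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  read <- make_read(random_dna(150))
  res <- trim_single(read, idx, panel)
  expect_equal(res$status, "UNTRIMMED")
  expect_identical(res$read, read)
})

test_that("read-through boundary search honours shifts, ties and overlap minimum", {
  set.seed(23)
  partner <- random_dna(20)
  insert <- random_dna(110)
  params <- trim_params()
  # exact partner at the expected offset
  expect_equal(find_readthrough_end(
    paste0(insert, reverse_complement(partner), random_dna(20)),
    partner, 110, params), 110L)
  # 2-bp shift (as after an upstream indel) is found within the slack
  expect_equal(find_readthrough_end(
    paste0(substr(insert, 1, 108), reverse_complement(partner),
           random_dna(22)),
    partner, 110, params), 108L)
  # no partner in the tail
  expect_null(find_readthrough_end(paste0(insert, random_dna(40)),
                                   partner, 110, params))
  # fewer than k overlapping bases cannot be verified
  expect_null(find_readthrough_end(
    paste0(insert, substr(reverse_complement(partner), 1, 5)),
    partner, 110, params))
  # a truncated partner with >= k bases still trims
  expect_equal(find_readthrough_end(
    paste0(insert, substr(reverse_complement(partner), 1, 12)),
    partner, 110, params), 110L)
})

test_that("read-through never triggers when the remainder fits the insert", {
  set.seed(27)
  panel <- amplicon_panel(random_dna(20), random_dna(20), 140)
  idx <- build_kmer_index(panel, 8)
  # remaining read (130) <= insert_len (140): must be normal condition
  read <- make_read(substr(paste0(panel$forward, random_dna(140)), 1, 150))
  expect_equal(trim_single(read, idx, panel)$status, "TRIMMED_NORMAL")
})

test_that("quality filter uses the mean Phred score", {
  q30 <- strrep("?", 50)          # Phred+33 code 63 -> Q30
  q10 <- strrep("+", 50)          # code 43 -> Q10
  expect_true(passes_quality(q30, 20, "PHRED33"))
  expect_false(passes_quality(q10, 20, "PHRED33"))
  mixed <- paste0(strrep("?", 25), strrep("+", 25))   # mean Q20
  expect_true(passes_quality(mixed, 20, "PHRED33"))
  expect_false(passes_quality(mixed, 20.5, "PHRED33"))
  # direct arithmetic oracle
  scores <- as.integer(charToRaw(mixed)) - 33L
  expect_equal(mean(scores), 20)
  # phred+64: same string decodes much lower
  expect_false(passes_quality(q30, 20, "PHRED64"))
  expect_true(passes_quality(q30, 0))
})

test_that("pairs stay synchronized when one mate fails quality", {
  set.seed(29)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  r1 <- make_read(paste0(panel$forward[1], random_dna(120)), "p/1")
  r2 <- make_read(paste0(panel$reverse[1], random_dna(120)), "p/2")
  r2$qual <- strrep("+", nchar(r2$seq))   # Q10
  res <- process_pair(r1, r2, idx, panel, trim_params(min_qual = 20))
  expect_equal(res[[1]]$status, "DROPPED_QUALITY")
  expect_equal(res[[2]]$status, "DROPPED_QUALITY")
  # with the filter off both mates are trimmed
  res2 <- process_pair(r1, r2, idx, panel, trim_params())
  expect_true(all(startsWith(c(res2[[1]]$status, res2[[2]]$status),
                             "TRIMMED")))
  expect_warning(process_pair(r1, make_read(r2$seq, "other/2"), idx, panel),
                 "mate id")
})

test_that("length conservation holds for every read under random error load", {
  set.seed(31)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  for (i in 1:60) {
    kind <- i %% 3
    seq <- if (kind == 0) random_dna(150) else {
      p <- if (kind == 1) panel$forward[1] else panel$reverse[2]
      mut <- p
      for (q in sample(nchar(p), sample(0:3, 1)))
        substr(mut, q, q) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(p, q, q)), 1)
      substr(paste0(mut, random_dna(140)), 1, sample(60:150, 1))
    }
    res <- trim_single(make_read(seq), idx, panel)
    expect_equal(res$bases_removed_5p + res$bases_removed_3p +
                   nchar(res$read$seq), nchar(seq))
    expect_equal(nchar(res$read$qual), nchar(res$read$seq))
    # surviving qualities are the contiguous matching substring
    expect_equal(res$read$seq,
                 substr(seq, res$bases_removed_5p + 1,
                        nchar(seq) - res$bases_removed_3p))
  }
})
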