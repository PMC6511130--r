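test_that("hamming_distance matches a positional brute force", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(hamming_distance("ACGT", "ACGA"), 1L)
  expect_equal(hamming_distance("NNNN", "ACGT"), 0L)   # primer-side wildcard
  expect_equal(hamming_distance("ACGT", "NCGT"), 1L)   # read-side N mismatches
  expect_error(hamming_distance("ACG", "ACGT"), "equal-length")
  set.seed(21)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    a <- random_dna(n); b <- random_dna(n)
    if (i %% 5 == 0) substr(a, 1, 1) <- "N"
    expect_equal(hamming_distance(a, b), hamming_oracle(a, b))
  }
})

test_that("nw_align equals the negated edit distance to the best text prefix", {
  set.seed(31)
  for (i in 1:200) {
    primer <- random_dna(sample(2:10, 1))
    text <- random_dna(sample(2:10, 1))
    got <- nw_align(primer, text)
    want <- semiglobal_oracle(primer, text)
    expect_equal(got$score, want$score,
                 info = paste(primer, text))
    expect_equal(got$text_end, want$text_end,
                 info = paste(primer, text))
  }
})

test_that("k-mers model places exact and shifted primers correctly", {
  set.seed(4)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  params <- match_params(max_mismatch = 3)
  insert <- random_dna(60)

  m <- kmer_model_match(paste0(panel$forward[1], insert), idx, params)
  expect_equal(m$model, "KMERS")
  expect_equal(m$primer_index, 1L)
  expect_equal(m$read_start, 0L)
  expect_equal(m$read_end, nchar(panel$forward[1]))
  expect_equal(m$cost, 0L)

  # two junk bases before the primer: placement shifts, oracle agrees
  shifted <- paste0("GG", panel$reverse[2], insert)
  m2 <- kmer_model_match(shifted, idx, params)
  expect_equal(m2$read_start, 2L)
  expect_equal(m2$role, "REVERSE_5P")
  want <- placement_oracle(shifted, panel, max_mismatch = 3)
  expect_equal(m2$primer_index, want$primer_index)
  expect_equal(m2$read_end, want$read_end)
  expect_equal(m2$cost, want$cost)

  # a substitution in every k-mer window defeats allowance 0
  p <- panel$forward[1]
  broken <- p
  for (pos in seq(4, nchar(p), by = 6)) substr(broken, pos, pos) <-
      setdiff(c("A", "C", "G", "T"), substr(p, pos, pos))[1]
  expect_null(kmer_model_match(paste0(broken, insert), idx,
                               match_params(max_mismatch = 0)))
})

test_that("k-mers model reports whole-primer Hamming cost within allowance", {
  set.seed(44)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  for (i in 1:30) {
    p <- sample(1:2, 1)
    primer <- panel$forward[p]
    mut <- primer
    pos <- sample(nchar(primer), 2)
    for (q in pos) substr(mut, q, q) <-
        sample(setdiff(c("A", "C", "G", "T"), substr(primer, q, q)), 1)
    read <- paste0(mut, random_dna(50))
    m <- kmer_model_match(read, idx, match_params(max_mismatch = 3))
    if (!is.null(m)) {
      covered <- substr(read, m$read_start + 1, m$read_end)
      src <- if (m$role == "FORWARD_5P") panel$forward[m$primer_index]
             else panel$reverse[m$primer_index]
      expect_equal(m$cost, hamming_oracle(src, covered))
      expect_lte(m$cost, 3)
    }
  }
})

test_that("dynamic model recovers indel-bearing primers that defeat seeding", {
  set.seed(6)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  p <- panel$forward[1]
  no_del <- paste0(substr(p, 1, 9), substr(p, 11, nchar(p)))  # 1-bp deletion
  read <- paste0(no_del, random_dna(50))
  m <- locate_primer(read, idx, match_params(max_mismatch = 1))
  expect_equal(m$model, "DYNAMIC")
  expect_equal(m$primer_index, 1L)
  expect_equal(m$cost, 1L)
  expect_equal(m$read_end, nchar(no_del))  # boundary lands after the region
  # edit-distance oracle confirms the cost
  expect_equal(lev_recursive(p, no_del), 1L)
  # direct invocation on an exact primer read
  exact <- paste0(p, random_dna(40))
  md <- dynamic_model_match(exact, idx, match_params())
  expect_equal(md$cost, 0L)
  expect_equal(md$read_end, nchar(p))
  # a read sharing no k-mer with the panel yields nothing
  expect_null(dynamic_model_match(strrep("A", 60), idx, match_params()))
})

test_that("locate_primer prefers the k-mers model and falls back cleanly", {
  set.seed(8)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  exact <- paste0(panel$forward[1], random_dna(40))
  expect_equal(locate_primer(exact, idx, match_params())$model, "KMERS")
  p <- panel$forward[2]
  ins <- paste0(substr(p, 1, 12), "T", substr(p, 13, nchar(p)))
  expect_equal(locate_primer(paste0(ins, random_dna(40)), idx,
                             match_params())$model, "DYNAMIC")
  expect_null(locate_primer(strrep("AC", 30), idx, match_params()))
})

test_that("match count is non-decreasing in the mismatch allowance", {
  set.seed(13)
  panel <- tiny_panel()
  idx <- build_kmer_index(panel, 8)
  reads <- character(40)
  for (i in seq_along(reads)) {
    p <- if (i %% 2) panel$forward[1] else panel$reverse[2]
    mut <- p
    for (q in sample(nchar(p), sample(0:4, 1)))
      substr(mut, q, q) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(p, q, q)), 1)
    reads[i] <- paste0(mut, random_dna(45))
  }
  counts <- vapply(0:5, function(mm) {
    sum(vapply(reads, function(r)
      !is.null(locate_primer(r, idx, match_params(max_mismatch = mm))),
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
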