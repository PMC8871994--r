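test_that("identical sequences align perfectly", {
  s <- "ACGTACGTACGTACGT"
  al <- local_align(s, s)
  expect_identical(al$score, 2 * nchar(s))
  expect_identical(al$identity, 1)
  expect_identical(al$coverage, 1)
})

test_that("both subject strands are searched", {
  q <- "ACGTTGCAACGTGGCATCAA"
  al <- local_align(q, revcomp(q))
  expect_identical(al$strand, "-")
  expect_identical(al$score, 2 * nchar(q))
  # with a strand-less subject the forward match wins
  expect_identical(local_align(q, q)$strand, "+")
})

test_that("planted substitutions show up as identity", {
  set.seed(42)
  parent <- random_dna(100, 0.5)
  child <- mutate_sequence(parent, 0.1)
  nmut <- sum(strsplit(parent, "")[[1]] != strsplit(child, "")[[1]])
  al <- local_align(child, parent)
  # ungapped planted pair: identity equals the realized substitution count
  # whenever the optimal local alignment keeps the full span
  expect_gt(al$identity, 0.8)
  expect_lt(abs(al$identity - (1 - nmut / 100)), 0.05)
})

test_that("alignment scores equal an independent full-DP reference", {
  set.seed(7)
  sc <- align_scoring()
  for (i in 1:250) {
    q <- random_dna(sample(5:30, 1), runif(1, 0.3, 0.7))
    s <- random_dna(sample(5:30, 1), runif(1, 0.3, 0.7))
    expect_identical(local_align(q, s, both_strands = FALSE)$score,
                     ref_sw_score(q, s))
  }
})

test_that("alignment scores agree with pairwiseAlignment as a cross-check", {
  set.seed(8)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:40) {
    q <- random_dna(sample(10:40, 1), 0.5)
    s <- random_dna(sample(10:40, 1), 0.5)
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    ours <- local_align(q, s, both_strands = FALSE)$score
    expect_identical(ours, max(0, Biostrings::score(ref)))
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  sc <- estimate_karlin(align_scoring())
  expect_gt(sc$K, 0)
  expect_gt(sc$lambda, 0)
  # linear in database size
  expect_equal(evalue(30, 100, 2e5, sc), 2 * evalue(30, 100, 1e5, sc))
  # monotone decreasing in score, vanishing for large scores
  expect_gt(evalue(20, 100, 1e5, sc), evalue(40, 100, 1e5, sc))
  expect_lt(evalue(500, 100, 1e5, sc), 1e-12)
  expect_error(evalue(30, 100, 1e5, align_scoring()), "Karlin")
  # the cached estimate is stable
  sc2 <- estimate_karlin(align_scoring())
  expect_identical(sc$K, sc2$K)
})

test_that("chance best hits of shuffled queries rarely look significant", {
  sc <- estimate_karlin(align_scoring())
  n_db <- 500L; len_db <- 200L
  db_len_total <- n_db * len_db
  fails <- with_seed(99, {
    db <- lapply(seq_len(n_db), function(i)
      protogenr:::.encode_dna(random_dna(len_db, 0.45)))
    vapply(1:30, function(i) {
      q <- protogenr:::.encode_dna(random_dna(200, 0.45))
      best <- max(vapply(db, function(s)
        protogenr:::sw_score_cpp(q, s, 2, -3, 5, 2), numeric(1)))
      evalue(best, 200, db_len_total, sc, both_strands = FALSE) < 0.01
    }, logical(1))
  })
  expect_lte(sum(fails), 1L)
})

test_that("recycling filters apply E-value, strict identity, and coverage", {
  set.seed(21)
  db <- data.frame(id = sprintf("db%02d", 1:30),
                   sequence = replicate(30, random_dna(300, 0.45)),
                   stringsAsFactors = FALSE)
  take_window <- function(s, len) {
    off <- sample(0:(nchar(s) - len), 1)
    substr(s, off + 1, off + len)
  }
  q10 <- mutate_sequence(take_window(db$sequence[5], 150), 0.10)
  q30 <- mutate_sequence(take_window(db$sequence[9], 150), 0.30)
  fresh <- random_dna(150, 0.45)
  res <- find_recycled_introns(
    data.frame(id = c("q10", "q30", "fresh"),
               sequence = c(q10, q30, fresh), stringsAsFactors = FALSE),
    db)
  rec <- setNames(res$recycled$recycled, res$recycled$query)
  expect_true(rec[["q10"]])    # 10% mutated copy is recovered
  expect_false(rec[["q30"]])   # 30% mutated copy fails the identity filter
  expect_false(rec[["fresh"]])
  # identity exactly 0.80 is rejected (strict >)
  qexact <- "ACGTACGTAC"
  sexact <- "ACGAACTTAC" # 8/10 matches, both mismatches interior
  res2 <- find_recycled_introns(
    data.frame(id = "q", sequence = qexact),
    data.frame(id = "s", sequence = sexact),
    max_evalue = Inf, min_identity = 0.80, min_coverage = 0)
  expect_false(res2$recycled$recycled)
  # empty database: nothing is recycled
  res3 <- find_recycled_introns(
    data.frame(id = "q", sequence = qexact),
    data.frame(id = character(0), sequence = character(0)))
  expect_false(res3$recycled$recycled)
})
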