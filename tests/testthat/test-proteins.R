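test_that("ORF translation uses the standard code and trims the stop", {
  expect_identical(translate_orf("ATGTAA"), "M")
  expect_identical(translate_orf("ATGGGGTGA"), "MG")
  expect_error(translate_orf("ATGGG"), "divisible")
  expect_error(translate_orf("ATGTAACCCTAA"), "internal stop")
})

test_that("hydrophobic cluster detection follows the breaker rules", {
  one <- detect_clusters("AAAVVVAAA")
  expect_identical(nrow(one), 1L)
  expect_identical(one$size, 3L)
  expect_identical(one$start, 3L)
  expect_identical(one$end, 6L)
  # proline always breaks
  expect_identical(nrow(detect_clusters("VVVPVVV")), 2L)
  # gap of 4 breaks, gap of 3 joins
  expect_identical(nrow(detect_clusters("VAAAAV")), 2L)
  expect_identical(nrow(detect_clusters("VAAAV")), 1L)
  expect_identical(detect_clusters("VAAAV")$size, 2L)
  # no hydrophobics at all
  expect_identical(nrow(detect_clusters("AAAA")), 0L)
  # span-based size option
  expect_identical(detect_clusters("VAAAV", size_by = "span")$size, 5L)
})

test_that("cluster detection equals the positional reference on random proteins", {
  set.seed(47)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:400) {
    p <- paste(sample(aas, sample(5:50, 1), replace = TRUE), collapse = "")
    got <- detect_clusters(p)
    want <- ref_clusters(p)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_identical(got$size, want$size)
    }
  }
})

test_that("concatenation with a wide spacer is local (cluster lists concatenate)", {
  set.seed(53)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:30) {
    p1 <- paste(sample(aas, 20, replace = TRUE), collapse = "")
    p2 <- paste(sample(aas, 20, replace = TRUE), collapse = "")
    joined <- paste0(p1, "AAAA", p2)
    a <- detect_clusters(p1)
    b <- detect_clusters(p2)
    b$start <- b$start + 24L; b$end <- b$end + 24L
    j <- detect_clusters(joined)
    expect_identical(j$size, c(a$size, b$size))
    expect_identical(j$start, c(a$start, b$start))
  }
})

test_that("cluster summaries exclude the oldest stratum and fit the age trend", {
  # constant two clusters per protein: slope 0, means 2
  prot <- expand.grid(age_class = paste0("I", 0:5),
                      position = position_labels(),
                      rep = 1:5, stringsAsFactors = FALSE)
  prot$orf_id <- sprintf("p%03d", seq_len(nrow(prot)))
  prot$sequence <- "AAVVLAAAAVVLAA"
  cs <- cluster_summary(prot)
  expect_false("I5" %in% cs$per_protein$age_class)
  expect_true(all(cs$by_stratum$mean_clusters == 2))
  expect_equal(cs$fit$slope, 0)
  # planted Poisson trend is recovered within its confidence interval
  set.seed(59)
  mk_protein <- function(k) {
    # k clusters separated by 4-residue spacers
    paste(rep("VVL", max(k, 0)), collapse = "AAAA")
  }
  rows <- do.call(rbind, lapply(0:4, function(a) {
    k <- stats::rpois(300, 1 + 0.17 * a)
    data.frame(orf_id = sprintf("a%d_%03d", a, seq_along(k)),
               sequence = vapply(k, mk_protein, character(1)),
               age_class = paste0("I", a), position = "intergenic",
               stringsAsFactors = FALSE)
  }))
  rows$sequence[rows$sequence == ""] <- "AAAA"
  cs2 <- cluster_summary(rows)
  expect_gt(cs2$fit$ci_high, 0.17 - 1e-9)
  expect_lt(cs2$fit$ci_low, 0.17 + 1e-9)
})

test_that("longest isoform selection is deterministic with id tie-breaks", {
  tx <- data.frame(
    transcript_id = c("G1.t2", "G1.t1", "G2.t1"),
    gene_id = c("G1", "G1", "G2"), contig = "c1", strand = "+",
    source = "established", biotype = "protein_coding",
    stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = c("G1.t2", "G1.t1", "G2.t1"),
                   start = c(0L, 0L, 500L), end = c(100L, 100L, 700L))
  a <- annotation_set(tx, ex)
  # equal lengths: id order breaks the tie
  expect_identical(longest_isoforms(a), c("G1.t1", "G2.t1"))
})

test_that("external domain tables parse and join to proteins", {
  path <- withr::local_tempfile()
  writeLines(c("# comment",
               "p1 PF00001 3 40 25.2",
               "p2 PF00002 1 20 11.0",
               "garbled line",
               "unknown PF00003 1 5 3.0"), path)
  expect_warning(expect_warning(
    d <- read_domain_table(path, protein_ids = c("p1", "p2")),
    "malformed"), "unknown")
  expect_identical(nrow(d), 2L)
  prot <- data.frame(orf_id = c("p1", "p2", "p3"), age_class = "I5",
                     position = "exonic", stringsAsFactors = FALSE)
  fr <- domain_fraction(d, prot)
  got <- fr$frac_with_domain[fr$age_class == "I5" & fr$position == "exonic"]
  expect_equal(got, 2 / 3)
  # empty table: zero percent everywhere
  empty <- withr::local_tempfile(); writeLines(character(0), empty)
  d0 <- read_domain_table(empty)
  fr0 <- domain_fraction(d0, prot)
  expect_equal(fr0$frac_with_domain[fr0$age_class == "I5" &
                                      fr0$position == "exonic"], 0)
})
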