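demo_motif <- function() {
  counts <- rbind(A = c(10, 0, 0, 2, 0),
                  C = c(0, 10, 0, 2, 0),
                  G = c(0, 0, 10, 4, 0),
                  T = c(0, 0, 0, 2, 10))
  list(id = "DEMO", name = "demo", counts = counts)
}

test_that("JASPAR PFM files parse, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M1 first",
               "A  [ 1 2 3 4 5 ]", "C  [ 0 0 0 0 0 ]",
               "G  [ 9 8 7 6 5 ]", "T  [ 0 0 0 0 0 ]"), path)
  m <- read_jaspar(path)
  expect_length(m, 1L)
  expect_identical(dim(m[[1]]$counts), c(4L, 5L))
  expect_identical(m[[1]]$counts["A", ], c(1, 2, 3, 4, 5))
  rt <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(m, rt)
  expect_identical(read_jaspar(rt)[[1]]$counts, m[[1]]$counts)
  # negative counts and ragged rows are rejected
  bad <- withr::local_tempfile()
  writeLines(c(">B x", "A 1 2", "C 1 2", "G 1 -2", "T 1 2"), bad)
  expect_error(read_jaspar(bad), "negative")
  ragged <- withr::local_tempfile()
  writeLines(c(">R x", "A 1 2", "C 1 2 3", "G 1 2", "T 1 2"), ragged)
  expect_error(read_jaspar(ragged), "unequal")
})

test_that("PSSM probabilities and log-odds follow the pseudocount formula", {
  m <- list(id = "X", name = "x", counts = rbind(A = 10, C = 0, G = 0, T = 0))
  p <- build_pssm(m, background = rep(0.25, 4), pseudocount = 0.8)
  expect_equal(unname(p$prob["A", 1]), 10.2 / 10.8)
  expect_equal(unname(p$prob["C", 1]), 0.2 / 10.8)
  expect_equal(unname(p$pssm["A", 1]), log2((10.2 / 10.8) / 0.25))
  expect_error(build_pssm(m, background = c(0.5, 0.5, 0, 0)), "positive")
  expect_error(build_pssm(m, background = c(0.9, 0.2, 0.2, 0.2)), "sum")
  # uniform counts + uniform background: all-zero log-odds, relative
  # score defined as 1 for the degenerate matrix
  u <- list(id = "U", name = "u",
            counts = matrix(1, 4, 3, dimnames = list(c("A","C","G","T"))))
  pu <- build_pssm(u)
  expect_true(all(abs(pu$pssm) < 1e-12))
  expect_identical(protogenr:::.rel_score(0, pu$min_score, pu$max_score), 1)
})

test_that("consensus words score the matrix maximum (relative score 1)", {
  p <- build_pssm(demo_motif())
  cons <- consensus_sequence(demo_motif())
  expect_identical(cons, "ACGGT")
  raw <- protogenr:::pssm_scores_cpp(protogenr:::.encode_dna(cons), p$pssm)
  expect_equal(raw[1], p$max_score)
})

test_that("window extraction is anchored at the TSS and strand-corrected", {
  g <- tiny_genome(c(c1 = random_dna(2000, 0.5)))
  a <- tiny_annotation(list(
    Tp = list(contig = "c1", strand = "+", blocks = cbind(1000L, 1400L)),
    Tm = list(contig = "c1", strand = "-", blocks = cbind(600L, 1000L))))
  w <- extract_windows(a, g, "upstream200", "test")
  wp <- w[w$id == "Tp", ]
  expect_identical(wp$start, 800L)
  expect_identical(wp$end, 1000L)
  expect_identical(wp$seq, genome_subseq(g, "c1", 800, 1000))
  # minus strand: upstream lies at higher coordinates, reverse-complemented
  wm <- w[w$id == "Tm", ]
  expect_identical(wm$start, 1000L)
  expect_identical(wm$end, 1200L)
  expect_identical(wm$seq, revcomp(genome_subseq(g, "c1", 1000, 1200)))
  # truncation at the contig edge is flagged
  b <- tiny_annotation(list(T0 = list(contig = "c1", strand = "+",
                                      blocks = cbind(50L, 300L))))
  wt <- extract_windows(b, g, "upstream200", "test")
  expect_true(wt$truncated)
  expect_identical(nchar(wt$seq), 50L)
  # core windows are 200 bp centred on the TSS
  wc <- extract_windows(a, g, "core", "test")
  expect_true(all(nchar(wc$seq) == 200L))
})

test_that("background window sampling respects exclusions and the seed", {
  sim <- small_sim()
  excl <- transcript_spans(sim$proto)[, c("contig", "start", "end")]
  w1 <- sample_background(sim$genome, sim$established, n = 10,
                          exclusions = excl, extra = sim$proto, seed = 3)
  w2 <- sample_background(sim$genome, sim$established, n = 10,
                          exclusions = excl, extra = sim$proto, seed = 3)
  expect_identical(w1, w2)
  expect_identical(nrow(w1), 10L)
  # pairwise disjoint
  for (i in 1:9) for (j in (i + 1):10) {
    expect_false(w1$contig[i] == w1$contig[j] &&
                   w1$start[i] < w1$end[j] && w1$end[i] > w1$start[j])
  }
  # none intersect the exclusions
  for (i in 1:10) {
    expect_false(any(excl$contig == w1$contig[i] &
                       excl$start < w1$end[i] & excl$end > w1$start[i]))
  }
  expect_error(
    sample_background(sim$genome, sim$established, n = 50000, seed = 3),
    "achievable")
})

test_that("scan counts equal a brute-force position-by-strand enumeration", {
  set.seed(31)
  motifs <- read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                                    package = "protogenr"))
  for (rep in 1:25) {
    w <- random_dna(sample(10:30, 1), runif(1, 0.3, 0.7))
    m <- motifs[[sample(length(motifs), 1)]]
    sim_thr <- sample(c(0.8, 0.95), 1)
    windows <- data.frame(id = "w1", dataset = "d", seq = w,
                          truncated = FALSE, contig = "c", start = 0,
                          end = nchar(w), strand = "+",
                          stringsAsFactors = FALSE)
    got <- scan_windows(windows, list(m), similarity = sim_thr,
                        background = "uniform")
    want <- ref_scan_count(w, m, sim_thr, background = rep(0.25, 4))
    expect_identical(got$counts$n_hits, as.integer(want))
  }
})

test_that("scan counts are invariant under window reverse-complementation", {
  set.seed(32)
  motifs <- read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                                    package = "protogenr"))
  for (rep in 1:10) {
    w <- random_dna(60, 0.5)
    mk <- function(s) data.frame(id = "w", dataset = "d", seq = s,
                                 truncated = FALSE, contig = "c",
                                 start = 0, end = nchar(s), strand = "+",
                                 stringsAsFactors = FALSE)
    a <- scan_windows(mk(w), motifs, similarity = 0.8,
                      background = "uniform")
    b <- scan_windows(mk(revcomp(w)), motifs, similarity = 0.8,
                      background = "uniform")
    expect_identical(a$counts$n_hits, b$counts$n_hits)
  }
})

test_that("promoter/enhancer partitioning splits by established-window frequency", {
  motifs <- read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                                    package = "protogenr"))[1:4]
  ids <- vapply(motifs, function(m) m$id, character(1))
  windows <- data.frame(id = sprintf("w%02d", 1:20), dataset = "est",
                        seq = "N", truncated = FALSE, contig = "c",
                        start = 0, end = 1, strand = "+",
                        stringsAsFactors = FALSE)
  # motif 1 in 90% of windows, motif 2 in 5%: the frequent one lands in
  # the promoter half, the rare one in the enhancer half
  hits <- rbind(
    data.frame(motif_id = ids[1], window_id = windows$id[1:18],
               offset = 0L, strand = "+", raw_score = 1, rel_score = 1),
    data.frame(motif_id = ids[2], window_id = windows$id[1],
               offset = 0L, strand = "+", raw_score = 1, rel_score = 1))
  part <- partition_motifs(hits, windows, motifs[1:2])
  expect_identical(part$promoter, ids[1])
  expect_identical(part$enhancer, ids[2])
  # all motifs equally frequent: deterministic id-ordered split
  eq_hits <- data.frame(motif_id = ids, window_id = windows$id[1],
                        offset = 0L, strand = "+", raw_score = 1,
                        rel_score = 1)
  p2 <- partition_motifs(eq_hits, windows, motifs)
  expect_identical(p2$promoter, sort(ids)[1:2])
  # quantile 0: everything is promoter
  p3 <- partition_motifs(eq_hits, windows, motifs, quantile = 0)
  expect_identical(p3$promoter, sort(ids))
})

test_that("dataset comparison handles equal and empty datasets", {
  a <- data.frame(window_id = 1:20, dataset = "a", n_hits = rep(3L, 20))
  b <- a; b$dataset <- "b"
  cmp <- compare_datasets(list(a = a, b = b))
  expect_equal(cmp$summary$mean_hits, c(3, 3))
  expect_equal(cmp$tests$statistic, 0)
  expect_equal(cmp$tests$p_value, 1)
  expect_warning(
    cmp2 <- compare_datasets(list(a = a, empty = a[0, ])), "excluded")
  expect_identical(cmp2$summary$dataset, "a")
})
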