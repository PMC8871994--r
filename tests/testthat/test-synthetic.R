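test_that("generated genomes hit the configured GC and are seed-deterministic", {
  spec <- synthetic_spec(seed = 3, n_contigs = 1, contig_length = 100000L,
                         background_gc = 0.5)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(as.character(g1), as.character(g2))
  expect_lt(abs(gc_content(as.character(g1[[1]])) - 0.5), 0.01)
  spec7 <- synthetic_spec(seed = 3, n_contigs = 1,
                          contig_length = 100000L, background_gc = 0.7)
  expect_lt(abs(gc_content(as.character(generate_genome(spec7)[[1]])) - 0.7),
            0.01)
  expect_error(synthetic_spec(background_gc = 1.2), "background_gc")
})

test_that("sequence mutation realizes the configured rate; indels only on request", {
  set.seed(71)
  s <- random_dna(2000, 0.5)
  m <- mutate_sequence(s, 0.1)
  expect_identical(nchar(m), nchar(s)) # substitutions only by default
  diff <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_lt(abs(diff - 0.1), 0.025)
  # protected ends stay untouched
  mp <- mutate_sequence(s, 1, protect_ends = 5L)
  expect_identical(substr(mp, 1, 5), substr(s, 1, 5))
  expect_identical(substr(mp, 1996, 2000), substr(s, 1996, 2000))
  # the indel flag changes lengths
  lens <- replicate(20, nchar(mutate_sequence(s, 0, indel_rate = 0.05)))
  expect_gt(stats::sd(lens), 0)
})

test_that("established genes are planted with the requested structure", {
  spec <- small_spec()
  est <- plant_established_genes(generate_genome(spec), spec)
  tx <- est$annotation$transcripts
  pc <- tx[tx$biotype == "protein_coding", ]
  expect_identical(nrow(pc), spec$established$n_genes)
  n_ex <- table(est$annotation$exons$transcript_id)[pc$transcript_id]
  expect_true(all(n_ex >= 2 & n_ex <= spec$established$n_exons[2]))
  # non-overlapping loci with at least the configured margin
  spans <- transcript_spans(est$annotation)
  for (ctg in unique(spans$contig)) {
    s <- spans[spans$contig == ctg, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) {
      expect_true(all(s$start[-1] - s$end[-nrow(s)] >=
                        spec$established$margin))
    }
  }
  # canonical GT...AG intron ends in transcript orientation
  ins <- all_introns(est$annotation, source = "established",
                     biotype = "protein_coding")
  for (i in sample(nrow(ins), 25)) {
    strand <- tx$strand[match(ins$transcript_id[i], tx$transcript_id)]
    s <- genome_subseq(est$genome, ins$contig[i], ins$start[i], ins$end[i],
                       strand = strand)
    expect_identical(substr(s, 1, 2), "GT")
    expect_identical(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }
})

test_that("identical spec and seed give byte-identical dataset files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_protogene_dataset(small_spec(seed = 9), dir = d1)
  simulate_protogene_dataset(small_spec(seed = 9), dir = d2)
  for (f in c("genome.fa", "established.gtf", "proto.gtf", "orfs.tsv",
              "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("recycled introns sit at the configured identity to their parents", {
  sim <- small_sim()
  est_introns <- all_introns(sim$established, source = "established",
                             biotype = "protein_coding")
  est_introns$id <- paste0(est_introns$transcript_id, "_i",
                           est_introns$ordinal)
  checked <- 0L
  for (oid in names(sim$truth)) {
    t <- sim$truth[[oid]]
    rp <- t$recycled_parent
    if (all(is.na(rp))) next
    pin <- transcript_introns(sim$proto, t$transcript_id)
    for (k in which(!is.na(rp))) {
      child <- genome_subseq(sim$genome, pin$contig[k], pin$start[k],
                             pin$end[k],
                             strand = t$strand)
      par <- est_introns[est_introns$id == rp[k], ]
      parent <- genome_subseq(sim$genome, par$contig, par$start, par$end)
      al <- local_align(child, parent)
      # expected identity = 1 - mutation rate
      expect_gt(al$identity, 0.85)
      expect_lt(al$identity, 0.97)
      expect_gte(al$coverage, 0.95)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("planted ground truth is self-consistent with the emitted files", {
  dir <- withr::local_tempdir()
  sim <- simulate_protogene_dataset(small_spec(seed = 13), dir = dir)
  genome <- load_genome(file.path(dir, "genome.fa"))
  est <- load_annotation(file.path(dir, "established.gtf"))
  orfs <- read_orf_table(file.path(dir, "orfs.tsv"))
  expect_true(all(validate_orf(orfs, genome) == "valid"))
  cl <- classify_genomic_position(orfs, est)
  truth_pos <- vapply(sim$truth[cl$orf_id], function(t) t$position,
                      character(1))
  expect_identical(unname(cl$position), unname(truth_pos))
})
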