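test_that("intron extraction returns the gaps with genome-matching sequence", {
  g <- tiny_genome(c(c1 = paste(rep("ACGTT", 100), collapse = "")))
  a <- tiny_annotation(list(T1 = list(
    contig = "c1", strand = "+",
    blocks = cbind(c(0L, 200L, 320L), c(100L, 300L, 400L)))))
  ins <- extract_introns(a, "T1", g)
  expect_identical(nrow(ins), 2L)
  expect_identical(ins$length, c(100L, 20L))
  expect_identical(ins$sequence[1], genome_subseq(g, "c1", 100, 200))
  # lengths sum to span minus exon lengths
  expect_identical(sum(ins$length), (400L - 0L) - 280L)
  # single exon: none
  b <- tiny_annotation(list(T1 = list(contig = "c1", strand = "+",
                                      blocks = cbind(0L, 100L))))
  expect_identical(nrow(extract_introns(b, "T1", g)), 0L)
})

test_that("single-exon-ORF calls use closed containment in one exon", {
  a <- tiny_annotation(list(T1 = list(
    contig = "c1", strand = "+",
    blocks = cbind(c(0L, 200L), c(100L, 300L)))))
  expect_identical(orf_single_exon(cbind(10L, 70L), a, "T1"), "out_orf")
  # spanning the splice junction
  expect_identical(orf_single_exon(cbind(c(80L, 200L), c(100L, 230L)),
                                   a, "T1"), "in_orf")
  # exactly coterminal with one exon
  expect_identical(orf_single_exon(cbind(0L, 100L), a, "T1"), "out_orf")
  # not applicable without introns
  b <- tiny_annotation(list(T1 = list(contig = "c1", strand = "+",
                                      blocks = cbind(0L, 300L))))
  expect_true(is.na(orf_single_exon(cbind(10L, 70L), b, "T1")))
})

test_that("per-stratum intron summaries report fixtures exactly", {
  g <- tiny_genome(c(c1 = paste(rep("A", 5000), collapse = "")))
  # two proto transcripts, both with 2 introns; one all-single-exon set
  a <- tiny_annotation(list(
    P1 = list(contig = "c1", strand = "+",
              blocks = cbind(c(0L, 150L, 300L), c(100L, 250L, 400L))),
    P2 = list(contig = "c1", strand = "+",
              blocks = cbind(c(1000L, 1150L, 1300L),
                             c(1100L, 1250L, 1400L)))),
    source = "proto", biotype = "proto")
  orfs <- data.frame(
    orf_id = c("o1", "o2"), transcript_id = c("P1", "P2"), contig = "c1",
    strand = "+", blocks = c("10-70", "1010-1070"),
    age_class = c("I0", "I0"), rpm = 1, sequence = "ATG",
    position = c("exonic", "exonic"), stringsAsFactors = FALSE)
  tab <- intron_summary(orfs, a, g)
  row <- tab[tab$age_class == "I0" & tab$position == "exonic", ]
  expect_identical(row$n, 2L)
  expect_identical(row$frac_with_intron, 1)
  expect_identical(row$mean_intron_count, 2)
  expect_identical(row$frac_out_orf, 1)
  # empty strata are NA, not zero
  empty <- tab[tab$age_class == "I5" & tab$position == "intergenic", ]
  expect_true(is.na(empty$frac_with_intron))
  # single-exon-only fixture: fraction 0 everywhere it has members
  b <- tiny_annotation(list(P1 = list(contig = "c1", strand = "+",
                                      blocks = cbind(0L, 400L))),
                       source = "proto", biotype = "proto")
  tab0 <- intron_summary(orfs[1, ], b, g)
  expect_identical(
    tab0$frac_with_intron[tab0$age_class == "I0" &
                            tab0$position == "exonic"], 0)
})

test_that("the intron subsample is seeded and reproducible", {
  introns <- data.frame(id = sprintf("i%03d", 1:40),
                        sequence = replicate(40, random_dna(50)),
                        stringsAsFactors = FALSE)
  s1 <- sample_intron_subset(introns, n = 10, seed = 4)
  s2 <- sample_intron_subset(introns, n = 10, seed = 4)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 10L)
  expect_warning(all_of_them <- sample_intron_subset(introns, n = 100,
                                                     seed = 4), "available")
  expect_identical(nrow(all_of_them), 40L)
})
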