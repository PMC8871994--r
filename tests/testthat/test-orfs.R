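make_orf_row <- function(orf_id = "o1", transcript_id = "t1", contig = "c1",
                         strand = "+", blocks = "0-9", age_class = "I0",
                         rpm = 1, sequence = "ATGAAATAA") {
  data.frame(orf_id = orf_id, transcript_id = transcript_id,
             contig = contig, strand = strand, blocks = blocks,
             age_class = age_class, rpm = rpm, sequence = sequence,
             stringsAsFactors = FALSE)
}

test_that("ORF validation separates valid, artifact and unusual-codon cases", {
  g <- tiny_genome(c(c1 = paste0("ATGAAATAA", "GGGG")))
  expect_identical(validate_orf(make_orf_row(), g), "valid")
  # one substituted base in the claimed sequence
  expect_identical(validate_orf(make_orf_row(sequence = "ATGAACTAA"), g),
                   "mapping_artifact")
  # non-ATG start present in the genome
  g2 <- tiny_genome(c(c1 = "TTGAAATAAGG"))
  expect_identical(
    validate_orf(make_orf_row(sequence = "TTGAAATAA"), g2),
    "unusual_codon")
  # block outside the contig
  expect_identical(validate_orf(make_orf_row(blocks = "0-99"), g),
                   "mapping_artifact")
  # N never matches
  gN <- tiny_genome(c(c1 = "ATGANATAAGG"))
  expect_identical(validate_orf(make_orf_row(sequence = "ATGANATAA"), gN),
                   "mapping_artifact")
})

test_that("spliced minus-strand ORFs validate through strand correction", {
  orf <- "ATGAAATAA" # exon pieces: ATGAAA + TAA, minus strand
  piece1 <- revcomp("TAA"); piece2 <- revcomp("ATGAAA")
  g <- tiny_genome(c(c1 = paste0("GG", piece1, "CCCC", piece2, "GG")))
  row <- make_orf_row(strand = "-", blocks = "2-5,9-15", sequence = orf)
  expect_identical(validate_orf(row, g), "valid")
})

test_that("validation is order-invariant and idempotent", {
  sim <- small_sim()
  st1 <- validate_orf(sim$orfs, sim$genome)
  idx <- rev(seq_len(nrow(sim$orfs)))
  st2 <- validate_orf(sim$orfs[idx, ], sim$genome)
  expect_identical(st1, rev(st2))
  expect_identical(st1, validate_orf(sim$orfs, sim$genome))
})

test_that("expression filter is strict at the threshold", {
  orfs <- rbind(make_orf_row("a", rpm = 0.5), make_orf_row("b", rpm = 0.51),
                make_orf_row("c", rpm = 0.499))
  kept <- filter_expression(orfs)
  expect_identical(kept$orf_id, "b")
  expect_identical(nrow(filter_expression(orfs[0, ])), 0L)
  orfs$rpm[1] <- NA
  expect_error(filter_expression(orfs), "rpm")
})

test_that("genomic position classification follows exonic > intronic > intergenic", {
  # established gene: exons [100,200) and [300,400), intron [200,300)
  aset <- tiny_annotation(list(E1 = list(
    gene = "G1", contig = "c1", strand = "+",
    blocks = cbind(c(100L, 300L), c(200L, 400L)))))
  orfs <- rbind(
    make_orf_row("inside_exon", blocks = "120-150"),
    make_orf_row("straddling", blocks = "180-220"),
    make_orf_row("inside_intron", blocks = "210-260"),
    make_orf_row("outside", blocks = "500-560"))
  cl <- classify_genomic_position(orfs, aset)
  expect_identical(cl$position,
                   c("exonic", "exonic", "intronic", "intergenic"))
  # every ORF gets exactly one label
  expect_true(all(cl$position %in% position_labels()))
  # antisense overlap still counts (strand-agnostic)
  anti <- classify_genomic_position(
    make_orf_row("anti", strand = "-", blocks = "120-150"), aset)
  expect_identical(anti$position, "exonic")
  # unknown contig -> intergenic with a warning
  expect_warning(
    off <- classify_genomic_position(
      make_orf_row("off", contig = "cX", blocks = "0-30"), aset),
    "absent")
  expect_identical(off$position, "intergenic")
})

test_that("ORF table writing round-trips through the reader", {
  sim <- small_sim()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_orf_table(sim$orfs, path)
  back <- read_orf_table(path)
  expect_identical(back$orf_id, sim$orfs$orf_id)
  expect_identical(back$blocks, sim$orfs$blocks)
  expect_equal(back$rpm, sim$orfs$rpm)
  expect_identical(back$sequence, sim$orfs$sequence)
})
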