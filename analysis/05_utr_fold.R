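#!/usr/bin/env Rscript
# 5'/3' UTR extraction with size and GC, and fold-ensemble statistics of
# the 5' UTRs (MFE, ensemble free energy, MFE frequency, ensemble
# diversity) for proto-genes, established genes and length-matched lncRNA
# controls.
suppressPackageStartupMessages({library(protogenr); library(Biostrings)})

dir <- "results/dataset"
genome <- load_genome(file.path(dir, "genome.fa"))
est <- load_annotation(file.path(dir, "established.gtf"))
pro <- load_annotation(file.path(dir, "proto.gtf"), source_tag = "proto")
orfs <- read_orf_table(file.path(dir, "orfs.tsv"))
orfs <- classify_genomic_position(
  filter_expression(orfs[validate_orf(orfs, genome) == "valid", ]), est)

rows <- lapply(seq_len(nrow(orfs)), function(i) {
  ts <- spliced_transcript_seq(pro, orfs$transcript_id[i], genome)
  u <- extract_utrs(orfs$sequence[i], ts)
  data.frame(id = orfs$orf_id[i],
             group = paste0("proto_", orfs$position[i]),
             seq = u$utr5, length = u$utr5_length, gc = u$utr5_gc,
             stringsAsFactors = FALSE)
})
utrs <- do.call(rbind, rows)
eu <- established_utrs(est, genome)
utrs <- rbind(utrs, data.frame(id = eu$transcript_id,
                               group = "established", seq = eu$utr5,
                               length = eu$utr5_length, gc = eu$utr5_gc))
lnc_ids <- est$transcripts$transcript_id[est$transcripts$biotype == "lncRNA"]
lnc <- do.call(rbind, lapply(lnc_ids, function(t) {
  s <- spliced_transcript_seq(est, t, genome)
  data.frame(id = t, group = "lncrna", seq = s, length = nchar(s),
             gc = gc_content(s), stringsAsFactors = FALSE)
}))
utrs <- rbind(utrs, match_length_range(lnc, utrs$length[utrs$length > 0]))

model <- energy_model()
utrs$e_mfe <- NA_real_; utrs$mfe_frequency <- NA_real_
utrs$ensemble_diversity <- NA_real_
idx <- which(utrs$length >= 5 & utrs$length <= 160)
# cap folds per group, seeded subsample
idx <- unlist(lapply(split(idx, utrs$group[idx]), function(v)
  if (length(v) > 100) {set.seed(31); sort(sample(v, 100))} else v))
for (i in idx) {
  f <- fold_sequence(utrs$seq[i], model)
  utrs$e_mfe[i] <- f$e_mfe
  utrs$mfe_frequency[i] <- f$mfe_frequency
  utrs$ensemble_diversity[i] <- f$ensemble_diversity
}
s <- utr_summary(utrs)
print(s$summary)
gc_test <- welch_t(utrs$gc[utrs$group == "established"],
                   utrs$gc[startsWith(utrs$group, "proto_") &
                             !is.na(utrs$gc)])
cat(sprintf("established vs proto 5' UTR GC: %.1f%% vs %.1f%% (p = %.2e)\n",
            100 * gc_test$mean_x, 100 * gc_test$mean_y, gc_test$p_value))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(s$summary, "results/tables/utr_group_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$tests, "results/tables/utr_group_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/tables/utr_group_{means,tests}.tsv\n")
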