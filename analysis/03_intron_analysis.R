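#!/usr/bin/env Rscript
# Intron structure by age and genomic position, single-exon (OutORF)
# fractions, and the recycling search of intergenic proto-gene introns
# against the established-intron database.
suppressPackageStartupMessages({library(protogenr); library(Biostrings)})

dir <- "results/dataset"
genome <- load_genome(file.path(dir, "genome.fa"))
est <- load_annotation(file.path(dir, "established.gtf"))
pro <- load_annotation(file.path(dir, "proto.gtf"), source_tag = "proto")
orfs <- read_orf_table(file.path(dir, "orfs.tsv"))
orfs <- classify_genomic_position(
  filter_expression(orfs[validate_orf(orfs, genome) == "valid", ]), est)

tab <- intron_summary(orfs, pro, genome)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(tab, "results/tables/introns_by_stratum.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_int <- vapply(orfs$transcript_id,
                function(t) nrow(transcript_introns(pro, t)), integer(1))
cat(sprintf("proto-genes with introns: %.1f%%\n", 100 * mean(n_int > 0)))
age_rank <- match(orfs$age_class, age_classes())
tr <- prop.trend.test(tapply(as.integer(n_int > 0), age_rank, sum),
                      tapply(n_int, age_rank, length),
                      score = sort(unique(age_rank)))
cat(sprintf("intron presence rises with age: trend p = %.2e\n", tr$p.value))

# recycling of intergenic proto-gene introns
inter <- orfs$transcript_id[orfs$position == "intergenic"]
queries <- do.call(rbind, lapply(inter, function(t)
  extract_introns(pro, t, genome)))
queries$id <- paste0(queries$transcript_id, "_i", queries$ordinal)
queries <- sample_intron_subset(queries, n = 500, seed = 12L)
db <- all_introns(est, source = "established", biotype = "protein_coding")
db$id <- paste0(db$transcript_id, "_i", db$ordinal)
db$sequence <- vapply(seq_len(nrow(db)), function(i)
  genome_subseq(genome, db$contig[i], db$start[i], db$end[i]), character(1))
rec <- find_recycled_introns(queries[, c("id", "sequence")],
                             db[, c("id", "sequence")])
cat(sprintf("recycled introns: %d of %d (%.1f%%)\n",
            sum(rec$recycled$recycled), nrow(queries),
            100 * mean(rec$recycled$recycled)))
write.table(rec$recycled, "results/tables/intron_recycling.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/tables/introns_by_stratum.tsv, intron_recycling.tsv\n")
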