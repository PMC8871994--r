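#!/usr/bin/env Rscript
# Validate the ORFs against the genome, apply the RPM > 0.5 expression
# filter, and classify each proto-gene as exonic / intronic / intergenic
# against the established annotation; check against the planted truth.
suppressPackageStartupMessages({library(protogenr); library(Biostrings)})

dir <- "results/dataset"
genome <- load_genome(file.path(dir, "genome.fa"))
est <- load_annotation(file.path(dir, "established.gtf"))
orfs <- read_orf_table(file.path(dir, "orfs.tsv"))
truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))

status <- validate_orf(orfs, genome)
cat("validation:", paste(names(table(status)), table(status),
                         collapse = ", "), "\n")
orfs <- filter_expression(orfs[status == "valid", ])
cat("after RPM > 0.5 filter:", nrow(orfs), "proto-genes\n")
orfs <- classify_genomic_position(orfs, est)
print(table(orfs$position, orfs$age_class))

truth_pos <- vapply(truth$orfs[orfs$orf_id], function(t) t$position,
                    character(1))
cat("agreement with planted positions:",
    sprintf("%.1f%%", 100 * mean(orfs$position == truth_pos)), "\n")

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
out <- orfs[, c("orf_id", "position", "age_class")]
write.table(out, "results/tables/classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/tables/classification.tsv\n")
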