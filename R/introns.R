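#' Extract intron records of a transcript
#'
#' One record per gap between consecutive exons of the unspliced
#' transcript, with sequences pulled from the genome (plus strand of the
#' genomic interval; ordinals in ascending genomic order).
#'
#' @param aset [annotation_set()] containing the transcript.
#' @param transcript_id transcript id.
#' @param genome named `DNAStringSet`.
#' @return data.frame (`transcript_id`, `ordinal`, `contig`, `start`,
#'   `end`, `strand`, `length`, `sequence`); zero rows for a single-exon
#'   transcript.
#' @export
extract_introns <- function(aset, transcript_id, genome) {
  ins <- transcript_introns(aset, transcript_id)
  ins$length <- ins$end - ins$start
  ins$sequence <- vapply(seq_len(nrow(ins)), function(i) {
    genome_subseq(genome, ins$contig[i], ins$start[i], ins$end[i])
  }, character(1))
  ins
}

#' Is an ORF confined to a single exon?
#'
#' For a spliced (multi-exon) transcript: `out_orf` if every genomic block
#' of the ORF lies within one exon (closed containment, so an ORF exactly
#' coterminal with an exon counts), i.e. the ORF is not affected by
#' splicing; otherwise `in_orf`. Not applicable to intron-less
#' transcripts.
#'
#' @param orf_blocks integer matrix of ORF genomic blocks (`start`, `end`,
#'   0-based half-open), or the `blocks` string of the ORF table.
#' @param aset [annotation_set()] with the proto transcript.
#' @param transcript_id the ORF's transcript.
#' @return `"out_orf"` or `"in_orf"`; `NA_character_` for a single-exon
#'   transcript.
#' @export
orf_single_exon <- function(orf_blocks, aset, transcript_id) {
  if (is.character(orf_blocks)) {
    orf_blocks <- parse_blocks(orf_blocks)
  }
  if (is.null(colnames(orf_blocks))) {
    colnames(orf_blocks) <- c("start", "end")
  }
  ex <- aset$exons[aset$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) < 2L) {
    return(NA_character_)
  }
  contained_in_one <- vapply(seq_len(nrow(ex)), function(k) {
    all(orf_blocks[, "start"] >= ex$start[k] &
          orf_blocks[, "end"] <= ex$end[k])
  }, logical(1))
  if (any(contained_in_one)) "out_orf" else "in_orf"
}

#' Per-stratum intron summary
#'
#' For each (age class x genomic position) stratum of classified
#' proto-genes: fraction of proto-genes with at least one intron, mean
#' intron count, mean intron length, and the single-exon-ORF (OutORF)
#' fraction among intron-containing proto-genes. Strata with no members
#' are reported as `NA`, not zero.
#'
#' @param orfs classified ORF table (with `position`).
#' @param proto_aset proto [annotation_set()].
#' @param genome named `DNAStringSet` (for intron lengths).
#' @return data.frame keyed by (`age_class`, `position`).
#' @export
intron_summary <- function(orfs, proto_aset, genome) {
  per_tx <- lapply(orfs$transcript_id, function(t)
    transcript_introns(proto_aset, t))
  n_int <- vapply(per_tx, nrow, integer(1))
  mean_len <- vapply(per_tx, function(x) {
    if (nrow(x) == 0L) NA_real_ else mean(x$end - x$start)
  }, numeric(1))
  se <- vapply(seq_len(nrow(orfs)), function(i) {
    if (n_int[i] == 0L) {
      return(NA_character_)
    }
    orf_single_exon(orfs$blocks[i], proto_aset, orfs$transcript_id[i])
  }, character(1))
  grid <- expand.grid(age_class = age_classes(),
                      position = position_labels(),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(g) {
    sel <- orfs$age_class == grid$age_class[g] &
      orfs$position == grid$position[g]
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(grid[g, ], n = 0L, frac_with_intron = NA_real_,
                        mean_intron_count = NA_real_,
                        mean_intron_length = NA_real_,
                        frac_out_orf = NA_real_))
    }
    wi <- sel & n_int > 0L
    data.frame(
      grid[g, ], n = n,
      frac_with_intron = mean(n_int[sel] > 0L),
      mean_intron_count = mean(n_int[sel]),
      mean_intron_length = if (any(wi)) mean(mean_len[wi]) else NA_real_,
      frac_out_orf = if (any(wi)) mean(se[wi] == "out_orf") else NA_real_)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$position, out$age_class, method = "radix"), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Seeded subsample of intron records
#'
#' Reproducible random subset (the "pick a few hundred queries" step of
#' the intron-recycling search). If fewer records exist than requested,
#' all are returned with a warning.
#'
#' @param introns intron data.frame ([extract_introns()] rows).
#' @param n subset size (the recycling analysis uses 500 at full scale).
#' @param seed integer seed.
#' @return subset of `introns`, original order preserved.
#' @export
sample_intron_subset <- function(introns, n = 500L, seed = 1L) {
  if (nrow(introns) <= n) {
    if (nrow(introns) < n) {
      warning("only ", nrow(introns), " introns available; using all")
    }
    return(introns)
  }
  idx <- with_seed(seed, sort(sample.int(nrow(introns), n)))
  out <- introns[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
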