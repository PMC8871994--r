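#' Spliced transcript sequence
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' for minus-strand transcripts, giving the mature transcript 5'->3'.
#'
#' @param aset [annotation_set()].
#' @param transcript_id transcript id.
#' @param genome named `DNAStringSet`.
#' @return character scalar.
#' @export
spliced_transcript_seq <- function(aset, transcript_id, genome) {
  tx <- aset$transcripts[aset$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) == 0L) stop("unknown transcript: ", transcript_id)
  ex <- aset$exons[aset$exons$transcript_id == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(ex)), function(i) {
    genome_subseq(genome, tx$contig, ex$start[i], ex$end[i])
  }, character(1)), collapse = "")
  if (tx$strand == "-") s <- revcomp(s) else s
}

#' Extract the UTRs around an ORF
#'
#' Maps the spliced ORF onto its spliced transcript. The transcription
#' direction is assessed by exact substring search: first in the given
#' orientation, then against the reverse complement of the transcript.
#' The 5' UTR is the prefix before the ORF start, the 3' UTR the suffix
#' after the stop codon (either may be empty). An ORF found in neither
#' orientation is a mapping failure.
#'
#' @param orf_seq spliced ORF sequence.
#' @param transcript_seq spliced transcript sequence.
#' @return list (`utr5`, `utr3`, `orientation` (`"forward"` or
#'   `"reverse"`), `utr5_length`, `utr3_length`, `utr5_gc`, `utr3_gc`).
#' @export
extract_utrs <- function(orf_seq, transcript_seq) {
  hit <- regexpr(orf_seq, transcript_seq, fixed = TRUE)
  orientation <- "forward"
  tseq <- transcript_seq
  if (hit < 0L) {
    tseq <- revcomp(transcript_seq)
    hit <- regexpr(orf_seq, tseq, fixed = TRUE)
    orientation <- "reverse"
  }
  if (hit < 0L) {
    stop("ORF not found in its spliced transcript (mapping failure)")
  }
  utr5 <- substr(tseq, 1L, hit - 1L)
  utr3 <- substr(tseq, hit + nchar(orf_seq), nchar(tseq))
  list(utr5 = utr5, utr3 = utr3, orientation = orientation,
       utr5_length = nchar(utr5), utr3_length = nchar(utr3),
       utr5_gc = gc_content(utr5), utr3_gc = gc_content(utr3))
}

#' UTRs of established transcripts
#'
#' Derives 5'/3' UTR sequences of protein-coding transcripts from their
#' annotated CDS blocks (spliced sequence minus CDS span, strand-aware).
#'
#' @param aset [annotation_set()] with a `cds` table.
#' @param genome named `DNAStringSet`.
#' @return data.frame (`transcript_id`, `utr5`, `utr3`, lengths, GC).
#' @export
established_utrs <- function(aset, genome) {
  if (is.null(aset$cds)) {
    stop("annotation has no CDS features")
  }
  tids <- intersect(
    aset$transcripts$transcript_id[aset$transcripts$biotype ==
                                     "protein_coding"],
    unique(aset$cds$transcript_id))
  rows <- lapply(tids, function(tid) {
    tx <- aset$transcripts[aset$transcripts$transcript_id == tid, ]
    ex <- aset$exons[aset$exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- aset$cds[aset$cds$transcript_id == tid, , drop = FALSE]
    # spliced (genomic-orientation) offset of a genomic position
    cum <- cumsum(c(0L, ex$end - ex$start))
    sp_of <- function(g) {
      k <- which(g >= ex$start & g <= ex$end)[1]
      cum[k] + (g - ex$start[k])
    }
    a <- sp_of(min(cds$start))
    b <- sp_of(max(cds$end))
    sg <- paste(vapply(seq_len(nrow(ex)), function(i) {
      genome_subseq(genome, tx$contig, ex$start[i], ex$end[i])
    }, character(1)), collapse = "")
    if (tx$strand == "+") {
      utr5 <- substr(sg, 1L, a)
      utr3 <- substr(sg, b + 1L, nchar(sg))
    } else {
      utr5 <- revcomp(substr(sg, b + 1L, nchar(sg)))
      utr3 <- revcomp(substr(sg, 1L, a))
    }
    data.frame(transcript_id = tid, utr5 = utr5, utr3 = utr3,
               utr5_length = nchar(utr5), utr3_length = nchar(utr3),
               utr5_gc = gc_content(utr5), utr3_gc = gc_content(utr3),
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Group-wise UTR/fold summary with pairwise tests
#'
#' Means per group for each metric plus pairwise Welch tests. Controls
#' intended as length-matched (e.g. lncRNA full sequences) should be
#' filtered with [match_length_range()] first.
#'
#' @param df data.frame with a `group` column and metric columns.
#' @param metrics metric column names present in `df`.
#' @return list (`summary`, `tests`).
#' @export
utr_summary <- function(df, metrics = c("length", "gc", "e_mfe",
                                        "mfe_frequency",
                                        "ensemble_diversity")) {
  metrics <- intersect(metrics, names(df))
  groups <- sort(unique(df$group))
  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- df[df$group == g, , drop = FALSE]
    cbind(data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(lapply(sub[metrics],
                               function(v) mean(v, na.rm = TRUE))))
  }))
  tests <- NULL
  if (length(groups) > 1L) {
    prs <- utils::combn(groups, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      do.call(rbind, lapply(metrics, function(mt) {
        a <- df[df$group == prs[1, i], mt]
        b <- df[df$group == prs[2, i], mt]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) {
          return(NULL)
        }
        tt <- welch_t(a, b)
        data.frame(metric = mt, group_a = prs[1, i], group_b = prs[2, i],
                   mean_a = mean(a), mean_b = mean(b),
                   statistic = tt$statistic, df = tt$df,
                   p_value = tt$p_value, stringsAsFactors = FALSE)
      }))
    }))
  }
  list(summary = summ, tests = tests)
}

#' Restrict control sequences to a length range
#'
#' Keeps controls whose length falls inside `[min(lengths), max(lengths)]`
#' of the reference set, the length-matching rule used for lncRNA-like
#' controls.
#'
#' @param df data.frame with a `length` column.
#' @param reference_lengths numeric vector of reference lengths.
#' @return the filtered data.frame.
#' @export
match_length_range <- function(df, reference_lengths) {
  rng <- range(reference_lengths, na.rm = TRUE)
  out <- df[df$length >= rng[1] & df$length <= rng[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}
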