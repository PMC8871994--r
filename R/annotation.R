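#' Build an annotation set
#'
#' An `annotation_set` bundles transcript models (exon intervals in the
#' internal 0-based half-open convention) for established genes, and
#' optionally proto-gene transcripts and non-coding loci. Exons of a
#' transcript must be pairwise non-overlapping, on a single contig and
#' strand; introns are the gaps between consecutive exons.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `contig`, `strand`, `source` (`"established"` or `"proto"`), `biotype`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open genomic coordinates).
#' @param cds optional data.frame with columns `transcript_id`, `start`,
#'   `end` giving CDS blocks of established transcripts (same convention).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts, exons, cds = NULL) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  need_t <- c("transcript_id", "gene_id", "contig", "strand", "source", "biotype")
  if (!all(need_t %in% names(transcripts))) {
    stop("transcripts must have columns: ", paste(need_t, collapse = ", "))
  }
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicated transcript_id in annotation")
  }
  need_e <- c("transcript_id", "start", "end")
  if (!all(need_e %in% names(exons))) {
    stop("exons must have columns: ", paste(need_e, collapse = ", "))
  }
  if (!all(exons$transcript_id %in% transcripts$transcript_id)) {
    stop("exon rows reference unknown transcript ids")
  }
  if (any(exons$start < 0 | exons$end <= exons$start)) {
    stop("malformed exon interval (need 0 <= start < end)")
  }
  # sort exons within transcript by ascending genomic start, check overlap
  ord <- order(match(exons$transcript_id, transcripts$transcript_id), exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L) {
      st <- exons$start[idx]
      en <- exons$end[idx]
      if (any(st[-1L] < en[-length(en)])) {
        stop("overlapping exons within transcript ",
             exons$transcript_id[idx[1L]])
      }
    }
  }
  structure(list(transcripts = transcripts, exons = exons, cds = cds),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  tab <- table(x$transcripts$source)
  cat("annotation_set:", nrow(x$transcripts), "transcripts (",
      paste(names(tab), as.integer(tab), collapse = ", "), ");",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Load a GTF annotation
#'
#' Imports exon (and, when present, CDS) features from a GTF via
#' \pkg{rtracklayer} and assembles transcript models. GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#' Exon features without a `transcript_id` attribute are skipped with a
#' warning.
#'
#' @param path path to a GTF file.
#' @param source_tag `"established"` or `"proto"`; stored per transcript.
#' @return An [annotation_set()].
#' @export
load_annotation <- function(path, source_tag = "established") {
  if (!file.exists(path)) {
    stop("GTF not found: ", path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_exon <- md$type == "exon"
  no_tx <- is_exon & (is.na(md$transcript_id) | md$transcript_id == "")
  if (any(no_tx)) {
    warning(sum(no_tx), " exon feature(s) without transcript_id skipped")
    is_exon <- is_exon & !no_tx
  }
  ex <- gr[is_exon]
  if (length(ex) == 0L) {
    stop("no usable exon features in ", path)
  }
  emd <- S4Vectors::mcols(ex)
  biotype <- if ("gene_biotype" %in% names(emd)) {
    as.character(emd$gene_biotype)
  } else {
    rep("protein_coding", length(ex))
  }
  biotype[is.na(biotype)] <- "protein_coding"
  exons <- data.frame(
    transcript_id = as.character(emd$transcript_id),
    contig = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )
  first <- !duplicated(exons$transcript_id)
  transcripts <- data.frame(
    transcript_id = exons$transcript_id[first],
    gene_id = as.character(emd$gene_id)[first],
    contig = exons$contig[first],
    strand = exons$strand[first],
    source = source_tag,
    biotype = biotype[first],
    stringsAsFactors = FALSE
  )
  # per-transcript consistency
  bad <- vapply(split(seq_len(nrow(exons)), exons$transcript_id), function(i) {
    length(unique(exons$contig[i])) > 1L || length(unique(exons$strand[i])) > 1L
  }, logical(1))
  if (any(bad)) {
    stop("transcript(s) spanning several contigs/strands: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  cds <- NULL
  is_cds <- md$type == "CDS" & !is.na(md$transcript_id)
  if (any(is_cds)) {
    cg <- gr[is_cds]
    cds <- data.frame(
      transcript_id = as.character(S4Vectors::mcols(cg)$transcript_id),
      start = GenomicRanges::start(cg) - 1L,
      end = GenomicRanges::end(cg),
      stringsAsFactors = FALSE
    )
  }
  annotation_set(transcripts,
                 exons[, c("transcript_id", "start", "end")],
                 cds = cds)
}

#' Write an annotation set as GTF
#'
#' Deterministic GTF writer (fixed column formatting and attribute order;
#' transcripts ordered by contig, start, transcript id). Coordinates are
#' converted back from the internal 0-based half-open convention to GTF
#' 1-based inclusive. `write_gtf(load_annotation(f))` reproduces a file
#' previously written by this writer byte for byte.
#'
#' @param aset an [annotation_set()].
#' @param path output path.
#' @param feature_source value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(aset, path, feature_source = "protogenr") {
  tx <- aset$transcripts
  ex <- aset$exons
  tx_start <- vapply(split(ex$start, ex$transcript_id), min, numeric(1))
  tx <- tx[order(tx$contig, tx_start[tx$transcript_id], tx$transcript_id,
                 method = "radix"), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    rows <- ex[ex$transcript_id == tid, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      tx$gene_id[i], tid, tx$biotype[i])
    lines <- c(lines, sprintf(
      "%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
      tx$contig[i], feature_source, rows$start + 1L, rows$end,
      tx$strand[i], attr_str))
    if (!is.null(aset$cds)) {
      crows <- aset$cds[aset$cds$transcript_id == tid, , drop = FALSE]
      if (nrow(crows) > 0L) {
        crows <- crows[order(crows$start), , drop = FALSE]
        lines <- c(lines, sprintf(
          "%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\t%s",
          tx$contig[i], feature_source, crows$start + 1L, crows$end,
          tx$strand[i], attr_str))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Introns of one transcript
#'
#' The gaps between consecutive exons, in ascending genomic order
#' (0-based half-open). A single-exon transcript has no introns.
#'
#' @param aset an [annotation_set()].
#' @param transcript_id transcript id.
#' @return data.frame with columns `transcript_id`, `ordinal`, `contig`,
#'   `start`, `end`, `strand`.
#' @export
transcript_introns <- function(aset, transcript_id) {
  tx <- aset$transcripts[aset$transcripts$transcript_id == transcript_id, ]
  if (nrow(tx) == 0L) {
    stop("unknown transcript: ", transcript_id)
  }
  ex <- aset$exons[aset$exons$transcript_id == transcript_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(transcript_id = character(0), ordinal = integer(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    transcript_id = transcript_id,
    ordinal = seq_len(n - 1L),
    contig = tx$contig,
    start = ex$end[-n],
    end = ex$start[-1L],
    strand = tx$strand,
    stringsAsFactors = FALSE
  )
}

#' All introns of a set of transcripts
#'
#' @param aset an [annotation_set()].
#' @param source restrict to transcripts with this `source` tag (`NULL` for
#'   all).
#' @param biotype restrict to this biotype (`NULL` for all).
#' @return data.frame as in [transcript_introns()].
#' @export
all_introns <- function(aset, source = NULL, biotype = NULL) {
  tx <- aset$transcripts
  if (!is.null(source)) tx <- tx[tx$source == source, , drop = FALSE]
  if (!is.null(biotype)) tx <- tx[tx$biotype == biotype, , drop = FALSE]
  out <- rbind_rows(lapply(tx$transcript_id,
                           function(t) transcript_introns(aset, t)))
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), ordinal = integer(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Transcription start sites
#'
#' 0-based genomic position of the TSS per transcript: the lowest exon
#' start on the plus strand, the highest exon end minus one on the minus
#' strand (the 5' end is the highest coordinate there).
#'
#' @param aset an [annotation_set()].
#' @return data.frame with columns `transcript_id`, `contig`, `strand`,
#'   `tss`, `biotype`, `source`.
#' @export
tss_positions <- function(aset) {
  tx <- aset$transcripts
  st <- vapply(split(aset$exons$start, aset$exons$transcript_id),
               min, numeric(1))
  en <- vapply(split(aset$exons$end, aset$exons$transcript_id),
               max, numeric(1))
  tss <- ifelse(tx$strand == "+", st[tx$transcript_id],
                en[tx$transcript_id] - 1)
  data.frame(transcript_id = tx$transcript_id, contig = tx$contig,
             strand = tx$strand, tss = as.integer(tss),
             biotype = tx$biotype, source = tx$source,
             stringsAsFactors = FALSE)
}

# internal: GRanges (1-based) from the internal exon table, one range per row
.exon_granges <- function(aset, source = "established",
                          biotype = "protein_coding") {
  tx <- aset$transcripts
  keep_tx <- tx$transcript_id[tx$source %in% source & tx$biotype %in% biotype]
  ex <- aset$exons[aset$exons$transcript_id %in% keep_tx, , drop = FALSE]
  contig <- tx$contig[match(ex$transcript_id, tx$transcript_id)]
  GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  )
}

.intron_granges <- function(aset, source = "established",
                            biotype = "protein_coding") {
  tx <- aset$transcripts
  keep_tx <- tx$transcript_id[tx$source %in% source & tx$biotype %in% biotype]
  ins <- rbind_rows(lapply(keep_tx, function(t)
    transcript_introns(aset, t)))
  if (is.null(ins) || nrow(ins) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = ins$contig,
    ranges = IRanges::IRanges(start = ins$start + 1L, end = ins$end)
  )
}

#' Genomic span of each transcript
#' @param aset an [annotation_set()].
#' @param source,biotype filters as in [all_introns()].
#' @return data.frame `transcript_id`, `contig`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
transcript_spans <- function(aset, source = NULL, biotype = NULL) {
  tx <- aset$transcripts
  if (!is.null(source)) tx <- tx[tx$source %in% source, , drop = FALSE]
  if (!is.null(biotype)) tx <- tx[tx$biotype %in% biotype, , drop = FALSE]
  st <- vapply(split(aset$exons$start, aset$exons$transcript_id),
               min, numeric(1))
  en <- vapply(split(aset$exons$end, aset$exons$transcript_id),
               max, numeric(1))
  data.frame(transcript_id = tx$transcript_id, contig = tx$contig,
             start = as.integer(st[tx$transcript_id]),
             end = as.integer(en[tx$transcript_id]),
             strand = tx$strand, stringsAsFactors = FALSE)
}
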