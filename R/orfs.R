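#' Read a proto-gene ORF table
#'
#' Tab-separated table with header
#' `orf_id transcript_id contig strand blocks age_class rpm sequence`,
#' where `blocks` is a comma-separated list of `start-end` genomic pieces
#' (0-based half-open, ascending) of the spliced ORF and `sequence` is the
#' claimed spliced ORF sequence in transcript orientation.
#'
#' @param path path to the TSV.
#' @return data.frame, one row per ORF.
#' @export
read_orf_table <- function(path) {
  orfs <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
  need <- c("orf_id", "transcript_id", "contig", "strand", "blocks",
            "age_class", "rpm", "sequence")
  if (!all(need %in% names(orfs))) {
    stop("ORF table must have columns: ", paste(need, collapse = " "))
  }
  orfs$rpm <- as.numeric(orfs$rpm)
  bad_age <- !orfs$age_class %in% age_classes()
  if (any(bad_age)) {
    stop("unknown age class: ", paste(unique(orfs$age_class[bad_age]),
                                      collapse = ", "))
  }
  orfs
}

#' @rdname read_orf_table
#' @param orfs ORF data.frame.
#' @export
write_orf_table <- function(orfs, path) {
  cols <- c("orf_id", "transcript_id", "contig", "strand", "blocks",
            "age_class", "rpm", "sequence")
  out <- orfs[, cols]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(lapply(out, as.character), list(sep = "\t"))),
             con, sep = "\n")
  invisible(path)
}

#' The six proto-gene age classes
#'
#' `I0` (lineage-specific) through `I5` (oldest stratum, ~90 Mya).
#' @return character vector of the six labels in age order.
#' @export
age_classes <- function() paste0("I", 0:5)

#' Positions labels in precedence order
#' @return `c("exonic", "intronic", "intergenic")`.
#' @export
position_labels <- function() c("exonic", "intronic", "intergenic")

# "a-b,c-d" -> integer matrix with columns start, end (0-based half-open)
parse_blocks <- function(blocks) {
  parts <- strsplit(blocks, ",", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
  colnames(m) <- c("start", "end")
  if (any(m[, "end"] <= m[, "start"]) || any(m[, "start"] < 0)) {
    stop("malformed ORF blocks: ", blocks)
  }
  m[order(m[, "start"]), , drop = FALSE]
}

#' Validate an ORF against the genome
#'
#' Re-extracts the spliced, strand-corrected ORF sequence from the genome
#' and compares it with the claimed sequence. A disagreement (including any
#' `N`, which never matches, and intervals outside the contig) flags a
#' mapping artifact; an ORF whose first codon is not `ATG` or whose last
#' codon is not a stop is flagged as beginning/ending with an unusual
#' codon; everything else is valid.
#'
#' @param orfs ORF data.frame (see [read_orf_table()]).
#' @param genome named `DNAStringSet` from [load_genome()].
#' @return character vector (one of `"valid"`, `"mapping_artifact"`,
#'   `"unusual_codon"`) aligned with the rows of `orfs`.
#' @export
validate_orf <- function(orfs, genome) {
  vapply(seq_len(nrow(orfs)), function(i) {
    claimed <- toupper(orfs$sequence[i])
    contig <- orfs$contig[i]
    if (!contig %in% names(genome)) {
      return("mapping_artifact")
    }
    blocks <- parse_blocks(orfs$blocks[i])
    clen <- length(genome[[contig]])
    if (any(blocks[, "start"] < 0) || any(blocks[, "end"] > clen)) {
      return("mapping_artifact")
    }
    pieces <- vapply(seq_len(nrow(blocks)), function(k) {
      genome_subseq(genome, contig, blocks[k, "start"], blocks[k, "end"])
    }, character(1))
    extracted <- paste(pieces, collapse = "")
    if (identical(orfs$strand[i], "-")) {
      extracted <- revcomp(extracted)
    }
    if (grepl("N", extracted, fixed = TRUE) || !identical(extracted, claimed)) {
      return("mapping_artifact")
    }
    n <- nchar(claimed)
    if (n %% 3L != 0L || n < 6L) {
      return("unusual_codon")
    }
    first <- substr(claimed, 1L, 3L)
    last <- substr(claimed, n - 2L, n)
    if (first != "ATG" || !last %in% c("TAA", "TAG", "TGA")) {
      return("unusual_codon")
    }
    "valid"
  }, character(1))
}

#' Filter proto-genes by expression strength
#'
#' Retains ORFs with `rpm` strictly greater than the threshold (reads per
#' million mapped reads; default threshold 0.5, so an ORF at exactly 0.5
#' is removed).
#'
#' @param orfs ORF data.frame with an `rpm` column.
#' @param threshold RPM threshold (default 0.5).
#' @return The retained rows of `orfs`.
#' @export
filter_expression <- function(orfs, threshold = 0.5) {
  if (nrow(orfs) == 0L) {
    return(orfs)
  }
  if (is.null(orfs$rpm) || anyNA(orfs$rpm)) {
    stop("every ORF must carry an rpm value")
  }
  out <- orfs[orfs$rpm > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify proto-genes by genomic position
#'
#' Labels each ORF `exonic` if at least 1 bp of its genomic blocks overlaps
#' an exon of an established protein-coding gene, else `intronic` if it
#' overlaps an established intron, else `intergenic` (precedence
#' exonic > intronic > intergenic). Overlap is strand-agnostic: emergence
#' on the antisense strand of an exon still counts as overprinting. ORFs on
#' contigs absent from the annotation are labelled `intergenic` with a
#' warning.
#'
#' @param orfs ORF data.frame.
#' @param aset [annotation_set()]; only `source == "established"`,
#'   protein-coding transcripts enter the index.
#' @return `orfs` with a `position` column added.
#' @export
classify_genomic_position <- function(orfs, aset) {
  if (nrow(orfs) == 0L) {
    orfs$position <- character(0)
    return(orfs)
  }
  exon_gr <- .exon_granges(aset, source = "established",
                           biotype = "protein_coding")
  intron_gr <- .intron_granges(aset, source = "established",
                               biotype = "protein_coding")
  known_contigs <- unique(aset$transcripts$contig)
  blocks <- lapply(orfs$blocks, parse_blocks)
  nb <- vapply(blocks, nrow, integer(1))
  bgr <- GenomicRanges::GRanges(
    seqnames = rep(orfs$contig, nb),
    ranges = IRanges::IRanges(
      start = unlist(lapply(blocks, function(b) b[, "start"])) + 1L,
      end = unlist(lapply(blocks, function(b) b[, "end"]))
    )
  )
  orf_of_block <- rep(seq_len(nrow(orfs)), nb)
  hit_exon <- rep(FALSE, nrow(orfs))
  hit_intron <- rep(FALSE, nrow(orfs))
  if (length(exon_gr) > 0L) {
    ov <- GenomicRanges::findOverlaps(bgr, exon_gr, minoverlap = 1L)
    hit_exon[unique(orf_of_block[S4Vectors::queryHits(ov)])] <- TRUE
  }
  if (length(intron_gr) > 0L) {
    ov <- GenomicRanges::findOverlaps(bgr, intron_gr, minoverlap = 1L)
    hit_intron[unique(orf_of_block[S4Vectors::queryHits(ov)])] <- TRUE
  }
  off_contig <- !orfs$contig %in% known_contigs
  if (any(off_contig)) {
    warning(sum(off_contig),
            " ORF(s) on contigs absent from the annotation -> intergenic")
  }
  position <- ifelse(hit_exon, "exonic",
                     ifelse(hit_intron, "intronic", "intergenic"))
  position[off_contig] <- "intergenic"
  orfs$position <- position
  orfs
}
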