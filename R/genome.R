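#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA genome into a named `DNAStringSet`. Sequences are
#' uppercased and any character outside `A`, `C`, `G`, `T`, `N` is mapped to
#' `N`. Record ids are taken as the first whitespace-delimited token of the
#' FASTA header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet-class], one entry per contig.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA: ", path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  # uppercase + collapse the IUPAC ambiguity codes to N
  chr <- toupper(as.character(seqs))
  chr <- gsub("[^ACGTN]", "N", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Write a genome to FASTA
#'
#' Deterministic FASTA writer (60-column wrapping) used by the synthetic
#' generator so that identical inputs produce byte-identical files.
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  seqs <- as.character(genome)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (id in names(seqs)) {
    s <- seqs[[id]]
    lines <- substring(s, seq(1L, nchar(s), 60L),
                       pmin(seq(1L, nchar(s), 60L) + 59L, nchar(s)))
    writeLines(c(paste0(">", id), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Extract a genomic interval
#'
#' Interval lookup in the package's internal convention: 0-based, half-open
#' `[start, end)`. For `strand == "-"` the reverse complement is returned.
#'
#' @param genome named `DNAStringSet`.
#' @param contig contig id.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A single character string of length `end - start`.
#' @export
genome_subseq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) {
    stop("contig not in genome: ", contig)
  }
  if (start < 0 || end <= start || end > length(genome[[contig]])) {
    stop("interval [", start, ",", end, ") outside contig ", contig)
  }
  s <- Biostrings::subseq(genome[[contig]], start + 1L, end)
  if (identical(strand, "-")) {
    s <- Biostrings::reverseComplement(s)
  }
  as.character(s)
}

#' Reverse complement of a DNA string
#' @param x character scalar (DNA).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC fraction of a sequence
#'
#' `(#G + #C) / length`; `N` (and `U`-free ambiguity) characters are
#' excluded from the denominator. Returns `NA` for an empty sequence or a
#' sequence of only `N`s.
#'
#' @param seq character scalar, DNA or RNA.
#' @return numeric fraction in `[0, 1]`, or `NA_real_`.
#' @export
gc_content <- function(seq) {
  if (is.na(seq) || nchar(seq) == 0L) {
    return(NA_real_)
  }
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  informative <- v %in% c("A", "C", "G", "T", "U")
  if (!any(informative)) {
    return(NA_real_)
  }
  sum(v == "G" | v == "C") / sum(informative)
}
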