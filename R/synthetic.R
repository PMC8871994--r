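#' Specification for a synthetic proto-gene dataset
#'
#' Bundles every tunable of the seeded genome/annotation/proto-gene
#' generator. The defaults encode the study conditions the pipeline is
#' validated under: intron-presence probabilities rising with age class
#' within each genomic position, a 41% recycled fraction among introns of
#' intergenic proto-genes mutated at 10% per base, single-exon-ORF
#' fractions falling with age, 5' UTRs that are longer in the youngest
#' strata, higher UTR GC for established genes than proto-genes (and for
#' exonic proto-genes than intronic/intergenic ones), and promoter-motif
#' planting enriched upstream of established genes and exonic proto-genes
#' versus enhancer-motif planting upstream of intronic/intergenic ones.
#'
#' @param seed master seed; every component stream is derived from it.
#' @param n_contigs,contig_length genome shape.
#' @param background_gc background GC fraction, in (0,1).
#' @param established,noncoding,proto,motifs component settings; see the
#'   defaults in the function body. Any sub-field can be overridden by
#'   passing a partial list.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_contigs = 4L,
                           contig_length = 700000L,
                           background_gc = 0.41,
                           established = list(),
                           noncoding = list(),
                           proto = list(),
                           motifs = list()) {
  if (background_gc <= 0 || background_gc >= 1) {
    stop("background_gc must be in (0,1)")
  }
  est <- utils::modifyList(list(
    n_genes = 130L,
    n_exons = c(5L, 7L),
    min_exon = 60L,
    cds_codons = c(80L, 260L),
    host_introns = 4L,              # per gene, long enough to host a proto
    host_intron_length = c(1500L, 2100L),
    intron_length = c(200L, 400L),
    utr5_length = c(40L, 100L),
    utr5_gc = 0.5926,
    utr3_length = c(60L, 150L),
    utr3_gc = 0.4520,
    canonical_splice = TRUE,
    margin = 460L
  ), established)
  nc <- utils::modifyList(list(
    n_pseudogenes = 40L,
    n_lncrnas = 40L,
    length = c(400L, 1200L),
    lnc_length = c(60L, 500L),   # overlaps the 5' UTR size range
    margin = 460L
  ), noncoding)
  pr <- utils::modifyList(list(
    n_per_stratum = 40L,
    orf_codons = c(40L, 120L),
    intron_presence = list(
      exonic = seq(0.75, 1.00, length.out = 6),
      intronic = seq(0.10, 0.30, length.out = 6),
      intergenic = seq(0.026, 0.30, length.out = 6)
    ),
    extra_intron_rate = list(exonic = 0.5, intronic = 0.06, intergenic = 0.25),
    single_exon_orf = list(
      exonic = seq(0.378, 0.039, length.out = 6),
      intronic = seq(0.735, 0.492, length.out = 6),
      intergenic = seq(0.762, 0.181, length.out = 6)
    ),
    intron_length = c(90L, 180L),
    recycled_fraction = 0.41,
    recycle_mutation_rate = 0.10,
    utr5_length_young = c(90L, 150L),
    utr5_length_old = c(30L, 80L),
    utr5_gc = list(exonic = 0.58, intronic = 0.51, intergenic = 0.51),
    utr3_length = c(60L, 150L),
    utr3_gc = 0.4719,
    rpm_meanlog = 0.5,
    rpm_sdlog = 1.0,
    margin = 250L
  ), proto)
  mo <- utils::modifyList(list(
    pfm_file = NULL,                 # default: bundled synthetic PFMs
    promoter_ids_prefix = "SYNPRM",
    enhancer_ids_prefix = "SYNENH",
    upstream_rates = list(           # per-window planting prob per motif
      established = c(promoter = 0.60, enhancer = 0.10),
      exonic = c(promoter = 0.45, enhancer = 0.15),
      intronic = c(promoter = 0.10, enhancer = 0.45),
      intergenic = c(promoter = 0.10, enhancer = 0.45),
      pseudogene = c(promoter = 0.08, enhancer = 0.08),
      lncrna = c(promoter = 0.08, enhancer = 0.08)
    ),
    tata_core_rates = c(established = 0.50, exonic = 0.20,
                        intronic = 0.35, intergenic = 0.35),
    tata_offset = -30L,              # position of the TATA box before the TSS
    minus_strand_prob = 0.3
  ), motifs)
  for (p in unlist(pr$intron_presence)) {
    if (p < 0 || p > 1) stop("intron presence probabilities must be in [0,1]")
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 background_gc = background_gc, established = est,
                 noncoding = nc, proto = pr, motifs = mo),
            class = "synthetic_spec")
}

# component RNG streams, all derived from the master seed
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Random DNA at a given GC fraction
#' @param n length.
#' @param gc GC fraction in (0,1).
#' @return character scalar. Uses the current RNG stream.
#' @export
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# sense codons (no stops); roughly uniform usage
.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

#' Random ORF sequence
#' @param n_codons number of internal codons (between ATG and the stop).
#' @return `ATG` + sense codons + a random stop codon.
#' @export
random_orf <- function(n_codons) {
  paste0("ATG",
         paste(sample(.sense_codons(), n_codons, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

#' Mutate a sequence
#'
#' Each position (outside `protect_ends` bases at both ends) is replaced by
#' a different base with probability `rate`. Substitutions only by default,
#' which keeps identity and coverage of mutated copies analytically
#' predictable; a small indel mode (single-base insertions/deletions at
#' `indel_rate` per position) is available behind the flag.
#'
#' @param seq DNA string.
#' @param rate per-base substitution probability.
#' @param protect_ends number of bases at each end left untouched.
#' @param indel_rate per-position probability of a single-base insertion or
#'   deletion (default 0: substitutions only).
#' @return mutated string.
#' @export
mutate_sequence <- function(seq, rate, protect_ends = 0L, indel_rate = 0) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  idx <- which(stats::runif(n) < rate)
  idx <- idx[idx > protect_ends & idx <= n - protect_ends]
  for (i in idx) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  if (indel_rate > 0) {
    keep <- protect_ends > 0 &
      (seq_len(n) <= protect_ends | seq_len(n) > n - protect_ends)
    hit <- stats::runif(n) < indel_rate & !keep
    out <- character(0)
    for (i in seq_len(n)) {
      if (hit[i] && stats::runif(1) < 0.5) next # deletion
      out <- c(out, v[i])
      if (hit[i] && stats::runif(1) < 0.5) {    # insertion after i
        out <- c(out, sample(c("A", "C", "G", "T"), 1L))
      }
    }
    v <- out
  }
  paste(v, collapse = "")
}

#' Generate the background genome
#'
#' iid nucleotide draws at the configured GC fraction, one stream derived
#' from the master seed; identical spec + seed give identical sequence.
#'
#' @param spec a [synthetic_spec()].
#' @return named `DNAStringSet`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$seed, "genome"))
  seqs <- vapply(seq_len(spec$n_contigs), function(i) {
    random_dna(spec$contig_length, spec$background_gc)
  }, character(1))
  names(seqs) <- paste0("ctg", seq_len(spec$n_contigs))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(seqs)
  out
}

# ---- mutable genome (raw vectors in an environment) ------------------------

.genome_env <- function(genome) {
  env <- new.env(parent = emptyenv())
  for (id in names(genome)) {
    assign(id, charToRaw(as.character(genome[[id]])), envir = env)
  }
  attr(env, "contigs") <- names(genome)
  env
}

.genome_fix <- function(env) {
  ids <- attr(env, "contigs")
  seqs <- vapply(ids, function(id) rawToChar(get(id, envir = env)),
                 character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

# write `s` at 0-based half-open [start, start+nchar(s)) on the plus strand
.genome_write <- function(env, contig, start, s) {
  v <- get(contig, envir = env)
  stopifnot(start >= 0, start + nchar(s) <= length(v))
  v[(start + 1L):(start + nchar(s))] <- charToRaw(s)
  assign(contig, v, envir = env)
  invisible(NULL)
}

# ---- transcript layout -----------------------------------------------------

# Layout of an unspliced transcript: exon/intron lengths in transcript
# order, genomic anchor g0 (leftmost base), strand. Provides genomic exon
# and intron tables (ascending) and the mapping of spliced intervals to
# genomic blocks. 0-based half-open throughout.
tx_layout <- function(exon_lens, intron_lens, g0, strand) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1L)
  n <- length(exon_lens)
  L <- sum(exon_lens) + sum(intron_lens)
  un_off <- cumsum(c(0L, utils::head(exon_lens, -1L) + intron_lens))
  sp_off <- cumsum(c(0L, utils::head(exon_lens, -1L)))
  g_of_un <- function(t) if (strand == "+") g0 + t else g0 + L - 1L - t
  exons_g <- data.frame(
    start = if (strand == "+") g0 + un_off else g0 + L - un_off - exon_lens,
    end = if (strand == "+") g0 + un_off + exon_lens else g0 + L - un_off
  )
  exons_g <- exons_g[order(exons_g$start), , drop = FALSE]
  introns_g <- if (n > 1L) {
    ist <- un_off[-1L] - intron_lens
    data.frame(
      start = if (strand == "+") g0 + ist else g0 + L - ist - intron_lens,
      end = if (strand == "+") g0 + ist + intron_lens else g0 + L - ist
    )
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  introns_g <- introns_g[order(introns_g$start), , drop = FALSE]
  map_spliced <- function(a, b) {
    # spliced [a, b) -> ascending genomic blocks
    out <- NULL
    for (k in seq_len(n)) {
      sa <- max(a, sp_off[k])
      sb <- min(b, sp_off[k] + exon_lens[k])
      if (sa < sb) {
        ua <- un_off[k] + (sa - sp_off[k])
        ub <- ua + (sb - sa)
        blk <- if (strand == "+") {
          c(g0 + ua, g0 + ub)
        } else {
          c(g0 + L - ub, g0 + L - ua)
        }
        out <- rbind(out, blk)
      }
    }
    out <- out[order(out[, 1]), , drop = FALSE]
    colnames(out) <- c("start", "end")
    out
  }
  list(L = L, exons = exons_g, introns = introns_g,
       tss = if (strand == "+") g0 else g0 + L - 1L,
       map_spliced = map_spliced, g_of_un = g_of_un)
}

# interleave exon pieces of the spliced sequence with intron sequences
.unspliced_seq <- function(spliced, exon_lens, intron_seqs) {
  sp_off <- cumsum(c(0L, utils::head(exon_lens, -1L)))
  pieces <- character(0)
  for (k in seq_along(exon_lens)) {
    pieces <- c(pieces,
                substr(spliced, sp_off[k] + 1L, sp_off[k] + exon_lens[k]))
    if (k < length(exon_lens)) pieces <- c(pieces, intron_seqs[k])
  }
  paste(pieces, collapse = "")
}

# ---- interval registry -----------------------------------------------------

.registry <- function() {
  env <- new.env(parent = emptyenv())
  env$tab <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), kind = character(0),
                        stringsAsFactors = FALSE)
  env
}

.reg_add <- function(reg, contig, start, end, kind = "x") {
  reg$tab <- rbind(reg$tab, data.frame(contig = contig, start = start,
                                       end = end, kind = kind,
                                       stringsAsFactors = FALSE))
  invisible(NULL)
}

.reg_free <- function(reg, contig, start, end) {
  t <- reg$tab
  !any(t$contig == contig & t$start < end & t$end > start)
}

# ---- established genes and non-coding loci ---------------------------------

#' Plant established genes (and non-coding loci) into a genome
#'
#' Writes multi-exon protein-coding gene models into the background genome:
#' UTR sequence at the configured GC, CDS as ATG + sense codons + stop,
#' introns at background GC with canonical `GT...AG` ends when
#' `canonical_splice` is set. A configurable number of introns per gene are
#' "host" introns long enough to later host an intronic proto-gene. Also
#' places single/two-exon pseudogene and lncRNA loci (annotation only).
#' Gene loci are non-overlapping and keep a margin wide enough that
#' upstream windows never collide.
#'
#' @param genome `DNAStringSet` from [generate_genome()].
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (modified), `annotation`
#'   ([annotation_set()]), `utr_blocks` (genomic UTR intervals),
#'   `protected` (intervals later plantings must not overwrite) and
#'   `truth` (per-gene structural record).
#' @export
plant_established_genes <- function(genome, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  est <- spec$established
  set.seed(derive_seed(spec$seed, "established"))
  env <- .genome_env(genome)
  contigs <- names(genome)
  clen <- spec$contig_length
  reg <- .registry()       # gene/locus spans incl. margins
  protected <- .registry() # regions later plantings must not overwrite
  tx_rows <- NULL; ex_rows <- NULL; cds_rows <- NULL
  utr_blocks <- NULL
  truth <- list()
  cursor <- stats::setNames(rep(400L, length(contigs)), contigs)
  ci <- 1L
  rint <- function(rg) if (rg[1] >= rg[2]) rg[1] else sample(rg[1]:rg[2], 1L)
  for (g in seq_len(est$n_genes)) {
    gid <- sprintf("EG%03d", g)
    tid <- paste0(gid, ".t1")
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    u5 <- rint(est$utr5_length); u3 <- rint(est$utr3_length)
    cds <- random_orf(rint(est$cds_codons))
    spliced <- paste0(random_dna(u5, est$utr5_gc), cds,
                      random_dna(u3, est$utr3_gc))
    S <- nchar(spliced)
    n_ex <- rint(est$n_exons)
    n_ex <- max(2L, min(n_ex, S %/% est$min_exon)) # keep the partition feasible
    # partition the spliced length into n_ex exon lengths >= min_exon
    # (min_exon each plus a random composition of the slack)
    slack <- S - n_ex * est$min_exon
    cuts <- sort(sample.int(slack + 1L, n_ex - 1L, replace = TRUE) - 1L)
    lens <- est$min_exon + diff(c(0L, cuts, slack))
    n_int <- n_ex - 1L
    ilens <- integer(n_int)
    host <- seq_len(min(est$host_introns, n_int))
    for (k in seq_len(n_int)) {
      ilens[k] <- if (k %in% host) rint(est$host_intron_length)
                  else rint(est$intron_length)
    }
    iseqs <- vapply(ilens, function(l) {
      s <- random_dna(l, spec$background_gc)
      if (est$canonical_splice) {
        substr(s, 1L, 2L) <- "GT"
        substr(s, l - 1L, l) <- "AG"
      }
      s
    }, character(1))
    # splice-site convention: intron ends are in transcript orientation
    unspliced_t <- .unspliced_seq(spliced, lens, iseqs)
    L <- nchar(unspliced_t)
    # find a slot
    placed <- FALSE
    for (try in seq_len(2L * length(contigs))) {
      contig <- contigs[ci]; ci <- ci %% length(contigs) + 1L
      g0 <- cursor[contig] + sample(0:200, 1L)
      if (g0 + L + est$margin < clen) {
        if (.reg_free(reg, contig, g0 - est$margin, g0 + L + est$margin)) {
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      stop("genome too small to place established gene ", gid)
    }
    cursor[contig] <- g0 + L + 2L * est$margin
    .reg_add(reg, contig, g0 - est$margin, g0 + L + est$margin, "gene")
    lay <- tx_layout(lens, ilens, g0, strand)
    wseq <- if (strand == "+") unspliced_t else revcomp(unspliced_t)
    .genome_write(env, contig, g0, wseq)
    # record annotation rows
    tx_rows <- rbind(tx_rows, data.frame(
      transcript_id = tid, gene_id = gid, contig = contig, strand = strand,
      source = "established", biotype = "protein_coding",
      stringsAsFactors = FALSE))
    ex_rows <- rbind(ex_rows, data.frame(
      transcript_id = tid, start = lay$exons$start, end = lay$exons$end,
      stringsAsFactors = FALSE))
    cds_blocks <- lay$map_spliced(u5, S - u3)
    cds_rows <- rbind(cds_rows, data.frame(
      transcript_id = tid, start = cds_blocks[, "start"],
      end = cds_blocks[, "end"], stringsAsFactors = FALSE))
    # protect UTR genomic blocks and the upstream window
    for (bl in list(lay$map_spliced(0L, u5), lay$map_spliced(S - u3, S))) {
      for (r in seq_len(nrow(bl))) {
        .reg_add(protected, contig, bl[r, "start"], bl[r, "end"], "utr")
        utr_blocks <- rbind(utr_blocks, data.frame(
          transcript_id = tid, start = bl[r, "start"], end = bl[r, "end"],
          stringsAsFactors = FALSE))
      }
    }
    win <- if (strand == "+") c(lay$tss - 210L, lay$tss)
           else c(lay$tss + 1L, lay$tss + 211L)
    .reg_add(protected, contig, win[1], win[2], "upstream")
    truth[[tid]] <- list(gene_id = gid, contig = contig, strand = strand,
                         n_introns = n_int,
                         host_introns = lay$introns[host, , drop = FALSE])
  }
  # non-coding loci: annotation-only (background sequence), 1-2 exons
  nc <- spec$noncoding
  nc_counts <- c(pseudogene = nc$n_pseudogenes, lncRNA = nc$n_lncrnas)
  for (bt in names(nc_counts)) {
    for (g in seq_len(nc_counts[[bt]])) {
      gid <- sprintf("%s%03d", ifelse(bt == "pseudogene", "PG", "NC"), g)
      tid <- paste0(gid, ".t1")
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      L <- rint(if (bt == "lncRNA") nc$lnc_length else nc$length)
      placed <- FALSE
      for (try in seq_len(2L * length(contigs))) {
        contig <- contigs[ci]; ci <- ci %% length(contigs) + 1L
        g0 <- cursor[contig] + sample(0:200, 1L)
        if (g0 + L + nc$margin < clen &&
            .reg_free(reg, contig, g0 - nc$margin, g0 + L + nc$margin)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("genome too small to place non-coding locus ", gid)
      cursor[contig] <- g0 + L + 2L * nc$margin
      .reg_add(reg, contig, g0 - nc$margin, g0 + L + nc$margin, "nc")
      n_ex <- sample(1:2, 1L)
      if (n_ex == 1L) {
        exs <- data.frame(start = g0, end = g0 + L)
      } else {
        half <- L %/% 3L
        exs <- data.frame(start = c(g0, g0 + 2L * half),
                          end = c(g0 + half, g0 + L))
      }
      tx_rows <- rbind(tx_rows, data.frame(
        transcript_id = tid, gene_id = gid, contig = contig,
        strand = strand, source = "established", biotype = bt,
        stringsAsFactors = FALSE))
      ex_rows <- rbind(ex_rows, data.frame(
        transcript_id = tid, start = exs$start, end = exs$end,
        stringsAsFactors = FALSE))
      tss <- if (strand == "+") g0 else g0 + L - 1L
      win <- if (strand == "+") c(tss - 210L, tss) else c(tss + 1L, tss + 211L)
      .reg_add(protected, contig, win[1], win[2], "upstream")
      .reg_add(protected, contig, g0, g0 + L, "nc_span")
    }
  }
  aset <- annotation_set(tx_rows, ex_rows, cds = cds_rows)
  list(genome = .genome_fix(env), annotation = aset,
       utr_blocks = utr_blocks, protected = protected$tab,
       gene_spans = reg$tab[reg$tab$kind == "gene", , drop = FALSE],
       truth = truth)
}
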