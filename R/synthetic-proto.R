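# Proto-gene planting and motif planting for the synthetic generator.
# Strata are planted intergenic -> intronic -> exonic so that source
# regions of recycled introns can be protected before anything else is
# allowed to overwrite them.

.genome_read <- function(env, contig, start, end) {
  v <- get(contig, envir = env)
  rawToChar(v[(start + 1L):end])
}

#' Plant proto-genes into an annotated genome
#'
#' Places one proto-gene per requested (position x age) slot: the ORF is
#' `ATG` + random sense codons + stop, UTRs are regenerated at the
#' stratum's GC target, introns are inserted inside the ORF (InORF) or
#' within the UTRs (OutORF, leaving the ORF on a single exon), and introns
#' of intergenic proto-genes are, at the configured fraction, mutated
#' copies of windows of established introns (substitutions only, splice
#' dinucleotides pinned). Exonic proto-genes anchor their ORF inside an
#' established exon, intronic ones sit wholly inside a long "host" intron,
#' intergenic ones in feature-free sequence. Every planted fact is
#' recorded in the returned ground truth.
#'
#' @param genome `DNAStringSet` (after [plant_established_genes()]).
#' @param established the list returned by [plant_established_genes()].
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (modified), `annotation` (proto transcripts
#'   only), `orfs` (ORF table data.frame), `truth` (per-ORF ground truth),
#'   `proto_regions` (reserved intervals incl. window space).
#' @export
plant_proto_genes <- function(genome, established, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pr <- spec$proto
  set.seed(derive_seed(spec$seed, "proto"))
  env <- .genome_env(genome)
  clen <- spec$contig_length
  contigs <- names(genome)
  aset_est <- established$annotation
  protected <- .registry()
  protected$tab <- established$protected
  gene_spans <- established$gene_spans
  proto_reg <- .registry()
  rint <- function(rg) if (rg[1] >= rg[2]) rg[1] else sample(rg[1]:rg[2], 1L)

  # candidate anchors
  tx_pc <- aset_est$transcripts[aset_est$transcripts$biotype == "protein_coding", ]
  exons_pc <- aset_est$exons[aset_est$exons$transcript_id %in% tx_pc$transcript_id, ]
  exons_pc$contig <- tx_pc$contig[match(exons_pc$transcript_id, tx_pc$transcript_id)]
  exons_pc <- exons_pc[exons_pc$end - exons_pc$start >= 40L, , drop = FALSE]
  host_tab <- NULL
  for (tid in names(established$truth)) {
    hi <- established$truth[[tid]]$host_introns
    if (!is.null(hi) && nrow(hi) > 0L) {
      host_tab <- rbind(host_tab, data.frame(
        transcript_id = tid,
        contig = established$truth[[tid]]$contig,
        start = hi$start, end = hi$end, stringsAsFactors = FALSE))
    }
  }
  introns_pc <- all_introns(aset_est, source = "established",
                            biotype = "protein_coding")
  introns_pc$intron_id <- paste0(introns_pc$transcript_id, "_i",
                                 introns_pc$ordinal)
  is_host <- paste0(introns_pc$contig, ":", introns_pc$start) %in%
    paste0(host_tab$contig, ":", host_tab$start)
  parents <- introns_pc[!is_host & (introns_pc$end - introns_pc$start) >=
                          (pr$intron_length[1] + 10L), , drop = FALSE]
  if (nrow(parents) == 0L) stop("no candidate parent introns for recycling")

  ages <- age_classes()
  tx_rows <- NULL; ex_rows <- NULL; orf_rows <- NULL
  truth <- list()
  k <- 0L
  for (pos in c("intergenic", "intronic", "exonic")) {
    for (ai in seq_along(ages)) {
      a <- ai - 1L
      for (rep_i in seq_len(pr$n_per_stratum)) {
        k <- k + 1L
        tid <- sprintf("PTG%04d.t1", k)
        oid <- sprintf("PTG%04d.orf", k)
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        # 5' UTR length interpolates from the young to the old range
        u5rg <- round(pr$utr5_length_young +
                        (pr$utr5_length_old - pr$utr5_length_young) * a / 5)
        u5 <- rint(as.integer(u5rg))
        u3 <- rint(pr$utr3_length)
        orf <- random_orf(rint(pr$orf_codons))
        orflen <- nchar(orf)
        spliced <- paste0(random_dna(u5, pr$utr5_gc[[pos]]), orf,
                          random_dna(u3, pr$utr3_gc))
        S <- nchar(spliced)
        has_introns <- stats::runif(1) < pr$intron_presence[[pos]][ai]
        n_int <- 0L
        out_orf <- NA
        if (has_introns) {
          n_int <- min(1L + stats::rpois(1, pr$extra_intron_rate[[pos]] * a), 4L)
          out_orf <- stats::runif(1) < pr$single_exon_orf[[pos]][ai]
        }
        pts <- integer(0)
        if (n_int > 0L) {
          if (isTRUE(out_orf)) {
            cand <- c(seq(2L, max(2L, u5 - 1L)),
                      seq(min(u5 + orflen + 1L, S - 2L), S - 2L))
            cand <- unique(cand[cand >= 2L & cand <= S - 2L &
                                  (cand <= u5 - 1L | cand >= u5 + orflen + 1L)])
          } else {
            cand <- seq(u5 + 3L, u5 + orflen - 3L)
          }
          n_int <- min(n_int, length(cand))
          pts <- sort(sample(cand, n_int))
        }
        exon_lens <- diff(c(0L, pts, S))
        # intron sequences (+ recycling for the intergenic stratum)
        iseqs <- character(n_int)
        recycled_parent <- rep(NA_character_, n_int)
        if (n_int > 0L) {
          for (ii in seq_len(n_int)) {
            l <- rint(pr$intron_length)
            if (pos == "intergenic" &&
                stats::runif(1) < pr$recycled_fraction) {
              p <- parents[sample(nrow(parents), 1L), ]
              plen <- p$end - p$start
              off <- if (plen > l) sample(0:(plen - l), 1L) else 0L
              l2 <- min(l, plen)
              src <- .genome_read(env, p$contig, p$start + off,
                                  p$start + off + l2)
              s <- mutate_sequence(src, pr$recycle_mutation_rate,
                                   protect_ends = 2L)
              recycled_parent[ii] <- p$intron_id
              # freeze the source region so later plantings keep it intact
              .reg_add(protected, p$contig, p$start, p$end, "recycle_parent")
            } else {
              s <- random_dna(l, spec$background_gc)
            }
            substr(s, 1L, 2L) <- "GT"
            substr(s, nchar(s) - 1L, nchar(s)) <- "AG"
            iseqs[ii] <- s
          }
        }
        unspliced_t <- .unspliced_seq(spliced, exon_lens, iseqs)
        L <- nchar(unspliced_t)
        ilens <- nchar(iseqs)
        if (n_int == 0L) ilens <- integer(0)
        rel <- tx_layout(exon_lens, as.integer(ilens), 0L, strand)
        orf_rel <- rel$map_spliced(u5, u5 + orflen)
        rmin <- min(orf_rel[, "start"])
        # placement
        placed <- FALSE
        g0 <- NA_integer_; contig <- NA_character_
        wlo <- function(g) if (strand == "+") g - 215L else g - 10L
        whi <- function(g) if (strand == "+") g + L + 10L else g + L + 215L
        if (pos == "exonic") {
          for (try in seq_len(800L)) {
            e <- exons_pc[sample(nrow(exons_pc), 1L), ]
            anchor <- sample(e$start:(e$end - 1L), 1L)
            g0c <- anchor - rmin
            lo <- wlo(g0c); hi <- whi(g0c)
            if (g0c < 300L || g0c + L > clen - 300L) next
            if (.reg_free(protected, e$contig, lo, hi) &&
                .reg_free(proto_reg, e$contig, lo, hi)) {
              g0 <- g0c; contig <- e$contig; placed <- TRUE
              break
            }
          }
        } else if (pos == "intronic") {
          cand_hosts <- host_tab[host_tab$end - host_tab$start >= L + 20L, ,
                                 drop = FALSE]
          for (try in seq_len(800L)) {
            h <- cand_hosts[sample(nrow(cand_hosts), 1L), ]
            g0c <- h$start + sample(10:(h$end - h$start - L - 10L), 1L)
            lo <- wlo(g0c); hi <- whi(g0c)
            if (.reg_free(protected, h$contig, lo, hi) &&
                .reg_free(proto_reg, h$contig, lo, hi)) {
              g0 <- g0c; contig <- h$contig; placed <- TRUE
              break
            }
          }
        } else { # intergenic
          for (try in seq_len(600L)) {
            ctg <- sample(contigs, 1L)
            g0c <- sample(300:(clen - L - 300L), 1L)
            lo <- wlo(g0c); hi <- whi(g0c)
            free_genes <- !any(gene_spans$contig == ctg &
                                 gene_spans$start < hi & gene_spans$end > lo)
            if (free_genes &&
                .reg_free(protected, ctg, lo, hi) &&
                .reg_free(proto_reg, ctg, lo, hi)) {
              g0 <- g0c; contig <- ctg; placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          stop("no placement found for stratum (", pos, ", ", ages[ai], ")")
        }
        .reg_add(proto_reg, contig, wlo(g0), whi(g0), pos)
        lay <- tx_layout(exon_lens, as.integer(ilens), g0, strand)
        wseq <- if (strand == "+") unspliced_t else revcomp(unspliced_t)
        .genome_write(env, contig, g0, wseq)
        orf_blocks <- lay$map_spliced(u5, u5 + orflen)
        tx_rows <- rbind(tx_rows, data.frame(
          transcript_id = tid, gene_id = sub("\\.t1$", "", tid),
          contig = contig, strand = strand, source = "proto",
          biotype = "proto", stringsAsFactors = FALSE))
        ex_rows <- rbind(ex_rows, data.frame(
          transcript_id = tid, start = lay$exons$start,
          end = lay$exons$end, stringsAsFactors = FALSE))
        orf_rows <- rbind(orf_rows, data.frame(
          orf_id = oid, transcript_id = tid, contig = contig,
          strand = strand,
          blocks = paste(sprintf("%d-%d", orf_blocks[, "start"],
                                 orf_blocks[, "end"]), collapse = ","),
          age_class = ages[ai],
          rpm = round(stats::rlnorm(1, pr$rpm_meanlog, pr$rpm_sdlog), 4),
          sequence = orf, stringsAsFactors = FALSE))
        truth[[oid]] <- list(
          transcript_id = tid, position = pos, age_class = ages[ai],
          strand = strand, contig = contig, tss = lay$tss,
          n_introns = n_int,
          single_exon_orf = if (n_int > 0L) isTRUE(out_orf) else NA,
          # intron-level records in ascending genomic order (the ordinal
          # convention of transcript_introns); construction was in
          # transcript order, which is reversed on the minus strand
          recycled_parent = if (strand == "+") recycled_parent
                            else rev(recycled_parent),
          intron_seqs = if (strand == "+") iseqs else rev(iseqs),
          utr5_length = u5, utr3_length = u3,
          utr5_gc_target = pr$utr5_gc[[pos]],
          intron_lengths = if (strand == "+") as.integer(ilens)
                           else rev(as.integer(ilens)))
      }
    }
  }
  aset_proto <- annotation_set(tx_rows, ex_rows)
  list(genome = .genome_fix(env), annotation = aset_proto, orfs = orf_rows,
       truth = truth, proto_regions = proto_reg$tab)
}

# write a motif occurrence into the genome through window coordinates.
# mode "upstream200": window offsets 0..199 are transcript positions
# -200..-1 relative to the TSS.
.plant_in_window <- function(env, contig, tss, strand, offset, seq_w,
                             window_strand) {
  eff <- if (window_strand == "+") seq_w else revcomp(seq_w)
  lm <- nchar(eff)
  if (strand == "+") {
    gs <- tss - 200L + offset
    .genome_write(env, contig, gs, eff)
    c(gs, gs + lm)
  } else {
    gs <- tss + 200L - offset - lm + 1L
    .genome_write(env, contig, gs, revcomp(eff))
    c(gs, gs + lm)
  }
}

#' Plant motif occurrences upstream of annotated entities
#'
#' Writes motif consensus sequences (highest-count base per column, so a
#' planted occurrence scores the matrix maximum) into the 200-bp upstream
#' windows of established genes, proto-genes (by genomic position),
#' pseudogenes and lncRNAs, at the per-dataset rates of the spec, plus a
#' TATA-box-like core motif at a fixed position before the TSS. Planted
#' occurrences never overlap each other within a window; each one is
#' recorded with its window offset and strand.
#'
#' @param genome `DNAStringSet` after proto-gene planting.
#' @param entities data.frame with columns `id`, `contig`, `tss`, `strand`,
#'   `dataset` (one of `established`, `exonic`, `intronic`, `intergenic`,
#'   `pseudogene`, `lncrna`).
#' @param motifs motif list from [read_jaspar()].
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (modified) and `planted` (data.frame of
#'   occurrences: `id`, `dataset`, `motif_id`, `offset`, `strand`,
#'   `in_core`).
#' @export
plant_motifs <- function(genome, entities, motifs, spec) {
  mo <- spec$motifs
  set.seed(derive_seed(spec$seed, "motifs"))
  env <- .genome_env(genome)
  ids <- vapply(motifs, function(m) m$id, character(1))
  grp <- ifelse(startsWith(ids, mo$promoter_ids_prefix), "promoter",
                ifelse(startsWith(ids, mo$enhancer_ids_prefix), "enhancer",
                       "other"))
  cons <- vapply(motifs, consensus_sequence, character(1))
  tata_idx <- which(grp == "promoter")[1L]
  rec <- list(); ri <- 0L
  for (i in seq_len(nrow(entities))) {
    ent <- entities[i, ]
    rates <- mo$upstream_rates[[ent$dataset]]
    if (is.null(rates)) next
    used <- NULL # window-offset intervals already written
    claim <- function(off, lm) {
      if (!is.null(used) &&
          any(used[, 1] < off + lm & used[, 2] > off)) {
        return(FALSE)
      }
      used <<- rbind(used, c(off, off + lm))
      TRUE
    }
    # fixed-position core TATA box
    tr <- mo$tata_core_rates[ent$dataset]
    if (!is.na(tr) && stats::runif(1) < tr) {
      lm <- nchar(cons[tata_idx])
      off <- 200L + mo$tata_offset # transcript position -30
      if (claim(off, lm)) {
        .plant_in_window(env, ent$contig, ent$tss, ent$strand, off,
                         cons[tata_idx], "+")
        ri <- ri + 1L
        rec[[ri]] <- data.frame(id = ent$id, dataset = ent$dataset,
                                motif_id = ids[tata_idx], offset = off,
                                strand = "+", in_core = TRUE,
                                stringsAsFactors = FALSE)
      }
    }
    for (mi in seq_along(motifs)) {
      if (grp[mi] == "other") next
      if (stats::runif(1) >= rates[[grp[mi]]]) next
      lm <- nchar(cons[mi])
      ws <- if (stats::runif(1) < mo$minus_strand_prob) "-" else "+"
      for (try in seq_len(25L)) {
        off <- sample(0:(200L - lm), 1L)
        if (claim(off, lm)) {
          .plant_in_window(env, ent$contig, ent$tss, ent$strand, off,
                           cons[mi], ws)
          ri <- ri + 1L
          rec[[ri]] <- data.frame(id = ent$id, dataset = ent$dataset,
                                  motif_id = ids[mi], offset = off,
                                  strand = ws, in_core = FALSE,
                                  stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  planted <- if (ri > 0L) {
    do.call(rbind, c(rec, list(make.row.names = FALSE)))
  } else {
    data.frame(id = character(0), dataset = character(0),
               motif_id = character(0), offset = integer(0),
               strand = character(0), in_core = logical(0))
  }
  list(genome = .genome_fix(env), planted = planted)
}

#' Generate a complete synthetic proto-gene dataset
#'
#' Runs the full generator (genome, established genes and non-coding loci,
#' proto-genes, motif planting) and writes the dataset to `dir`:
#' `genome.fa`, `established.gtf`, `proto.gtf`, `orfs.tsv`,
#' `ground_truth.json`. Identical spec + seed produce byte-identical
#' files.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @return list with the in-memory objects: `genome`, `established`
#'   (annotation), `proto` (annotation), `orfs`, `truth` (per-ORF ground
#'   truth), `planted_motifs`, `motifs`, and the written `paths`.
#' @export
simulate_protogene_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  genome <- generate_genome(spec)
  est <- plant_established_genes(genome, spec)
  pro <- plant_proto_genes(est$genome, est, spec)
  pfm <- spec$motifs$pfm_file
  if (is.null(pfm)) {
    pfm <- system.file("extdata", "synthetic_motifs.jaspar",
                       package = "protogenr")
  }
  motifs <- read_jaspar(pfm)
  # window entities
  tss_est <- tss_positions(est$annotation)
  tss_pro <- tss_positions(pro$annotation)
  ds_est <- c(protein_coding = "established", pseudogene = "pseudogene",
              lncRNA = "lncrna")
  pos_of <- vapply(pro$truth, function(t) t$position, character(1))
  tx_of <- vapply(pro$truth, function(t) t$transcript_id, character(1))
  entities <- rbind(
    data.frame(id = tss_est$transcript_id, contig = tss_est$contig,
               tss = tss_est$tss, strand = tss_est$strand,
               dataset = unname(ds_est[tss_est$biotype]),
               stringsAsFactors = FALSE),
    data.frame(id = tss_pro$transcript_id, contig = tss_pro$contig,
               tss = tss_pro$tss, strand = tss_pro$strand,
               dataset = unname(pos_of[match(tss_pro$transcript_id, tx_of)]),
               stringsAsFactors = FALSE)
  )
  pm <- plant_motifs(pro$genome, entities, motifs, spec)
  # per-proto rpm etc. already in orfs
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      established_gtf = file.path(dir, "established.gtf"),
      proto_gtf = file.path(dir, "proto.gtf"),
      orfs = file.path(dir, "orfs.tsv"),
      truth = file.path(dir, "ground_truth.json")
    )
    write_genome(pm$genome, paths$genome)
    write_gtf(est$annotation, paths$established_gtf)
    write_gtf(pro$annotation, paths$proto_gtf)
    write_orf_table(pro$orfs, paths$orfs)
    truth_out <- list(spec_seed = spec$seed, orfs = pro$truth,
                      planted_motifs = pm$planted)
    jsonlite::write_json(truth_out, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(genome = pm$genome, established = est$annotation,
       proto = pro$annotation, orfs = pro$orfs, truth = pro$truth,
       planted_motifs = pm$planted, motifs = motifs,
       utr_blocks = est$utr_blocks, established_truth = est$truth,
       entities = entities, paths = paths, spec = spec)
}
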