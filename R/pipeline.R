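#' Run the full proto-gene characterization pipeline
#'
#' End-to-end analysis over a dataset (typically a
#' [simulate_protogene_dataset()] result): ORF validation against the
#' genome, expression filtering, genomic-position classification, intron
#' structure and recycling search, the six-dataset motif scan with
#' promoter/enhancer partitioning, UTR extraction with GC and
#' fold-ensemble statistics, hydrophobic-cluster analysis, and the
#' assembled stratified report. Deterministic for a fixed dataset and
#' `seed`.
#'
#' @param data list with `genome`, `established` and `proto`
#'   ([annotation_set()]s), `orfs` (ORF table), `motifs` (motif list).
#' @param seed seed for the pipeline's own sampling steps (background
#'   windows, intron subsample, fold subsamples).
#' @param rpm_threshold expression filter (default 0.5, strict).
#' @param similarity stage-2 motif similarity threshold (default 0.80; the
#'   companion run uses 0.95).
#' @param recycle_n intron subsample size for the recycling search.
#' @param n_background number of random background windows per control
#'   dataset.
#' @param fold_per_group cap on folded 5' UTRs per group.
#' @param fold_max_len longest UTR/control folded (longer ones skipped).
#' @return list of class `protogene_run` with all stage outputs and a
#'   `report`.
#' @export
run_pipeline <- function(data, seed = 1L, rpm_threshold = 0.5,
                         similarity = 0.8, recycle_n = 500L,
                         n_background = 250L, fold_per_group = 100L,
                         fold_max_len = 160L) {
  genome <- data$genome
  est <- data$established
  pro <- data$proto
  motifs <- data$motifs

  # --- classification -------------------------------------------------------
  status <- validate_orf(data$orfs, genome)
  orfs <- data$orfs[status == "valid", , drop = FALSE]
  orfs <- filter_expression(orfs, rpm_threshold)
  orfs <- classify_genomic_position(orfs, est)
  rownames(orfs) <- NULL

  # --- introns --------------------------------------------------------------
  intron_tab <- intron_summary(orfs, pro, genome)
  inter_tx <- orfs$transcript_id[orfs$position == "intergenic"]
  inter_introns <- rbind_rows(
    lapply(inter_tx, function(t) extract_introns(pro, t, genome)))
  recycling <- NULL
  if (!is.null(inter_introns) && nrow(inter_introns) > 0L) {
    inter_introns$id <- paste0(inter_introns$transcript_id, "_i",
                               inter_introns$ordinal)
    queries <- sample_intron_subset(inter_introns, n = recycle_n,
                                    seed = seed + 11L)
    db <- all_introns(est, source = "established",
                      biotype = "protein_coding")
    db$id <- paste0(db$transcript_id, "_i", db$ordinal)
    db$sequence <- vapply(seq_len(nrow(db)), function(i) {
      genome_subseq(genome, db$contig[i], db$start[i], db$end[i])
    }, character(1))
    recycling <- find_recycled_introns(
      queries[, c("id", "sequence")], db[, c("id", "sequence")])
    recycling$n_queries <- nrow(queries)
    recycling$n_recycled <- sum(recycling$recycled$recycled)
  }

  # --- motifs ---------------------------------------------------------------
  pos_of_tx <- stats::setNames(orfs$position, orfs$transcript_id)
  proto_ids <- orfs$transcript_id
  est_pc <- est$transcripts$transcript_id[est$transcripts$biotype ==
                                            "protein_coding"]
  est_pg <- est$transcripts$transcript_id[est$transcripts$biotype ==
                                            "pseudogene"]
  est_lnc <- est$transcripts$transcript_id[est$transcripts$biotype ==
                                             "lncRNA"]
  win <- list(
    proto_upstream = extract_windows(pro, genome, "upstream200",
                                     "proto_upstream", proto_ids),
    established_upstream = extract_windows(est, genome, "upstream200",
                                           "established_upstream", est_pc),
    pseudogene_upstream = extract_windows(est, genome, "upstream200",
                                          "pseudogene_upstream", est_pg),
    lncrna_upstream = extract_windows(est, genome, "upstream200",
                                      "lncrna_upstream", est_lnc)
  )
  proto_regions <- transcript_spans(pro)
  proto_regions <- proto_regions[, c("contig", "start", "end")]
  win$random_intergenic <- sample_background(
    genome, est, n = n_background, mode = "intergenic",
    exclusions = proto_regions, extra = pro, seed = seed + 21L)
  win$random_intronic <- sample_background(
    genome, est, n = n_background, mode = "intronic",
    exclusions = proto_regions, seed = seed + 22L)
  scans <- lapply(win, scan_windows, motifs = motifs,
                  similarity = similarity)
  part <- partition_motifs(scans$established_upstream$hits,
                           win$established_upstream, motifs)
  comparison <- compare_datasets(lapply(scans, `[[`, "counts"))
  # promoter/enhancer content of proto upstream windows, by stratum
  ph <- scans$proto_upstream$hits
  grp_of <- function(m) ifelse(m %in% part$promoter, "promoter", "enhancer")
  by_window <- data.frame(window_id = win$proto_upstream$id,
                          stringsAsFactors = FALSE)
  for (g in c("promoter", "enhancer")) {
    cnt <- table(factor(ph$window_id[grp_of(ph$motif_id) == g],
                        levels = by_window$window_id))
    by_window[[paste0(g, "_hits")]] <- as.integer(cnt)
  }
  by_window$position <- unname(pos_of_tx[by_window$window_id])
  by_window$age_class <- orfs$age_class[match(by_window$window_id,
                                              orfs$transcript_id)]
  strat <- expand.grid(age_class = age_classes(),
                       position = position_labels(),
                       stringsAsFactors = FALSE)
  motif_by_stratum <- do.call(rbind, lapply(seq_len(nrow(strat)),
                                            function(g) {
    sel <- by_window$position == strat$position[g] &
      by_window$age_class == strat$age_class[g]
    data.frame(strat[g, ], n = sum(sel),
               mean_promoter_hits = if (any(sel))
                 mean(by_window$promoter_hits[sel]) else NA_real_,
               mean_enhancer_hits = if (any(sel))
                 mean(by_window$enhancer_hits[sel]) else NA_real_)
  }))
  rownames(motif_by_stratum) <- NULL
  # core-promoter windows
  core <- list(
    proto = extract_windows(pro, genome, "core", "proto_core", proto_ids),
    established = extract_windows(est, genome, "core", "established_core",
                                  est_pc)
  )
  core_scans <- lapply(core, scan_windows, motifs = motifs,
                       similarity = similarity)
  core_comparison <- compare_datasets(lapply(core_scans, `[[`, "counts"))

  # --- UTRs and folding -----------------------------------------------------
  utr_rows <- lapply(seq_len(nrow(orfs)), function(i) {
    ts <- spliced_transcript_seq(pro, orfs$transcript_id[i], genome)
    u <- extract_utrs(orfs$sequence[i], ts)
    data.frame(id = orfs$orf_id[i],
               group = paste0("proto_", orfs$position[i]),
               age_class = orfs$age_class[i], seq = u$utr5,
               length = u$utr5_length, gc = u$utr5_gc,
               utr3_length = u$utr3_length, utr3_gc = u$utr3_gc,
               stringsAsFactors = FALSE)
  })
  utrs <- rbind_rows(utr_rows)
  est_utr <- established_utrs(est, genome)
  utrs <- rbind(utrs, data.frame(
    id = est_utr$transcript_id, group = "established",
    age_class = NA_character_, seq = est_utr$utr5,
    length = est_utr$utr5_length, gc = est_utr$utr5_gc,
    utr3_length = est_utr$utr3_length, utr3_gc = est_utr$utr3_gc,
    stringsAsFactors = FALSE))
  # lncRNA-like controls: entire transcripts, length-matched to the UTRs
  lnc_rows <- lapply(est_lnc, function(tid) {
    s <- spliced_transcript_seq(est, tid, genome)
    data.frame(id = tid, group = "lncrna", age_class = NA_character_,
               seq = s, length = nchar(s), gc = gc_content(s),
               utr3_length = NA_integer_, utr3_gc = NA_real_,
               stringsAsFactors = FALSE)
  })
  lnc <- rbind_rows(lnc_rows)
  if (!is.null(lnc)) {
    utrs <- rbind(utrs,
                  match_length_range(lnc, utrs$length[utrs$length > 0]))
  }
  # fold a capped, seeded subsample per group
  foldable <- which(utrs$length >= 5L & utrs$length <= fold_max_len)
  fold_idx <- unlist(lapply(split(foldable, utrs$group[foldable]),
                            function(idx) {
    if (length(idx) <= fold_per_group) {
      idx
    } else {
      with_seed(seed + 31L, sort(sample(idx, fold_per_group)))
    }
  }))
  model <- energy_model()
  utrs$e_mfe <- NA_real_
  utrs$mfe_frequency <- NA_real_
  utrs$ensemble_diversity <- NA_real_
  for (i in fold_idx) {
    f <- fold_sequence(utrs$seq[i], model)
    utrs$e_mfe[i] <- f$e_mfe
    utrs$mfe_frequency[i] <- f$mfe_frequency
    utrs$ensemble_diversity[i] <- f$ensemble_diversity
  }
  utr_sum <- utr_summary(utrs)

  # --- proteins -------------------------------------------------------------
  proteins <- data.frame(
    orf_id = orfs$orf_id,
    sequence = vapply(orfs$sequence, translate_orf, character(1),
                      USE.NAMES = FALSE),
    age_class = orfs$age_class, position = orfs$position,
    stringsAsFactors = FALSE)
  clusters <- cluster_summary(proteins)

  report <- build_report(
    introns = list(summary = intron_tab),
    recycling = recycling,
    motifs = list(summary = comparison$summary, tests = comparison$tests,
                  by_stratum = motif_by_stratum),
    utrs = utr_sum,
    clusters = clusters)
  structure(list(
    orfs = orfs, validation = table(status), introns = intron_tab,
    recycling = recycling,
    motifs = list(windows = win, scans = scans, partition = part,
                  comparison = comparison, by_stratum = motif_by_stratum,
                  core = core_scans, core_comparison = core_comparison),
    utrs = utrs, utr_summary = utr_sum, proteins = proteins,
    clusters = clusters, report = report, seed = seed),
    class = "protogene_run")
}
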