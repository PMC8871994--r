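#' Read motifs in JASPAR PFM format
#'
#' Parses JASPAR-style position frequency matrices: a header line
#' `>ID NAME` followed by four count rows (`A`, `C`, `G`, `T`), with or
#' without the bracketed row format. Column totals may differ between
#' columns; counts must be non-negative and all four rows equally long.
#'
#' @param path path to a PFM text file (one or more motifs).
#' @return list of motifs; each is a list with `id`, `name` and `counts`
#'   (4 x L numeric matrix with rownames A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR headers in ", path)
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else id
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4L) stop("motif ", id, ": expected 4 count rows")
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    len <- unique(vapply(rows, length, integer(1)))
    if (length(len) != 1L) {
      stop("motif ", id, ": count rows of unequal length")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("motif ", id, ": negative count")
    if (len < 1L) stop("motif ", id, ": empty matrix")
    out[[i]] <- list(id = id, name = name, counts = counts)
  }
  out
}

#' @rdname read_jaspar
#' @param motifs motif list as returned by [read_jaspar()].
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$id, " ", m$name), con, sep = "\n")
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, "  [ ",
                        paste(format(m$counts[b, ], trim = TRUE),
                              collapse = " "),
                        " ]"), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Consensus sequence of a PFM
#'
#' Highest-count base per column (ties broken in A, C, G, T order), so a
#' planted consensus occurrence always attains the matrix maximum score.
#'
#' @param motif one motif from [read_jaspar()].
#' @return character scalar.
#' @export
consensus_sequence <- function(motif) {
  paste(rownames(motif$counts)[apply(motif$counts, 2, which.max)],
        collapse = "")
}

#' Build the PWM/PSSM of a motif
#'
#' Probabilities with a background-distributed pseudocount,
#' `p[b,j] = (count[b,j] + pc * bg[b]) / (total_j + pc)`, and log-odds
#' `s[b,j] = log2(p[b,j] / bg[b])`. Also precomputes the per-column score
#' extrema used for max-min normalized ("relative") scores.
#'
#' @param motif one motif from [read_jaspar()].
#' @param background base frequencies (A, C, G, T), summing to 1; all > 0.
#' @param pseudocount total pseudocount per column (default 0.8).
#' @return the motif with `prob`, `pssm`, `min_score`, `max_score` added.
#' @export
build_pssm <- function(motif, background = rep(0.25, 4), pseudocount = 0.8) {
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies must sum to 1")
  }
  if (any(background <= 0)) {
    stop("background frequencies must all be positive")
  }
  counts <- motif$counts
  totals <- colSums(counts)
  prob <- sweep(counts + pseudocount * background, 2, totals + pseudocount,
                "/")
  pssm <- log2(prob / background)
  motif$prob <- prob
  motif$pssm <- pssm
  motif$min_score <- sum(apply(pssm, 2, min))
  motif$max_score <- sum(apply(pssm, 2, max))
  motif$background <- background
  motif$pseudocount <- pseudocount
  motif
}

# relative (max-min normalized) score; degenerate columns (max == min)
# define relative score 1
.rel_score <- function(raw, min_s, max_s) {
  if (max_s - min_s < 1e-12) {
    return(rep(1, length(raw)))
  }
  (raw - min_s) / (max_s - min_s)
}

.encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[v]) -> out
  out[is.na(out)] <- -1L
  out
}

#' Extract TSS-anchored windows
#'
#' `upstream200`: the 200 bp upstream of each transcript's TSS
#' (`[tss-200, tss)` on the plus strand; the reverse complement of the
#' mirrored interval on the minus strand). `core`: 100 bp before to 100 bp
#' after the TSS, strand-corrected. Windows clipped at contig edges are
#' flagged as truncated.
#'
#' @param aset [annotation_set()].
#' @param genome named `DNAStringSet`.
#' @param mode `"upstream200"` or `"core"`.
#' @param dataset label stored with the windows.
#' @param transcript_ids optional subset of transcripts.
#' @return data.frame (`id`, `dataset`, `seq`, `truncated`, `contig`,
#'   `start`, `end`, `strand`).
#' @export
extract_windows <- function(aset, genome, mode = c("upstream200", "core"),
                            dataset = "windows", transcript_ids = NULL) {
  mode <- match.arg(mode)
  tss <- tss_positions(aset)
  if (!is.null(transcript_ids)) {
    tss <- tss[tss$transcript_id %in% transcript_ids, , drop = FALSE]
  }
  rows <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    t <- tss[i, ]
    clen <- length(genome[[t$contig]])
    if (mode == "upstream200") {
      iv <- if (t$strand == "+") c(t$tss - 200L, t$tss)
            else c(t$tss + 1L, t$tss + 201L)
    } else {
      iv <- if (t$strand == "+") c(t$tss - 100L, t$tss + 100L)
            else c(t$tss - 99L, t$tss + 101L)
    }
    civ <- c(max(0L, iv[1]), min(clen, iv[2]))
    if (civ[2] <= civ[1]) next
    s <- genome_subseq(genome, t$contig, civ[1], civ[2], t$strand)
    rows[[i]] <- data.frame(
      id = t$transcript_id, dataset = dataset, seq = s,
      truncated = !identical(civ, iv), contig = t$contig,
      start = civ[1], end = civ[2], strand = t$strand,
      stringsAsFactors = FALSE)
  }
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), dataset = character(0),
                      seq = character(0), truncated = logical(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  }
  out
}

#' Sample background windows
#'
#' Draws `n` non-overlapping fixed-length regions from the intergenic or
#' intronic candidate space of the genome (annotated feature spans
#' subtracted), excluding user-supplied intervals (e.g. proto-gene
#' regions) and any previously drawn region. Deterministic under `seed`.
#'
#' @param genome named `DNAStringSet`.
#' @param aset [annotation_set()] of the established annotation.
#' @param n number of regions.
#' @param length region length (default 200).
#' @param mode `"intergenic"` or `"intronic"`.
#' @param exclusions optional data.frame (`contig`, `start`, `end`).
#' @param extra optional further annotation (e.g. the proto
#'   [annotation_set()]) whose transcript spans are subtracted as well.
#' @param seed integer seed.
#' @param dataset label for the returned windows.
#' @return window data.frame as in [extract_windows()].
#' @export
sample_background <- function(genome, aset, n, length = 200L,
                              mode = c("intergenic", "intronic"),
                              exclusions = NULL, extra = NULL, seed = 1L,
                              dataset = NULL) {
  mode <- match.arg(mode)
  if (is.null(dataset)) dataset <- paste0("random_", mode)
  spans <- transcript_spans(aset)
  if (!is.null(extra)) {
    spans <- rbind(spans, transcript_spans(extra))
  }
  excl <- spans[, c("contig", "start", "end")]
  if (!is.null(exclusions)) {
    excl <- rbind(excl, exclusions[, c("contig", "start", "end")])
  }
  candidates <- list()
  if (mode == "intergenic") {
    for (ctg in names(genome)) {
      clen <- length(genome[[ctg]])
      sp <- spans[spans$contig == ctg, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(sp$start + 1L, sp$end))
      free <- IRanges::setdiff(IRanges::IRanges(1L, clen), ir)
      free <- free[IRanges::width(free) >= length]
      if (base::length(free) > 0L) {
        candidates[[ctg]] <- data.frame(
          start = IRanges::start(free) - 1L, end = IRanges::end(free))
      }
    }
  } else {
    ins <- all_introns(aset, source = "established",
                       biotype = "protein_coding")
    for (ctg in unique(ins$contig)) {
      sub <- ins[ins$contig == ctg & ins$end - ins$start >= length, ]
      if (nrow(sub) > 0L) {
        candidates[[ctg]] <- data.frame(start = sub$start, end = sub$end)
      }
    }
  }
  if (base::length(candidates) == 0L) {
    stop("no candidate space for background sampling (mode ", mode, ")")
  }
  cand <- do.call(rbind, lapply(names(candidates), function(ctg) {
    data.frame(contig = ctg, candidates[[ctg]], stringsAsFactors = FALSE)
  }))
  cand$w <- cand$end - cand$start
  taken <- NULL
  out <- vector("list", n)
  got <- 0L
  with_seed(seed, {
    tries <- 0L
    max_tries <- 200L * n
    fail_streak <- 0L
    while (got < n && tries < max_tries && fail_streak < 2000L) {
      tries <- tries + 1L
      ri <- sample.int(nrow(cand), 1L, prob = cand$w)
      row <- cand[ri, ]
      if (row$w < length) next
      st <- row$start + sample.int(row$w - length + 1L, 1L) - 1L
      en <- st + length
      clash <- FALSE
      if (!is.null(taken)) {
        clash <- any(taken$contig == row$contig & taken$start < en &
                       taken$end > st)
      }
      if (!clash) {
        clash <- any(excl$contig == row$contig & excl$start < en &
                       excl$end > st & mode == "intergenic")
      }
      if (!clash && !is.null(exclusions)) {
        clash <- any(exclusions$contig == row$contig &
                       exclusions$start < en & exclusions$end > st)
      }
      if (clash) {
        fail_streak <- fail_streak + 1L
        next
      }
      fail_streak <- 0L
      got <- got + 1L
      taken <- rbind(taken, data.frame(contig = row$contig, start = st,
                                       end = en, stringsAsFactors = FALSE))
      out[[got]] <- data.frame(
        id = sprintf("%s_%04d", dataset, got), dataset = dataset,
        seq = genome_subseq(genome, row$contig, st, en),
        truncated = FALSE, contig = row$contig, start = st, end = en,
        strand = "+", stringsAsFactors = FALSE)
    }
  })
  if (got < n) {
    stop("background sampling exhausted: requested ", n, ", achievable ", got)
  }
  rbind_rows(out[seq_len(got)])
}

#' Scan windows with a motif set
#'
#' Slides every PSSM over both strands of every window. Stage 1 keeps
#' positions whose max-min normalized (relative) score reaches
#' `score_threshold`; stage 2 keeps, of those, hits at or above the
#' `similarity` threshold on the same relative-score scale. Hit offsets
#' are reported on the window's forward coordinates; all (possibly
#' overlapping) occurrences are counted. Windows shorter than a motif
#' simply contribute no hits for it.
#'
#' @param windows window data.frame ([extract_windows()]).
#' @param motifs motif list ([read_jaspar()]).
#' @param score_threshold stage-1 relative-score gate (default 0.7).
#' @param similarity stage-2 relative-score gate (0.80 or 0.95 in the two
#'   standard runs).
#' @param background `"auto"` (composition of the scanned windows),
#'   `"uniform"`, or a numeric 4-vector.
#' @param pseudocount PSSM pseudocount.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return list: `hits` (motif_id, window_id, offset, strand, raw_score,
#'   rel_score), `counts` (window_id, dataset, n_hits of stage 2),
#'   `stage1` (per-window count of stage-1 survivors).
#' @export
scan_windows <- function(windows, motifs, score_threshold = 0.7,
                         similarity = 0.8, background = "auto",
                         pseudocount = 0.8, both_strands = TRUE) {
  if (nrow(windows) == 0L) {
    stop("no windows to scan")
  }
  bg <- if (identical(background, "auto")) {
    all <- paste(windows$seq, collapse = "")
    v <- .encode_dna(all)
    v <- v[v >= 0L]
    p <- tabulate(v + 1L, 4L) / base::length(v)
    # both strands are scanned: symmetrize
    (p + rev(p)) / 2
  } else if (identical(background, "uniform")) {
    rep(0.25, 4)
  } else {
    background
  }
  pssms <- lapply(motifs, build_pssm, background = bg,
                  pseudocount = pseudocount)
  enc <- lapply(windows$seq, .encode_dna)
  enc_rc <- if (both_strands) lapply(enc, function(v) rev(3L - v)) else NULL
  hit_rows <- list(); hi <- 0L
  stage1 <- integer(nrow(windows))
  n_hits <- integer(nrow(windows))
  for (mi in seq_along(pssms)) {
    m <- pssms[[mi]]
    L <- ncol(m$pssm)
    for (wi in seq_len(nrow(windows))) {
      v <- enc[[wi]]
      wlen <- base::length(v)
      if (wlen < L) next
      raw_f <- pssm_scores_cpp(v, m$pssm)
      rel_f <- .rel_score(raw_f, m$min_score, m$max_score)
      offs <- which(rel_f >= score_threshold) # stage 1
      strands <- rep("+", base::length(offs))
      raws <- raw_f[offs]; rels <- rel_f[offs]
      offs <- offs - 1L
      if (both_strands) {
        raw_r <- pssm_scores_cpp(enc_rc[[wi]], m$pssm)
        rel_r <- .rel_score(raw_r, m$min_score, m$max_score)
        o2 <- which(rel_r >= score_threshold)
        if (base::length(o2) > 0L) {
          offs <- c(offs, wlen - (o2 - 1L) - L)
          strands <- c(strands, rep("-", base::length(o2)))
          raws <- c(raws, raw_r[o2]); rels <- c(rels, rel_r[o2])
        }
      }
      stage1[wi] <- stage1[wi] + base::length(offs)
      keep <- rels >= similarity # stage 2
      if (any(keep)) {
        n_hits[wi] <- n_hits[wi] + sum(keep)
        hi <- hi + 1L
        hit_rows[[hi]] <- data.frame(
          motif_id = m$id, window_id = windows$id[wi],
          offset = offs[keep], strand = strands[keep],
          raw_score = raws[keep], rel_score = rels[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (hi > 0L) {
    do.call(rbind, c(hit_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(motif_id = character(0), window_id = character(0),
               offset = integer(0), strand = character(0),
               raw_score = numeric(0), rel_score = numeric(0))
  }
  counts <- data.frame(window_id = windows$id, dataset = windows$dataset,
                       n_hits = n_hits, stringsAsFactors = FALSE)
  list(hits = hits, counts = counts,
       stage1 = data.frame(window_id = windows$id, n_stage1 = stage1),
       background = bg)
}

#' Partition motifs into promoter and enhancer sets
#'
#' Ranks motifs by their mean per-window hit count in the upstream windows
#' of established genes; the top `1 - quantile` share (default: top half,
#' i.e. the motifs most present upstream of established genes) is labelled
#' promoter-specific, the remainder enhancer-specific. Ties are broken by
#' motif id, so the split is deterministic.
#'
#' @param hits hit data.frame from [scan_windows()] on the established
#'   upstream dataset.
#' @param windows the scanned established-upstream windows.
#' @param motifs motif list.
#' @param quantile split quantile (default 0.5 = median; 0 sends every
#'   motif to the promoter set).
#' @return list with `promoter`, `enhancer` (character vectors of motif
#'   ids) and `means` (per-motif mean hits/window).
#' @export
partition_motifs <- function(hits, windows, motifs, quantile = 0.5) {
  if (nrow(windows) == 0L) {
    stop("empty established window set")
  }
  ids <- vapply(motifs, function(m) m$id, character(1))
  nw <- nrow(windows)
  tab <- table(factor(hits$motif_id, levels = ids))
  means <- as.numeric(tab) / nw
  names(means) <- ids
  ord <- order(-means, ids, method = "radix")
  n_prom <- ceiling((1 - quantile) * base::length(ids))
  promoter <- sort(ids[ord[seq_len(n_prom)]])
  list(promoter = promoter, enhancer = sort(setdiff(ids, promoter)),
       means = means)
}

#' Compare motif content across window datasets
#'
#' Mean hits per window for each dataset plus pairwise Welch tests.
#'
#' @param counts_list named list of `counts` data.frames from
#'   [scan_windows()] (one per dataset).
#' @return list with `summary` (dataset, n_windows, mean_hits, sd_hits)
#'   and `tests` (pairwise Welch t results).
#' @export
compare_datasets <- function(counts_list) {
  keep <- vapply(counts_list, function(x) nrow(x) > 0L, logical(1))
  if (any(!keep)) {
    warning("empty dataset(s) excluded: ",
            paste(names(counts_list)[!keep], collapse = ", "))
  }
  counts_list <- counts_list[keep]
  summ <- do.call(rbind, lapply(names(counts_list), function(nm) {
    x <- counts_list[[nm]]$n_hits
    data.frame(dataset = nm, n_windows = base::length(x),
               mean_hits = mean(x), sd_hits = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
  nms <- names(counts_list)
  tests <- NULL
  if (base::length(nms) > 1L) {
    prs <- utils::combn(nms, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      a <- counts_list[[prs[1, i]]]$n_hits
      b <- counts_list[[prs[2, i]]]$n_hits
      tt <- welch_t(a, b)
      data.frame(dataset_a = prs[1, i], dataset_b = prs[2, i],
                 statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, tests = tests)
}
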