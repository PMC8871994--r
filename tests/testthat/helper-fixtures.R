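# Shared fixtures and independent reference implementations (oracles).
# The synthetic datasets are generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function(seed = 5L) {
  synthetic_spec(
    seed = seed, n_contigs = 2L, contig_length = 200000L,
    established = list(n_genes = 12L),
    noncoding = list(n_pseudogenes = 5L, n_lncrnas = 5L,
                     length = c(60L, 400L)),
    proto = list(n_per_stratum = 2L))
}

small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    .fixture_env$small_sim <- simulate_protogene_dataset(small_spec())
  }
  .fixture_env$small_sim
}

# study-scale dataset: all 18 (position x age) strata at full depth
full_sim <- function() {
  if (is.null(.fixture_env$full_sim)) {
    .fixture_env$full_sim <- simulate_protogene_dataset(synthetic_spec(seed = 11L))
  }
  .fixture_env$full_sim
}

full_run <- function() {
  if (is.null(.fixture_env$full_run)) {
    .fixture_env$full_run <- run_pipeline(full_sim(), seed = 1L)
  }
  .fixture_env$full_run
}

# a tiny in-memory genome from named character sequences
tiny_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# compact annotation builder: exons as list(tx_id = list(gene, contig,
# strand, blocks = matrix(start, end)))
tiny_annotation <- function(spec_list, source = "established",
                            biotype = "protein_coding") {
  tx <- do.call(rbind, lapply(names(spec_list), function(tid) {
    s <- spec_list[[tid]]
    data.frame(transcript_id = tid, gene_id = s$gene %||% tid,
               contig = s$contig, strand = s$strand, source = source,
               biotype = s$biotype %||% biotype, stringsAsFactors = FALSE)
  }))
  ex <- do.call(rbind, lapply(names(spec_list), function(tid) {
    b <- spec_list[[tid]]$blocks
    data.frame(transcript_id = tid, start = b[, 1], end = b[, 2],
               stringsAsFactors = FALSE)
  }))
  annotation_set(tx, ex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent full-DP Smith-Waterman (score only), affine gaps ----------
ref_sw_score <- function(q, s, match = 2, mismatch = -3, gap_open = 5,
                         gap_extend = 2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      sub <- if (qv[i - 1] == sv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- brute-force motif hit enumeration over both strands -------------------
ref_scan_count <- function(window, motif, similarity, background,
                           pseudocount = 0.8, score_threshold = 0.7) {
  m <- build_pssm(motif, background = background,
                  pseudocount = pseudocount)
  count_one <- function(w) {
    v <- strsplit(w, "")[[1]]
    L <- ncol(m$pssm)
    if (length(v) < L) return(0L)
    hits <- 0L
    for (off in 1:(length(v) - L + 1)) {
      word <- v[off:(off + L - 1)]
      if (any(!word %in% c("A", "C", "G", "T"))) next
      raw <- sum(vapply(seq_len(L), function(k) m$pssm[word[k], k],
                        numeric(1)))
      rel <- (raw - m$min_score) / (m$max_score - m$min_score)
      if (rel >= score_threshold && rel >= similarity) hits <- hits + 1L
    }
    hits
  }
  count_one(window) + count_one(revcomp(window))
}

# --- positional reference for hydrophobic clusters -------------------------
ref_clusters <- function(protein, max_gap = 4L) {
  hset <- c("V", "I", "L", "F", "M", "Y", "W")
  v <- strsplit(protein, "")[[1]]
  clusters <- list()
  cur <- integer(0)
  last_h <- NA_integer_
  for (i in seq_along(v)) {
    if (v[i] %in% hset) {
      if (length(cur) > 0L) {
        gap <- i - last_h - 1L
        between <- if (gap > 0L) v[(last_h + 1):(i - 1)] else character(0)
        if (gap >= max_gap || any(between == "P")) {
          clusters[[length(clusters) + 1L]] <- cur
          cur <- integer(0)
        }
      }
      cur <- c(cur, i)
      last_h <- i
    }
  }
  if (length(cur) > 0L) clusters[[length(clusters) + 1L]] <- cur
  if (length(clusters) == 0L) {
    return(NULL)
  }
  do.call(rbind, c(lapply(clusters, function(p) {
    data.frame(start = min(p) - 1L, end = max(p), size = length(p))
  }), list(make.row.names = FALSE)))
}
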