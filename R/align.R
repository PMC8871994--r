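#' Local alignment scoring scheme
#'
#' Match/mismatch and affine gap parameters (a gap of length k costs
#' `gap_open + k * gap_extend`), defaulting to the classic nucleotide
#' local-alignment values (+2/-3, open 5, extend 2). The Karlin-Altschul
#' parameters `K` and `lambda` used by [evalue()] are estimated per
#' scheme by simulation ([estimate_karlin()]) rather than hard-coded.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap_open,gap_extend affine gap penalties (>= 0).
#' @param K,lambda optional Karlin-Altschul parameters; left `NA` they are
#'   filled in by [estimate_karlin()] on first use.
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2, K = NA_real_, lambda = NA_real_) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda),
            class = "align_scoring")
}

.karlin_cache <- new.env(parent = emptyenv())

#' Estimate Karlin-Altschul parameters by simulation
#'
#' Simulates optimal local-alignment scores of shuffled (iid) sequence
#' pairs and fits a Gumbel law by the method of moments
#' (`lambda = pi / (sd * sqrt(6))`, `K = exp(lambda * mu) / (m n)` with
#' `mu = mean - gamma / lambda`). Estimates are cached per scoring scheme;
#' the simulation seed is fixed so repeated calls are identical.
#'
#' @param scoring an [align_scoring()].
#' @param n_sim number of simulated pairs.
#' @param m,n lengths of the simulated query/subject.
#' @param gc GC content of the simulated sequences.
#' @param seed simulation seed (fixed default: the estimate is part of the
#'   scoring scheme, not of the analysis randomness).
#' @return the scoring list with `K` and `lambda` filled in.
#' @export
estimate_karlin <- function(scoring, n_sim = 120L, m = 150L, n = 400L,
                            gc = 0.45, seed = 20220131L) {
  key <- paste(scoring$match, scoring$mismatch, scoring$gap_open,
               scoring$gap_extend, n_sim, m, n, gc, seed, sep = "_")
  if (!is.null(.karlin_cache[[key]])) {
    sc <- .karlin_cache[[key]]
    scoring$K <- sc$K
    scoring$lambda <- sc$lambda
    return(scoring)
  }
  scores <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      q <- .encode_dna(random_dna(m, gc))
      s <- .encode_dna(random_dna(n, gc))
      sw_score_cpp(q, s, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
    }, numeric(1))
  })
  lam <- pi / (stats::sd(scores) * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lam
  K <- exp(lam * mu) / (as.numeric(m) * n)
  scoring$K <- K
  scoring$lambda <- lam
  .karlin_cache[[key]] <- scoring
  scoring
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman alignment under the given scoring, searching the
#' subject's forward and (by default) reverse-complement strand; the
#' higher-scoring strand is reported. Identity is matches over alignment
#' columns; coverage is the aligned query span over the query length.
#'
#' @param query,subject DNA strings.
#' @param scoring an [align_scoring()].
#' @param both_strands search the subject's reverse complement too.
#' @return list (`score`, `identity`, `coverage`, `strand`, `qstart`,
#'   `qend`, `sstart`, `send`, `matches`, `columns`); coordinates 1-based
#'   on the input sequences, subject coordinates on the forward strand's
#'   frame for `strand == "+"` and on the reverse complement for `"-"`.
#' @export
local_align <- function(query, subject, scoring = align_scoring(),
                        both_strands = TRUE) {
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L)
  q <- .encode_dna(query)
  run <- function(sv, strand) {
    r <- sw_align_cpp(q, sv, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
    r$strand <- strand
    r
  }
  best <- run(.encode_dna(subject), "+")
  if (both_strands) {
    alt <- run(.encode_dna(revcomp(subject)), "-")
    if (alt$score > best$score) best <- alt
  }
  qlen <- nchar(query)
  list(score = best$score,
       identity = if (best$columns > 0L) best$matches / best$columns else 0,
       coverage = if (is.na(best$qstart)) 0
                  else (best$qend - best$qstart + 1L) / qlen,
       strand = best$strand, qstart = best$qstart, qend = best$qend,
       sstart = best$sstart, send = best$send, matches = best$matches,
       columns = best$columns)
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` in a search of a length-`m` query
#' against `n` database letters. Monotone decreasing in `S`, linear in
#' both search-space sizes.
#'
#' @param score raw alignment score.
#' @param m query length.
#' @param n total database length (summed subject lengths; doubled
#'   internally when `both_strands`).
#' @param scoring an [align_scoring()] with `K` and `lambda` set.
#' @param both_strands whether both subject strands were searched.
#' @return numeric E-value.
#' @export
evalue <- function(score, m, n, scoring, both_strands = TRUE) {
  if (is.na(scoring$K) || is.na(scoring$lambda)) {
    stop("scoring has no Karlin-Altschul parameters; run estimate_karlin()")
  }
  eff_n <- if (both_strands) 2 * as.numeric(n) else as.numeric(n)
  scoring$K * as.numeric(m) * eff_n * exp(-scoring$lambda * score)
}

#' Find recycled introns
#'
#' Aligns each query intron against every database intron (both strands)
#' and labels a query "recycled" when at least one hit passes all three
#' filters: E-value at most `max_evalue`, identity strictly above
#' `min_identity`, and query coverage at least `min_coverage` (the strict
#' vs non-strict comparisons follow the filter as printed). A fast
#' score-only pass bounds each pair before the full traceback is done, so
#' only plausible pairs are aligned in full.
#'
#' @param queries data.frame with `id` and `sequence` (e.g. introns of
#'   intergenic proto-genes), or a character vector.
#' @param database same shape: the established-intron database.
#' @param scoring an [align_scoring()]; `K`/`lambda` estimated on demand.
#' @param max_evalue,min_identity,min_coverage the three filters
#'   (defaults 0.01, 0.80, 0.80).
#' @return list: `hits` (all passing hits: query, subject, score,
#'   identity, coverage, evalue) and `recycled` (per-query logical
#'   data.frame).
#' @export
find_recycled_introns <- function(queries, database,
                                  scoring = align_scoring(),
                                  max_evalue = 0.01, min_identity = 0.80,
                                  min_coverage = 0.80) {
  as_tab <- function(x, prefix) {
    if (is.character(x)) {
      data.frame(id = sprintf("%s%04d", prefix, seq_along(x)), sequence = x,
                 stringsAsFactors = FALSE)
    } else {
      x
    }
  }
  queries <- as_tab(queries, "q")
  database <- as_tab(database, "s")
  if (is.na(scoring$K)) {
    scoring <- estimate_karlin(scoring)
  }
  if (nrow(database) == 0L) {
    return(list(hits = NULL,
                recycled = data.frame(query = queries$id,
                                      recycled = FALSE)))
  }
  db_total <- sum(nchar(database$sequence))
  db_enc <- lapply(database$sequence, .encode_dna)
  db_enc_rc <- lapply(database$sequence, function(s) {
    v <- .encode_dna(s)
    rev(3L - v)
  })
  hit_rows <- list(); hi <- 0L
  recycled <- logical(nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$sequence[qi]
    qv <- .encode_dna(qseq)
    m <- base::length(qv)
    # minimal score that could clear the E-value filter
    s_min <- (log(scoring$K * m * 2 * db_total) - log(max_evalue)) /
      scoring$lambda
    for (si in seq_len(nrow(database))) {
      sc_f <- sw_score_cpp(qv, db_enc[[si]], scoring$match,
                           scoring$mismatch, scoring$gap_open,
                           scoring$gap_extend)
      sc_r <- sw_score_cpp(qv, db_enc_rc[[si]], scoring$match,
                           scoring$mismatch, scoring$gap_open,
                           scoring$gap_extend)
      if (max(sc_f, sc_r) < s_min) next
      al <- local_align(qseq, database$sequence[si], scoring)
      ev <- evalue(al$score, m, db_total, scoring)
      if (ev <= max_evalue && al$identity > min_identity &&
          al$coverage >= min_coverage) {
        recycled[qi] <- TRUE
        hi <- hi + 1L
        hit_rows[[hi]] <- data.frame(
          query = queries$id[qi], subject = database$id[si],
          score = al$score, identity = al$identity,
          coverage = al$coverage, evalue = ev, strand = al$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (hi > 0L) {
    do.call(rbind, c(hit_rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  list(hits = hits,
       recycled = data.frame(query = queries$id, recycled = recycled,
                             stringsAsFactors = FALSE))
}
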