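#' Translate a validated ORF
#'
#' Standard genetic code; the terminal stop is trimmed. An internal stop
#' codon is an error (such ORFs should have been removed upstream).
#'
#' @param orf_seq spliced ORF DNA (`ATG ... stop`, length divisible by 3).
#' @return amino-acid string.
#' @export
translate_orf <- function(orf_seq) {
  if (nchar(orf_seq) %% 3L != 0L) {
    stop("ORF length not divisible by 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(orf_seq)))
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") {
    aa <- substr(aa, 1L, n - 1L)
  }
  if (grepl("*", aa, fixed = TRUE)) {
    stop("internal stop codon in ORF")
  }
  aa
}

#' Strong hydrophobic residues of the HCA alphabet
#' @return character vector `V I L F M Y W`.
#' @export
strong_hydrophobics <- function() c("V", "I", "L", "F", "M", "Y", "W")

#' Detect hydrophobic clusters
#'
#' Hydrophobic-cluster-analysis style detection: a cluster is a maximal
#' set of strong hydrophobic positions in which consecutive hydrophobic
#' residues are separated by fewer than `max_gap` non-hydrophobic
#' residues none of which is a proline; a run of `max_gap` or more
#' non-hydrophobics, or any proline, terminates the cluster. The cluster
#' span runs from its first to its last hydrophobic residue; its size is
#' the number of hydrophobic residues inside.
#'
#' @param protein amino-acid string.
#' @param hydrophobic the strong-hydrophobic alphabet (configurable).
#' @param max_gap breaker gap length (default 4).
#' @param size_by `"hydrophobics"` (default) or `"span"`.
#' @return data.frame (`start`, `end` 0-based half-open, `size`).
#' @export
detect_clusters <- function(protein, hydrophobic = strong_hydrophobics(),
                            max_gap = 4L, size_by = c("hydrophobics",
                                                      "span")) {
  size_by <- match.arg(size_by)
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  hpos <- which(v %in% hydrophobic)
  if (length(hpos) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      size = integer(0)))
  }
  breaks <- integer(0)
  if (length(hpos) > 1L) {
    for (k in seq_len(length(hpos) - 1L)) {
      a <- hpos[k]; b <- hpos[k + 1L]
      gap <- b - a - 1L
      linker <- if (gap > 0L) v[(a + 1L):(b - 1L)] else character(0)
      if (gap >= max_gap || any(linker == "P")) {
        breaks <- c(breaks, k)
      }
    }
  }
  grp <- cumsum(c(0L, seq_len(length(hpos) - 1L) %in% breaks))
  rows <- lapply(split(hpos, grp), function(p) {
    data.frame(start = min(p) - 1L, end = max(p),
               size = if (size_by == "hydrophobics") length(p)
                      else max(p) - min(p) + 1L)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$start), , drop = FALSE]
}

#' Per-stratum hydrophobic cluster summary
#'
#' Cluster count and size by (age class x genomic position) for
#' proto-proteins, with the oldest stratum (`I5`) excluded by default
#' (it is dominated by annotated domains), plus the OLS regression of the
#' per-protein cluster count on the age rank.
#'
#' @param proteins data.frame with `orf_id`, `sequence` (amino acids),
#'   `age_class`, `position`.
#' @param exclude_ages age classes dropped from the summary (default
#'   `"I5"`).
#' @param ... passed to [detect_clusters()].
#' @return list (`by_stratum`, `by_age`, `fit` ([ols_fit()] of count on
#'   age rank), `per_protein`).
#' @export
cluster_summary <- function(proteins, exclude_ages = "I5", ...) {
  keep <- !proteins$age_class %in% exclude_ages
  proteins <- proteins[keep, , drop = FALSE]
  cl <- lapply(proteins$sequence, detect_clusters, ...)
  per_protein <- data.frame(
    orf_id = proteins$orf_id, age_class = proteins$age_class,
    position = proteins$position,
    n_clusters = vapply(cl, nrow, integer(1)),
    mean_size = vapply(cl, function(x) {
      if (nrow(x) == 0L) NA_real_ else mean(x$size)
    }, numeric(1)), stringsAsFactors = FALSE)
  ages <- setdiff(age_classes(), exclude_ages)
  grid <- expand.grid(age_class = ages, position = position_labels(),
                      stringsAsFactors = FALSE)
  by_stratum <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- per_protein$age_class == grid$age_class[g] &
      per_protein$position == grid$position[g]
    if (!any(sel)) {
      return(data.frame(grid[g, ], n = 0L, mean_clusters = NA_real_,
                        mean_size = NA_real_))
    }
    data.frame(grid[g, ], n = sum(sel),
               mean_clusters = mean(per_protein$n_clusters[sel]),
               mean_size = mean(per_protein$mean_size[sel], na.rm = TRUE))
  }))
  rownames(by_stratum) <- NULL
  by_age <- do.call(rbind, lapply(ages, function(a) {
    sel <- per_protein$age_class == a
    data.frame(age_class = a, n = sum(sel),
               mean_clusters = if (any(sel))
                 mean(per_protein$n_clusters[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  age_rank <- match(per_protein$age_class, age_classes()) - 1L
  fit <- if (length(unique(age_rank)) > 1L) {
    ols_fit(age_rank, per_protein$n_clusters)
  } else {
    NULL
  }
  list(by_stratum = by_stratum, by_age = by_age, fit = fit,
       per_protein = per_protein)
}

#' Pick the longest isoform per gene
#'
#' Deterministic: longest spliced length wins, ties broken by transcript
#' id.
#'
#' @param aset [annotation_set()].
#' @return character vector of transcript ids, one per gene.
#' @export
longest_isoforms <- function(aset) {
  len <- vapply(split(aset$exons$end - aset$exons$start,
                      aset$exons$transcript_id), sum, numeric(1))
  tx <- aset$transcripts
  tx$len <- len[tx$transcript_id]
  tx <- tx[order(tx$gene_id, -tx$len, tx$transcript_id, method = "radix"), ]
  tx$transcript_id[!duplicated(tx$gene_id)]
}

#' Read an external domain-scan table
#'
#' Whitespace-delimited tabular output of an external profile scan:
#' columns `protein_id`, `domain_accession`, `env_start`, `env_end`,
#' `score` (extra columns ignored). Records for unknown proteins are
#' dropped with a warning; malformed lines are skipped.
#'
#' @param path table path.
#' @param protein_ids known protein ids (optional filter).
#' @return data.frame of domain annotations.
#' @export
read_domain_table <- function(path, protein_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  rows <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[3])))) {
      return(NULL)
    }
    data.frame(protein_id = f[1], domain_accession = f[2],
               env_start = as.integer(f[3]), env_end = as.integer(f[4]),
               score = suppressWarnings(as.numeric(f[5])),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " malformed line(s) skipped")
  }
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0),
                      domain_accession = character(0),
                      env_start = integer(0), env_end = integer(0),
                      score = numeric(0))
  }
  if (!is.null(protein_ids)) {
    unknown <- !out$protein_id %in% protein_ids
    if (any(unknown)) {
      warning(sum(unknown), " record(s) with unknown protein id dropped")
      out <- out[!unknown, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Fraction of proteins with at least one annotated domain, per stratum
#'
#' @param domains data.frame from [read_domain_table()].
#' @param proteins data.frame with `orf_id`, `age_class`, `position`.
#' @return data.frame keyed by (`age_class`, `position`).
#' @export
domain_fraction <- function(domains, proteins) {
  has <- proteins$orf_id %in% domains$protein_id
  grid <- expand.grid(age_class = age_classes(),
                      position = position_labels(),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- proteins$age_class == grid$age_class[g] &
      proteins$position == grid$position[g]
    data.frame(grid[g, ], n = sum(sel),
               frac_with_domain = if (any(sel)) mean(has[sel]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
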