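#' Simplified nearest-neighbour RNA energy model
#'
#' The folder's thermodynamic parameters: stacking energies for the six
#' canonical pair types (Watson-Crick plus GU wobble; magnitudes in the
#' usual Turner range; the table is symmetric, and with wobble pairs
#' disabled a sequence and its reverse complement fold to the same
#' minimum), linear hairpin / internal-bulge / multiloop
#' penalties, a minimum hairpin size of `hmin` unpaired bases, and the
#' temperature entering `RT`. No dangling ends or coaxial stacking. All
#' energies kcal/mol.
#'
#' @param pair_strength named stacking half-weights per pair type; the
#'   stack of pairs `a` over `b` costs `-(w[a] + w[b])`.
#' @param hairpin_a,hairpin_b hairpin loop penalty `a + b * size`.
#' @param internal_a,internal_b internal/bulge loop penalty
#'   `a + b * unpaired`.
#' @param multi_a,multi_b,multi_c multiloop penalty
#'   `a + b * branches + c * unpaired` (the closing pair counts as a
#'   branch).
#' @param hmin minimum hairpin size (>= 3).
#' @param wobble allow GU/UG wobble pairs (default TRUE). Disabling them
#'   restricts the ensemble to Watson-Crick pairs, under which a sequence
#'   and its reverse complement fold to mirror-image ensembles.
#' @param max_internal cap on unpaired bases in an internal loop.
#' @param temperature Kelvin; default 37 degrees C.
#' @return list of class `energy_model` (includes the expanded 6x6 `stack`
#'   table and `RT`).
#' @export
energy_model <- function(pair_strength = c(AU = 0.9, UA = 0.9, GC = 1.5,
                                           CG = 1.5, GU = 0.5, UG = 0.5),
                         hairpin_a = 4.0, hairpin_b = 0.1,
                         internal_a = 2.0, internal_b = 0.3,
                         multi_a = 3.4, multi_b = 0.4, multi_c = 0.1,
                         hmin = 3L, max_internal = 30L,
                         temperature = 310.15, wobble = TRUE) {
  stopifnot(hmin >= 3L, temperature > 0)
  w <- pair_strength[c("AU", "UA", "GC", "CG", "GU", "UG")]
  stack <- -outer(w, w, "+")
  dimnames(stack) <- list(names(w), names(w))
  structure(list(stack = stack, hairpin_a = hairpin_a,
                 hairpin_b = hairpin_b, internal_a = internal_a,
                 internal_b = internal_b, multi_a = multi_a,
                 multi_b = multi_b, multi_c = multi_c,
                 hmin = as.integer(hmin), wobble = isTRUE(wobble),
                 max_internal = as.integer(max_internal),
                 temperature = temperature,
                 RT = 0.0019872041 * temperature),
            class = "energy_model")
}

#' Transcribe DNA to RNA
#' @param seq DNA or RNA string.
#' @return uppercase RNA string (`T` mapped to `U`).
#' @export
transcribe <- function(seq) {
  chartr("Tt", "Uu", toupper(seq))
}

.encode_rna <- function(seq) {
  v <- strsplit(transcribe(seq), "", fixed = TRUE)[[1]]
  out <- unname(c(A = 0L, C = 1L, G = 2L, U = 3L)[v])
  if (anyNA(out)) {
    stop("invalid RNA character(s): ",
         paste(unique(v[is.na(out)]), collapse = ", "))
  }
  out
}

.pair_type <- function(a, b, wobble = TRUE) {
  key <- paste0(c("A", "C", "G", "U")[a + 1L], c("A", "C", "G", "U")[b + 1L])
  t <- match(key, c("AU", "UA", "GC", "CG", "GU", "UG"))
  if (!wobble && !is.na(t) && t > 4L) NA_integer_ else t
}

.model_for_cpp <- function(model) {
  list(stack = unname(model$stack), hairpin_a = model$hairpin_a,
       hairpin_b = model$hairpin_b, internal_a = model$internal_a,
       internal_b = model$internal_b, multi_a = model$multi_a,
       multi_b = model$multi_b, multi_c = model$multi_c,
       hmin = model$hmin, wobble = model$wobble,
       max_internal = model$max_internal, RT = model$RT)
}

.dot_bracket <- function(pairs) {
  n <- length(pairs)
  db <- rep(".", n)
  db[!is.na(pairs) & pairs > seq_len(n)] <- "("
  db[!is.na(pairs) & pairs < seq_len(n)] <- ")"
  paste(db, collapse = "")
}

#' Minimum-free-energy fold
#'
#' Dynamic-programming minimum over all nested, `hmin`-respecting
#' structures under the [energy_model()], with a deterministic traceback.
#' An unpairable sequence gets the open chain at 0 kcal/mol.
#'
#' @param seq RNA (or DNA; transcribed first) string.
#' @param model an [energy_model()].
#' @return list (`structure` dot-bracket, `energy`, `pairs` 1-based
#'   partner vector with `NA` for unpaired).
#' @export
mfe_fold <- function(seq, model = energy_model()) {
  v <- .encode_rna(seq)
  r <- fold_mfe_cpp(v, .model_for_cpp(model))
  list(structure = .dot_bracket(r$pairs), energy = r$energy,
       pairs = r$pairs)
}

#' Partition function and base-pair probabilities
#'
#' McCaskill-style inside-outside recursions over the same structure
#' space and energies as [mfe_fold()]: ensemble free energy
#' `G = -RT ln Z` and the matrix of pair probabilities.
#'
#' @inheritParams mfe_fold
#' @return list (`G`, `bpp` symmetric n x n matrix).
#' @export
partition_function <- function(seq, model = energy_model()) {
  v <- .encode_rna(seq)
  r <- fold_partition_cpp(v, .model_for_cpp(model))
  list(G = r$G, bpp = r$bpp)
}

#' MFE frequency and ensemble diversity
#'
#' The Boltzmann probability of the MFE structure,
#' `exp(-(E_mfe - G) / RT)`, and the ensemble diversity: the expected
#' base-pair distance between two independent draws from the ensemble,
#' `2 * sum_{i<j} p_ij (1 - p_ij)`.
#'
#' @param e_mfe MFE energy.
#' @param G ensemble free energy.
#' @param bpp base-pair probability matrix.
#' @param model an [energy_model()].
#' @return list (`mfe_frequency`, `ensemble_diversity`).
#' @export
ensemble_stats <- function(e_mfe, G, bpp, model = energy_model()) {
  freq <- exp(-(e_mfe - G) / model$RT)
  p <- bpp[upper.tri(bpp)]
  list(mfe_frequency = freq, ensemble_diversity = 2 * sum(p * (1 - p)))
}

#' Fold one sequence and report all ensemble statistics
#'
#' @inheritParams mfe_fold
#' @return list (`structure`, `e_mfe`, `G`, `bpp`, `mfe_frequency`,
#'   `ensemble_diversity`, `length`).
#' @export
fold_sequence <- function(seq, model = energy_model()) {
  mfe <- mfe_fold(seq, model)
  pf <- partition_function(seq, model)
  es <- ensemble_stats(mfe$energy, pf$G, pf$bpp, model)
  list(structure = mfe$structure, e_mfe = mfe$energy, G = pf$G,
       bpp = pf$bpp, mfe_frequency = es$mfe_frequency,
       ensemble_diversity = es$ensemble_diversity, length = nchar(seq))
}

#' Energy of one explicit structure (reference evaluator)
#'
#' Loop-decomposition energy of a given pair set, written independently
#' of the dynamic programs: hairpins, stacks, internal/bulge loops and
#' multiloops are identified from the nesting tree and scored directly.
#' Used by the exhaustive enumeration oracle.
#'
#' @param pairs integer matrix with columns `i`, `j` (1-based, i < j);
#'   zero rows for the open chain.
#' @param n sequence length.
#' @param enc encoded sequence (internal 0..3 alphabet).
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(pairs, n, enc, model = energy_model()) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(0)
  }
  np <- nrow(pairs)
  st <- unname(model$stack)
  # immediate enclosing pair of each pair (smallest strictly containing span)
  parent <- rep(0L, np)
  for (a in seq_len(np)) {
    best <- 0L; bw <- Inf
    for (b in seq_len(np)) {
      if (b == a) next
      if (pairs[b, 1] < pairs[a, 1] && pairs[a, 2] < pairs[b, 2]) {
        w <- pairs[b, 2] - pairs[b, 1]
        if (w < bw) { bw <- w; best <- b }
      }
    }
    parent[a] <- best
  }
  e <- 0
  for (a in seq_len(np)) {
    i <- pairs[a, 1]; j <- pairs[a, 2]
    kids <- which(parent == a)
    if (length(kids) == 0L) {
      e <- e + model$hairpin_a + model$hairpin_b * (j - i - 1L)
    } else if (length(kids) == 1L) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      if (k == i + 1L && l == j - 1L) {
        pt_out <- .pair_type(enc[i], enc[j])
        pt_in <- .pair_type(enc[k], enc[l])
        e <- e + st[pt_out, pt_in]
      } else {
        e <- e + model$internal_a +
          model$internal_b * ((k - i - 1L) + (j - l - 1L))
      }
    } else {
      unpaired <- (j - i - 1L) - sum(pairs[kids, 2] - pairs[kids, 1] + 1L)
      e <- e + model$multi_a + model$multi_b * (length(kids) + 1L) +
        model$multi_c * unpaired
    }
  }
  e
}

#' Exhaustively enumerate the structure ensemble
#'
#' Generates every nested, `hmin`-respecting secondary structure of a
#' short sequence, evaluates each with [structure_energy()] and returns
#' the exact ensemble: partition function, pair probabilities, MFE,
#' ensemble free energy, MFE frequency, and the ensemble diversity
#' computed directly as the Boltzmann-weighted mean pairwise base-pair
#' distance. This is the independent oracle for the dynamic programs; a
#' combinatorial guard restricts it to sequences of length at most
#' `max_len`.
#'
#' @inheritParams mfe_fold
#' @param max_len guard (default 16).
#' @return list (`structures`, `energies`, `Z`, `bpp`, `e_mfe`, `G`,
#'   `mfe_frequency`, `ensemble_diversity`, `n_structures`).
#' @export
enumerate_structures <- function(seq, model = energy_model(),
                                 max_len = 16L) {
  enc <- .encode_rna(seq)
  n <- length(enc)
  if (n > max_len) {
    stop("enumeration limited to length <= ", max_len)
  }
  h <- model$hmin
  pairable <- function(i, j)
    !is.na(.pair_type(enc[i], enc[j], wobble = model$wobble))
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i + 1L < h + 2L) {
      return(list(matrix(integer(0), 0, 2)))
    }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) {
      return(got)
    }
    res <- lapply(gen(i + 1L, j), identity) # i unpaired
    for (l in seq(i + h + 1L, j)) {
      if (!pairable(i, l)) next
      inner <- gen(i + 1L, l - 1L)
      rest <- if (l + 1L <= j) gen(l + 1L, j) else
        list(matrix(integer(0), 0, 2))
      for (si in inner) {
        for (sr in rest) {
          res[[length(res) + 1L]] <- rbind(c(i, l), si, sr)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  structs <- if (n >= 2L) gen(1L, n) else list(matrix(integer(0), 0, 2))
  energies <- vapply(structs, structure_energy, numeric(1), n = n,
                     enc = enc, model = model)
  RT <- model$RT
  wts <- exp(-energies / RT)
  Z <- sum(wts)
  probs <- wts / Z
  bpp <- matrix(0, n, n)
  for (s in seq_along(structs)) {
    ps <- structs[[s]]
    if (nrow(ps) > 0L) {
      for (r in seq_len(nrow(ps))) {
        bpp[ps[r, 1], ps[r, 2]] <- bpp[ps[r, 1], ps[r, 2]] + probs[s]
      }
    }
  }
  bpp <- bpp + t(bpp)
  e_mfe <- min(energies)
  G <- -RT * log(Z)
  # diversity straight from the definition: the Boltzmann-weighted mean
  # pairwise distance sum_{a,b} p_a p_b |S_a xor S_b|, evaluated over the
  # full cross table of enumerated structures
  keys <- lapply(structs, function(ps) {
    if (nrow(ps) == 0L) character(0) else paste(ps[, 1], ps[, 2])
  })
  universe <- unique(unlist(keys))
  M <- length(structs)
  if (length(universe) > 0L) {
    X <- matrix(0, M, length(universe))
    for (a in seq_len(M)) {
      X[a, match(keys[[a]], universe)] <- 1
    }
    sz <- rowSums(X)
    common <- X %*% t(X)               # |S_a intersect S_b|
    dist <- outer(sz, sz, "+") - 2 * common
    div <- as.numeric(t(probs) %*% dist %*% probs)
  } else {
    div <- 0
  }
  list(structures = structs, energies = energies, Z = Z, bpp = bpp,
       e_mfe = e_mfe, G = G,
       mfe_frequency = exp(-(e_mfe - G) / RT),
       ensemble_diversity = div, n_structures = M)
}
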