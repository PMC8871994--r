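# independent count of nested, h-respecting structures (pure recursion on
# pairability, no energies) -- used to check the enumeration itself
count_structures <- function(seq, h = 3) {
  v <- strsplit(transcribe(seq), "")[[1]]
  can_pair <- function(a, b) {
    paste0(v[a], v[b]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env()
  cnt <- function(i, j) {
    if (j - i < h + 1) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (l in (i + h + 1):j) {
      if (can_pair(i, l)) {
        total <- total + cnt(i + 1, l - 1) * (if (l < j) cnt(l + 1, j) else 1)
      }
    }
    memo[[key]] <- total
    total
  }
  cnt(1, length(v))
}

test_that("unpairable sequences are open chains with a trivial ensemble", {
  f <- fold_sequence("AAAA")
  expect_identical(f$e_mfe, 0)
  expect_identical(f$structure, "....")
  expect_identical(f$mfe_frequency, 1)
  expect_identical(f$ensemble_diversity, 0)
  en <- enumerate_structures("AAAA")
  expect_identical(en$n_structures, 1L)
  expect_true(all(en$bpp == 0))
})

test_that("the minimum hairpin size limits pairing", {
  en <- enumerate_structures("GGGAAACCC")
  max_pairs <- max(vapply(en$structures, nrow, integer(1)))
  expect_identical(max_pairs, 3L)
  # h = 3 means no pair with fewer than 3 unpaired bases inside
  expect_identical(enumerate_structures("GAAAC")$n_structures, 2L)
  expect_identical(enumerate_structures("GAAC")$n_structures, 1L)
})

test_that("enumeration agrees with an independent structure count", {
  for (s in c("GCGCAAAAGCGC", "GGGAAACCC", "AUAUAUAUAU", "ACGUACGUACGU")) {
    expect_identical(enumerate_structures(s)$n_structures,
                     as.integer(count_structures(s)), label = s)
  }
})

test_that("invalid characters are rejected", {
  expect_error(mfe_fold("ACGX"), "invalid")
})

test_that("DP fold and partition function match exhaustive enumeration", {
  set.seed(19)
  model <- energy_model()
  for (i in 1:60) {
    n <- sample(5:14, 1)
    gc <- sample(c(0.3, 0.5, 0.7), 1)
    s <- random_dna(n, gc)
    en <- enumerate_structures(s, model)
    mf <- mfe_fold(s, model)
    pf <- partition_function(s, model)
    es <- ensemble_stats(mf$energy, pf$G, pf$bpp, model)
    expect_lt(abs(mf$energy - en$e_mfe), 1e-6)
    expect_lt(abs(pf$G - en$G), 1e-6)
    expect_lt(max(abs(pf$bpp - en$bpp)), 1e-6)
    expect_lt(abs(es$mfe_frequency - en$mfe_frequency), 1e-6)
    expect_lt(abs(es$ensemble_diversity - en$ensemble_diversity), 1e-6)
  }
})

test_that("the MFE structure is valid and its energy matches the evaluator", {
  set.seed(23)
  model <- energy_model()
  for (i in 1:25) {
    s <- random_dna(sample(15:60, 1), 0.55)
    mf <- mfe_fold(s, model)
    pairs <- which(!is.na(mf$pairs) & mf$pairs > seq_along(mf$pairs))
    pm <- cbind(pairs, mf$pairs[pairs])
    # well-nested, h-respecting
    if (nrow(pm) > 0) {
      expect_true(all(pm[, 2] - pm[, 1] - 1 >= model$hmin))
    }
    ev <- structure_energy(pm, nchar(s), protogenr:::.encode_rna(s), model)
    expect_lt(abs(ev - mf$energy), 1e-6)
    # the ensemble free energy never exceeds the MFE
    pf <- partition_function(s, model)
    expect_lte(pf$G, mf$energy + 1e-9)
    fr <- ensemble_stats(mf$energy, pf$G, pf$bpp, model)$mfe_frequency
    expect_gt(fr, 0)
    expect_lte(fr, 1 + 1e-12)
  }
})

test_that("reverse complements fold to the same minimum under Watson-Crick pairing", {
  # reverse-complementation maps GC<->CG and AU<->UA but destroys GU
  # wobble pairs, so the mirror symmetry holds exactly in the
  # Watson-Crick-only ensemble
  wc <- energy_model(wobble = FALSE)
  set.seed(29)
  for (i in 1:15) {
    s <- random_dna(sample(10:40, 1), 0.5)
    rc <- revcomp(s)
    expect_equal(mfe_fold(s, wc)$energy, mfe_fold(rc, wc)$energy,
                 tolerance = 1e-9)
  }
  # and the wobble-free DP still matches its enumeration oracle
  for (i in 1:10) {
    s <- random_dna(sample(6:13, 1), 0.5)
    en <- enumerate_structures(s, wc)
    expect_lt(abs(mfe_fold(s, wc)$energy - en$e_mfe), 1e-6)
    expect_lt(abs(partition_function(s, wc)$G - en$G), 1e-6)
  }
})

test_that("longer random sequences fold to stochastically lower minimum energies", {
  set.seed(37)
  lens <- rep(c(20L, 40L, 60L, 80L, 100L), each = 12)
  e <- vapply(lens, function(n) mfe_fold(random_dna(n, 0.5))$energy,
              numeric(1))
  ct <- suppressWarnings(cor.test(lens, e, method = "spearman"))
  expect_lt(ct$estimate, -0.5)
  expect_lt(ct$p.value, 1e-6)
})

test_that("the high-temperature ensemble approaches the uniform structure ensemble", {
  hot <- energy_model(temperature = 1e7)
  set.seed(41)
  for (i in 1:10) {
    s <- random_dna(sample(8:13, 1), 0.6)
    en <- enumerate_structures(s, hot)
    pf <- partition_function(s, hot)
    # uniform-ensemble pairing fractions from the enumeration
    expect_lt(max(abs(pf$bpp - en$bpp)), 1e-6)
    expect_lt(abs(en$Z - en$n_structures), 1e-3 * en$n_structures)
  }
})
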