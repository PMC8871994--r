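# The statistical toolkit used across the report: variance F test for
# routing, Student/Welch two-sample t, Kruskal-Wallis, OLS over age
# ranks. Thin, typed wrappers over the base R tests.

.test_result <- function(test, statistic, df, p_value, ...) {
  c(list(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value)), list(...))
}

#' Variance-ratio (Fisher) test
#'
#' `F = s2_x / s2_y` with an F-distribution p-value; used to decide
#' between the Student and Welch two-sample tests. If both samples have
#' zero variance the ratio is undefined and `NA` is returned (the router
#' then falls back to Welch).
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list (`test`, `statistic`, `df` = c(df1, df2), `p_value`).
#' @export
f_variance_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(.test_result("F", NA_real_, c(length(x) - 1L, length(y) - 1L),
                        NA_real_))
  }
  r <- stats::var.test(x, y)
  .test_result("F", r$statistic, r$parameter, r$p.value)
}

#' Two-sample t tests
#'
#' `student_t` assumes equal variances; `welch_t` uses the
#' Welch-Satterthwaite degrees of freedom. Two-sided p-values. Fully
#' degenerate input (both samples constant and equal) returns `t = 0`,
#' `p = 1`.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return list (`test`, `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`).
#' @export
student_t <- function(x, y) {
  .t_wrap(x, y, var.equal = TRUE, name = "student_t")
}

#' @rdname student_t
#' @export
welch_t <- function(x, y) {
  .t_wrap(x, y, var.equal = FALSE, name = "welch_t")
}

.t_wrap <- function(x, y, var.equal, name) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(.test_result(name, 0, length(x) + length(y) - 2L, 1,
                          mean_x = mean(x), mean_y = mean(y)))
    }
    return(.test_result(name, ifelse(mean(x) > mean(y), Inf, -Inf),
                        length(x) + length(y) - 2L, 0,
                        mean_x = mean(x), mean_y = mean(y)))
  }
  r <- stats::t.test(x, y, var.equal = var.equal)
  .test_result(name, r$statistic, r$parameter, r$p.value,
               mean_x = mean(x), mean_y = mean(y))
}

#' Variance-routed two-sample test
#'
#' Applies the routing rule used throughout the report: Fisher variance
#' test first; equal variances (p >= alpha) send the comparison to the
#' Student test, unequal variances to Welch. Ambiguous routing (an
#' undefined variance ratio) defaults to Welch.
#'
#' @param x,y numeric samples.
#' @param alpha routing level (default 0.05).
#' @return a test result as in [student_t()], with `routed_by` added.
#' @export
two_sample_test <- function(x, y, alpha = 0.05) {
  f <- f_variance_test(x, y)
  out <- if (is.na(f$p_value) || f$p_value < alpha) {
    welch_t(x, y)
  } else {
    student_t(x, y)
  }
  out$routed_by <- f$p_value
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction and a chi-square p-value. All
#' observations identical gives `H = 0`, `p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return list (`test`, `statistic`, `df`, `p_value`).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    return(.test_result("kruskal_wallis", 0, length(groups) - 1L, 1))
  }
  r <- stats::kruskal.test(groups)
  .test_result("kruskal_wallis", r$statistic, r$parameter, r$p.value)
}

#' Ordinary least squares over age ranks
#'
#' Least-squares intercept and slope of `y` on `x` (typically the age
#' rank 0..5), with the slope's standard error and 95% confidence
#' interval.
#'
#' @param x numeric predictor (must not be constant).
#' @param y numeric response, same length.
#' @return list (`intercept`, `slope`, `se_slope`, `ci_low`, `ci_high`,
#'   `residual_variance`, `n`, `p_value`).
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::var(x) == 0) {
    stop("constant predictor: slope undefined")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit, "x", level = 0.95)
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       se_slope = unname(co[2, 2]), ci_low = ci[1], ci_high = ci[2],
       residual_variance = sm$sigma^2, n = length(x),
       p_value = unname(co[2, 4]))
}

#' Assemble the stratified report
#'
#' A pure function of the stage outputs: collects one tidy table per
#' analysis, keyed by (age class, genomic position) where applicable,
#' with deterministic ordering; missing stages appear as explicit `NULL`
#' gaps rather than being dropped.
#'
#' @param introns intron summary table ([intron_summary()]).
#' @param recycling recycled-introns result ([find_recycled_introns()]).
#' @param motifs motif comparison ([compare_datasets()] result plus the
#'   promoter/enhancer split).
#' @param utrs UTR/fold summary ([utr_summary()] result).
#' @param clusters protein-cluster summary ([cluster_summary()] result).
#' @return list of class `protogene_report`.
#' @export
build_report <- function(introns = NULL, recycling = NULL, motifs = NULL,
                         utrs = NULL, clusters = NULL) {
  structure(list(introns = introns, recycling = recycling, motifs = motifs,
                 utrs = utrs, clusters = clusters),
            class = "protogene_report")
}

#' Write report tables as TSV
#'
#' Deterministic writer (fixed column order, fixed row order, 10
#' significant digits): identical report objects produce byte-identical
#' files.
#'
#' @param report a `protogene_report`.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) {
      return(NULL)
    }
    path <- file.path(dir, paste0(name, ".tsv"))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) {
      ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g"))
    })
    con <- file(path, open = "wb")
    writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
    if (nrow(df) > 0L) {
      writeLines(do.call(paste, c(lapply(df, as.character),
                                  list(sep = "\t"))), con, sep = "\n")
    }
    close(con)
    paths <<- c(paths, path)
  }
  emit(report$introns$summary, "introns_by_stratum")
  emit(report$recycling$recycled, "intron_recycling")
  emit(report$recycling$hits, "intron_recycling_hits")
  emit(report$motifs$summary, "motif_dataset_means")
  emit(report$motifs$tests, "motif_dataset_tests")
  emit(report$motifs$by_stratum, "motif_by_stratum")
  emit(report$utrs$summary, "utr_group_means")
  emit(report$utrs$tests, "utr_group_tests")
  emit(report$clusters$by_stratum, "clusters_by_stratum")
  emit(report$clusters$by_age, "clusters_by_age")
  invisible(paths)
}
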