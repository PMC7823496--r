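# Temperature-series aggregation and per-temperature genotype comparisons.

#' Aggregate replicate measurements into per-temperature mean and SE
#'
#' Technical replicates nested in biological replicates are averaged within
#' each biological replicate first; the reported mean and standard error
#' (sample SD / sqrt(n)) are then taken across the biological-replicate
#' means.
#'
#' @param data A data frame in long format.
#' @param value Name of the value column (e.g. `"S"`, `"tau2B_s"`).
#' @param temperature Name of the measurement-temperature column.
#' @param bio Name of the biological-replicate column, or `NULL` if every
#'   row is already an independent replicate.
#' @return A data frame with one row per temperature: the temperature
#'   column, `n` (biological replicates), `mean`, `se` (0 for n = 1... `NA`
#'   is never produced; a single replicate reports `se = NA`).
#' @examples
#' d <- data.frame(T = c(0, 0, 0), bio = c(1, 1, 2), v = c(1, 3, 2))
#' aggregate_replicates(d, "v", "T", "bio")
#' @export
aggregate_replicates <- function(data, value, temperature = "measurement_temperature_C",
                                 bio = NULL) {
  stopifnot(is.data.frame(data), value %in% names(data),
            temperature %in% names(data))
  if (!is.null(bio) && !bio %in% names(data)) stop("column not found: ", bio)
  data <- data[!is.na(data[[value]]), , drop = FALSE]
  if (nrow(data) == 0L) stop("no non-missing values to aggregate")
  per_temp <- split(data, data[[temperature]])
  rows <- lapply(per_temp, function(d) {
    vals <- if (is.null(bio)) d[[value]] else {
      vapply(split(d[[value]], d[[bio]]), mean, 0)
    }
    n <- length(vals)
    data.frame(temperature = d[[temperature]][1L], n = n, mean = mean(vals),
               se = if (n > 1L) stats::sd(vals) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, rows)
  names(out)[1L] <- temperature
  out <- out[order(out[[temperature]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pooled-variance two-sample Student's t, two-sided. Degenerate samples
# (zero pooled variance) give t = 0 / p = 1 when the means agree and
# p = 0 with a degeneracy flag when they differ.
student_t_compare <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 replicates per group")
  }
  degenerate <- FALSE
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      tt <- list(statistic = 0, p.value = 1, parameter = length(x) + length(y) - 2)
    } else {
      degenerate <- TRUE
      tt <- list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                 parameter = length(x) + length(y) - 2)
    }
  } else {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
               parameter = unname(ht$parameter))
  }
  data.frame(mean_a = mean(x), mean_b = mean(y),
             se_a = stats::sd(x) / sqrt(length(x)),
             se_b = stats::sd(y) / sqrt(length(y)),
             t_statistic = tt$statistic, df = tt$parameter,
             p_value = tt$p.value,
             significant = tt$p.value <= alpha,
             degenerate = degenerate)
}

#' Per-temperature genotype comparison (Student's t-test)
#'
#' For every measurement temperature shared by the two series, runs a
#' two-sided pooled-variance Student's t-test on the replicate values and
#' flags significance at `p <= alpha`. This mirrors the convention of
#' comparing two genotypes separately at each EPR measurement temperature;
#' no multiple-testing correction is applied across temperatures (each
#' temperature is reported as its own comparison), which the caller should
#' keep in mind when reading long series.
#'
#' @param series_a,series_b Data frames with a temperature column and a value
#'   column holding biological-replicate values (one row per replicate).
#'   Flagged/`NA` values should be excluded upstream (e.g. out-of-range S).
#' @param value,temperature Column names, as in [aggregate_replicates()].
#' @param alpha Significance level; default 0.05, applied as `p <= alpha`.
#' @return A data frame ordered by temperature with columns
#'   `measurement_temperature_C`, `mean_a`, `mean_b`, `se_a`, `se_b`,
#'   `t_statistic`, `df`, `p_value`, `significant`, `degenerate`, `letters_a`,
#'   `letters_b` (same letter iff not significant, as in composition tables).
#' @examples
#' a <- data.frame(T = rep(c(0, 5), each = 3), v = c(1, 2, 3, 4, 5, 6))
#' b <- data.frame(T = rep(c(0, 5), each = 3), v = c(1, 2, 3, 9, 10, 11))
#' compare_genotypes(a, b, value = "v", temperature = "T")
#' @export
compare_genotypes <- function(series_a, series_b, value = "value",
                              temperature = "measurement_temperature_C",
                              alpha = 0.05) {
  stopifnot(value %in% names(series_a), value %in% names(series_b),
            temperature %in% names(series_a), temperature %in% names(series_b))
  ta <- unique(series_a[[temperature]])
  tb <- unique(series_b[[temperature]])
  shared <- sort(intersect(ta, tb))
  if (length(shared) == 0L) stop("temperature grids do not overlap")
  rows <- lapply(shared, function(tt) {
    x <- series_a[[value]][series_a[[temperature]] == tt]
    y <- series_b[[value]][series_b[[temperature]] == tt]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    cmp <- student_t_compare(x, y, alpha)
    cbind(data.frame(measurement_temperature_C = tt), cmp)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) stop("no temperature with >= 2 replicates in both groups")
  out <- do.call(rbind, rows)
  out$letters_a <- "a"
  out$letters_b <- ifelse(out$significant, "b", "a")
  rownames(out) <- NULL
  out
}

#' Two-condition comparison for one genotype
#'
#' The same pooled-variance Student's t machinery as [compare_genotypes()],
#' applied to one genotype measured under two conditions (e.g. growth at
#' 20 vs 5 degrees C for a brassinosteroid or composition table).
#'
#' @param values_a,values_b Numeric replicate values for the two conditions
#'   (>= 2 each).
#' @param alpha Significance level (`p <= alpha`).
#' @return A one-row data frame with `mean_a`, `mean_b`, `se_a`, `se_b`,
#'   `t_statistic`, `df`, `p_value`, `significant`, `degenerate`.
#' @export
paired_condition_compare <- function(values_a, values_b, alpha = 0.05) {
  student_t_compare(values_a, values_b, alpha)
}
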