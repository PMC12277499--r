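#' Per-patient, per-organ measurements from several methods
#'
#' A long-format table of SUV measurements where each `(patient, organ,
#' method)` combination appears at most once. Used for method-agreement
#' summaries between a commercial workflow and this package's VOI and
#' whole-organ contour measurements.
#'
#' @param df data.frame with columns `patient`, `organ`, `method`,
#'   `value`.
#' @return A `paired_measurement_table` (a classed data.frame).
#' @export
paired_measurement_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("patient", "organ", "method", "value")
  if (!all(need %in% names(df))) {
    stop("table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  key <- paste(df$patient, df$organ, df$method, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient, organ, method) rows", call. = FALSE)
  }
  class(df) <- c("paired_measurement_table", "data.frame")
  df
}

# Tolerant matching of organ/method labels: case-insensitive, ignoring
# punctuation and whitespace, so "Breast_R", "Breast (right)" and
# "breast right" resolve against the table's own spelling.
normalize_label <- function(x) {
  x <- tolower(gsub("[^[:alnum:]]", "", x))
  x <- sub("breastright$|breastr$|rightbreast$", "breastright", x)
  x <- sub("breastleft$|breastl$|leftbreast$", "breastleft", x)
  x
}

match_label <- function(wanted, available, what) {
  hit <- which(normalize_label(available) == normalize_label(wanted))
  if (!length(hit)) {
    stop(sprintf("%s '%s' not found; available: %s", what, wanted,
                 paste(unique(available), collapse = ", ")), call. = FALSE)
  }
  available[hit[1]]
}

#' Extract one method's values for one organ, keyed by patient
#'
#' @param table a [paired_measurement_table()].
#' @param method,organ labels (matched tolerantly to the table spelling).
#' @return Named numeric vector of values, names = patient ids.
#' @export
table_values <- function(table, method, organ) {
  stopifnot(inherits(table, "paired_measurement_table"))
  organ <- match_label(organ, table$organ, "organ")
  method <- match_label(method, table$method, "method")
  sub <- table[table$organ == organ & table$method == method, ]
  stats::setNames(sub$value, as.character(sub$patient))
}

#' Mean and spread of absolute between-method differences
#'
#' For one organ, pairs the two methods' values by patient and summarizes
#' the absolute differences: the mean, and the population standard
#' deviation (divisor n) of the absolute differences — the convention
#' that reproduces the printed "mean±sd" summary rows of the study
#' tables (sample sd with divisor n-1 does not).
#'
#' @param table a [paired_measurement_table()].
#' @param method_a,method_b method labels.
#' @param organ organ label.
#' @return List with `mean`, `sd`, `n`, and the per-patient absolute
#'   `differences`.
#' @examples
#' t2 <- load_table_fixture("table2")
#' s <- abs_diff_summary(t2, "MIM", "contour", "Breast_R")
#' round(c(s$mean, s$sd), 2)  # 0.34 0.27
#' @export
abs_diff_summary <- function(table, method_a, method_b, organ) {
  a <- table_values(table, method_a, organ)
  b <- table_values(table, method_b, organ)
  missing_a <- setdiff(names(b), names(a))
  missing_b <- setdiff(names(a), names(b))
  if (length(missing_a) || length(missing_b)) {
    stop("unpaired patients: ",
         paste(sort(unique(c(missing_a, missing_b))), collapse = ", "),
         call. = FALSE)
  }
  d <- abs(a - b[names(a)])
  list(mean = mean(d),
       sd = sqrt(mean((d - mean(d))^2)),
       n = length(d),
       differences = d)
}

#' Aggregate per-organ mean differences into one figure
#'
#' Unweighted mean of the per-organ mean absolute differences, with
#' their range — the "average difference (range, lo–hi)" aggregate the
#' study reports across organs.
#'
#' @param summaries list of [abs_diff_summary()] results (or any list of
#'   lists with a `mean` element), or a bare numeric vector of organ
#'   means.
#' @return List with `mean`, `min`, `max`.
#' @export
grand_mean_of_organ_means <- function(summaries) {
  if (is.numeric(summaries)) {
    means <- summaries
  } else {
    means <- vapply(summaries, function(s) as.numeric(s$mean), 0)
  }
  if (!length(means)) stop("no organ summaries given", call. = FALSE)
  list(mean = mean(means), min = min(means), max = max(means))
}

#' Method-agreement report across all organs of a table
#'
#' Convenience wrapper running [abs_diff_summary()] for every organ in
#' the table and appending the [grand_mean_of_organ_means()] aggregate.
#'
#' @param table a [paired_measurement_table()].
#' @param method_a,method_b method labels.
#' @return data.frame with one row per organ (mean, sd) plus an
#'   `"(average)"` row holding the aggregate mean and range as sd = NA.
#' @export
agreement_report <- function(table, method_a, method_b) {
  organs <- unique(table$organ)
  sums <- lapply(organs, function(o) abs_diff_summary(table, method_a, method_b, o))
  agg <- grand_mean_of_organ_means(sums)
  data.frame(
    organ = c(organs, "(average)"),
    mean_abs_diff = c(vapply(sums, `[[`, 0, "mean"), agg$mean),
    sd_abs_diff = c(vapply(sums, `[[`, 0, "sd"), NA_real_),
    min = c(rep(NA_real_, length(organs)), agg$min),
    max = c(rep(NA_real_, length(organs)), agg$max))
}
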