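# 2x2 contingency tables and the concordance-statistic suite with
# percentile-bootstrap confidence intervals.
#
# Conventions: all metrics are fractions in [0,1] (kappa in [-1,1]); a
# metric whose denominator is empty is "undefined" and represented as
# NA_real_, never as 0 and never as an error — the bootstrap machinery
# drops undefined replicates and reports how many were dropped.

ACCURACY_METRICS <- c("percent_agreement", "aucr", "sensitivity",
                      "specificity", "npv", "ppv", "kappa")

#' Build a 2x2 contingency table
#'
#' Cross-tabulates reference-method against test-method labels for one
#' comparison (`overall` diagnosis or one of the `SE`/`OE`/`DE` subtypes).
#' Subtype comparisons use all participants: the subtype-negative class
#' contains both non-cases and cases of other subtypes.
#'
#' @param reference,test Label data frames as returned by
#'   [reference_labels()] and [test_labels()]; they must cover the same
#'   participant set.
#' @param key One of `"overall"`, `"SE"`, `"OE"`, `"DE"`.
#' @return A `contingency_table`: a list with integer fields `tp`, `fp`,
#'   `fn`, `tn` summing to the number of participants.
#' @export
build_contingency <- function(reference, test, key = "overall") {
  key <- match.arg(key, COMPARISONS)
  if (!setequal(reference$participant_id, test$participant_id) ||
      nrow(reference) != nrow(test)) {
    stop("reference and test labels cover different participant sets")
  }
  ord <- match(reference$participant_id, test$participant_id)
  r <- reference[[key]]
  t <- test[[key]][ord]
  contingency_table(tp = sum(r & t), fp = sum(!r & t),
                    fn = sum(r & !t), tn = sum(!r & !t))
}

#' @rdname build_contingency
#' @param tp,fp,fn,tn Non-negative cell counts (true positive, false
#'   positive, false negative, true negative).
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  cells <- as.integer(cells)
  structure(list(tp = cells[1L], fp = cells[2L], fn = cells[3L],
                 tn = cells[4L]),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(reference = c("positive", "negative"),
                              test = c("positive", "negative")))
  print(m)
  invisible(x)
}

ct_n <- function(t) t$tp + t$fp + t$fn + t$tn

#' Diagnostic accuracy metrics for a 2x2 table
#'
#' The standard conditional-probability metrics of a binary test against a
#' reference standard, plus chance-corrected agreement:
#' \itemize{
#'   \item `sensitivity(t)` = tp / (tp + fn)
#'   \item `specificity(t)` = tn / (tn + fp)
#'   \item `ppv(t)` = tp / (tp + fp); `npv(t)` = tn / (tn + fn)
#'   \item `percent_agreement(t)` = (tp + tn) / N (a fraction; multiply by
#'     100 for display)
#'   \item `aucr(t)` = (sensitivity + specificity) / 2 — for a single
#'     dichotomous test the empirical ROC curve has one interior operating
#'     point, and the trapezoidal area under it equals balanced accuracy.
#'   \item `cohens_kappa(t)` = (p_o - p_e) / (1 - p_e), with observed
#'     agreement p_o = (tp + tn)/N and chance agreement
#'     p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / N^2.
#' }
#' A metric with an empty denominator returns `NA_real_` (undefined), not 0.
#' For kappa, `p_e = 1` (both raters constant) is defined as 1 when
#' agreement is perfect and undefined otherwise; N = 0 is an error.
#'
#' @param t A `contingency_table`.
#' @return A numeric scalar (fraction; kappa in `[-1, 1]`).
#' @name accuracy_metrics
NULL

#' @rdname accuracy_metrics
#' @export
sensitivity <- function(t) if ((t$tp + t$fn) == 0L) NA_real_ else t$tp / (t$tp + t$fn)

#' @rdname accuracy_metrics
#' @export
specificity <- function(t) if ((t$tn + t$fp) == 0L) NA_real_ else t$tn / (t$tn + t$fp)

#' @rdname accuracy_metrics
#' @export
ppv <- function(t) if ((t$tp + t$fp) == 0L) NA_real_ else t$tp / (t$tp + t$fp)

#' @rdname accuracy_metrics
#' @export
npv <- function(t) if ((t$tn + t$fn) == 0L) NA_real_ else t$tn / (t$tn + t$fn)

#' @rdname accuracy_metrics
#' @export
percent_agreement <- function(t) {
  n <- ct_n(t)
  if (n == 0L) NA_real_ else (t$tp + t$tn) / n
}

#' @rdname accuracy_metrics
#' @export
aucr <- function(t) {
  se <- sensitivity(t)
  sp <- specificity(t)
  if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
}

#' @rdname accuracy_metrics
#' @export
cohens_kappa <- function(t) {
  n <- ct_n(t)
  if (n == 0L) stop("cohens_kappa() is undefined for an empty table")
  p_o <- (t$tp + t$tn) / n
  p_e <- ((t$tp + t$fp) * (t$tp + t$fn) + (t$fn + t$tn) * (t$fp + t$tn)) / n^2
  if (p_e == 1) {
    if (p_o == 1) return(1)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  switch(match.arg(metric, ACCURACY_METRICS),
         percent_agreement = percent_agreement, aucr = aucr,
         sensitivity = sensitivity, specificity = specificity,
         npv = npv, ppv = ppv, kappa = cohens_kappa)
}

# One bootstrap pass: resample participants (paired labels travel
# together), recompute the 2x2 cell counts per comparison, apply `fun`.
resample_metric <- function(r, t, fun, B) {
  n <- length(r)
  out <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rb <- r[idx]
    tb <- t[idx]
    tab <- contingency_table(tp = sum(rb & tb), fp = sum(!rb & tb),
                             fn = sum(rb & !tb), tn = sum(!rb & !tb))
    out[b] <- fun(tab)
  }
  out
}

percentile_ci <- function(values, ci_level) {
  alpha <- (1 - ci_level) / 2
  q <- stats::quantile(values, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = q[1L], upper = q[2L])
}

#' Percentile-bootstrap confidence interval for one metric
#'
#' Resamples participants with replacement `bootstrap_reps` times (paired
#' reference/test labels travel together, preserving the agreement
#' structure), recomputes the metric on each replicate, and takes the
#' empirical percentile interval (2.5th/97.5th percentiles at `ci_level =
#' 0.95`) over the defined replicates. Replicates where the metric is
#' undefined (empty denominator) are dropped and counted; more than 50%
#' undefined replicates is an error advising a larger sample. The resampling
#' is seeded from `config$rng_seed` and fully reproducible.
#'
#' @inheritParams build_contingency
#' @param metric A metric name (see [accuracy_metrics]) or a function of a
#'   `contingency_table`.
#' @param config A [run_config()] supplying `bootstrap_reps`, `ci_level`,
#'   `rng_seed`.
#' @return A list with `lower`, `upper` and `n_undefined`.
#' @export
bootstrap_ci <- function(reference, test, metric, config = run_config(),
                         key = "overall") {
  key <- match.arg(key, COMPARISONS)
  if (nrow(reference) < 2L) stop("bootstrap requires at least 2 participants")
  ord <- match(reference$participant_id, test$participant_id)
  if (anyNA(ord)) stop("reference and test labels cover different participant sets")
  r <- reference[[key]]
  t <- test[[key]][ord]
  fun <- metric_fun(metric)
  values <- with_rng_seed(config$rng_seed,
                          resample_metric(r, t, fun, config$bootstrap_reps))
  n_undef <- sum(is.na(values))
  if (n_undef > length(values) / 2) {
    stop(sprintf("metric undefined in %d of %d bootstrap replicates; a larger sample is needed",
                 n_undef, length(values)))
  }
  ci <- percentile_ci(values[!is.na(values)], config$ci_level)
  list(lower = ci$lower, upper = ci$upper, n_undefined = n_undef)
}

#' Full accuracy report: seven metrics by four comparisons
#'
#' Computes percent agreement, AUCR, sensitivity, specificity, NPV, PPV and
#' Cohen's kappa — each with a percentile-bootstrap CI — for the overall
#' diagnosis and the SE/OE/DE subtype comparisons. All comparisons use all
#' participants (a subtype-negative participant may be a non-case or a case
#' of another subtype). One set of bootstrap resamples per comparison is
#' shared across the seven metrics, so paired structure and seeding are
#' consistent. If a metric's point estimate is undefined on the observed
#' table, its CI is reported as `NA` without error; a defined point estimate
#' with more than 50% undefined replicates raises an error.
#'
#' @inheritParams bootstrap_ci
#' @return An `accuracy_report`: a data frame with columns `comparison`,
#'   `metric`, `estimate`, `lower`, `upper`, `n_undefined`.
#' @export
full_report <- function(reference, test, config = run_config()) {
  ord <- match(reference$participant_id, test$participant_id)
  if (anyNA(ord) || nrow(reference) != nrow(test)) {
    stop("reference and test labels cover different participant sets")
  }
  rows <- list()
  funs <- lapply(ACCURACY_METRICS, metric_fun)
  names(funs) <- ACCURACY_METRICS
  with_rng_seed(config$rng_seed, {
    for (key in COMPARISONS) {
      r <- reference[[key]]
      t <- test[[key]][ord]
      obs <- contingency_table(tp = sum(r & t), fp = sum(!r & t),
                               fn = sum(r & !t), tn = sum(!r & !t))
      n <- length(r)
      B <- config$bootstrap_reps
      boot <- matrix(NA_real_, B, length(funs),
                     dimnames = list(NULL, names(funs)))
      for (b in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        rb <- r[idx]
        tb <- t[idx]
        tab <- contingency_table(tp = sum(rb & tb), fp = sum(!rb & tb),
                                 fn = sum(rb & !tb), tn = sum(!rb & !tb))
        for (m in names(funs)) boot[b, m] <- funs[[m]](tab)
      }
      for (m in names(funs)) {
        est <- funs[[m]](obs)
        vals <- boot[, m]
        n_undef <- sum(is.na(vals))
        if (is.na(est)) {
          lo <- hi <- NA_real_
        } else {
          if (n_undef > B / 2) {
            stop(sprintf("%s (%s): metric undefined in %d of %d bootstrap replicates; a larger sample is needed",
                         m, key, n_undef, B))
          }
          ci <- percentile_ci(vals[!is.na(vals)], config$ci_level)
          lo <- ci$lower
          hi <- ci$upper
        }
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = key, metric = m, estimate = est,
          lower = lo, upper = hi, n_undefined = n_undef,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("accuracy_report", "data.frame"))
}

format_cell <- function(metric, est, lo, hi) {
  if (is.na(est)) return("undefined")
  if (metric == "percent_agreement") {
    if (is.na(lo)) return(sprintf("%.1f%%", 100 * est))
    sprintf("%.1f%%(%.0f%%, %.0f%%)", 100 * est, 100 * lo, 100 * hi)
  } else {
    if (is.na(lo)) return(sprintf("%.2f", est))
    sprintf("%.2f(%.2f, %.2f)", est, lo, hi)
  }
}

#' Format an accuracy report as a text table
#'
#' Lays the report out as metric rows by comparison columns with
#' `point(lower, upper)` cells — agreement as percent at 1 decimal, all
#' other metrics at 2 decimals.
#'
#' @param report An `accuracy_report` from [full_report()].
#' @return A character vector of lines.
#' @export
format_accuracy_table <- function(report) {
  comps <- unique(report$comparison)
  header <- c("Measure", comps)
  body <- lapply(ACCURACY_METRICS, function(m) {
    cells <- vapply(comps, function(k) {
      row <- report[report$metric == m & report$comparison == k, ]
      format_cell(m, row$estimate, row$lower, row$upper)
    }, "")
    c(m, cells)
  })
  mat <- rbind(header, do.call(rbind, body))
  widths <- apply(nchar(mat), 2, max)
  apply(mat, 1, function(r) {
    paste(mapply(formatC, r, width = widths, MoreArgs = list(flag = "-")),
          collapse = "  ")
  })
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(format_accuracy_table(x), sep = "\n")
  invisible(x)
}
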