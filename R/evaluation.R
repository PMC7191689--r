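# Evaluation: overall Pearson correlation plus per-score-interval Pearson
# and mean squared error. Intervals are the five unit bins of the gold
# score, half-open with a closed top bin: [0,1) [1,2) [2,3) [3,4) [4,5].

#' Pearson correlation between predictions and gold scores
#'
#' Standard sample Pearson correlation. When either input is constant the
#' coefficient is undefined and `NA_real_` is returned (no `NaN`
#' propagation).
#'
#' @param pred,gold Equal-length numeric vectors, length >= 2.
#' @return A real in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop("pred and gold must have equal length", call. = FALSE)
  if (length(pred) < 2L) return(NA_real_)
  if (stats::sd(pred) == 0 || stats::sd(gold) == 0) return(NA_real_)
  stats::cor(pred, gold)
}

interval_labels <- function() c("[0,1)", "[1,2)", "[2,3)", "[3,4)", "[4,5]")

#' Per-interval evaluation report
#'
#' Assigns each pair to a score interval by its gold score and reports, per
#' interval: pair count, within-interval Pearson correlation (`NA` when
#' fewer than two pairs or constant input) and mean squared error; plus the
#' overall Pearson and MSE. The count-weighted mean of the per-interval
#' MSEs equals the overall MSE.
#'
#' @param pred Predicted scores.
#' @param gold Gold scores in `[0, 5]`, aligned with `pred`.
#' @return An `sts_eval` list: `overall_pearson`, `overall_mse`, `n`, and a
#'   `per_interval` data.frame with columns `interval`, `count`, `pearson`,
#'   `mse`.
#' @export
interval_report <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop("pred and gold must have equal length", call. = FALSE)
  if (any(gold < 0 | gold > 5))
    stop("gold scores must lie in [0,5]", call. = FALSE)
  iv <- score_interval(gold)
  rows <- lapply(1:5, function(k) {
    in_k <- iv == k
    n_k <- sum(in_k)
    data.frame(interval = interval_labels()[k], count = n_k,
               pearson = if (n_k >= 2L) pearson(pred[in_k], gold[in_k]) else NA_real_,
               mse = if (n_k >= 1L) mean((pred[in_k] - gold[in_k])^2) else NA_real_)
  })
  structure(list(overall_pearson = pearson(pred, gold),
                 overall_mse = mean((pred - gold)^2),
                 n = length(pred),
                 per_interval = do.call(rbind, rows)),
            class = "sts_eval")
}

#' @export
print.sts_eval <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "   -  ", sprintf("%6.4f", v))
  cat("Score interval ", paste(sprintf("%7s", x$per_interval$interval), collapse = " "),
      "  Overall\n", sep = "")
  cat("Count          ", paste(sprintf("%7d", x$per_interval$count), collapse = " "),
      sprintf("  %7d\n", x$n), sep = "")
  cat("Pearson        ", paste(sprintf("%7s", fmt(x$per_interval$pearson)), collapse = " "),
      sprintf("  %7s\n", fmt(x$overall_pearson)), sep = "")
  cat("MSE            ", paste(sprintf("%7s", fmt(x$per_interval$mse)), collapse = " "),
      sprintf("  %7s\n", fmt(x$overall_mse)), sep = "")
  invisible(x)
}

#' Write an evaluation report as text and JSON
#'
#' @param report An `sts_eval`.
#' @param path Base path: `<path>.txt` (aligned table) and `<path>.json`
#'   (structured) are written.
#' @return Character vector of the two paths, invisibly.
#' @export
write_eval_report <- function(report, path) {
  txt <- paste0(path, ".txt"); js <- paste0(path, ".json")
  con <- textConnection("captured", "w", local = TRUE)
  sink(con); print(report); sink()
  close(con)
  writeLines(captured, txt)
  jsonlite::write_json(list(overall_pearson = report$overall_pearson,
                            overall_mse = report$overall_mse, n = report$n,
                            per_interval = report$per_interval),
                       js, auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(c(txt, js))
}
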