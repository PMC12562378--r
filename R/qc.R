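#' Read per-sample exome QC metrics
#'
#' Expected TSV columns: `sample`, `mean_coverage` (x), `pct_ge20x` (%),
#' `pct_ge50x` (%), `aligned_reads` (count), `uniformity` (% of target at
#' >0.2x the sample mean).
#'
#' @param path Path to the TSV.
#' @return Tibble of per-sample metrics.
#' @export
read_qc_metrics <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(sample = "c", .default = "d")
  )
}

#' Cohort means of per-sample coverage metrics
#'
#' Arithmetic column means over samples, reported at the conventional
#' precision for sequencing QC tables: coverage depth to 3 decimals,
#' percentages to 2, aligned reads to 1.
#'
#' @param metrics Tibble from [read_qc_metrics()].
#' @return One-row tibble of rounded column means.
#' @export
summarize_coverage <- function(metrics) {
  if (nrow(metrics) == 0L) stop("no samples in QC metrics", call. = FALSE)
  num <- c("mean_coverage", "pct_ge20x", "pct_ge50x", "aligned_reads",
           "uniformity")
  missing_cols <- setdiff(num, names(metrics))
  if (length(missing_cols) > 0) {
    stop("QC metrics lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pct <- metrics[, c("pct_ge20x", "pct_ge50x", "uniformity")]
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("percentage metrics outside [0, 100]", call. = FALSE)
  }
  tibble::tibble(
    n_samples = nrow(metrics),
    mean_coverage = round_half_up(mean(metrics$mean_coverage), 3),
    pct_ge20x = round_half_up(mean(metrics$pct_ge20x), 2),
    pct_ge50x = round_half_up(mean(metrics$pct_ge50x), 2),
    aligned_reads = round_half_up(mean(metrics$aligned_reads), 1),
    uniformity = round_half_up(mean(metrics$uniformity), 2)
  )
}

#' Percentage breakdown of exonic consequence classes
#'
#' Shares of each class in the total, rounded half-up to one decimal (so a
#' 100/10/4 split reports 87.7 / 8.8 / 3.5).
#'
#' @param counts Named non-negative numeric vector of per-class counts.
#' @return Named numeric vector of percentages.
#' @export
class_breakdown <- function(counts) {
  if (length(counts) == 0L || sum(counts) == 0) {
    stop("class breakdown needs a positive total", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative class count", call. = FALSE)
  round_half_up(100 * counts / sum(counts), 1)
}
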