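#' Assemble the final analysis report
#'
#' Bundles the outputs of the pipeline stages — filtering funnels, model
#' candidate tables, twin concordance, panel screen, review verdicts —
#' into one deterministic structure ready for JSON/TSV serialization.
#' Candidates admitted by more than one model are cross-referenced via
#' `also_in_models`.
#'
#' @param funnels Named list of `funnel_result`s (e.g. one per model
#'   chain).
#' @param models Cohort table from [screen_models()] (with the model
#'   pass columns), possibly already carrying `review_verdict`.
#' @param concordance A `concordance_summary` from [twin_concordance()],
#'   or `NULL`.
#' @param panel_report A `panel_report` from [panel_screen()], or `NULL`.
#' @return A list of class `analysis_report`.
#' @export
build_report <- function(funnels = list(), models = NULL,
                         concordance = NULL, panel_report = NULL) {
  model_cols <- c("de_novo", "autosomal_recessive", "autosomal_dominant",
                  "homozygous_affected")
  candidate_tables <- list()
  model_counts <- list()
  if (!is.null(models) && nrow(models) > 0) {
    present <- intersect(model_cols, names(models))
    for (m in present) {
      hits <- models[models[[m]], , drop = FALSE]
      if (nrow(hits) > 0) {
        others <- setdiff(present, m)
        hits$also_in_models <- vapply(seq_len(nrow(hits)), function(i) {
          paste(others[vapply(others, function(o) isTRUE(hits[[o]][i]),
                              logical(1))], collapse = ";")
        }, character(1))
        hits$model <- m
        ord <- order(chrom_rank(hits$chrom), hits$pos, hits$alt)
        hits <- hits[ord, , drop = FALSE]
      }
      candidate_tables[[m]] <- hits
      model_counts[[m]] <- nrow(hits)
    }
  } else {
    for (m in model_cols) model_counts[[m]] <- 0L
  }
  structure(
    list(
      funnels = lapply(funnels, function(f) f$funnel),
      model_counts = model_counts,
      candidates = candidate_tables,
      concordance = if (!is.null(concordance)) {
        list(
          shared_count = concordance$shared_count,
          unique_to_affected = concordance$unique_to_affected,
          unique_to_unaffected = concordance$unique_to_unaffected,
          percent_shared = if (is.na(concordance$percent_shared)) NULL else
            round_half_up(concordance$percent_shared, 1)
        )
      },
      panel = if (!is.null(panel_report)) panel_report$totals
    ),
    class = "analysis_report"
  )
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the whole structure) plus TSV mirrors: one
#' candidate table per model (via [write_candidates()]) and one funnel TSV
#' per chain.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    funnels = lapply(report$funnels, function(f) {
      stats::setNames(as.list(f$count), f$stage)
    }),
    model_counts = report$model_counts,
    concordance = report$concordance,
    panel = report$panel
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (m in names(report$candidates)) {
    tab <- report$candidates[[m]]
    keep <- intersect(
      c("chrom", "pos", "ref", "alt", "gene", "func_region", "exonic_class",
        "cdna_change", "protein_change", "clinvar", COHORT_AF_COLS,
        "cadd_phred", "revel", "sift_pred", "sift_score", "polyphen2_pred",
        "polyphen2_score", "mutation_taster_pred", "mutation_taster_score",
        "gt", "model", "model_notes", "review_verdict", "also_in_models",
        "filter_status"),
      names(tab)
    )
    write_candidates(tab[, keep, drop = FALSE],
                     file.path(dir, paste0("candidates_", m, ".tsv")))
  }
  for (f in names(report$funnels)) {
    readr::write_tsv(report$funnels[[f]],
                     file.path(dir, paste0("funnel_", f, ".tsv")))
  }
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Family variant-prioritization report\n")
  for (m in names(x$model_counts)) {
    cat(sprintf("  %-22s %d candidates\n", m, x$model_counts[[m]]))
  }
  if (!is.null(x$concordance) && !is.null(x$concordance$percent_shared)) {
    cat(sprintf("  twin concordance: %.1f%% shared\n",
                x$concordance$percent_shared))
  }
  if (!is.null(x$panel)) {
    cat(sprintf("  panel: %d genes screened, %d discordant\n",
                x$panel$genes_screened, x$panel$genes_discordant))
  }
  invisible(x)
}
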