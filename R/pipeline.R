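#' End-to-end family prioritization pipeline
#'
#' Orchestrates all stages over a file bundle: reads the pedigree and the
#' annotated VCF, applies the staged filter, runs the four genotype-model
#' screens on the quality/rarity/consequence survivors, summarizes twin
#' concordance, screens the gene panel, attaches read-evidence review
#' verdicts where pileup evidence exists, and writes the report bundle.
#' Any stage failure is re-raised with the stage name prefixed.
#'
#' @param vcf Path to the annotated multi-sample VCF.
#' @param ped_file Path to the PED file.
#' @param twin_pair `c(affected_twin_id, unaffected_twin_id)`.
#' @param out_dir Output directory for the report bundle.
#' @param panel_file Optional panel TSV path.
#' @param pileup_file Optional pileup-summary TSV path.
#' @param qc_file Optional QC metrics TSV path.
#' @param filter_cfg,model_cfg,thresholds Stage configurations.
#' @param dialect VCF annotation dialect.
#' @return The `analysis_report`, invisibly; the bundle is written under
#'   `out_dir`.
#' @export
run_pipeline <- function(vcf, ped_file, twin_pair, out_dir,
                         panel_file = NULL, pileup_file = NULL,
                         qc_file = NULL,
                         filter_cfg = filter_config(),
                         model_cfg = model_config(),
                         thresholds = review_thresholds(),
                         dialect = default_dialect()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  ped <- stage("pedigree", read_pedigree(ped_file, twin_pair))
  cohort <- stage("vcf", read_cohort(vcf, dialect = dialect,
                                     expected_samples = pedigree_samples(ped)))
  funnel <- stage("filtering", apply_funnel(cohort, filter_cfg))
  # model screens run on quality/rarity/consequence survivors; the two
  # pathogenicity tiers are applied per candidate table afterwards
  functional <- funnel$stages$protein_altering
  models <- stage("models", screen_models(functional, ped, model_cfg))
  concord <- stage("concordance",
                   twin_concordance(funnel$stages$quality, ped))
  panel_rep <- NULL
  if (!is.null(panel_file)) {
    panel <- stage("panel", load_panel(panel_file))
    panel_rep <- stage("panel", panel_screen(funnel$stages$quality,
                                             panel, ped))
  }
  if (!is.null(pileup_file)) {
    pileup <- stage("review", read_pileup(pileup_file))
    reviewed <- stage("review",
                      review_cohort(models, pileup, ped, thresholds))
    models$review_verdict <- NA_character_
    if (nrow(reviewed) > 0) {
      mk <- variant_keys(models)
      rk <- variant_keys(reviewed)
      models$review_verdict[match(rk, mk)] <- reviewed$review_verdict
    }
  }
  qc_summary <- NULL
  if (!is.null(qc_file)) {
    qc_summary <- stage("qc", summarize_coverage(read_qc_metrics(qc_file)))
  }
  report <- stage("report", build_report(
    funnels = list(cohort = funnel),
    models = models, concordance = concord, panel_report = panel_rep
  ))
  stage("report", write_report(report, out_dir))
  if (!is.null(qc_summary)) {
    readr::write_tsv(qc_summary, file.path(out_dir, "qc_summary.tsv"))
  }
  invisible(report)
}
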