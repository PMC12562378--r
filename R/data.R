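#' Bundled example candidate tables
#'
#' The package ships, as plain-text fixtures under `extdata/`, the three
#' published candidate-variant tables from a whole-exome study of a family
#' with monozygotic twins discordant for congenital scoliosis: the
#' high-confidence de novo, autosomal recessive and autosomal dominant
#' candidates with their printed CADD, REVEL, SIFT, PolyPhen-2 HDIV and
#' MutationTaster annotations. They exercise the pathogenicity tiers on
#' real annotation values.
#'
#' @param model One of `"de_novo"`, `"autosomal_recessive"`,
#'   `"autosomal_dominant"`.
#' @return A [cohort table][cohort-table] (without genotypes; positions are
#'   `NA` where the source table did not print them).
#' @export
bundled_candidates <- function(model = c("de_novo", "autosomal_recessive",
                                         "autosomal_dominant")) {
  model <- match.arg(model)
  f <- c(de_novo = "candidates_denovo.tsv",
         autosomal_recessive = "candidates_recessive.tsv",
         autosomal_dominant = "candidates_dominant.tsv")[[model]]
  read_candidates(system.file("extdata", f, package = "twinwes",
                              mustWork = TRUE))
}

#' Bundled example QC metrics
#'
#' Per-sample exome QC metrics (mean target coverage, fraction at >=20x
#' and >=50x, aligned reads, coverage uniformity) for the eight-member
#' study family behind [bundled_candidates()].
#'
#' @return Tibble of per-sample metrics (see [read_qc_metrics()]).
#' @export
bundled_qc_metrics <- function() {
  read_qc_metrics(system.file("extdata", "qc_metrics.tsv",
                              package = "twinwes", mustWork = TRUE))
}

#' Bundled synthetic gene panel
#'
#' A congenital-spinal-deformity panel fixture with the category sizes of
#' a literature-curated panel (19 Klippel-Feil, 24 congenital scoliosis,
#' 83 other CSD genes; 126 unique symbols). Fifteen well-known CSD genes
#' (TBX6, DLL3, MESP2, JAG1, NOTCH2, FZD6, DACT1, DISP2, PAX3, FBN1,
#' COL5A1, VANGL1, VANGL2, SCRIB, CELSR1) are real; the remaining entries
#' are synthetic placeholder symbols, so this file is a testing fixture,
#' not a clinical panel.
#'
#' @return A `gene_panel` (see [load_panel()]).
#' @export
bundled_panel <- function() {
  load_panel(system.file("extdata", "panel_csd_synthetic.tsv",
                         package = "twinwes", mustWork = TRUE))
}
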