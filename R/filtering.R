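#' Configuration for the staged variant filter
#'
#' Defaults encode the analysis conventions for rare-disease exome
#' prioritization used throughout this package: keep caller-PASS sites,
#' drop variants with population MAF above 1%, keep protein-altering
#' exonic/splicing consequences, then apply two pathogenicity tiers —
#' *liberal* (damaging call by at least one of SIFT, PolyPhen-2 HDIV,
#' MutationTaster) and *strict* (liberal plus CADD > 20, strictly, and
#' REVEL >= 0.5, inclusive).
#'
#' @param maf_threshold Maximum population allele frequency retained
#'   (inclusive bound; variants with every source absent are retained as
#'   putatively novel).
#' @param require_pass Keep only `FILTER == "PASS"` records. A bare `.`
#'   FILTER is *not* PASS under this setting.
#' @param protein_altering_classes Exonic consequence classes counted as
#'   protein-altering.
#' @param allowed_regions Functional regions retained.
#' @param cadd_min Strict-tier CADD threshold (strict inequality).
#' @param revel_min Strict-tier REVEL threshold (inclusive).
#' @param damaging_categories Per-tool sets of category calls counted as
#'   damaging. PolyPhen-2 counts probably (`D`) and possibly (`P`)
#'   damaging; MutationTaster counts disease-causing (`A`, `D`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          require_pass = TRUE,
                          protein_altering_classes = c(
                            "nonsynonymous_SNV", "stopgain", "stoploss",
                            "frameshift_insertion", "frameshift_deletion"),
                          allowed_regions = c("exonic", "splicing"),
                          cadd_min = 20,
                          revel_min = 0.5,
                          damaging_categories = list(
                            sift = "D",
                            polyphen2 = c("D", "P"),
                            mutation_taster = c("D", "A"))) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 1,
            cadd_min >= 0, revel_min >= 0, revel_min <= 1)
  bad_cls <- setdiff(protein_altering_classes, EXONIC_CLASSES)
  if (length(bad_cls)) {
    stop("unknown exonic class: ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(maf_threshold = maf_threshold, require_pass = require_pass,
         protein_altering_classes = protein_altering_classes,
         allowed_regions = allowed_regions,
         cadd_min = cadd_min, revel_min = revel_min,
         damaging_categories = damaging_categories),
    class = "filter_config"
  )
}

#' Caller-quality gate
#'
#' @param cohort A [cohort table][cohort-table].
#' @param cfg A [filter_config()].
#' @return Logical vector: `TRUE` iff `filter_status == "PASS"` when
#'   `require_pass` is on; all `TRUE` otherwise.
#' @export
passes_quality <- function(cohort, cfg = filter_config()) {
  if (!cfg$require_pass) return(rep(TRUE, nrow(cohort)))
  !is.na(cohort$filter_status) & cohort$filter_status == "PASS"
}

#' Population-rarity gate
#'
#' A variant is rare when the *maximum* allele frequency over the present
#' population sources (gnomAD exome/genome, ExAC) does not exceed the
#' threshold. A variant absent from every source is retained — novel
#' variants are exactly the interesting ones in a de novo screen.
#'
#' @inheritParams passes_quality
#' @return Logical vector.
#' @export
is_rare <- function(cohort, cfg = filter_config()) {
  af <- as.matrix(cohort[, COHORT_AF_COLS, drop = FALSE])
  max_af <- apply(af, 1, function(r) {
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  })
  is.na(max_af) | max_af <= cfg$maf_threshold
}

#' Protein-altering-consequence gate
#'
#' Keeps variants whose functional region intersects the allowed regions
#' (an `exonic;splicing` annotation counts as both) and whose exonic class
#' is protein-altering; a splicing variant with no exonic class (intronic
#' side of a splice site) is also kept. Synonymous variants are excluded
#' here.
#'
#' @inheritParams passes_quality
#' @return Logical vector.
#' @export
is_protein_altering <- function(cohort, cfg = filter_config()) {
  if (nrow(cohort) == 0L) return(logical())
  regions <- strsplit(ifelse(is.na(cohort$func_region), "",
                             cohort$func_region), ";", fixed = TRUE)
  in_region <- vapply(regions, function(r) any(r %in% cfg$allowed_regions),
                      logical(1))
  splicing <- vapply(regions, function(r) "splicing" %in% r, logical(1))
  cls_ok <- !is.na(cohort$exonic_class) &
    cohort$exonic_class %in% cfg$protein_altering_classes
  in_region & (cls_ok | (splicing & is.na(cohort$exonic_class)))
}

#' Liberal pathogenicity tier
#'
#' `TRUE` iff at least one of SIFT, PolyPhen-2 HDIV or MutationTaster calls
#' the variant damaging (per-tool damaging category sets in `cfg`). A tool
#' with no prediction contributes nothing, so an unannotated variant fails.
#'
#' @inheritParams passes_quality
#' @return Logical vector.
#' @export
liberal_tier <- function(cohort, cfg = filter_config()) {
  dmg <- cfg$damaging_categories
  in_set <- function(pred, set) !is.na(pred) & pred %in% set
  in_set(cohort$sift_pred, dmg$sift) |
    in_set(cohort$polyphen2_pred, dmg$polyphen2) |
    in_set(cohort$mutation_taster_pred, dmg$mutation_taster)
}

#' Strict pathogenicity tier
#'
#' The liberal condition plus quantitative thresholds: CADD strictly above
#' `cadd_min` and REVEL at or above `revel_min`. A variant missing either
#' score fails — absent scores never pass a threshold.
#'
#' @inheritParams passes_quality
#' @return Logical vector.
#' @export
strict_tier <- function(cohort, cfg = filter_config()) {
  liberal_tier(cohort, cfg) &
    !is.na(cohort$cadd_phred) & cohort$cadd_phred > cfg$cadd_min &
    !is.na(cohort$revel) & cohort$revel >= cfg$revel_min
}

#' Run the full filtering funnel
#'
#' Applies the five gates in order — caller quality, population rarity,
#' protein-altering consequence, liberal tier, strict tier — each on the
#' survivors of the previous stage, and records the count after every
#' stage. Strict survivors are by construction a subset of liberal
#' survivors.
#'
#' @inheritParams passes_quality
#' @return A `funnel_result`: list with `funnel` (tibble of stage name and
#'   count, starting from the input count) and `stages` (named list of
#'   surviving cohort tables per stage).
#' @export
apply_funnel <- function(cohort, cfg = filter_config()) {
  gates <- list(
    quality = passes_quality,
    rare = is_rare,
    protein_altering = is_protein_altering,
    liberal = liberal_tier,
    strict = strict_tier
  )
  stages <- list(input = cohort)
  counts <- c(input = nrow(cohort))
  current <- cohort
  for (nm in names(gates)) {
    keep <- gates[[nm]](current, cfg)
    current <- current[keep, , drop = FALSE]
    stages[[nm]] <- current
    counts[nm] <- nrow(current)
  }
  structure(
    list(
      funnel = tibble::tibble(stage = names(counts),
                              count = as.integer(unname(counts))),
      stages = stages
    ),
    class = "funnel_result"
  )
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("Variant filtering funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-18s %8d\n", x$funnel$stage[i], x$funnel$count[i]))
  }
  invisible(x)
}

#' Write funnel counts as TSV
#' @param fr A `funnel_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_funnel <- function(fr, path) {
  readr::write_tsv(fr$funnel, path)
  invisible(path)
}
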