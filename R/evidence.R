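#' Review thresholds for read-level variant validation
#'
#' Numeric rules that turn the manual BAM/IGV inspection criteria —
#' limited coverage, weak alternate support, strand bias, allele fraction
#' inconsistent with the called genotype — into computable flags. The
#' defaults are package conventions (a 20x depth floor, a 3-read /
#' 20% allele-fraction support floor for carriers, the usual het and
#' hom-alt allele-fraction windows, Fisher p < 0.05 for strand imbalance);
#' they are not derived quantities, and every one is configurable.
#'
#' @param min_depth Depth below which a sample is flagged `low_depth`.
#' @param min_alt_reads Carrier alternate-read floor.
#' @param min_carrier_aaf Carrier alternate-allele-fraction floor.
#' @param het_aaf_range Expected allele-fraction window for heterozygotes.
#' @param hom_alt_aaf_min Minimum allele fraction for a homozygous call.
#' @param hom_ref_aaf_max Maximum allele fraction for a reference call.
#' @param strand_p Two-sided Fisher exact p-value below which strand
#'   imbalance is flagged.
#' @param strand_min_alt Minimum alternate reads before an
#'   all-one-strand pattern alone triggers the flag.
#' @return A list of class `review_thresholds`.
#' @export
review_thresholds <- function(min_depth = 20,
                              min_alt_reads = 3,
                              min_carrier_aaf = 0.20,
                              het_aaf_range = c(0.25, 0.75),
                              hom_alt_aaf_min = 0.90,
                              hom_ref_aaf_max = 0.05,
                              strand_p = 0.05,
                              strand_min_alt = 3) {
  structure(
    list(min_depth = min_depth, min_alt_reads = min_alt_reads,
         min_carrier_aaf = min_carrier_aaf, het_aaf_range = het_aaf_range,
         hom_alt_aaf_min = hom_alt_aaf_min,
         hom_ref_aaf_max = hom_ref_aaf_max,
         strand_p = strand_p, strand_min_alt = strand_min_alt),
    class = "review_thresholds"
  )
}

#' Alternate allele fraction
#'
#' @param alt_reads Alternate-supporting read counts.
#' @param depth Total read depths.
#' @return `alt_reads / depth`; `NA` where depth is zero.
#' @export
allele_fraction <- function(alt_reads, depth) {
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Strand-bias flag with Fisher exact p-value
#'
#' Flags a site/sample when either (a) there are at least `min_alt`
#' alternate reads and every one of them lies on a single strand, or (b)
#' the two-sided Fisher exact test on the 2x2 table
#' `[(ref_fwd, ref_rev), (alt_fwd, alt_rev)]` gives p below `p_threshold`.
#' The p-value is returned regardless of the flag.
#'
#' @param alt_fwd,alt_rev Alternate reads on forward/reverse strand.
#' @param ref_fwd,ref_rev Reference reads on forward/reverse strand.
#' @param p_threshold,min_alt See [review_thresholds()].
#' @return Tibble with columns `flag` (logical) and `p_value`.
#' @export
strand_bias_flag <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                             p_threshold = 0.05, min_alt = 3) {
  n <- length(alt_fwd)
  p <- numeric(n)
  for (i in seq_len(n)) {
    tab <- matrix(c(ref_fwd[i], ref_rev[i], alt_fwd[i], alt_rev[i]),
                  nrow = 2, byrow = TRUE)
    p[i] <- if (sum(tab) == 0) 1 else stats::fisher.test(tab)$p.value
  }
  alt <- alt_fwd + alt_rev
  one_strand <- alt >= min_alt & (alt_fwd == 0L | alt_rev == 0L)
  tibble::tibble(flag = one_strand | p < p_threshold, p_value = p)
}

VERDICT_LEVELS <- c("supported", "uncertain", "likely_artifact")

worst_verdict <- function(v) {
  if (length(v) == 0) return("uncertain")
  VERDICT_LEVELS[max(match(v, VERDICT_LEVELS))]
}

#' Review one variant against per-sample read evidence
#'
#' Computes, for every sample with evidence, the validation flags
#' (`low_depth`, `low_alt_support`, `strand_bias`,
#' `aaf_genotype_conflict`) and a per-sample verdict:
#' `likely_artifact` when a called carrier shows weak alternate support or
#' strand bias; `uncertain` when only depth or an allele-fraction/genotype
#' conflict is at issue, or when the genotype is a no-call; `supported`
#' otherwise. The cohort verdict is the worst verdict among carrier
#' samples (uncertain when no carrier has evidence).
#'
#' @param variant A single-row [cohort table][cohort-table].
#' @param evidence Tibble with columns `sample`, `depth`, `alt_fwd`,
#'   `alt_rev`, `ref_fwd`, `ref_rev` (one row per sample; at least the
#'   twin pair is expected).
#' @param ped A [twin_pedigree()].
#' @param thresholds A [review_thresholds()].
#' @return List with `per_sample` (flags tibble) and `verdict`.
#' @export
review_variant <- function(variant, evidence, ped,
                           thresholds = review_thresholds()) {
  stopifnot(nrow(variant) == 1L)
  th <- thresholds
  gts <- variant$gt[[1]]
  unknown <- setdiff(evidence$sample, names(gts))
  if (length(unknown) > 0) {
    stop("evidence sample(s) without genotype: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  twins <- c(ped$affected_twin, ped$unaffected_twin)
  if (!all(twins %in% evidence$sample)) {
    stop("evidence must cover the twin pair; missing: ",
         paste(setdiff(twins, evidence$sample), collapse = ", "),
         call. = FALSE)
  }
  cls <- unname(classify_genotype(gts[evidence$sample]))
  alt_reads <- evidence$alt_fwd + evidence$alt_rev
  aaf <- allele_fraction(alt_reads, evidence$depth)
  carrier <- cls %in% c("het", "hom_alt")
  low_depth <- evidence$depth < th$min_depth
  low_alt <- carrier &
    (alt_reads < th$min_alt_reads | (!is.na(aaf) & aaf < th$min_carrier_aaf))
  sb <- strand_bias_flag(evidence$alt_fwd, evidence$alt_rev,
                         evidence$ref_fwd, evidence$ref_rev,
                         p_threshold = th$strand_p,
                         min_alt = th$strand_min_alt)
  conflict <- !is.na(aaf) & (
    (cls == "het" & (aaf < th$het_aaf_range[1] | aaf > th$het_aaf_range[2])) |
    (cls == "hom_alt" & aaf < th$hom_alt_aaf_min) |
    (cls == "hom_ref" & aaf > th$hom_ref_aaf_max)
  )
  verdict <- ifelse(
    cls == "no_call", "uncertain",
    ifelse(carrier & (low_alt | sb$flag), "likely_artifact",
           ifelse(low_depth | conflict, "uncertain", "supported"))
  )
  per_sample <- tibble::tibble(
    sample = evidence$sample, genotype_class = cls,
    depth = evidence$depth, alt_reads = alt_reads, aaf = aaf,
    low_depth = low_depth, low_alt_support = low_alt,
    strand_bias = sb$flag, strand_p = sb$p_value,
    aaf_genotype_conflict = conflict, verdict = verdict
  )
  list(per_sample = per_sample, verdict = worst_verdict(verdict[carrier]))
}

#' Review every cohort variant that has pileup evidence
#'
#' @param cohort A [cohort table][cohort-table].
#' @param pileup Pileup-summary tibble with columns `sample`, `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_fwd`, `alt_rev`, `ref_fwd`,
#'   `ref_rev` (1-based positions), e.g. from [read_pileup()].
#' @param ped A [twin_pedigree()].
#' @param thresholds A [review_thresholds()].
#' @return The cohort restricted to variants with evidence, with appended
#'   `review_verdict` column; per-sample detail in attribute
#'   `"per_sample"` (one tibble per variant).
#' @export
review_cohort <- function(cohort, pileup, ped,
                          thresholds = review_thresholds()) {
  key <- paste(cohort$chrom, cohort$pos, cohort$ref, cohort$alt)
  pkey <- paste(pileup$chrom, pileup$pos, pileup$ref, pileup$alt)
  has_ev <- key %in% pkey
  out <- cohort[has_ev, , drop = FALSE]
  details <- vector("list", nrow(out))
  verdicts <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    k <- paste(out$chrom[i], out$pos[i], out$ref[i], out$alt[i])
    ev <- pileup[pkey == k, , drop = FALSE]
    r <- review_variant(out[i, , drop = FALSE], ev, ped, thresholds)
    details[[i]] <- r$per_sample
    verdicts[i] <- r$verdict
  }
  out$review_verdict <- verdicts
  attr(out, "per_sample") <- details
  out
}

#' Read a pileup-summary TSV
#'
#' Expected columns: `sample`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `depth`, `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`.
#'
#' @param path Path to the TSV.
#' @return Tibble with the columns above, counts as integers.
#' @export
read_pileup <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      sample = "c", chrom = "c", pos = "i", ref = "c", alt = "c",
      depth = "i", alt_fwd = "i", alt_rev = "i", ref_fwd = "i",
      ref_rev = "i"
    )
  )
}
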