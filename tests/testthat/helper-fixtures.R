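# in-code fixtures shared by the unit tests

FAM <- default_family()
FAM_SAMPLES <- pedigree_samples(FAM)

# one-row cohort tibble with sensible defaults, overridable field by field
make_variant <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                         filter = "PASS", gene = "GENE1",
                         func_region = "exonic",
                         exonic_class = "nonsynonymous_SNV",
                         af_gnomad_exome = NA_real_,
                         af_gnomad_genome = NA_real_, af_exac = NA_real_,
                         cadd = NA_real_, revel = NA_real_,
                         sift = NA_character_, polyphen2 = NA_character_,
                         mutation_taster = NA_character_,
                         gt = NULL) {
  if (is.null(gt)) {
    gt <- stats::setNames(rep("0/0", length(FAM_SAMPLES)), FAM_SAMPLES)
  }
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    filter_status = filter, gene = gene, func_region = func_region,
    exonic_class = exonic_class, cdna_change = NA_character_,
    protein_change = NA_character_, clinvar = NA_character_,
    af_gnomad_exome = af_gnomad_exome, af_gnomad_genome = af_gnomad_genome,
    af_exac = af_exac, cadd_phred = cadd, revel = revel,
    sift_pred = sift, sift_score = NA_real_,
    polyphen2_pred = polyphen2, polyphen2_score = NA_real_,
    mutation_taster_pred = mutation_taster,
    mutation_taster_score = NA_real_,
    gt = list(gt)
  )
}

# genotype vector for the default family; unspecified members are 0/0
fam_gt <- function(...) {
  over <- c(...)
  g <- stats::setNames(rep("0/0", length(FAM_SAMPLES)), FAM_SAMPLES)
  g[names(over)] <- over
  g
}

# shorthand role ids in the default family
AFF <- FAM$affected_twin      # WES-008
UNAFF <- FAM$unaffected_twin  # WES-007
FATHER <- FAM$father          # WES-001
MOTHER <- FAM$mother          # WES-002
SIB1 <- FAM$siblings[1]       # WES-003

# randomized cohort rows (annotation only) for property tests
random_score_cohort <- function(n) {
  pick <- function(v, p = NULL) sample(v, n, replace = TRUE, prob = p)
  base_gt <- stats::setNames(rep("0/0", length(FAM_SAMPLES)), FAM_SAMPLES)
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
    filter_status = pick(c("PASS", "LowQual", ".")),
    gene = sprintf("G%d", seq_len(n)),
    func_region = pick(c("exonic", "splicing", "exonic;splicing",
                         "intronic", "UTR", "intergenic")),
    exonic_class = pick(c("nonsynonymous_SNV", "synonymous_SNV",
                          "stopgain", "frameshift_insertion",
                          NA_character_)),
    cdna_change = NA_character_, protein_change = NA_character_,
    clinvar = NA_character_,
    af_gnomad_exome = ifelse(stats::runif(n) < 0.3, NA,
                             stats::runif(n, 0, 0.2)),
    af_gnomad_genome = NA_real_,
    af_exac = ifelse(stats::runif(n) < 0.5, NA, stats::runif(n, 0, 0.2)),
    cadd_phred = ifelse(stats::runif(n) < 0.15, NA, stats::runif(n, 0, 45)),
    revel = ifelse(stats::runif(n) < 0.15, NA, stats::runif(n)),
    sift_pred = pick(c("D", "T", NA_character_)),
    sift_score = NA_real_,
    polyphen2_pred = pick(c("D", "P", "B", NA_character_)),
    polyphen2_score = NA_real_,
    mutation_taster_pred = pick(c("D", "A", "P", "N", NA_character_)),
    mutation_taster_score = NA_real_,
    gt = replicate(n, base_gt, simplify = FALSE)
  )
}

# two-sided Fisher exact p by direct hypergeometric enumeration; the
# independent oracle for stats::fisher.test on 2x2 tables
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# evidence row for review tests
ev_row <- function(sample, depth, alt_fwd, alt_rev,
                   ref_fwd = NULL, ref_rev = NULL) {
  ref_n <- depth - alt_fwd - alt_rev
  if (is.null(ref_fwd)) ref_fwd <- ref_n %/% 2
  if (is.null(ref_rev)) ref_rev <- ref_n - ref_fwd
  tibble::tibble(sample = sample, depth = depth, alt_fwd = alt_fwd,
                 alt_rev = alt_rev, ref_fwd = ref_fwd, ref_rev = ref_rev)
}
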