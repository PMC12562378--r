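#!/usr/bin/env Rscript
# Stage 2: staged variant filtering.
#
# Reads the annotated cohort VCF and applies the funnel: caller PASS ->
# population MAF <= 1% -> protein-altering exonic/splicing consequence ->
# liberal pathogenicity tier (one damaging tool call) -> strict tier
# (CADD > 20 and REVEL >= 0.5). Also reports the exonic class composition
# of the quality/rarity survivors.

suppressPackageStartupMessages(library(twinwes))

ped <- default_family()
cohort <- read_cohort("results/sim/cohort.vcf",
                      expected_samples = pedigree_samples(ped))

fr <- apply_funnel(cohort)
print(fr)
write_funnel(fr, "results/funnel.tsv")

survivors <- fr$stages$rare
cls_counts <- table(survivors$exonic_class[!is.na(survivors$exonic_class)])
pct <- class_breakdown(as.vector(cls_counts))
names(pct) <- names(cls_counts)
cat("\nExonic class composition after quality/rarity filtering:\n")
for (k in names(pct)) cat(sprintf("  %-22s %5.1f%%\n", k, pct[[k]]))
readr::write_tsv(
  tibble::tibble(class = names(cls_counts),
                 count = as.vector(cls_counts),
                 percent = unname(pct)),
  "results/class_breakdown.tsv"
)
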