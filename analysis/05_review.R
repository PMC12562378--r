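#!/usr/bin/env Rscript
# Stage 5: read-evidence review of model candidates.
#
# Formalizes manual BAM/IGV inspection as computable flags on the pileup
# summary: depth, alternate-read support, allele fraction vs called
# genotype, and strand bias (Fisher exact on the 2x2 strand table). The
# three injected artifacts must be demoted; clean planted candidates stay
# supported.

suppressPackageStartupMessages(library(twinwes))

ped <- default_family()
cohort <- read_cohort("results/sim/cohort.vcf",
                      expected_samples = pedigree_samples(ped))
pileup <- read_pileup("results/sim/pileup.tsv")
models <- screen_models(apply_funnel(cohort)$stages$protein_altering, ped)

candidates <- models[models$de_novo | models$autosomal_recessive |
                       models$autosomal_dominant |
                       models$homozygous_affected, , drop = FALSE]
reviewed <- review_cohort(candidates, pileup, ped, review_thresholds())
cat("Reviewed", nrow(reviewed), "candidates with pileup evidence:\n")
print(table(reviewed$review_verdict))

truth <- readr::read_tsv("results/sim/truth.tsv", show_col_types = FALSE)
tk <- match(variant_keys(reviewed), variant_keys(truth))
cat("\nVerdict by injected artifact:\n")
print(table(truth$artifact[tk], reviewed$review_verdict))

out <- reviewed[, c("chrom", "pos", "ref", "alt", "gene", "review_verdict",
                    "model_notes")]
readr::write_tsv(out, "results/review_verdicts.tsv")
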