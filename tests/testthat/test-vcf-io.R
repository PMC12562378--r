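vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=Gene.refGene,Number=.,Type=String,Description=\"g\">",
    "##INFO=<ID=Func.refGene,Number=.,Type=String,Description=\"f\">",
    "##INFO=<ID=ExonicFunc.refGene,Number=.,Type=String,Description=\"e\">",
    "##INFO=<ID=CADD_phred,Number=.,Type=String,Description=\"c\">",
    "##INFO=<ID=REVEL,Number=.,Type=String,Description=\"r\">",
    "##INFO=<ID=gnomAD_exome_ALL,Number=.,Type=String,Description=\"a\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_mini_vcf <- function(records, samples = FAM_SAMPLES) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(vcf_header(samples), records), f)
  f
}

test_that("a minimal biallelic record reads with per-sample genotypes", {
  gts <- c(rep("0/0", 7), "0/1")
  rec <- paste(c("chr10", "70587543", ".", "C", "T", "50", "PASS",
                 "Gene.refGene=STOX1;Func.refGene=exonic;ExonicFunc.refGene=nonsynonymous_SNV;CADD_phred=26.4;REVEL=0.535",
                 "GT", gts), collapse = "\t")
  f <- write_mini_vcf(rec)
  cohort <- read_cohort(f, expected_samples = FAM_SAMPLES)
  expect_equal(nrow(cohort), 1)
  expect_equal(cohort$gene, "STOX1")
  expect_equal(cohort$cadd_phred, 26.4)
  expect_equal(cohort$revel, 0.535)
  cls <- classify_genotype(cohort$gt[[1]])
  expect_equal(sum(cls == "hom_ref"), 7)
  expect_equal(sum(cls == "het"), 1)
  expect_equal(unname(cls["WES-008"]), "het")
})

test_that("multiallelic decomposition remaps alleles conservatively", {
  # hand-worked mapping for G -> A,T with one 1/2 sample: in the record
  # decomposed on A, allele 1 stays 1 and allele 2 (the other alt) becomes
  # missing; on T, allele 2 becomes 1 and allele 1 becomes missing
  gts <- c("1/2", "0/1", "0/2", rep("0/0", 5))
  rec <- paste(c("chr1", "500", ".", "G", "A,T", "50", "PASS",
                 "Gene.refGene=G1;Func.refGene=exonic",
                 "GT", gts), collapse = "\t")
  f <- write_mini_vcf(rec)
  cohort <- read_cohort(f, expected_samples = FAM_SAMPLES)
  expect_equal(nrow(cohort), 2)
  expect_equal(cohort$alt, c("A", "T"))
  on_a <- cohort$gt[[1]]
  on_t <- cohort$gt[[2]]
  expect_equal(unname(on_a[1:3]), c("1/.", "0/1", "0/."))
  expect_equal(unname(on_t[1:3]), c("./1", "0/.", "0/1"))
  # no phantom hom_ref: the masked alt allele classifies as no_call
  expect_equal(unname(classify_genotype(on_a[3])), "no_call")
})

test_that("allele-indexed annotation values split per decomposed alt", {
  rec <- paste(c("chr2", "900", ".", "G", "A,T", "50", "PASS",
                 "Gene.refGene=G2;Func.refGene=exonic;gnomAD_exome_ALL=0.001,0.2;CADD_phred=11.1,22.2",
                 "GT", rep("0/0", 8)), collapse = "\t")
  f <- write_mini_vcf(rec)
  cohort <- read_cohort(f, expected_samples = FAM_SAMPLES)
  expect_equal(cohort$af_gnomad_exome, c(0.001, 0.2))
  expect_equal(cohort$cadd_phred, c(11.1, 22.2))
})

test_that("decomposition conserves sites (one row per alt allele)", {
  recs <- c(
    paste(c("chr1", "100", ".", "A", "T", ".", "PASS", ".", "GT",
            rep("0/0", 8)), collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "G,T", ".", "PASS", ".", "GT",
            rep("0/0", 8)), collapse = "\t"),
    paste(c("chr1", "300", ".", "G", "A,C,T", ".", "PASS", ".", "GT",
            rep("0/0", 8)), collapse = "\t")
  )
  f <- write_mini_vcf(recs)
  cohort <- read_cohort(f)
  expect_equal(nrow(cohort), 1 + 2 + 3)
})

test_that("absent annotations become NA, never defaults", {
  rec <- paste(c("chr1", "100", ".", "A", "T", ".", "PASS",
                 "Gene.refGene=G1", "GT", rep("0/0", 8)), collapse = "\t")
  f <- write_mini_vcf(rec)
  cohort <- read_cohort(f)
  expect_true(is.na(cohort$cadd_phred))
  expect_true(is.na(cohort$revel))
  expect_true(is.na(cohort$func_region))
  expect_true(is.na(cohort$af_gnomad_exome))
})

test_that("missing expected samples and malformed genotypes are hard errors", {
  rec <- paste(c("chr1", "100", ".", "A", "T", ".", "PASS", ".",
                 "GT", rep("0/0", 8)), collapse = "\t")
  f <- write_mini_vcf(rec)
  expect_error(read_cohort(f, expected_samples = c(FAM_SAMPLES, "WES-009")),
               "WES-009")
  bad <- paste(c("chr1", "100", ".", "A", "T", ".", "PASS", ".",
                 "GT", c("0/1/1", rep("0/0", 7))), collapse = "\t")
  f2 <- write_mini_vcf(bad)
  expect_error(read_cohort(f2), "malformed genotype")
})

test_that("cohort VCF writer round-trips keys, genotypes and scores", {
  sim <- simulate_cohort(sim_config(seed = 5, n_background = 60), FAM)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim$cohort, f)
  back <- read_cohort(f, expected_samples = FAM_SAMPLES)
  expect_equal(variant_keys(back), variant_keys(sim$cohort))
  expect_equal(back$gt, sim$cohort$gt)
  expect_equal(back$cadd_phred, sim$cohort$cadd_phred)
  expect_equal(back$revel, sim$cohort$revel)
  expect_equal(back$sift_pred, sim$cohort$sift_pred)
  expect_equal(back$af_gnomad_exome, sim$cohort$af_gnomad_exome)
  expect_equal(back$filter_status, sim$cohort$filter_status)
})

test_that("candidate tables round-trip through write/read", {
  tab <- bundled_candidates("de_novo")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(tab, f)
  back <- read_candidates(f)
  back <- back[match(tab$gene, back$gene), ]  # writer reorders rows
  for (col in c("gene", "cadd_phred", "revel", "sift_pred", "sift_score",
                "polyphen2_pred", "polyphen2_score", "mutation_taster_pred",
                "mutation_taster_score")) {
    expect_equal(back[[col]], tab[[col]], info = col)
  }
  # an empty candidate set writes a header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(tab[0, ], f2)
  expect_equal(length(readLines(f2)), 1)
  # one candidate -> two-line file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(tab[1, ], f3)
  expect_equal(length(readLines(f3)), 2)
})
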