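test_that("identical seeds give byte-identical output bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  a <- simulate_cohort(sim_config(seed = 11, n_background = 120), FAM, d1)
  b <- simulate_cohort(sim_config(seed = 11, n_background = 120), FAM, d2)
  for (f in c("vcf", "pileup", "qc", "truth")) {
    expect_identical(readLines(a$paths[[f]]), readLines(b$paths[[f]]),
                     info = f)
  }
  c3 <- simulate_cohort(sim_config(seed = 12, n_background = 120), FAM)
  expect_false(identical(variant_keys(c3$cohort), variant_keys(a$cohort)))
})

test_that("twins are genotype-identical at background sites", {
  sim <- simulate_cohort(sim_config(seed = 23, n_background = 800), FAM)
  bg <- sim$cohort[sim$truth$label == "background", ]
  aff <- vapply(bg$gt, `[[`, character(1), FAM$affected_twin)
  unaff <- vapply(bg$gt, `[[`, character(1), FAM$unaffected_twin)
  expect_identical(classify_genotype(aff), classify_genotype(unaff))
})

test_that("simulator output is Mendelian-consistent outside exempt sites", {
  sim <- simulate_cohort(sim_config(seed = 29, n_background = 500), FAM)
  exempt <- variant_keys(sim$truth)[sim$truth$mendelian_exempt]
  expect_equal(mendelian_check(sim$cohort, FAM, exempt), 0)
})

test_that("mendelian_check counts impossible offspring genotypes", {
  v <- make_variant(gt = fam_gt(stats::setNames("1/1", SIB1)))
  expect_equal(mendelian_check(v, FAM), 1)
  # a no-call parent is uninformative, not a violation
  v2 <- make_variant(gt = fam_gt(stats::setNames(c("./.", "0/1", "0/1"),
                                                 c(FATHER, MOTHER, SIB1))))
  expect_equal(mendelian_check(v2, FAM), 0)
  expect_equal(mendelian_check(v[0, ], FAM), 0)
})

test_that("planted variants carry their intended genotype patterns", {
  sim <- simulate_cohort(sim_config(seed = 37, n_background = 100), FAM)
  tr <- sim$truth
  for (i in which(tr$label != "background")) {
    intended <- unlist(tr[i, paste0("gt_", FAM_SAMPLES)])
    names(intended) <- FAM_SAMPLES
    expect_identical(sim$cohort$gt[[i]], intended)
  }
  ar <- which(tr$label == "autosomal_recessive")[1]
  g <- sim$cohort$gt[[ar]]
  expect_equal(unname(g[c(FAM$affected_twin, FAM$father, FAM$mother)]),
               c("1/1", "0/1", "0/1"))
})

test_that("tier targets are realized against the filtering module", {
  cfg <- sim_config(
    seed = 41, n_background = 50,
    n_de_novo = 6, n_recessive = 3, n_dominant = 3,
    n_homozygous_concordant = 0,
    tier_targets = list(de_novo = c("strict_pass", "liberal_only", "fail"))
  )
  sim <- simulate_cohort(cfg, FAM)
  planted <- sim$truth$label != "background"
  coh <- sim$cohort[planted, ]
  tt <- sim$truth$tier_target[planted]
  lib <- liberal_tier(coh)
  str <- strict_tier(coh)
  expect_true(all(str[tt == "strict_pass"]))
  expect_true(all(lib[tt == "liberal_only"] & !str[tt == "liberal_only"]))
  expect_true(all(!lib[tt == "fail"]))
})

test_that("background allele frequencies are recovered at large n", {
  sim <- simulate_cohort(sim_config(seed = 43, n_background = 4000,
                                    n_de_novo = 0, n_recessive = 0,
                                    n_dominant = 0,
                                    n_homozygous_concordant = 0), FAM)
  # founder alt-allele dosage should average 2 * af across sites
  af <- sim$cohort$af_gnomad_exome
  dose <- vapply(sim$cohort$gt, function(g) {
    sum(classify_genotype(g[c(FAM$father, FAM$mother)]) == "het") +
      2 * sum(classify_genotype(g[c(FAM$father, FAM$mother)]) == "hom_alt")
  }, double(1))
  # binomial(4, af) mean comparison, pooled
  expect_equal(mean(dose), mean(4 * af), tolerance = 0.05)
})

test_that("artifact injections land where the truth table says", {
  cfg <- sim_config(
    seed = 47, n_background = 60,
    artifact_injections = list(
      list(model = "de_novo", index = 1, type = "no_call_others"),
      list(model = "autosomal_dominant", index = 2, type = "low_depth"))
  )
  sim <- simulate_cohort(cfg, FAM)
  tr <- sim$truth
  nc <- which(tr$artifact == "no_call_others")
  expect_length(nc, 1)
  g <- sim$cohort$gt[[nc]]
  others <- setdiff(FAM_SAMPLES, FAM$affected_twin)
  expect_true(all(g[others] == "./."))
  expect_equal(unname(g[FAM$affected_twin]), "0/1")
  ld <- which(tr$artifact == "low_depth")
  key <- variant_keys(sim$truth)[ld]
  pk <- paste(sim$pileup$chrom, sim$pileup$pos, sim$pileup$ref,
              sim$pileup$alt, sep = ":")
  expect_true(all(sim$pileup$depth[pk == key] < 20))
  # planting more sites than background context is rejected
  expect_error(
    simulate_cohort(sim_config(seed = 1, n_background = 3), FAM),
    "planted"
  )
})

test_that("the simulated bundle drives the full pipeline end to end", {
  d <- withr::local_tempdir()
  out <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(seed = 53, n_background = 250), FAM, d)
  rep <- run_pipeline(sim$paths$vcf, sim$paths$ped,
                      c(FAM$affected_twin, FAM$unaffected_twin), out,
                      pileup_file = sim$paths$pileup,
                      qc_file = sim$paths$qc)
  # every planted strict-pass variant of each model shows up as a candidate
  tr <- sim$truth
  strict_planted <- tr[tr$label == "de_novo" & tr$tier_target == "strict_pass", ]
  dn_keys <- variant_keys(rep$candidates$de_novo)
  expect_true(all(variant_keys(strict_planted) %in% dn_keys))
  expect_true(file.exists(file.path(out, "report.json")))
  # a missing pedigree file fails naming the stage
  expect_error(
    run_pipeline(sim$paths$vcf, file.path(d, "nope.ped"),
                 c(FAM$affected_twin, FAM$unaffected_twin), out),
    "\\[pedigree\\]"
  )
})
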