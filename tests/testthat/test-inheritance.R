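aff_het <- function(...) fam_gt(stats::setNames("0/1", AFF), ...)

test_that("de novo screen admits affected-only variants", {
  clean <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  expect_true(de_novo_screen(clean, FAM)$pass)
  # hom-alt in the affected twin still counts as present
  hom <- make_variant(gt = fam_gt(stats::setNames("1/1", AFF)))
  expect_true(de_novo_screen(hom, FAM)$pass)
  # carrier elsewhere defeats it
  shared <- make_variant(gt = fam_gt(stats::setNames(c("0/1", "0/1"),
                                                     c(AFF, UNAFF))))
  expect_false(de_novo_screen(shared, FAM)$pass)
})

test_that("no-calls elsewhere: permissive admits with a flag, strict excludes", {
  g <- stats::setNames(rep("./.", 8), FAM_SAMPLES)
  g[AFF] <- "1/1"
  v <- make_variant(gt = g)
  perm <- de_novo_screen(v, FAM, model_config("permissive"))
  expect_true(perm$pass)
  expect_match(perm$notes, "no_call_supported")
  strict <- de_novo_screen(v, FAM, model_config("strict"))
  expect_false(strict$pass)
})

test_that("recessive screen needs hom-alt affected and two carrier parents", {
  base <- c(stats::setNames("1/1", AFF), stats::setNames("0/1", FATHER),
            stats::setNames("0/1", MOTHER), stats::setNames("0/1", UNAFF))
  v <- make_variant(gt = fam_gt(base, stats::setNames("0/1", SIB1)))
  res <- autosomal_recessive_screen(v, FAM)
  expect_true(res$pass)
  # hom-alt unaffected twin eliminates it
  v2 <- make_variant(gt = fam_gt(base, stats::setNames("1/1", UNAFF)))
  expect_false(autosomal_recessive_screen(v2, FAM)$pass)
  # a hom-ref parent eliminates it
  v3 <- make_variant(gt = fam_gt(base, stats::setNames("0/0", FATHER)))
  expect_false(autosomal_recessive_screen(v3, FAM)$pass)
})

test_that("dominant screen with and without incomplete penetrance", {
  v <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  expect_true(autosomal_dominant_screen(v, FAM)$pass)
  # one carrier parent: only admitted with penetrance on, and flagged
  v2 <- make_variant(gt = fam_gt(stats::setNames(c("0/1", "0/1"),
                                                 c(AFF, FATHER))))
  off <- autosomal_dominant_screen(v2, FAM, model_config())
  expect_false(off$pass)
  on <- autosomal_dominant_screen(
    v2, FAM, model_config(incomplete_penetrance = TRUE))
  expect_true(on$pass)
  expect_match(on$notes, "penetrance_exception")
  # a carrier sibling defeats it either way
  v3 <- make_variant(gt = fam_gt(stats::setNames(c("0/1", "0/1"),
                                                 c(AFF, SIB1))))
  expect_false(autosomal_dominant_screen(
    v3, FAM, model_config(incomplete_penetrance = TRUE))$pass)
})

test_that("homozygous screen keys on the affected twin only", {
  conc <- make_variant(gt = fam_gt(stats::setNames(c("1/1", "1/1", "0/1", "0/1"),
                                                   c(AFF, UNAFF, FATHER, MOTHER))))
  res <- homozygous_screen(conc, FAM)
  expect_true(res$pass)
  expect_match(res$notes, "concordant_twin")
  disc <- make_variant(gt = fam_gt(stats::setNames(c("1/1", "0/1", "0/1"),
                                                   c(AFF, FATHER, MOTHER))))
  res2 <- homozygous_screen(disc, FAM)
  expect_true(res2$pass)
  expect_false(grepl("concordant_twin", res2$notes))
  het <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  expect_false(homozygous_screen(het, FAM)$pass)
})

test_that("model screens are restricted to autosomes by default", {
  v <- make_variant(chrom = "chrX", gt = fam_gt(stats::setNames("0/1", AFF)))
  expect_false(de_novo_screen(v, FAM)$pass)
  expect_true(de_novo_screen(v, FAM,
                             model_config(autosomes_only = FALSE))$pass)
})

test_that("a missing pedigree member in the genotypes is a hard error", {
  g <- stats::setNames(rep("0/0", 7), FAM_SAMPLES[1:7])
  v <- make_variant(gt = g)
  expect_error(de_novo_screen(v, FAM), "WES-008")
})

test_that("dominant (penetrance off) and recessive screens are disjoint", {
  withr::local_seed(7)
  classes <- c("0/0", "0/1", "1/1", "./.")
  for (i in 1:300) {
    g <- stats::setNames(sample(classes, 8, replace = TRUE), FAM_SAMPLES)
    v <- make_variant(gt = g)
    ad <- autosomal_dominant_screen(v, FAM)$pass
    ar <- autosomal_recessive_screen(v, FAM)$pass
    expect_false(ad && ar)
  }
})

test_that("strict no-call policy candidate sets nest inside permissive ones", {
  sim <- simulate_cohort(sim_config(seed = 13, n_background = 300), FAM)
  cohort <- sim$cohort
  # knock out some genotypes to create no-calls
  withr::local_seed(13)
  hit <- sample(nrow(cohort), 60)
  for (i in hit) {
    g <- cohort$gt[[i]]
    g[sample(setdiff(FAM_SAMPLES, AFF), 2)] <- "./."
    cohort$gt[[i]] <- g
  }
  for (screen in list(de_novo_screen, autosomal_recessive_screen,
                      autosomal_dominant_screen, homozygous_screen)) {
    p <- screen(cohort, FAM, model_config("permissive"))$pass
    s <- screen(cohort, FAM, model_config("strict"))$pass
    expect_true(all(s <= p))
  }
})

test_that("twin concordance arithmetic matches its definition", {
  both <- make_variant(pos = 1, gt = fam_gt(stats::setNames(c("0/1", "0/1"),
                                                            c(AFF, UNAFF))))
  v <- dplyr::bind_rows(replicate(98, both, simplify = FALSE))
  v$pos <- 1:98
  only_a <- make_variant(pos = 99, gt = fam_gt(stats::setNames("0/1", AFF)))
  only_u <- make_variant(pos = 100, gt = fam_gt(stats::setNames("0/1", UNAFF)))
  cc <- twin_concordance(dplyr::bind_rows(v, only_a, only_u), FAM)
  expect_equal(cc$shared_count, 98)
  expect_equal(cc$unique_to_affected, 1)
  expect_equal(cc$unique_to_unaffected, 1)
  expect_equal(cc$percent_shared, 98.0)  # 100 * 98 / 100
  # degenerate directions
  all_shared <- twin_concordance(dplyr::bind_rows(v), FAM)
  expect_equal(all_shared$percent_shared, 100)
  none <- twin_concordance(only_a, FAM)
  expect_equal(none$percent_shared, 0)
})

test_that("screens are order-independent over the cohort", {
  sim <- simulate_cohort(sim_config(seed = 21, n_background = 200), FAM)
  fwd <- de_novo_screen(sim$cohort, FAM)$pass
  perm <- rev(seq_len(nrow(sim$cohort)))
  bwd <- de_novo_screen(sim$cohort[perm, ], FAM)$pass
  expect_equal(bwd, fwd[perm])
})
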