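test_that("allele fraction is alt/depth, absent at zero depth", {
  expect_equal(allele_fraction(1, 19), 1 / 19)
  expect_equal(allele_fraction(0, 30), 0)
  expect_true(is.na(allele_fraction(0, 0)))
  withr::local_seed(1)
  alt <- sample(0:50, 200, replace = TRUE)
  depth <- alt + sample(0:50, 200, replace = TRUE)
  aaf <- allele_fraction(alt, depth)
  ok <- !is.na(aaf)
  expect_true(all(aaf[ok] >= 0 & aaf[ok] <= 1))
})

test_that("strand bias flags one-sided alt support and Fisher imbalance", {
  # all six alt reads on one strand against balanced reference
  r <- strand_bias_flag(6, 0, 20, 20)
  expect_true(r$flag)
  expect_equal(r$p_value, fisher_p_enum(20, 20, 6, 0), tolerance = 1e-10)
  # balanced alt support
  expect_false(strand_bias_flag(5, 5, 20, 20)$flag)
  # a single alt read is below the one-strand minimum
  expect_false(strand_bias_flag(1, 0, 20, 20)$flag)
})

test_that("Fisher p-value matches hypergeometric enumeration on small tables", {
  for (n in c(4, 9, 16)) {
    tabs <- expand.grid(a = 0:n, b = 0:n, c = 0:n, d = 0:n)
    tabs <- tabs[rowSums(tabs) == n, ]
    p_pkg <- strand_bias_flag(tabs$c, tabs$d, tabs$a, tabs$b)$p_value
    p_oracle <- mapply(fisher_p_enum, tabs$a, tabs$b, tabs$c, tabs$d)
    expect_equal(p_pkg, unname(p_oracle), tolerance = 1e-8)
  }
})

test_that("review reproduces the three published verdict scenarios", {
  th <- review_thresholds()
  # low-fraction strand-skewed het call: technical artifact
  v1 <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  ev1 <- dplyr::bind_rows(ev_row(AFF, 44, 4, 0), ev_row(UNAFF, 40, 0, 0))
  r1 <- review_variant(v1, ev1, FAM, th)
  expect_equal(r1$verdict, "likely_artifact")
  s1 <- r1$per_sample[r1$per_sample$sample == AFF, ]
  expect_true(s1$low_alt_support)
  expect_true(s1$aaf_genotype_conflict)
  expect_equal(s1$aaf, 4 / 44)
  # single alternate read under a homozygous call: technical artifact
  v2 <- make_variant(gt = fam_gt(stats::setNames("1/1", AFF)))
  ev2 <- dplyr::bind_rows(ev_row(AFF, 19, 1, 0), ev_row(UNAFF, 25, 0, 0))
  r2 <- review_variant(v2, ev2, FAM, th)
  expect_equal(r2$verdict, "likely_artifact")
  # low depth with balanced, adequate support: uncertain
  v3 <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  ev3 <- dplyr::bind_rows(ev_row(AFF, 18, 4, 5), ev_row(UNAFF, 30, 0, 0))
  r3 <- review_variant(v3, ev3, FAM, th)
  expect_equal(r3$verdict, "uncertain")
  # clean deep het: supported
  v4 <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  ev4 <- dplyr::bind_rows(ev_row(AFF, 40, 9, 9), ev_row(UNAFF, 40, 0, 0))
  expect_equal(review_variant(v4, ev4, FAM, th)$verdict, "supported")
})

test_that("no-call genotypes always review as uncertain", {
  v <- make_variant(gt = fam_gt(stats::setNames("./.", AFF)))
  ev <- dplyr::bind_rows(ev_row(AFF, 40, 10, 10), ev_row(UNAFF, 40, 0, 0))
  r <- review_variant(v, ev, FAM)
  expect_equal(r$per_sample$verdict[r$per_sample$sample == AFF],
               "uncertain")
})

test_that("evidence must cover the twin pair and match genotyped samples", {
  v <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  expect_error(review_variant(v, ev_row(AFF, 40, 10, 10), FAM),
               "twin pair")
  bad <- dplyr::bind_rows(ev_row(AFF, 40, 10, 10), ev_row(UNAFF, 40, 0, 0),
                          ev_row("WES-099", 40, 0, 0))
  expect_error(review_variant(v, bad, FAM), "WES-099")
})

test_that("added genotype-concordant reads never worsen the verdict", {
  v <- make_variant(gt = fam_gt(stats::setNames("0/1", AFF)))
  lvl <- function(verdict) {
    match(verdict, c("supported", "uncertain", "likely_artifact"))
  }
  prev <- Inf
  for (extra in seq(0, 40, by = 4)) {
    # each step adds two alt and two ref reads, strand-balanced, so the
    # allele fraction stays consistent with the het call
    ev <- dplyr::bind_rows(
      ev_row(AFF, 18 + 4 * extra, 4 + extra, 5 + extra),
      ev_row(UNAFF, 30, 0, 0)
    )
    cur <- lvl(review_variant(v, ev, FAM)$verdict)
    expect_lte(cur, prev)
    prev <- cur
  }
})
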