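#' Configuration for the family exome simulator
#'
#' The simulator produces a cohort with the statistical structure the
#' prioritization pipeline assumes: unlinked biallelic exonic sites,
#' founder genotypes drawn binomially from a site allele frequency,
#' offspring by Mendelian transmission, the monozygotic twins
#' genotype-identical at every background site, plus planted
#' model-specific candidate variants with deterministic genotypes and
#' tier-targeted annotation scores, and optional injected artifacts that
#' reproduce the failure modes read-level review is meant to catch.
#'
#' Default planted counts mirror the strict-tier candidate yield of the
#' motivating family study (5 de novo, 4 recessive, 6 dominant, 9
#' twin-concordant homozygous).
#'
#' @param seed Integer seed; mandatory. Each generation component
#'   (background sites, planted sites, artifacts, pileup, QC) reseeds from
#'   a sub-seed derived from it, so outputs are byte-identical across runs.
#' @param n_background Number of background (non-planted) sites.
#' @param n_de_novo,n_recessive,n_dominant,n_homozygous_concordant Planted
#'   variant counts per genotype model.
#' @param tier_targets Named list (`de_novo`, `autosomal_recessive`,
#'   `autosomal_dominant`, `homozygous_concordant`) of per-variant
#'   pathogenicity tier targets, each a character vector recycled to the
#'   planted count with values in `strict_pass`, `liberal_only`, `fail`.
#' @param artifact_injections List of `list(model =, index =, type =)`
#'   entries; `type` is one of `low_depth`, `strand_biased_alt`,
#'   `no_call_others`, `low_aaf_carrier`.
#' @param af_shape Beta distribution shape parameters for background
#'   allele frequencies.
#' @param af_bounds Truncation bounds for background allele frequencies.
#' @param panel_spike Optional gene symbol: adds one twin-discordant
#'   variant annotated to that gene (for panel-screen testing).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_background = 5000,
                       n_de_novo = 5,
                       n_recessive = 4,
                       n_dominant = 6,
                       n_homozygous_concordant = 9,
                       tier_targets = list(),
                       artifact_injections = list(),
                       af_shape = c(0.5, 5),
                       af_bounds = c(1e-4, 0.5),
                       panel_spike = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  counts <- c(de_novo = n_de_novo, autosomal_recessive = n_recessive,
              autosomal_dominant = n_dominant,
              homozygous_concordant = n_homozygous_concordant)
  if (any(counts < 0) || n_background < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tiers <- lapply(names(counts), function(m) {
    tt <- tier_targets[[m]] %||% "strict_pass"
    bad <- setdiff(tt, c("strict_pass", "liberal_only", "fail"))
    if (length(bad)) stop("unknown tier target: ", bad[1], call. = FALSE)
    if (counts[[m]] == 0) character() else rep_len(tt, counts[[m]])
  })
  names(tiers) <- names(counts)
  structure(
    list(seed = as.integer(seed), n_background = n_background,
         n_planted = counts, tier_targets = tiers,
         artifact_injections = artifact_injections,
         af_shape = af_shape, af_bounds = af_bounds,
         panel_spike = panel_spike),
    class = "sim_config"
  )
}

# sub-seed per generation component, kept well under 2^31
sub_seed <- function(seed, k) (abs(seed) %% 2^20) * 1024L + k

rbeta_trunc <- function(n, shape, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rbeta(n, shape[1], shape[2])
    out <- c(out, draw[draw >= bounds[1] & draw <= bounds[2]])
  }
  out[seq_len(n)]
}

gt_string <- function(count) c("0/0", "0/1", "1/1")[count + 1L]

# transmit one allele from a parent with `count` alt alleles (0/1/2)
transmit <- function(count) {
  rbinom(length(count), 1L, count / 2)
}

PLANT_PATTERNS <- list(
  de_novo = function(ped) {
    g <- stats::setNames(rep("0/0", nrow(ped$members)),
                         ped$members$sample_id)
    g[ped$affected_twin] <- "0/1"
    g
  },
  autosomal_recessive = function(ped) {
    g <- stats::setNames(rep("0/1", nrow(ped$members)),
                         ped$members$sample_id)
    g[ped$affected_twin] <- "1/1"
    g
  },
  autosomal_dominant = function(ped) {
    g <- stats::setNames(rep("0/0", nrow(ped$members)),
                         ped$members$sample_id)
    g[ped$affected_twin] <- "0/1"
    g
  },
  homozygous_concordant = function(ped) {
    g <- stats::setNames(rep("0/1", nrow(ped$members)),
                         ped$members$sample_id)
    g[c(ped$affected_twin, ped$unaffected_twin)] <- "1/1"
    g
  }
)

# models whose screen predicate the planted genotype pattern satisfies
# (affected het + everyone reference is both a de novo and a dominant
# pattern; an affected homozygote is always seen by the homozygous screen)
PLANT_COMPATIBLE <- list(
  de_novo = c("de_novo", "autosomal_dominant"),
  autosomal_recessive = c("autosomal_recessive", "homozygous_affected"),
  autosomal_dominant = c("autosomal_dominant", "de_novo"),
  homozygous_concordant = "homozygous_affected"
)

tier_scores <- function(tier) {
  switch(tier,
    strict_pass = list(cadd = runif(1, 21, 35), revel = runif(1, 0.5, 0.99),
                       sift = "D", pp2 = "D", mt = "D"),
    liberal_only = list(cadd = runif(1, 5, 19.5), revel = runif(1, 0, 0.45),
                        sift = "D", pp2 = "P", mt = "D"),
    fail = list(cadd = runif(1, 0, 10), revel = runif(1, 0, 0.3),
                sift = "T", pp2 = "B", mt = "N")
  )
}

#' Simulate an annotated family exome cohort
#'
#' Generates the full input bundle for the pipeline: an annotated
#' multi-sample VCF-shaped cohort table, a pileup evidence summary, QC
#' metrics, and a truth table recording what was planted where. When
#' `dir` is given, all five files (VCF, pileup TSV, QC TSV, truth TSV,
#' PED) are written there; identical seeds give byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param ped A [twin_pedigree()]; defaults to the eight-member
#'   [default_family()].
#' @param dir Optional output directory.
#' @return List with `cohort`, `truth`, `pileup`, `qc`, and (when `dir`
#'   is given) `paths`.
#' @export
simulate_cohort <- function(cfg, ped = default_family(), dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ped, "twin_pedigree"))
  samples <- pedigree_samples(ped)
  n_total_planted <- sum(cfg$n_planted) + as.integer(!is.null(cfg$panel_spike))
  if (cfg$n_background > 0 && n_total_planted > cfg$n_background) {
    stop("more planted sites than background context", call. = FALSE)
  }

  # --- component 1: site scaffold (positions, alleles, frequencies) ----
  set.seed(sub_seed(cfg$seed, 1L))
  n_sites <- cfg$n_background + n_total_planted
  repeat {
    chrom <- sample(paste0("chr", 1:22), n_sites, replace = TRUE)
    pos <- sample.int(2e8L, n_sites, replace = TRUE) + 1e6L
    if (!anyDuplicated(paste(chrom, pos))) break
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  is_bg <- c(rep(TRUE, cfg$n_background), rep(FALSE, n_total_planted))
  af <- rbeta_trunc(n_sites, cfg$af_shape, cfg$af_bounds)

  # --- component 2: background genotypes by Mendelian transmission -----
  set.seed(sub_seed(cfg$seed, 2L))
  nb <- cfg$n_background
  gt_mat <- matrix("0/0", nrow = n_sites, ncol = length(samples),
                   dimnames = list(NULL, samples))
  if (nb > 0) {
    fa_cnt <- rbinom(nb, 2L, af[seq_len(nb)])
    mo_cnt <- rbinom(nb, 2L, af[seq_len(nb)])
    gt_mat[seq_len(nb), ped$father] <- gt_string(fa_cnt)
    gt_mat[seq_len(nb), ped$mother] <- gt_string(mo_cnt)
    twin_cnt <- transmit(fa_cnt) + transmit(mo_cnt)
    gt_mat[seq_len(nb), ped$affected_twin] <- gt_string(twin_cnt)
    gt_mat[seq_len(nb), ped$unaffected_twin] <- gt_string(twin_cnt)
    for (s in ped$siblings) {
      gt_mat[seq_len(nb), s] <- gt_string(transmit(fa_cnt) + transmit(mo_cnt))
    }
  }

  # background annotations
  func_region <- rep(NA_character_, n_sites)
  exonic_class <- rep(NA_character_, n_sites)
  gene <- sprintf("GENE%05d", seq_len(n_sites))
  filter_status <- rep("PASS", n_sites)
  cadd <- revel <- rep(NA_real_, n_sites)
  sift_p <- pp2_p <- mt_p <- rep(NA_character_, n_sites)
  af_gx <- af_gg <- af_ex <- rep(NA_real_, n_sites)
  if (nb > 0) {
    i <- seq_len(nb)
    func_region[i] <- sample(c("exonic", "intronic", "UTR", "splicing",
                               "intergenic"),
                             nb, replace = TRUE,
                             prob = c(0.55, 0.2, 0.15, 0.05, 0.05))
    exonic_class[i] <- ifelse(
      func_region[i] == "exonic",
      sample(c("nonsynonymous_SNV", "synonymous_SNV", "stopgain",
               "frameshift_insertion", "frameshift_deletion"),
             nb, replace = TRUE, prob = c(0.5, 0.35, 0.05, 0.05, 0.05)),
      NA_character_)
    filter_status[i] <- sample(c("PASS", "LowQual"), nb, replace = TRUE,
                               prob = c(0.95, 0.05))
    cadd[i] <- round(runif(nb, 0, 35), 2)
    revel[i] <- round(runif(nb, 0, 1), 3)
    sift_p[i] <- sample(c("D", "T", NA), nb, replace = TRUE,
                        prob = c(0.25, 0.6, 0.15))
    pp2_p[i] <- sample(c("D", "P", "B", NA), nb, replace = TRUE,
                       prob = c(0.15, 0.15, 0.55, 0.15))
    mt_p[i] <- sample(c("D", "A", "P", "N", NA), nb, replace = TRUE,
                      prob = c(0.1, 0.1, 0.3, 0.35, 0.15))
    af_gx[i] <- signif(af[i], 4)
    af_gg[i] <- signif(pmin(af[i] * runif(nb, 0.7, 1.3), 1), 4)
    af_ex[i] <- ifelse(runif(nb) < 0.7, signif(af[i], 4), NA_real_)
  }

  # --- component 3: planted sites --------------------------------------
  set.seed(sub_seed(cfg$seed, 3L))
  label <- c(rep("background", nb),
             rep(names(cfg$n_planted), cfg$n_planted),
             if (!is.null(cfg$panel_spike)) "panel_spike")
  tier <- rep(NA_character_, n_sites)
  gene_codes <- c(de_novo = "PLDN", autosomal_recessive = "PLAR",
                  autosomal_dominant = "PLAD",
                  homozygous_concordant = "PLHC")
  idx <- nb
  planted_index <- rep(NA_integer_, n_sites)
  for (m in names(cfg$n_planted)) {
    for (j in seq_len(cfg$n_planted[[m]])) {
      idx <- idx + 1L
      planted_index[idx] <- j
      gt_mat[idx, ] <- PLANT_PATTERNS[[m]](ped)[samples]
      tt <- cfg$tier_targets[[m]][j]
      tier[idx] <- tt
      sc <- tier_scores(tt)
      cadd[idx] <- round(sc$cadd, 2)
      revel[idx] <- round(sc$revel, 3)
      sift_p[idx] <- sc$sift
      pp2_p[idx] <- sc$pp2
      mt_p[idx] <- sc$mt
      gene[idx] <- sprintf("%s%d", gene_codes[[m]], j)
      func_region[idx] <- "exonic"
      exonic_class[idx] <- "nonsynonymous_SNV"
      filter_status[idx] <- "PASS"
      af_gx[idx] <- if (runif(1) < 0.5) NA_real_ else signif(runif(1, 0, 9e-4), 3)
    }
  }
  if (!is.null(cfg$panel_spike)) {
    idx <- idx + 1L
    gt_mat[idx, ] <- PLANT_PATTERNS$de_novo(ped)[samples]
    gene[idx] <- toupper(cfg$panel_spike)
    func_region[idx] <- "exonic"
    exonic_class[idx] <- "nonsynonymous_SNV"
    filter_status[idx] <- "PASS"
    cadd[idx] <- 10
    revel[idx] <- 0.1
    sift_p[idx] <- "T"
    tier[idx] <- "fail"
  }

  # intended genotypes, before any artifact touches the VCF
  intended_gt <- gt_mat

  # --- component 4: artifact injection ---------------------------------
  set.seed(sub_seed(cfg$seed, 4L))
  artifact <- rep("none", n_sites)
  art_rows <- integer(0)
  for (inj in cfg$artifact_injections) {
    row <- which(label == inj$model)[inj$index]
    if (is.na(row)) {
      stop("artifact injection points at a non-existent planted site",
           call. = FALSE)
    }
    artifact[row] <- inj$type
    art_rows <- c(art_rows, row)
    if (inj$type == "no_call_others") {
      others <- setdiff(samples, ped$affected_twin)
      gt_mat[row, others] <- "./."
    }
    if (inj$type == "low_aaf_carrier") {
      gt_mat[row, ped$affected_twin] <- "0/1"
    }
  }

  cohort <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    filter_status = filter_status, gene = gene,
    func_region = func_region, exonic_class = exonic_class,
    cdna_change = NA_character_, protein_change = NA_character_,
    clinvar = NA_character_,
    af_gnomad_exome = af_gx, af_gnomad_genome = af_gg, af_exac = af_ex,
    cadd_phred = cadd, revel = revel,
    sift_pred = sift_p, sift_score = ifelse(is.na(sift_p), NA_real_, 0.01),
    polyphen2_pred = pp2_p,
    polyphen2_score = ifelse(is.na(pp2_p), NA_real_, 0.9),
    mutation_taster_pred = mt_p,
    mutation_taster_score = ifelse(is.na(mt_p), NA_real_, 0.9),
    gt = lapply(seq_len(n_sites), function(i) {
      stats::setNames(gt_mat[i, ], samples)
    })
  )

  truth <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    label = label, planted_index = planted_index,
    tier_target = tier, artifact = artifact,
    mendelian_exempt = label %in% c("de_novo", "autosomal_dominant",
                                    "panel_spike"),
    compatible_models = vapply(label, function(l) {
      paste(PLANT_COMPATIBLE[[l]] %||% character(), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  )
  for (s in samples) truth[[paste0("gt_", s)]] <- intended_gt[, s]

  # --- component 5: pileup evidence at planted sites -------------------
  set.seed(sub_seed(cfg$seed, 5L))
  ev_rows <- which(!is_bg)
  pileup <- make_pileup(cohort, ev_rows, artifact, ped, samples)

  # --- component 6: per-sample QC metrics ------------------------------
  set.seed(sub_seed(cfg$seed, 6L))
  mean_cov <- round(stats::rnorm(length(samples), 159, 15), 2)
  qc <- tibble::tibble(
    sample = samples,
    mean_coverage = mean_cov,
    pct_ge20x = round(pmin(stats::rnorm(length(samples), 94.9, 0.15), 100), 2),
    pct_ge50x = round(pmin(stats::rnorm(length(samples), 92.1, 0.8), 100), 2),
    aligned_reads = round(mean_cov * 443400),
    uniformity = round(pmin(stats::rnorm(length(samples), 94.1, 0.06), 100), 2)
  )
  qc$pct_ge50x <- pmin(qc$pct_ge50x, qc$pct_ge20x)

  # deterministic site order
  ord <- order(chrom_rank(cohort$chrom), cohort$pos, cohort$alt)
  cohort <- cohort[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]

  out <- list(cohort = cohort, truth = truth, pileup = pileup, qc = qc)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      pileup = file.path(dir, "pileup.tsv"),
      qc = file.path(dir, "qc_metrics.tsv"),
      truth = file.path(dir, "truth.tsv"),
      ped = file.path(dir, "family.ped")
    )
    write_cohort_vcf(cohort, paths$vcf)
    readr::write_tsv(pileup, paths$pileup)
    readr::write_tsv(qc, paths$qc)
    readr::write_tsv(truth, paths$truth)
    write_pedigree(ped, paths$ped)
    out$paths <- paths
  }
  out
}

make_pileup <- function(cohort, rows, artifact, ped, samples) {
  recs <- vector("list", length(rows) * length(samples))
  k <- 0L
  for (r in rows) {
    gts <- cohort$gt[[r]]
    art <- artifact[r]
    for (s in samples) {
      cls <- classify_genotype(gts[[s]])
      depth <- max(30L, as.integer(round(stats::rnorm(1, 155, 20))))
      alt_n <- switch(cls,
        het = rbinom(1, depth, 0.5),
        hom_alt = depth - rbinom(1, depth, 0.03),
        0L)
      if (art == "low_depth") {
        depth <- sample(10:19, 1)
        alt_n <- switch(cls, het = rbinom(1, depth, 0.5),
                        hom_alt = depth - rbinom(1, depth, 0.03),
                        0L)
      }
      # clean evidence is strand-balanced by construction; artifacts below
      # are the only source of imbalance
      alt_f <- alt_n %/% 2L
      if (art == "strand_biased_alt" && cls %in% c("het", "hom_alt")) {
        alt_f <- alt_n
      }
      if (art == "low_aaf_carrier" && s == ped$affected_twin) {
        depth <- 44L
        alt_n <- 4L
        alt_f <- alt_n
      }
      if (art == "no_call_others") {
        if (s == ped$affected_twin) {
          depth <- 19L; alt_n <- 1L; alt_f <- 1L
        } else {
          depth <- sample(18:28, 1); alt_n <- 0L; alt_f <- 0L
        }
      }
      ref_n <- depth - alt_n
      ref_f <- ref_n %/% 2L
      k <- k + 1L
      recs[[k]] <- tibble::tibble(
        sample = s, chrom = cohort$chrom[r], pos = cohort$pos[r],
        ref = cohort$ref[r], alt = cohort$alt[r],
        depth = as.integer(depth), alt_fwd = as.integer(alt_f),
        alt_rev = as.integer(alt_n - alt_f),
        ref_fwd = as.integer(ref_f), ref_rev = as.integer(ref_n - ref_f)
      )
    }
  }
  if (k == 0L) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), depth = integer(),
                          alt_fwd = integer(), alt_rev = integer(),
                          ref_fwd = integer(), ref_rev = integer()))
  }
  dplyr::bind_rows(recs[seq_len(k)])
}

#' Count Mendelian-inconsistent offspring genotypes
#'
#' For every non-exempt site and every offspring with both parents in the
#' pedigree, checks that the offspring genotype can be formed from one
#' allele of each parent. No-call genotypes (offspring or parent) are
#' uninformative and never counted as violations.
#'
#' @param cohort A [cohort table][cohort-table].
#' @param ped A [twin_pedigree()].
#' @param exempt_keys Character vector of `chrom:pos:ref:alt` keys to skip
#'   (e.g. planted de novo sites).
#' @return Integer violation count (offspring-genotype granularity).
#' @export
mendelian_check <- function(cohort, ped, exempt_keys = character()) {
  if (nrow(cohort) == 0L) return(0L)
  keys <- variant_keys(cohort)
  keep <- !(keys %in% exempt_keys)
  if (!any(keep)) return(0L)
  cls <- gt_class_matrix(cohort)[keep, , drop = FALSE]
  has0 <- function(x) x %in% c("hom_ref", "het", "no_call")
  has1 <- function(x) x %in% c("hom_alt", "het", "no_call")
  m <- ped$members
  offspring <- m$sample_id[!is.na(m$father_id) & !is.na(m$mother_id)]
  violations <- 0L
  for (child in offspring) {
    fa <- cls[, m$father_id[m$sample_id == child]]
    mo <- cls[, m$mother_id[m$sample_id == child]]
    ch <- cls[, child]
    ok <- rep(TRUE, length(ch))
    ok[ch == "hom_ref"] <- (has0(fa) & has0(mo))[ch == "hom_ref"]
    ok[ch == "hom_alt"] <- (has1(fa) & has1(mo))[ch == "hom_alt"]
    ok[ch == "het"] <- ((has0(fa) & has1(mo)) |
                          (has1(fa) & has0(mo)))[ch == "het"]
    violations <- violations + sum(!ok)
  }
  violations
}

#' Canonical `chrom:pos:ref:alt` variant keys
#' @param x A cohort or truth table with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_keys <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}
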