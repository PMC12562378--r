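#' @section Cohort tables:
#' Most functions in this package exchange a *cohort table*: a tibble with
#' one row per biallelic (site, alternate allele) pair and columns
#' `chrom`, `pos`, `ref`, `alt`, `filter_status`, `gene`, `func_region`,
#' `exonic_class`, `cdna_change`, `protein_change`, `clinvar`,
#' `af_gnomad_exome`, `af_gnomad_genome`, `af_exac`, `cadd_phred`, `revel`,
#' `sift_pred`, `sift_score`, `polyphen2_pred`, `polyphen2_score`,
#' `mutation_taster_pred`, `mutation_taster_score`, and `gt` — a list-column
#' holding, per variant, a named character vector of genotype strings
#' covering every pedigree sample.
#' @name cohort-table
NULL

COHORT_SCORE_COLS <- c("cadd_phred", "revel", "sift_score",
                       "polyphen2_score", "mutation_taster_score")
COHORT_AF_COLS <- c("af_gnomad_exome", "af_gnomad_genome", "af_exac")

empty_cohort <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), filter_status = character(),
    gene = character(), func_region = character(),
    exonic_class = character(), cdna_change = character(),
    protein_change = character(), clinvar = character(),
    af_gnomad_exome = double(), af_gnomad_genome = double(),
    af_exac = double(),
    cadd_phred = double(), revel = double(),
    sift_pred = character(), sift_score = double(),
    polyphen2_pred = character(), polyphen2_score = double(),
    mutation_taster_pred = character(), mutation_taster_score = double(),
    gt = list()
  )
}

info_field <- function(info_list, key, missing_token) {
  if (is.na(key) || is.null(key)) return(rep(NA_character_, length(info_list)))
  v <- vapply(info_list, function(kv) kv[key] %||% NA_character_,
              character(1), USE.NAMES = FALSE)
  v[!is.na(v) & (v == missing_token | v == "")] <- NA_character_
  v
}

# pick the i-th entry of an allele-indexed (Number=A) comma list; scalar
# fields pass through unchanged
alt_indexed <- function(x, i, n_alt) {
  if (is.na(x)) return(NA_character_)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  if (length(parts) == n_alt) parts[i] else x
}

#' Read an annotated multi-sample VCF into a cohort table
#'
#' Parses a VCFv4.2 file (plain or bgzip-compressed) whose INFO column
#' carries ANNOVAR-style annotations, and returns one row per (site,
#' alternate allele): multiallelic records are decomposed into biallelic
#' ones. In a decomposed record, sample alleles equal to the current
#' alternate become `1`, reference stays `0`, and alleles belonging to any
#' *other* alternate become missing (`.`) — this avoids phantom
#' homozygous-reference calls when screening genotype models.
#'
#' Annotation INFO fields are mapped through `dialect`; fields absent from a
#' record become `NA`, never a default. Allele-indexed (comma-separated,
#' one entry per alternate) annotation values are split per decomposed
#' allele.
#'
#' @param path Path to the VCF file.
#' @param dialect An [annotation_dialect()].
#' @param expected_samples Optional character vector; every listed sample
#'   must be present in the VCF header or the read fails naming the missing
#'   sample.
#' @return A [cohort table][cohort-table].
#' @export
read_cohort <- function(path, dialect = default_dialect(),
                        expected_samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(expected_samples)) {
    absent <- setdiff(expected_samples, samples)
    if (length(absent) > 0) {
      stop("expected sample(s) missing from VCF header: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(fix)
  if (n == 0L) return(empty_cohort())

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = n, dimnames = list(NULL, samples))
  }
  bad <- !is.na(gt_raw) & !grepl("^(\\.|\\d+)[/|](\\.|\\d+)$", gt_raw)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype '%s' for sample %s at %s:%s",
                 gt_raw[bad][1], samples[idx[2]],
                 fix[idx[1], "CHROM"], fix[idx[1], "POS"]), call. = FALSE)
  }
  gt_raw[is.na(gt_raw)] <- "./."

  info_list <- lapply(fix[, "INFO"], function(s) {
    if (is.na(s) || s == "" || s == ".") return(character())
    kv <- strsplit(s, ";", fixed = TRUE)[[1]]
    eq <- regexpr("=", kv, fixed = TRUE)
    keys <- ifelse(eq > 0, substr(kv, 1, eq - 1), kv)
    vals <- ifelse(eq > 0, substr(kv, eq + 1, nchar(kv)), "TRUE")
    stats::setNames(vals, keys)
  })

  slot_raw <- list()
  scalar_slots <- c("gene", "func_region", "exonic_class", "aachange",
                    "clinvar", "cadd", "revel", "sift_pred", "sift_score",
                    "polyphen2_pred", "polyphen2_score",
                    "mutation_taster_pred", "mutation_taster_score")
  for (s in scalar_slots) {
    slot_raw[[s]] <- info_field(info_list, dialect[[s]], dialect$missing_token)
  }
  af_raw <- lapply(dialect$pop_freqs, function(k) {
    info_field(info_list, k, dialect$missing_token)
  })

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    per_alt <- vector("list", n_alt)
    for (j in seq_len(n_alt)) {
      gt_j <- remap_gt(gt_raw[i, ], j)
      grab <- function(s) alt_indexed(slot_raw[[s]][i], j, n_alt)
      aach <- parse_aachange(grab("aachange"))
      per_alt[[j]] <- tibble::tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[j],
        filter_status = unname(fix[i, "FILTER"] %|na|% "."),
        gene = grab("gene"),
        func_region = normalize_func_region(grab("func_region")),
        exonic_class = normalize_exonic_class(grab("exonic_class")),
        cdna_change = aach[1, "cdna_change"],
        protein_change = aach[1, "protein_change"],
        clinvar = grab("clinvar"),
        af_gnomad_exome = num_or_na(alt_indexed(af_raw$gnomad_exome[i], j, n_alt)),
        af_gnomad_genome = num_or_na(alt_indexed(af_raw$gnomad_genome[i], j, n_alt)),
        af_exac = num_or_na(alt_indexed(af_raw$exac[i], j, n_alt)),
        cadd_phred = num_or_na(grab("cadd")),
        revel = num_or_na(grab("revel")),
        sift_pred = grab("sift_pred"),
        sift_score = num_or_na(grab("sift_score")),
        polyphen2_pred = grab("polyphen2_pred"),
        polyphen2_score = num_or_na(grab("polyphen2_score")),
        mutation_taster_pred = grab("mutation_taster_pred"),
        mutation_taster_score = num_or_na(grab("mutation_taster_score")),
        gt = list(stats::setNames(gt_j, samples))
      )
    }
    rows[[i]] <- dplyr::bind_rows(per_alt)
  }
  dplyr::bind_rows(rows)
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# remap a vector of raw genotype strings onto the j-th alternate allele:
# j -> 1, 0 -> 0, anything else (other alts, missing) -> .
remap_gt <- function(gt, j) {
  vapply(gt, function(g) {
    sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
    alleles <- strsplit(g, sep, fixed = TRUE)[[1]]
    mapped <- vapply(alleles, function(a) {
      if (a == "0") "0" else if (a == as.character(j)) "1" else "."
    }, character(1))
    paste(mapped, collapse = sep)
  }, character(1), USE.NAMES = FALSE)
}

#' Write a cohort table as an annotated VCFv4.2 file
#'
#' Emits a plain-text multi-sample VCF whose INFO keys follow `dialect`.
#' `NA` annotation values are written as the dialect's missing token so the
#' file round-trips through [read_cohort()].
#'
#' @param cohort A [cohort table][cohort-table].
#' @param path Output path (plain text).
#' @param dialect An [annotation_dialect()].
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, dialect = default_dialect()) {
  samples <- if (nrow(cohort) > 0) names(cohort$gt[[1]]) else character()
  tok <- dialect$missing_token
  fmt <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x) | x == "", tok, x)
  }
  info_keys <- c(dialect$gene, dialect$func_region, dialect$exonic_class,
                 dialect$aachange, unname(dialect$pop_freqs), dialect$clinvar,
                 dialect$cadd, dialect$revel,
                 dialect$sift_pred, dialect$sift_score,
                 dialect$polyphen2_pred, dialect$polyphen2_score,
                 dialect$mutation_taster_pred, dialect$mutation_taster_score)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"Annotation\">",
            info_keys),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  aach <- ifelse(
    is.na(cohort$cdna_change) & is.na(cohort$protein_change), NA_character_,
    paste(fmt(cohort$gene),
          sub("^(NM_[0-9]+):.*$", "\\1", fmt(cohort$cdna_change)),
          "exon1",
          sub("^NM_[0-9]+:", "", fmt(cohort$cdna_change)),
          fmt(cohort$protein_change), sep = ":")
  )
  body <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    info <- paste0(
      dialect$gene, "=", fmt(cohort$gene[i]), ";",
      dialect$func_region, "=", fmt(cohort$func_region[i]), ";",
      dialect$exonic_class, "=", fmt(cohort$exonic_class[i]), ";",
      dialect$aachange, "=", fmt(aach[i]), ";",
      dialect$pop_freqs[["gnomad_exome"]], "=", fmt(cohort$af_gnomad_exome[i]), ";",
      dialect$pop_freqs[["gnomad_genome"]], "=", fmt(cohort$af_gnomad_genome[i]), ";",
      dialect$pop_freqs[["exac"]], "=", fmt(cohort$af_exac[i]), ";",
      dialect$clinvar, "=", fmt(cohort$clinvar[i]), ";",
      dialect$cadd, "=", fmt(cohort$cadd_phred[i]), ";",
      dialect$revel, "=", fmt(cohort$revel[i]), ";",
      dialect$sift_pred, "=", fmt(cohort$sift_pred[i]), ";",
      dialect$sift_score, "=", fmt(cohort$sift_score[i]), ";",
      dialect$polyphen2_pred, "=", fmt(cohort$polyphen2_pred[i]), ";",
      dialect$polyphen2_score, "=", fmt(cohort$polyphen2_score[i]), ";",
      dialect$mutation_taster_pred, "=", fmt(cohort$mutation_taster_pred[i]), ";",
      dialect$mutation_taster_score, "=", fmt(cohort$mutation_taster_score[i])
    )
    body[i] <- paste(c(cohort$chrom[i], cohort$pos[i], ".", cohort$ref[i],
                       cohort$alt[i], ".", cohort$filter_status[i], info,
                       "GT", unname(cohort$gt[[i]][samples])),
                     collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# "D (0.001)" / "D" / "." -> pred + score
parse_pred_score <- function(x) {
  x <- trimws(as.character(x))
  pred <- rep(NA_character_, length(x))
  score <- rep(NA_real_, length(x))
  has <- !is.na(x) & x != "" & x != "." & x != "-"
  m <- regmatches(x[has], regexec("^([A-Za-z]+)\\s*(?:\\(([-0-9.eE]+)\\))?$",
                                  x[has]))
  pred[has] <- vapply(m, function(g) if (length(g)) g[2] else NA_character_,
                      character(1))
  score[has] <- vapply(m, function(g) {
    if (length(g) >= 3 && nzchar(g[3])) as.numeric(g[3]) else NA_real_
  }, double(1))
  list(pred = pred, score = score)
}

format_pred_score <- function(pred, score) {
  ifelse(is.na(pred), ".",
         ifelse(is.na(score), pred, paste0(pred, " (", score, ")")))
}

#' Write a candidate-variant table
#'
#' Writes prioritized candidates as a tab-separated table in the layout used
#' for reporting: variant key, annotation, scores in `category (score)`
#' style, one genotype column per sample, and the admitting inheritance
#' model. Rows are ordered deterministically by chromosome (natural order),
#' position and alternate allele.
#'
#' @param cohort A [cohort table][cohort-table] (may carry a `model`
#'   column; if absent, `model` is written empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_candidates()] for the inverse.
#' @export
write_candidates <- function(cohort, path) {
  ord <- order(chrom_rank(cohort$chrom), cohort$pos, cohort$alt)
  cohort <- cohort[ord, , drop = FALSE]
  samples <- if (nrow(cohort) > 0 && length(cohort$gt) > 0) {
    names(cohort$gt[[1]])
  } else {
    character()
  }
  out <- tibble::tibble(
    Gene = cohort$gene, Chr = cohort$chrom, Pos = cohort$pos,
    Ref = cohort$ref, Alt = cohort$alt,
    cDNA = cohort$cdna_change, Protein = cohort$protein_change,
    ExonicClass = cohort$exonic_class,
    CADD = cohort$cadd_phred, REVEL = cohort$revel,
    SIFT = format_pred_score(cohort$sift_pred, cohort$sift_score),
    PolyPhen2 = format_pred_score(cohort$polyphen2_pred,
                                  cohort$polyphen2_score),
    MutationTaster = format_pred_score(cohort$mutation_taster_pred,
                                       cohort$mutation_taster_score)
  )
  for (s in samples) {
    out[[paste0("GT_", s)]] <- vapply(cohort$gt, `[[`, character(1), s)
  }
  out$Model <- if ("model" %in% names(cohort)) cohort$model else ""
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' Read a candidate-variant table back into a cohort table
#'
#' Inverse of [write_candidates()]: score columns in `category (score)`
#' style are parsed back into separate prediction and score fields, and
#' `GT_*` columns are folded back into the genotype list-column.
#'
#' @param path Path to a TSV written by [write_candidates()].
#' @return A [cohort table][cohort-table] (with `filter_status` `NA`; the
#'   candidate layout does not carry it).
#' @export
read_candidates <- function(path) {
  raw <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  gt_cols <- grep("^GT_", names(raw), value = TRUE)
  sift <- parse_pred_score(raw$SIFT)
  pp2 <- parse_pred_score(raw$PolyPhen2)
  mt <- parse_pred_score(raw$MutationTaster)
  out <- tibble::tibble(
    chrom = raw$Chr, pos = as.integer(raw$Pos),
    ref = raw$Ref, alt = raw$Alt,
    filter_status = NA_character_,
    gene = raw$Gene, func_region = "exonic",
    exonic_class = normalize_exonic_class(raw$ExonicClass),
    cdna_change = raw$cDNA, protein_change = raw$Protein,
    clinvar = NA_character_,
    af_gnomad_exome = NA_real_, af_gnomad_genome = NA_real_,
    af_exac = NA_real_,
    cadd_phred = as.numeric(raw$CADD), revel = as.numeric(raw$REVEL),
    sift_pred = sift$pred, sift_score = sift$score,
    polyphen2_pred = pp2$pred, polyphen2_score = pp2$score,
    mutation_taster_pred = mt$pred, mutation_taster_score = mt$score,
    gt = lapply(seq_len(nrow(raw)), function(i) {
      stats::setNames(
        vapply(gt_cols, function(cn) raw[[cn]][i] %|na|% "./.", character(1)),
        sub("^GT_", "", gt_cols)
      )
    })
  )
  if ("Model" %in% names(raw)) out$model <- raw$Model %|na|% ""
  out
}
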