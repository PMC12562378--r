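#' Classify diploid genotype calls
#'
#' Maps VCF-style genotype strings onto the four classes used throughout the
#' family screens: `hom_ref` (0/0), `het` (0/1 or 1/0), `hom_alt` (1/1) and
#' `no_call` (any missing allele, including half-calls such as `./1`).
#' Phasing separators (`|` vs `/`) are ignored: phased and unphased encodings
#' of the same allele pair classify identically.
#'
#' All cohorts handled by this package are biallelic after multiallelic
#' decomposition, so allele indices other than 0 and 1 are treated as missing
#' (they refer to an alternate allele that is not the one under test).
#'
#' @param gt Character vector of genotype strings (`"0/1"`, `"1|1"`, `"./."`,
#'   ...). `NA` classifies as `no_call`.
#' @return Character vector, same length as `gt`, with values in
#'   `c("hom_ref", "het", "hom_alt", "no_call")`.
#' @examples
#' classify_genotype(c("0/0", "0/1", "1|0", "1/1", "./.", "0/."))
#' @export
classify_genotype <- function(gt) {
  nm <- names(gt)
  gt <- as.character(gt)
  out <- rep("no_call", length(gt))
  names(out) <- nm
  norm <- gsub("|", "/", gt, fixed = TRUE)
  out[norm %in% c("0/0")] <- "hom_ref"
  out[norm %in% c("0/1", "1/0")] <- "het"
  out[norm %in% c("1/1")] <- "hom_alt"
  out
}

#' Does a genotype carry at least one alternate allele?
#'
#' Carrier status underlies both the de novo "presence" test and the twin
#' concordance tally: a sample is a carrier iff its genotype class is `het`
#' or `hom_alt`. No-calls are not carriers.
#'
#' @param gt Character vector of genotype strings.
#' @return Logical vector.
#' @export
is_carrier <- function(gt) {
  classify_genotype(gt) %in% c("het", "hom_alt")
}

# genotype class matrix (variants x samples) from a cohort's gt list-column
gt_class_matrix <- function(cohort) {
  if (nrow(cohort) == 0L) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  samples <- names(cohort$gt[[1]])
  m <- matrix(
    classify_genotype(unlist(cohort$gt, use.names = FALSE)),
    nrow = nrow(cohort), byrow = TRUE,
    dimnames = list(NULL, samples)
  )
  m
}

AUTOSOMES <- c(as.character(1:22), paste0("chr", 1:22))

#' Is a chromosome name an autosome?
#'
#' Accepts both plain (`"10"`) and prefixed (`"chr10"`) hg19-style names.
#'
#' @param chrom Character vector of chromosome names.
#' @return Logical vector.
#' @export
is_autosome <- function(chrom) {
  as.character(chrom) %in% AUTOSOMES
}

# natural chromosome order for deterministic output tables
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom))
  n <- suppressWarnings(as.integer(stripped))
  special <- match(stripped, c("X", "Y", "MT", "M"))
  ifelse(!is.na(n), n, ifelse(!is.na(special), 22L + special, 100L))
}
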