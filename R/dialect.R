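#' Annotation dialect: mapping semantic slots to INFO keys
#'
#' ANNOVAR emits annotation columns whose names vary by release and database
#' set. An annotation dialect maps the semantic slots this package consumes
#' (gene symbol, functional region, exonic consequence class, pathogenicity
#' scores, population allele frequencies, ClinVar) onto concrete VCF INFO
#' keys. Every slot maps to at most one INFO key; a slot whose key is absent
#' from a record yields an absent value, never a default.
#'
#' @param gene,func_region,exonic_class,aachange,clinvar INFO keys for the
#'   annotation slots. `aachange` holds the combined
#'   transcript/exon/cDNA/protein string from which `cdna_change` and
#'   `protein_change` are parsed.
#' @param cadd,revel,sift_pred,sift_score,polyphen2_pred,polyphen2_score,mutation_taster_pred,mutation_taster_score
#'   INFO keys for the in silico scores.
#' @param pop_freqs Named character vector: population frequency source ->
#'   INFO key.
#' @param missing_token String that annotation fields use for "no value"
#'   (ANNOVAR writes `.`).
#' @return A named list of class `annotation_dialect`.
#' @export
annotation_dialect <- function(gene = "Gene.refGene",
                               func_region = "Func.refGene",
                               exonic_class = "ExonicFunc.refGene",
                               aachange = "AAChange.refGene",
                               clinvar = "CLNSIG",
                               cadd = "CADD_phred",
                               revel = "REVEL",
                               sift_pred = "SIFT_pred",
                               sift_score = "SIFT_score",
                               polyphen2_pred = "Polyphen2_HDIV_pred",
                               polyphen2_score = "Polyphen2_HDIV_score",
                               mutation_taster_pred = "MutationTaster_pred",
                               mutation_taster_score = "MutationTaster_score",
                               pop_freqs = c(gnomad_exome = "gnomAD_exome_ALL",
                                             gnomad_genome = "gnomAD_genome_ALL",
                                             exac = "ExAC_ALL"),
                               missing_token = ".") {
  d <- list(
    gene = gene, func_region = func_region, exonic_class = exonic_class,
    aachange = aachange, clinvar = clinvar,
    cadd = cadd, revel = revel,
    sift_pred = sift_pred, sift_score = sift_score,
    polyphen2_pred = polyphen2_pred, polyphen2_score = polyphen2_score,
    mutation_taster_pred = mutation_taster_pred,
    mutation_taster_score = mutation_taster_score,
    pop_freqs = pop_freqs, missing_token = missing_token
  )
  keys <- c(unlist(d[setdiff(names(d), c("pop_freqs", "missing_token"))]),
            pop_freqs)
  keys <- keys[!is.na(keys)]
  if (anyDuplicated(keys)) {
    stop("annotation dialect maps two slots to the same INFO key",
         call. = FALSE)
  }
  structure(d, class = "annotation_dialect")
}

#' Default ANNOVAR table-output dialect
#' @return An [annotation_dialect()] with refGene/dbNSFP-style key names.
#' @export
default_dialect <- function() annotation_dialect()

# closed vocabularies ---------------------------------------------------

FUNC_REGIONS <- c("exonic", "splicing", "exonic;splicing", "intronic",
                  "UTR", "intergenic", "other")

EXONIC_CLASSES <- c("nonsynonymous_SNV", "synonymous_SNV", "stopgain",
                    "stoploss", "frameshift_insertion", "frameshift_deletion",
                    "nonframeshift", "unknown")

normalize_func_region <- function(x) {
  x <- as.character(x)
  x[x %in% c("UTR3", "UTR5", "UTR5;UTR3")] <- "UTR"
  out <- ifelse(is.na(x), NA_character_,
                ifelse(x %in% FUNC_REGIONS, x, "other"))
  out
}

normalize_exonic_class <- function(x) {
  x <- gsub(" ", "_", as.character(x))
  x[grepl("^nonframeshift", x)] <- "nonframeshift"
  ifelse(is.na(x), NA_character_,
         ifelse(x %in% EXONIC_CLASSES, x, "unknown"))
}

# "GENE:NM_x:exonN:c.C163T:p.R55C[,...]" -> c(cdna, protein) of first entry
parse_aachange <- function(x) {
  out <- matrix(NA_character_, nrow = length(x), ncol = 2,
                dimnames = list(NULL, c("cdna_change", "protein_change")))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || x[i] == "") next
    first <- strsplit(x[i], ",", fixed = TRUE)[[1]][1]
    parts <- strsplit(first, ":", fixed = TRUE)[[1]]
    cd <- grep("^c\\.", parts, value = TRUE)
    pr <- grep("^p\\.", parts, value = TRUE)
    nm <- grep("^NM_", parts, value = TRUE)
    if (length(cd)) {
      out[i, 1] <- if (length(nm)) paste0(nm[1], ":", cd[1]) else cd[1]
    }
    if (length(pr)) out[i, 2] <- pr[1]
  }
  out
}
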