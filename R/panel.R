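#' Load a curated disease gene panel
#'
#' Reads a tab-separated table of panel genes with columns `gene`,
#' `category` and optionally `note`. Categories come from a closed set:
#' `KFS` (Klippel-Feil syndrome), `CS` (congenital scoliosis) and
#' `OTHER_CSD` (other congenital spinal deformities). Symbols are
#' uppercased; duplicate symbols (within or across categories) are
#' collapsed to their first entry with a warning.
#'
#' @param path Path to the panel TSV (header required).
#' @return A `gene_panel`: tibble with columns `gene`, `category`, `note`.
#' @export
load_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(c("gene", "category") %in% names(raw))) {
    stop("panel file must have 'gene' and 'category' columns", call. = FALSE)
  }
  if (!"note" %in% names(raw)) raw$note <- NA_character_
  raw$gene <- toupper(trimws(raw$gene))
  bad <- setdiff(unique(raw$category), PANEL_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown panel category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(raw$gene)
  if (any(dup)) {
    warning("collapsing duplicate panel symbol(s): ",
            paste(unique(raw$gene[dup]), collapse = ", "), call. = FALSE)
    raw <- raw[!dup, , drop = FALSE]
  }
  structure(tibble::as_tibble(raw[, c("gene", "category", "note")]),
            class = c("gene_panel", class(tibble::tibble())))
}

PANEL_CATEGORIES <- c("KFS", "CS", "OTHER_CSD")

# does any semicolon-joined annotation symbol match the panel gene?
gene_matches <- function(annot_gene, panel_gene) {
  if (is.na(annot_gene)) return(FALSE)
  panel_gene %in% toupper(strsplit(annot_gene, ";", fixed = TRUE)[[1]])
}

#' Screen a cohort against a gene panel
#'
#' Collects, for every panel gene, the cohort variants annotated to that
#' gene (matching is case-insensitive on the symbol; semicolon-joined
#' multi-gene annotations match on any component) and tests whether the
#' twin pair carries identical genotype classes at every such variant.
#'
#' @param cohort A [cohort table][cohort-table].
#' @param panel A [load_panel()] result.
#' @param ped A [twin_pedigree()].
#' @return A `panel_report`: list with `per_gene` (tibble: gene, category,
#'   n_variants, twin_concordant) and `totals` (genes screened, genes with
#'   at least one variant, genes with any twin-discordant genotype).
#' @export
panel_screen <- function(cohort, panel, ped) {
  stopifnot(inherits(ped, "twin_pedigree"))
  n_var <- integer(nrow(panel))
  concordant <- rep(NA, nrow(panel))
  if (nrow(cohort) > 0) {
    cls <- gt_class_matrix(cohort)
    aff <- cls[, ped$affected_twin]
    unaff <- cls[, ped$unaffected_twin]
    ann_genes <- lapply(ifelse(is.na(cohort$gene), "", cohort$gene),
                        function(g) toupper(strsplit(g, ";", fixed = TRUE)[[1]]))
    for (i in seq_len(nrow(panel))) {
      hit <- vapply(ann_genes, function(g) panel$gene[i] %in% g, logical(1))
      n_var[i] <- sum(hit)
      if (n_var[i] > 0) concordant[i] <- all(aff[hit] == unaff[hit])
    }
  }
  per_gene <- tibble::tibble(
    gene = panel$gene, category = panel$category,
    n_variants = n_var, twin_concordant = concordant
  )
  structure(
    list(
      per_gene = per_gene,
      totals = list(
        genes_screened = nrow(panel),
        genes_with_variants = sum(n_var > 0),
        genes_discordant = sum(!concordant, na.rm = TRUE)
      )
    ),
    class = "panel_report"
  )
}

#' @export
print.panel_report <- function(x, ...) {
  t <- x$totals
  cat("Gene panel screen:\n")
  cat("  genes screened:        ", t$genes_screened, "\n")
  cat("  genes with variants:   ", t$genes_with_variants, "\n")
  cat("  genes twin-discordant: ", t$genes_discordant, "\n")
  invisible(x)
}
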