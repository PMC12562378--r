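#' Configuration for the family genotype-model screens
#'
#' @param no_call_policy How a missing genotype (`./.`) in a family member
#'   whose genotype must be compatible with reference is handled:
#'   `"permissive"` treats it as compatible but attaches a
#'   `no_call_supported` note (so the review stage sees the weakness);
#'   `"strict"` excludes the variant. Under either policy a *required*
#'   carrier or heterozygous-parent genotype is never satisfied by a
#'   no-call.
#' @param incomplete_penetrance Dominant model: also admit variants where
#'   exactly one parent is heterozygous (a non-penetrant carrier parent),
#'   noted as `penetrance_exception`.
#' @param autosomes_only Restrict model screens to autosomes (chr1-22).
#' @return A list of class `model_config`.
#' @export
model_config <- function(no_call_policy = c("permissive", "strict"),
                         incomplete_penetrance = FALSE,
                         autosomes_only = TRUE) {
  no_call_policy <- match.arg(no_call_policy)
  structure(
    list(no_call_policy = no_call_policy,
         incomplete_penetrance = incomplete_penetrance,
         autosomes_only = autosomes_only),
    class = "model_config"
  )
}

# shared scaffolding: genotype class matrix with pedigree coverage check
screen_classes <- function(cohort, ped) {
  stopifnot(inherits(ped, "twin_pedigree"))
  if (nrow(cohort) == 0L) return(NULL)
  need <- pedigree_samples(ped)
  have <- names(cohort$gt[[1]])
  absent <- setdiff(need, have)
  if (length(absent) > 0) {
    stop("cohort genotypes do not cover pedigree member(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  gt_class_matrix(cohort)
}

screen_result <- function(pass, notes) {
  tibble::tibble(pass = pass,
                 notes = vapply(notes, paste, character(1), collapse = ";"))
}

empty_screen <- function() {
  tibble::tibble(pass = logical(), notes = character())
}

# TRUE where member class is compatible with "carries no alt":
# hom_ref always; no_call only under the permissive policy (noted)
absent_ok <- function(cls, cfg) {
  ok <- cls == "hom_ref"
  if (cfg$no_call_policy == "permissive") ok <- ok | cls == "no_call"
  ok
}

#' De novo screen
#'
#' Admits variants present (at least one alternate allele, heterozygous or
#' homozygous) in the affected twin and absent from the unaffected twin,
#' both parents and all siblings. Under the permissive no-call policy a
#' missing genotype in a non-affected member counts as absent but attaches
#' a `no_call_supported` note; under the strict policy it excludes the
#' variant.
#'
#' @param cohort A [cohort table][cohort-table] covering all pedigree
#'   samples.
#' @param ped A [twin_pedigree()].
#' @param cfg A [model_config()].
#' @return Tibble with columns `pass` (logical) and `notes`
#'   (semicolon-joined flags), one row per variant.
#' @export
de_novo_screen <- function(cohort, ped, cfg = model_config()) {
  cls <- screen_classes(cohort, ped)
  if (is.null(cls)) return(empty_screen())
  others <- setdiff(pedigree_samples(ped), ped$affected_twin)
  aff <- cls[, ped$affected_twin]
  oth <- cls[, others, drop = FALSE]
  pass <- aff %in% c("het", "hom_alt") &
    apply(oth, 1, function(r) all(absent_ok(r, cfg))) &
    autosome_ok(cohort, cfg)
  notes <- lapply(seq_len(nrow(cls)), function(i) {
    n <- character()
    if (pass[i] && any(oth[i, ] == "no_call")) n <- c(n, "no_call_supported")
    n
  })
  screen_result(pass, notes)
}

#' Autosomal recessive screen
#'
#' Admits variants homozygous alternate in the affected twin with both
#' parents heterozygous carriers, excluding any variant that is also
#' homozygous alternate in the unaffected twin or a sibling. A parent
#' no-call never satisfies the carrier requirement.
#'
#' @inheritParams de_novo_screen
#' @return Tibble with `pass` and `notes` columns.
#' @export
autosomal_recessive_screen <- function(cohort, ped, cfg = model_config()) {
  cls <- screen_classes(cohort, ped)
  if (is.null(cls)) return(empty_screen())
  sibs_and_twin <- c(ped$siblings, ped$unaffected_twin)
  aff <- cls[, ped$affected_twin]
  fa <- cls[, ped$father]
  mo <- cls[, ped$mother]
  rest <- cls[, sibs_and_twin, drop = FALSE]
  rest_ok <- apply(rest, 1, function(r) {
    if (cfg$no_call_policy == "strict" && any(r == "no_call")) return(FALSE)
    all(r != "hom_alt")
  })
  pass <- aff == "hom_alt" & fa == "het" & mo == "het" & rest_ok &
    autosome_ok(cohort, cfg)
  notes <- lapply(seq_len(nrow(cls)), function(i) {
    n <- character()
    if (pass[i] && any(rest[i, ] == "no_call")) n <- c(n, "no_call_supported")
    n
  })
  screen_result(pass, notes)
}

#' Autosomal dominant screen
#'
#' Admits variants heterozygous in the affected twin with the unaffected
#' twin, siblings and (by default) both parents homozygous reference. With
#' `incomplete_penetrance` on, a variant with exactly one heterozygous
#' parent is also admitted and noted as `penetrance_exception`.
#'
#' @inheritParams de_novo_screen
#' @return Tibble with `pass` and `notes` columns.
#' @export
autosomal_dominant_screen <- function(cohort, ped, cfg = model_config()) {
  cls <- screen_classes(cohort, ped)
  if (is.null(cls)) return(empty_screen())
  aff <- cls[, ped$affected_twin]
  fa <- cls[, ped$father]
  mo <- cls[, ped$mother]
  rest <- cls[, c(ped$siblings, ped$unaffected_twin), drop = FALSE]
  rest_ok <- apply(rest, 1, function(r) all(absent_ok(r, cfg)))
  parents_ref <- absent_ok(fa, cfg) & absent_ok(mo, cfg)
  one_carrier <- (fa == "het" & absent_ok(mo, cfg)) |
    (mo == "het" & absent_ok(fa, cfg))
  parents_ok <- parents_ref |
    (if (cfg$incomplete_penetrance) one_carrier else FALSE)
  pass <- aff == "het" & rest_ok & parents_ok & autosome_ok(cohort, cfg)
  notes <- lapply(seq_len(nrow(cls)), function(i) {
    n <- character()
    if (!pass[i]) return(n)
    if (one_carrier[i] && !parents_ref[i]) n <- c(n, "penetrance_exception")
    if (any(rest[i, ] == "no_call") || fa[i] == "no_call" ||
        mo[i] == "no_call") {
      n <- c(n, "no_call_supported")
    }
    n
  })
  screen_result(pass, notes)
}

#' Homozygous-in-affected screen
#'
#' Admits every variant homozygous alternate in the affected twin, with no
#' constraint on other members; variants also homozygous in the unaffected
#' twin are noted `concordant_twin` so the report can discount them.
#'
#' @inheritParams de_novo_screen
#' @return Tibble with `pass` and `notes` columns.
#' @export
homozygous_screen <- function(cohort, ped, cfg = model_config()) {
  cls <- screen_classes(cohort, ped)
  if (is.null(cls)) return(empty_screen())
  aff <- cls[, ped$affected_twin]
  unaff <- cls[, ped$unaffected_twin]
  pass <- aff == "hom_alt" & autosome_ok(cohort, cfg)
  notes <- lapply(seq_len(nrow(cls)), function(i) {
    if (pass[i] && unaff[i] == "hom_alt") "concordant_twin" else character()
  })
  screen_result(pass, notes)
}

autosome_ok <- function(cohort, cfg) {
  if (!cfg$autosomes_only) rep(TRUE, nrow(cohort)) else is_autosome(cohort$chrom)
}

#' Run all four genotype-model screens
#'
#' @inheritParams de_novo_screen
#' @return The cohort table with appended logical columns `de_novo`,
#'   `autosomal_recessive`, `autosomal_dominant`, `homozygous_affected`
#'   and a `model_notes` column (semicolon-joined, prefixed by model).
#' @export
screen_models <- function(cohort, ped, cfg = model_config()) {
  screens <- list(
    de_novo = de_novo_screen(cohort, ped, cfg),
    autosomal_recessive = autosomal_recessive_screen(cohort, ped, cfg),
    autosomal_dominant = autosomal_dominant_screen(cohort, ped, cfg),
    homozygous_affected = homozygous_screen(cohort, ped, cfg)
  )
  out <- cohort
  all_notes <- rep("", nrow(cohort))
  for (nm in names(screens)) {
    out[[nm]] <- screens[[nm]]$pass
    has_note <- nzchar(screens[[nm]]$notes)
    all_notes[has_note] <- paste0(
      all_notes[has_note],
      ifelse(nzchar(all_notes[has_note]), ";", ""),
      nm, ":", screens[[nm]]$notes[has_note]
    )
  }
  out$model_notes <- all_notes
  out
}

#' Genotype concordance between the twin pair
#'
#' Tallies variant *presence* (at least one alternate allele) in each twin
#' over a cohort: variants present in both, in the affected twin only, and
#' in the unaffected twin only. The shared percentage is
#' `100 * shared / (shared + unique_affected + unique_unaffected)`.
#' Variants present in neither twin do not enter the tally.
#'
#' @param cohort A [cohort table][cohort-table].
#' @param ped A [twin_pedigree()].
#' @return A list of class `concordance_summary`: `shared_count`,
#'   `unique_to_affected`, `unique_to_unaffected`, `percent_shared`.
#' @export
twin_concordance <- function(cohort, ped) {
  stopifnot(inherits(ped, "twin_pedigree"))
  if (nrow(cohort) == 0L) {
    return(structure(list(shared_count = 0L, unique_to_affected = 0L,
                          unique_to_unaffected = 0L,
                          percent_shared = NA_real_),
                     class = "concordance_summary"))
  }
  cls <- gt_class_matrix(cohort)
  in_aff <- cls[, ped$affected_twin] %in% c("het", "hom_alt")
  in_unaff <- cls[, ped$unaffected_twin] %in% c("het", "hom_alt")
  shared <- sum(in_aff & in_unaff)
  ua <- sum(in_aff & !in_unaff)
  uu <- sum(!in_aff & in_unaff)
  total <- shared + ua + uu
  structure(
    list(shared_count = shared, unique_to_affected = ua,
         unique_to_unaffected = uu,
         percent_shared = if (total > 0) 100 * shared / total else NA_real_),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Twin variant concordance:\n")
  cat("  shared:               ", x$shared_count, "\n")
  cat("  unique to affected:   ", x$unique_to_affected, "\n")
  cat("  unique to unaffected: ", x$unique_to_unaffected, "\n")
  if (!is.na(x$percent_shared)) {
    cat(sprintf("  shared: %.1f%%\n", round_half_up(x$percent_shared, 1)))
  }
  invisible(x)
}
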