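#' Build and validate a twin-pair pedigree
#'
#' A `twin_pedigree` describes a nuclear family with two genotyped parents,
#' any number of additional siblings, and one monozygotic twin pair that is
#' discordant for the phenotype: exactly one family member is affected and
#' that member must be one of the twins. Family size is not fixed; the
#' eight-member design (two parents, four siblings, twins) is just the
#' motivating case.
#'
#' @param members Data frame with columns `sample_id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`, `"female"` or `"unknown"`) and `affected`
#'   (logical). Founders carry `NA` parent ids.
#' @param twin_pair Character vector of length 2:
#'   `c(affected_twin_id, unaffected_twin_id)`.
#' @return A `twin_pedigree` object: the member table with a derived `role`
#'   column (`father`, `mother`, `sibling`, `affected_twin`,
#'   `unaffected_twin`) plus twin-pair accessors.
#' @export
twin_pedigree <- function(members, twin_pair) {
  members <- tibble::as_tibble(members)
  req <- c("sample_id", "father_id", "mother_id", "sex", "affected")
  missing_cols <- setdiff(req, names(members))
  if (length(missing_cols) > 0) {
    stop("pedigree members table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(members$sample_id)) {
    stop("duplicate sample ids in pedigree", call. = FALSE)
  }
  if (length(twin_pair) != 2L || anyDuplicated(twin_pair)) {
    stop("twin_pair must name two distinct members", call. = FALSE)
  }
  if (!all(twin_pair %in% members$sample_id)) {
    stop("twin not in family: ",
         paste(setdiff(twin_pair, members$sample_id), collapse = ", "),
         call. = FALSE)
  }

  parents_known <- !is.na(members$father_id) & !is.na(members$mother_id)
  parent_refs <- stats::na.omit(c(members$father_id, members$mother_id))
  unresolved <- setdiff(unique(parent_refs), members$sample_id)
  if (length(unresolved) > 0) {
    stop("parent ids not present in family: ",
         paste(unresolved, collapse = ", "), call. = FALSE)
  }

  n_affected <- sum(members$affected)
  if (n_affected == 0L) stop("no affected member in pedigree", call. = FALSE)
  if (n_affected > 1L) {
    stop("two or more affected members; exactly one is required", call. = FALSE)
  }
  affected_id <- members$sample_id[members$affected]
  if (!affected_id %in% twin_pair) {
    stop("the affected member must be one of the twin pair", call. = FALSE)
  }
  affected_twin <- affected_id
  unaffected_twin <- setdiff(twin_pair, affected_twin)

  twins <- members[members$sample_id %in% twin_pair, ]
  if (any(is.na(twins$father_id)) || any(is.na(twins$mother_id))) {
    stop("twin not in family offspring: twins must have recorded parents",
         call. = FALSE)
  }
  if (length(unique(twins$father_id)) != 1L ||
      length(unique(twins$mother_id)) != 1L) {
    stop("twins do not share the same declared parents", call. = FALSE)
  }
  father_id <- twins$father_id[1]
  mother_id <- twins$mother_id[1]

  role <- rep("sibling", nrow(members))
  role[members$sample_id == father_id] <- "father"
  role[members$sample_id == mother_id] <- "mother"
  role[members$sample_id == affected_twin] <- "affected_twin"
  role[members$sample_id == unaffected_twin] <- "unaffected_twin"
  members$role <- role

  structure(
    list(
      members = members,
      father = father_id,
      mother = mother_id,
      affected_twin = affected_twin,
      unaffected_twin = unaffected_twin,
      siblings = members$sample_id[role == "sibling"]
    ),
    class = "twin_pedigree"
  )
}

#' @export
print.twin_pedigree <- function(x, ...) {
  cat("Twin-pair pedigree:", nrow(x$members), "members\n")
  cat("  parents:  ", x$father, "(father),", x$mother, "(mother)\n")
  cat("  siblings: ", if (length(x$siblings)) paste(x$siblings, collapse = ", ")
      else "(none)", "\n")
  cat("  twins:    ", x$affected_twin, "(affected) /",
      x$unaffected_twin, "(unaffected)\n")
  invisible(x)
}

#' Sample ids of a pedigree
#' @param ped A `twin_pedigree`.
#' @return Character vector of all member sample ids.
#' @export
pedigree_samples <- function(ped) {
  stopifnot(inherits(ped, "twin_pedigree"))
  ped$members$sample_id
}

#' Read a PLINK-style PED file into a twin pedigree
#'
#' Consumes the standard six-column PED layout (family, individual, father,
#' mother, sex, phenotype). `0` in parent columns means founder. Sex coding:
#' 1 = male, 2 = female, other = unknown. Phenotype coding: 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown (treated as unaffected for model logic,
#' with a warning, since the screens need a single affected twin).
#'
#' PED has no twin field, so the twin pair is supplied separately.
#'
#' @param path Path to a whitespace-delimited 6-column PED file (no header).
#' @param twin_pair `c(affected_twin_id, unaffected_twin_id)`.
#' @return A validated [twin_pedigree()].
#' @export
read_pedigree <- function(path, twin_pair) {
  if (!file.exists(path)) {
    stop("pedigree file not found: ", path, call. = FALSE)
  }
  ped_raw <- utils::read.table(
    path, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype"),
    colClasses = c("character", "character", "character", "character",
                   "character", "character")
  )
  if (any(!ped_raw$phenotype %in% c("1", "2", "0", "-9"))) {
    stop("unrecognized phenotype code in PED file", call. = FALSE)
  }
  if (any(ped_raw$phenotype %in% c("0", "-9"))) {
    warning("unknown phenotype codes (0/-9) treated as unaffected",
            call. = FALSE)
  }
  members <- tibble::tibble(
    sample_id = ped_raw$sample_id,
    father_id = ifelse(ped_raw$father_id == "0", NA_character_,
                       ped_raw$father_id),
    mother_id = ifelse(ped_raw$mother_id == "0", NA_character_,
                       ped_raw$mother_id),
    sex = c("1" = "male", "2" = "female")[ped_raw$sex],
    affected = ped_raw$phenotype == "2"
  )
  members$sex[is.na(members$sex)] <- "unknown"
  twin_pedigree(members, twin_pair)
}

#' Write a twin pedigree as a PED file
#'
#' @param ped A `twin_pedigree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  m <- ped$members
  out <- data.frame(
    family_id = "FAM1",
    sample_id = m$sample_id,
    father_id = ifelse(is.na(m$father_id), "0", m$father_id),
    mother_id = ifelse(is.na(m$mother_id), "0", m$mother_id),
    sex = c(male = "1", female = "2", unknown = "0")[m$sex],
    phenotype = ifelse(m$affected, "2", "1")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The study-design family: 2 parents, 4 siblings, a discordant twin pair
#'
#' Convenience constructor for the eight-member family layout used throughout
#' the examples and the simulator defaults: father `WES-001`, mother
#' `WES-002`, four unaffected siblings `WES-003`..`WES-006`, unaffected twin
#' `WES-007` and affected twin `WES-008`.
#'
#' @return A `twin_pedigree`.
#' @export
default_family <- function() {
  ids <- sprintf("WES-%03d", 1:8)
  members <- tibble::tibble(
    sample_id = ids,
    father_id = c(NA, NA, rep(ids[1], 6)),
    mother_id = c(NA, NA, rep(ids[2], 6)),
    sex = c("male", "female", "male", "female", "male", "female",
            "female", "female"),
    affected = c(rep(FALSE, 7), TRUE)
  )
  twin_pedigree(members, twin_pair = c("WES-008", "WES-007"))
}
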