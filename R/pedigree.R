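# Pedigree data model: one row per individual with parent links, sex,
# birth order, affection status, ICD-10 diagnosis and age at onset.
# The parent graph must be acyclic; individuals whose both parents are
# absent are founders.

MEMBER_COLUMNS <- c("id", "father_id", "mother_id", "sex", "birth_order",
                    "birth_year", "affected", "icd10", "onset_age")

#' Construct a pedigree
#'
#' Builds a validated pedigree from a member table. Members require `id`,
#' `sex` (`"male"`/`"female"`, `1`/`2` accepted) and `affected` (logical);
#' `father_id`/`mother_id` are optional (absent parents mark founders), as
#' are `birth_order` (1-based rank within the full sibship), `birth_year`,
#' `icd10` and `onset_age`. When `birth_order` is missing it is derived from
#' `birth_year`, ascending, ties broken by id (with a warning); affected
#' members must carry an ICD-10 code and unaffected members must not.
#'
#' @param members data.frame of individuals (see Details).
#' @param family_id opaque identifier for the kindred.
#' @param kindred_mode `"nuclear"` (collection of continental families with
#'   unrelated parents) or `"endemic"` (one deep consanguineous family).
#' @param mapping optional ICD-10 mapping table passed to [classify_icd10()].
#' @param validate logical; run [validate_pedigree()] (default `TRUE`).
#' @return an object of class `mbd_pedigree`: a list with `members` (the
#'   normalised member frame, plus a derived `label` column), `family_id`
#'   and `kindred_mode`.
#' @export
#' @examples
#' ped <- pedigree(data.frame(
#'   id = c("f", "m", "c"), father_id = c(NA, NA, "f"),
#'   mother_id = c(NA, NA, "m"), sex = c("male", "female", "male"),
#'   birth_order = c(1, 1, 1), affected = c(FALSE, FALSE, TRUE),
#'   icd10 = c(NA, NA, "C91.1")))
#' ped
pedigree <- function(members, family_id = "F1",
                     kindred_mode = c("nuclear", "endemic"),
                     mapping = NULL, validate = TRUE) {
  kindred_mode <- match.arg(kindred_mode)
  m <- normalise_members(members, mapping = mapping)
  ped <- structure(list(members = m, family_id = as.character(family_id),
                        kindred_mode = kindred_mode),
                   class = "mbd_pedigree")
  if (validate) validate_pedigree(ped)
  ped
}

# Coerce a raw member table to the canonical column set and types.
normalise_members <- function(members, mapping = NULL) {
  m <- as.data.frame(members, stringsAsFactors = FALSE)
  need <- c("id", "sex", "affected")
  miss <- setdiff(need, names(m))
  if (length(miss))
    abort_mbd(paste0("member table lacks column(s): ",
                     paste(miss, collapse = ", ")))
  for (col in setdiff(MEMBER_COLUMNS, names(m))) m[[col]] <- NA
  blank_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
    x
  }
  m$id <- as.character(m$id)
  m$father_id <- blank_na(m$father_id)
  m$mother_id <- blank_na(m$mother_id)
  m$sex <- normalise_sex(m$sex)
  m$affected <- normalise_logical(m$affected)
  m$birth_order <- suppressWarnings(as.integer(m$birth_order))
  m$birth_year <- suppressWarnings(as.integer(m$birth_year))
  m$icd10 <- blank_na(m$icd10)
  m$onset_age <- suppressWarnings(as.numeric(m$onset_age))
  m <- m[, c(MEMBER_COLUMNS, setdiff(names(m), MEMBER_COLUMNS)), drop = FALSE]
  m <- derive_birth_order(m)
  m$label <- classify_icd10(m$icd10, mapping = mapping)
  rownames(m) <- NULL
  m
}

normalise_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("male", "m", "1"), "male",
                ifelse(x %in% c("female", "f", "2"), "female", NA_character_))
  if (anyNA(out))
    abort_mbd(paste0("sex must be male/female; offending value(s): ",
                     paste(unique(x[is.na(out)]), collapse = ", ")))
  out
}

normalise_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% c("true", "t", "1", "yes"), TRUE,
                ifelse(x %in% c("false", "f", "0", "no"), FALSE, NA))
  if (anyNA(out)) abort_mbd("affected must be logical (TRUE/FALSE)")
  out
}

# Fill missing birth_order per full sibship from birth_year (ties by id).
derive_birth_order <- function(m) {
  non_founder <- !(is.na(m$father_id) & is.na(m$mother_id))
  todo <- non_founder & is.na(m$birth_order)
  if (!any(todo)) return(m)
  key <- paste(ifelse(is.na(m$father_id), "<none>", m$father_id),
               ifelse(is.na(m$mother_id), "<none>", m$mother_id), sep = "|")
  warned <- FALSE
  for (k in unique(key[todo])) {
    ix <- which(key == k & non_founder)
    if (all(is.na(m$birth_order[ix]))) {
      o <- order(m$birth_year[ix], m$id[ix], na.last = TRUE)
      m$birth_order[ix[o]] <- seq_along(ix)
      warned <- TRUE
    }
  }
  if (warned)
    warning("birth_order missing for whole sibship(s): ranks derived from birth_year (ties by id)",
            call. = FALSE)
  m
}

#' Validate a pedigree
#'
#' Checks the structural and phenotype invariants: unique ids; parent
#' references resolve within the pedigree or are absent; fathers are male
#' and mothers female; the parent graph is acyclic (no individual is its own
#' ancestor); affected members carry a diagnosis and unaffected members do
#' not; and birth orders within each full sibship are distinct and form
#' `1..s`.
#'
#' @param ped an `mbd_pedigree`.
#' @return invisibly `TRUE`; otherwise an error of class
#'   `mbd_structural_error` (cycles, naming the cycle) or
#'   `mbd_validation_error` (all other violations, listing the ids).
#' @export
validate_pedigree <- function(ped) {
  m <- ped$members
  if (nrow(m) == 0L) abort_mbd("pedigree has no members")

  dup <- unique(m$id[duplicated(m$id)])
  if (length(dup))
    abort_mbd(paste0("duplicate id(s): ", paste(dup, collapse = ", ")))

  refs <- unique(stats::na.omit(c(m$father_id, m$mother_id)))
  unresolved <- setdiff(refs, m$id)
  if (length(unresolved))
    abort_mbd(paste0("parent id(s) not present in pedigree: ",
                     paste(unresolved, collapse = ", ")))

  sex_of <- stats::setNames(m$sex, m$id)
  bad_f <- m$id[!is.na(m$father_id) & sex_of[m$father_id] != "male"]
  bad_m <- m$id[!is.na(m$mother_id) & sex_of[m$mother_id] != "female"]
  if (length(bad_f) || length(bad_m))
    abort_mbd(paste0("sex-inconsistent parent for: ",
                     paste(unique(c(bad_f, bad_m)), collapse = ", ")))

  cyc <- find_parent_cycle(m)
  if (!is.null(cyc))
    abort_mbd(paste0("cycle in parent graph: ",
                     paste(c(cyc, cyc[1]), collapse = " -> ")),
              class = "mbd_structural_error")

  no_dx <- m$id[m$affected & is.na(m$icd10)]
  if (length(no_dx))
    abort_mbd(paste0("affected without diagnosis: ",
                     paste(no_dx, collapse = ", ")))
  spurious <- m$id[!m$affected & !is.na(m$icd10)]
  if (length(spurious))
    abort_mbd(paste0("diagnosis on unaffected member(s): ",
                     paste(spurious, collapse = ", ")))

  non_founder <- !(is.na(m$father_id) & is.na(m$mother_id))
  if (any(non_founder & is.na(m$birth_order)))
    abort_mbd(paste0("missing birth_order for: ",
                     paste(m$id[non_founder & is.na(m$birth_order)],
                           collapse = ", ")))
  key <- paste(ifelse(is.na(m$father_id), "<none>", m$father_id),
               ifelse(is.na(m$mother_id), "<none>", m$mother_id), sep = "|")
  for (k in unique(key[non_founder])) {
    ix <- which(key == k & non_founder)
    bo <- sort(m$birth_order[ix])
    if (!identical(bo, seq_along(ix)) && !identical(bo, as.integer(seq_along(ix))))
      abort_mbd(paste0("birth_order within sibship of (",
                       sub("\\|", ", ", k),
                       ") must be distinct ranks 1..s; members: ",
                       paste(m$id[ix], collapse = ", ")))
  }
  invisible(TRUE)
}

# Return one cycle (vector of ids) in the parent graph, or NULL if acyclic.
find_parent_cycle <- function(m) {
  parents <- function(id) {
    i <- match(id, m$id)
    stats::na.omit(c(m$father_id[i], m$mother_id[i]))
  }
  state <- stats::setNames(integer(nrow(m)), m$id)  # 0 new, 1 open, 2 done
  path <- character(0)
  visit <- function(id) {
    if (state[[id]] == 2L) return(NULL)
    if (state[[id]] == 1L) return(path[which(path == id)[1]:length(path)])
    state[[id]] <<- 1L
    path <<- c(path, id)
    for (p in parents(id)) {
      cyc <- visit(p)
      if (!is.null(cyc)) return(cyc)
    }
    path <<- path[-length(path)]
    state[[id]] <<- 2L
    NULL
  }
  for (id in m$id) {
    cyc <- visit(id)
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' @export
print.mbd_pedigree <- function(x, ...) {
  m <- x$members
  cat(sprintf("<mbd_pedigree> family %s (%s): %d members, %d affected, %d founders\n",
              x$family_id, x$kindred_mode, nrow(m), sum(m$affected),
              sum(is.na(m$father_id) & is.na(m$mother_id))))
  if (any(m$affected)) {
    tab <- sort(table(m$label[m$affected]), decreasing = TRUE)
    cat("  diagnoses:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Full sibships of a pedigree
#'
#' Partitions the non-founders into full sibships (same father AND same
#' mother; half-sibs form separate records). Members within a record are
#' ordered by `birth_order` ascending.
#'
#' @param ped an `mbd_pedigree`.
#' @return list of class `mbd_sibships`; each record is a list with
#'   `father_id`, `mother_id`, `ids` (ordered member ids) and `size`.
#' @export
sibships <- function(ped) {
  m <- ped$members
  nf <- m[!(is.na(m$father_id) & is.na(m$mother_id)), , drop = FALSE]
  if (nrow(nf) == 0L) return(structure(list(), class = "mbd_sibships"))
  key <- paste(ifelse(is.na(nf$father_id), "<none>", nf$father_id),
               ifelse(is.na(nf$mother_id), "<none>", nf$mother_id), sep = "|")
  recs <- lapply(split(seq_len(nrow(nf)), key), function(ix) {
    rows <- nf[ix, , drop = FALSE]
    o <- order(rows$birth_order, rows$id)
    list(father_id = rows$father_id[1], mother_id = rows$mother_id[1],
         ids = rows$id[o], size = nrow(rows))
  })
  structure(unname(recs), class = "mbd_sibships")
}

#' @export
print.mbd_sibships <- function(x, ...) {
  cat(sprintf("<mbd_sibships> %d sibship(s); sizes: %s\n", length(x),
              paste(vapply(x, `[[`, 1L, "size"), collapse = ", ")))
  invisible(x)
}

#' Generation depth of every member
#'
#' Depth of a member is the maximum parent-path length to any founder
#' (founders have depth 0). Used as the operational definition of a
#' "generation" stratum in anticipation analysis.
#'
#' @param ped an `mbd_pedigree`.
#' @return named integer vector, one entry per member id.
#' @export
generation_depth <- function(ped) {
  m <- ped$members
  depth <- stats::setNames(rep(NA_integer_, nrow(m)), m$id)
  founder <- is.na(m$father_id) & is.na(m$mother_id)
  depth[m$id[founder]] <- 0L
  # parents precede children in any acyclic order; iterate until settled
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      ps <- stats::na.omit(c(m$father_id[i], m$mother_id[i]))
      dps <- depth[ps]
      if (!anyNA(dps)) {
        depth[i] <- max(dps) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) abort_mbd("cycle in parent graph",
                               class = "mbd_structural_error")
  }
  depth
}
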