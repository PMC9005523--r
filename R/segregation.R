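# Proband-crude / affected-relative (Pc-AR) enumeration and parental
# affiliation.
#
# Every affected member is taken as proband crude (Pc) in turn; its affected
# ancestors within a generation cap, connected through at most a capped
# number of healthy (unaffected) intermediates, are its affected relatives
# (ARs). The lineage of a pair is paternal (PA) when the first ancestral
# step from the Pc passes through its father, maternal (MA) through its
# mother. In consanguineous pedigrees one ancestor can be reachable through
# both parents; such pairs are emitted once per distinct first edge and
# flagged, so both readings remain available downstream.

pair_columns <- function() {
  data.frame(pc_id = character(0), ar_id = character(0),
             lineage = character(0), generation_gap = integer(0),
             healthy_intermediates = integer(0),
             relation_class = character(0), consanguineous = logical(0),
             pc_sex = character(0), ar_sex = character(0),
             pc_dx = character(0), ar_dx = character(0),
             stringsAsFactors = FALSE)
}

# For one proband, walk the parent graph up to `max_gap` generations and
# return, per (ancestor, first edge), the shortest ancestral path's
# generation gap and its count of unaffected intermediates.
ancestor_summary <- function(m, father, mother, affected_of, pc) {
  # returns environment keyed "<ancestor>|<edge>" -> c(gap, healthy)
  best <- new.env(parent = emptyenv())
  walk <- function(id, edge, gap, healthy, max_gap) {
    if (gap > max_gap) return()
    key <- paste0(id, "|", edge)
    cur <- get0(key, envir = best)
    cand <- c(gap, healthy)
    if (is.null(cur) || cand[1] < cur[1] ||
        (cand[1] == cur[1] && cand[2] < cur[2]))
      assign(key, cand, envir = best)
    h_step <- healthy + as.integer(!affected_of[[id]])
    f <- father[[id]]; mo <- mother[[id]]
    if (!is.na(f)) walk(f, edge, gap + 1L, h_step, max_gap)
    if (!is.na(mo)) walk(mo, edge, gap + 1L, h_step, max_gap)
  }
  list(best = best, walk = walk)
}

#' Enumerate proband-crude / affected-relative pairs
#'
#' Takes every affected member as proband crude (Pc) in turn and pairs it
#' with each affected ancestor (AR) within `max_generations`, provided the
#' shortest ancestral path for that first edge contains at most
#' `max_healthy_intermediates` unaffected members strictly between Pc and
#' AR (affected intermediates do not count against the cap). One individual
#' may serve as AR to many Pcs, so the number of pairs can exceed the number
#' of patients. Ancestors reachable through both the father and the mother
#' (consanguinity loops) yield one pair per first edge, both flagged
#' `consanguineous`.
#'
#' @param ped an `mbd_pedigree`.
#' @param max_generations maximum generation gap (1 = parent); default 5.
#' @param max_healthy_intermediates maximum number of unaffected members on
#'   the connecting path; default 5.
#' @return data.frame of class `mbd_pairs` with columns `pc_id`, `ar_id`,
#'   `lineage` (`PA`/`MA`), `generation_gap`, `healthy_intermediates`,
#'   `relation_class` (always `"vertical"`: ancestor pairs), `consanguineous`,
#'   plus sexes and diagnosis labels of both members.
#' @export
enumerate_pc_ar <- function(ped, max_generations = 5L,
                            max_healthy_intermediates = 5L) {
  m <- ped$members
  father <- as.list(stats::setNames(m$father_id, m$id))
  mother <- as.list(stats::setNames(m$mother_id, m$id))
  affected_of <- as.list(stats::setNames(m$affected, m$id))
  sex_of <- stats::setNames(m$sex, m$id)
  label_of <- stats::setNames(m$label, m$id)

  rows <- list()
  for (pc in m$id[m$affected]) {
    acc <- ancestor_summary(m, father, mother, affected_of, pc)
    f <- father[[pc]]; mo <- mother[[pc]]
    if (!is.na(f))
      acc$walk(f, "PA", 1L, 0L, max_generations)
    if (!is.na(mo))
      acc$walk(mo, "MA", 1L, 0L, max_generations)
    keys <- ls(acc$best)
    if (!length(keys)) next
    anc <- sub("\\|..$", "", keys)
    edge <- sub("^.*\\|", "", keys)
    both <- anc[duplicated(anc)]
    for (i in seq_along(keys)) {
      a <- anc[i]
      if (!affected_of[[a]]) next
      gh <- get(keys[i], envir = acc$best)
      if (gh[2] > max_healthy_intermediates) next
      rows[[length(rows) + 1L]] <- data.frame(
        pc_id = pc, ar_id = a, lineage = edge[i],
        generation_gap = gh[1], healthy_intermediates = gh[2],
        relation_class = "vertical", consanguineous = a %in% both,
        pc_sex = unname(sex_of[pc]), ar_sex = unname(sex_of[a]),
        pc_dx = unname(label_of[pc]), ar_dx = unname(label_of[a]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else pair_columns()
  out <- out[order(out$pc_id, out$ar_id, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mbd_pairs", "data.frame")
  out
}

#' Classify the parental lineage of a proband-ancestor relation
#'
#' Lineage is paternal (`"PA"`) when the unique first ancestral step from
#' the proband towards the ancestor passes through the proband's father,
#' maternal (`"MA"`) through the mother. In a consanguinity loop the
#' ancestor may be reachable through both parents; both lineages are then
#' returned and a warning of class `mbd_lineage_ambiguity` is signalled
#' (downstream the pair is duplicated once per first edge).
#'
#' @param ped an `mbd_pedigree`.
#' @param pc_id proband id.
#' @param ancestor_id id of a strict ancestor of `pc_id`.
#' @return character vector: `"PA"`, `"MA"`, or both.
#' @export
classify_lineage <- function(ped, pc_id, ancestor_id) {
  m <- ped$members
  if (!pc_id %in% m$id || !ancestor_id %in% m$id)
    abort_mbd("unknown id", class = "mbd_relation_error")
  father <- as.list(stats::setNames(m$father_id, m$id))
  mother <- as.list(stats::setNames(m$mother_id, m$id))
  reachable <- function(from, target) {
    if (is.na(from)) return(FALSE)
    if (from == target) return(TRUE)
    reachable(father[[from]], target) || reachable(mother[[from]], target)
  }
  edges <- c(if (reachable(father[[pc_id]], ancestor_id)) "PA",
             if (reachable(mother[[pc_id]], ancestor_id)) "MA")
  if (!length(edges))
    abort_mbd(sprintf("%s is not an ancestor of %s", ancestor_id, pc_id),
              class = "mbd_relation_error")
  if (length(edges) == 2L)
    warning(warningCondition(
      sprintf("ancestor %s of %s reachable through both parents; pair is duplicated per first edge",
              ancestor_id, pc_id),
      class = c("mbd_lineage_ambiguity", "warning", "condition")))
  edges
}

#' Horizontal (sibling concordance) pairs
#'
#' Unordered pairs of affected full siblings. Reported separately for
#' completeness: horizontal pairs are deliberately excluded from the
#' vertical pair table, which only admits relations permitting direct
#' transgenerational transfer.
#'
#' @param ped an `mbd_pedigree`.
#' @return data.frame with columns `id1`, `id2`, `dx1`, `dx2`.
#' @export
horizontal_pairs <- function(ped) {
  label_of <- stats::setNames(ped$members$label, ped$members$id)
  affected <- stats::setNames(ped$members$affected, ped$members$id)
  rows <- list()
  for (sib in sibships(ped)) {
    aff <- sib$ids[affected[sib$ids]]
    if (length(aff) < 2L) next
    cmb <- utils::combn(aff, 2L)
    for (j in seq_len(ncol(cmb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = cmb[1, j], id2 = cmb[2, j],
        dx1 = unname(label_of[cmb[1, j]]), dx2 = unname(label_of[cmb[2, j]]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(id1 = character(0), id2 = character(0),
                  dx1 = character(0), dx2 = character(0))
}

#' Extract strictly vertical pairs and cross-tabulate them
#'
#' Retains only vertical pairs with `generation_gap <= max_gap`
#' (parent-offspring and grandparent-grandchild by default) and builds the
#' CLL/nonCLL-by-lineage-by-offspring-sex cross-tabulation; oblique
#' relations (uncle/aunt-nephew, cousins) never enter. The offspring-side
#' member of each pair is the proband (the descendant).
#'
#' @param pairs an `mbd_pairs` data.frame (from [enumerate_pc_ar()] or
#'   constructed with the same columns).
#' @param max_gap maximum generation gap retained (default 2).
#' @return object of class `mbd_pair_table`: list with `pairs` (the retained
#'   rows, plus `parent_class`/`offspring_class` columns collapsing the
#'   diagnoses to CLL/nonCLL) and `xtab` (a 4-way contingency table
#'   lineage x parent class x offspring class x offspring sex).
#' @export
extract_vertical_pairs <- function(pairs, max_gap = 2L) {
  keep <- pairs$relation_class == "vertical" & pairs$generation_gap <= max_gap
  v <- pairs[keep, , drop = FALSE]
  v$parent_class <- ifelse(!is.na(v$ar_dx) & v$ar_dx == "CLL", "CLL", "nonCLL")
  v$offspring_class <- ifelse(!is.na(v$pc_dx) & v$pc_dx == "CLL", "CLL", "nonCLL")
  xtab <- table(lineage = factor(v$lineage, c("PA", "MA")),
                parent = factor(v$parent_class, c("CLL", "nonCLL")),
                offspring = factor(v$offspring_class, c("CLL", "nonCLL")),
                offspring_sex = factor(v$pc_sex, c("male", "female")))
  stopifnot(sum(xtab) == nrow(v))  # marginal consistency with the pair list
  structure(list(pairs = v, xtab = xtab), class = "mbd_pair_table")
}

#' @export
print.mbd_pair_table <- function(x, ...) {
  n <- nrow(x$pairs)
  sh <- lineage_shares(x)
  cat(sprintf("<mbd_pair_table> %d vertical pair(s)", n))
  if (n > 0)
    cat(sprintf(": PA %d (%d%%), MA %d (%d%%)",
                sh$n[sh$lineage == "PA"], sh$pct[sh$lineage == "PA"],
                sh$n[sh$lineage == "MA"], sh$pct[sh$lineage == "MA"]))
  cat("\n")
  invisible(x)
}

#' Lineage shares of a vertical pair table
#'
#' @param pair_table an `mbd_pair_table`.
#' @return data.frame with columns `lineage`, `n`, `pct` (half-up integer
#'   percent of all vertical pairs).
#' @export
lineage_shares <- function(pair_table) {
  v <- pair_table$pairs
  n <- c(PA = sum(v$lineage == "PA"), MA = sum(v$lineage == "MA"))
  total <- sum(n)
  data.frame(lineage = names(n), n = as.integer(n),
             pct = if (total > 0) as.integer(round_half_up(100 * n / total))
                   else NA_integer_,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Offspring sex percentages by pair group and lineage
#'
#' For each pair group (CLL-CLL, CLL parent-nonCLL offspring, nonCLL
#' parent-CLL offspring, nonCLL-nonCLL, and all pairs) and each lineage,
#' reports the offspring counts by sex and their half-up-rounded integer
#' percentages. Empty strata yield `NA` percentages (undefined, not 0).
#'
#' @param pair_table an `mbd_pair_table`.
#' @return data.frame with columns `pair_group`, `lineage`, `n_offspring`,
#'   `males`, `females`, `pct_male`, `pct_female`.
#' @export
pair_percentages <- function(pair_table) {
  v <- pair_table$pairs
  if (nrow(v) == 0L)
    abort_mbd("empty pair table", class = "mbd_usage_error")
  groups <- list(
    "CLL-CLL" = v$parent_class == "CLL" & v$offspring_class == "CLL",
    "CLL-nonCLL" = v$parent_class == "CLL" & v$offspring_class == "nonCLL",
    "nonCLL-CLL" = v$parent_class == "nonCLL" & v$offspring_class == "CLL",
    "nonCLL-nonCLL" = v$parent_class == "nonCLL" & v$offspring_class == "nonCLL",
    "all" = rep(TRUE, nrow(v)))
  rows <- list()
  for (g in names(groups)) {
    for (lin in c("PA", "MA")) {
      sel <- groups[[g]] & v$lineage == lin
      n <- sum(sel)
      males <- sum(sel & v$pc_sex == "male")
      females <- n - males
      rows[[length(rows) + 1L]] <- data.frame(
        pair_group = g, lineage = lin, n_offspring = n,
        males = males, females = females,
        pct_male = if (n > 0) as.integer(round_half_up(100 * males / n)) else NA_integer_,
        pct_female = if (n > 0) as.integer(round_half_up(100 * females / n)) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export a pair list to CSV
#'
#' @param pairs an `mbd_pairs` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  out <- pairs[, c("pc_id", "ar_id", "lineage", "generation_gap",
                   "healthy_intermediates", "relation_class",
                   "pc_dx", "ar_dx")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
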