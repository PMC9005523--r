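# Reference fixtures: the printed summary tables of the two familial MBD
# cohorts (112 continental Scandinavian families with unrelated parents;
# one endemic consanguineous Faroese kindred). The raw registry pedigrees
# are not publicly available, so these printed counts are the inputs for
# every exact reproduction: per-diagnosis case counts with sex split and
# prevalence, the vertical parent/grandparent-offspring pair table by
# lineage, the observed-vs-expected AR cells, and the one AR pool size the
# source reports (121 AR LPD related to HL probands).

#' Reference case counts per diagnosis
#'
#' Familial case counts (total, male, female) per diagnosis and disease
#' group for one of the two cohorts, with the printed prevalence percent
#' for comparison.
#'
#' @param cohort `"continental"` (Norwegian/Danish families) or
#'   `"faroese"` (the endemic kindred).
#' @return data.frame with columns `group`, `label`, `icd10`, `total`,
#'   `male`, `female`, `pct_printed`, `source`.
#' @export
mbd_reference_counts <- function(cohort = c("continental", "faroese")) {
  cohort <- match.arg(cohort)
  tab <- if (cohort == "continental") data.frame(
    group = c(rep("LPD", 9), rep("MPD", 3), "OTHER"),
    label = c("CLL", "ALL", "other-leukemia", "MM", "MGUS", "HL", "DLBCL",
              "FL", "other-lymphoma", "AML", "CML", "other-MPD", "L-NOS"),
    total = c(181, 4, 14, 10, 2, 11, 16, 19, 19, 9, 3, 12, 1),
    male = c(98, 2, 7, 6, 1, 8, 9, 13, 11, 6, 1, 6, 1),
    female = c(83, 2, 7, 4, 1, 3, 7, 6, 8, 3, 2, 6, 0),
    pct_printed = c(65.6, 1.4, 5.1, 3.6, 0.7, 4.0, 5.8, 6.9, 6.8,
                    37.6, 12.5, 50.0, NA),
    stringsAsFactors = FALSE)
  else data.frame(
    group = c(rep("LPD", 8), rep("MPD", 3), "OTHER", "OTHER"),
    label = c("CLL", "ALL", "other-leukemia", "MM", "HL", "DLBCL", "FL",
              "other-lymphoma", "AML", "CML", "other-MPD", "L-NOS", "MH"),
    total = c(50, 16, 5, 50, 19, 34, 14, 31, 44, 14, 29, 7, 2),
    male = c(29, 10, 3, 31, 12, 21, 9, 16, 28, 9, 15, 2, 0),
    female = c(21, 6, 2, 19, 7, 13, 5, 15, 16, 5, 14, 5, 2),
    pct_printed = c(22.8, 7.3, 2.3, 22.8, 8.7, 15.6, 6.4, 14.1,
                    50.6, 16.1, 33.3, NA, NA),
    stringsAsFactors = FALSE)
  tab$icd10 <- icd10_for_label(tab$label)
  tab$source <- paste0(cohort, " cohort summary counts")
  tab[, c("group", "label", "icd10", "total", "male", "female",
          "pct_printed", "source")]
}

#' Reference median ages at onset
#'
#' @return data.frame: median onset age (overall, male, female) per cohort
#'   and disease group.
#' @export
mbd_reference_onset <- function() {
  data.frame(
    cohort = c("continental", "faroese", "continental", "faroese"),
    group = c("LPD", "LPD", "MPD", "MPD"),
    median_all = c(67, 61, 63, 54),
    median_male = c(65, 58, 59, 49),
    median_female = c(69, 64, 68, 60),
    source = "cohort summary counts",
    stringsAsFactors = FALSE)
}

#' Reference vertical pair strata (continental cohort)
#'
#' Counts of strictly vertical affected pairs by pair group
#' (CLL/nonCLL parent side x CLL/nonCLL offspring side), lineage (PA/MA)
#' and generation gap (1 = parent-offspring, 2 = grandparent-grandchild),
#' with sex splits of the parent-side and offspring-side members.
#'
#' @return data.frame with one row per stratum.
#' @export
mbd_reference_pairs <- function() {
  s <- function(pg, lin, gap, n, pm, pf, om, of) data.frame(
    pair_group = pg, lineage = lin, generation_gap = gap, n = n,
    parent_male = pm, parent_female = pf, off_male = om, off_female = of,
    stringsAsFactors = FALSE)
  out <- rbind(
    s("CLL-CLL", "PA", 1L, 16L, 16L, 0L, 11L, 5L),
    s("CLL-CLL", "MA", 1L, 26L, 0L, 26L, 11L, 15L),
    s("CLL-CLL", "PA", 2L, 1L, 1L, 0L, 1L, 0L),
    s("CLL-CLL", "MA", 2L, 13L, 7L, 6L, 8L, 5L),
    s("CLL-nonCLL", "PA", 1L, 7L, 7L, 0L, 2L, 5L),
    s("CLL-nonCLL", "MA", 1L, 11L, 0L, 11L, 5L, 6L),
    s("CLL-nonCLL", "PA", 2L, 0L, 0L, 0L, 0L, 0L),
    s("CLL-nonCLL", "MA", 2L, 6L, 2L, 4L, 2L, 4L),
    s("nonCLL-CLL", "PA", 1L, 9L, 9L, 0L, 3L, 6L),
    s("nonCLL-CLL", "MA", 1L, 9L, 0L, 9L, 5L, 4L),
    s("nonCLL-CLL", "PA", 2L, 8L, 8L, 0L, 4L, 4L),
    s("nonCLL-CLL", "MA", 2L, 7L, 4L, 3L, 5L, 2L),
    s("nonCLL-nonCLL", "PA", 1L, 6L, 6L, 0L, 4L, 2L),
    s("nonCLL-nonCLL", "MA", 1L, 5L, 0L, 5L, 3L, 2L),
    s("nonCLL-nonCLL", "PA", 2L, 3L, 3L, 0L, 3L, 0L),
    s("nonCLL-nonCLL", "MA", 2L, 11L, 5L, 6L, 2L, 9L))
  out$source <- "continental vertical pair table"
  out
}

#' Reference vertical pairs expanded to a pair list
#'
#' Expands [mbd_reference_pairs()] to one row per pair in the `mbd_pairs`
#' layout, so the pair-table machinery ([extract_vertical_pairs()],
#' [pair_percentages()], [lineage_shares()]) can run on the printed counts.
#' Diagnoses are carried at the table's CLL/nonCLL resolution; member ids
#' are synthetic placeholders.
#'
#' @return data.frame of class `mbd_pairs`.
#' @export
mbd_reference_pair_list <- function() {
  strata <- mbd_reference_pairs()
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    if (st$n == 0L) next
    stopifnot(st$parent_male + st$parent_female == st$n,
              st$off_male + st$off_female == st$n)
    pdx <- sub("-.*$", "", st$pair_group)
    odx <- sub("^.*-", "", st$pair_group)
    for (j in seq_len(st$n)) {
      tag <- sprintf("%s.%s.g%d.%02d", st$pair_group, st$lineage,
                     st$generation_gap, j)
      rows[[length(rows) + 1L]] <- data.frame(
        pc_id = paste0(tag, ".off"), ar_id = paste0(tag, ".par"),
        lineage = st$lineage, generation_gap = st$generation_gap,
        healthy_intermediates = st$generation_gap - 1L,
        relation_class = "vertical", consanguineous = FALSE,
        pc_sex = if (j <= st$off_male) "male" else "female",
        ar_sex = if (j <= st$parent_male) "male" else "female",
        pc_dx = odx, ar_dx = pdx, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mbd_pairs", "data.frame")
  out
}

#' Reference observed-vs-expected AR cells (endemic cohort)
#'
#' The printed observed and expected affected-relative counts (total, male,
#' female) per proband diagnosis / AR diagnosis combination, with the
#' printed direction call.
#'
#' @return data.frame with one row per combination.
#' @export
mbd_reference_obsexp <- function() {
  r <- function(pc, ar, ot, om, of, et, em, ef, call) data.frame(
    pc_dx = pc, ar_dx = ar, obs_total = ot, obs_male = om, obs_female = of,
    exp_total = et, exp_male = em, exp_female = ef, printed_call = call,
    stringsAsFactors = FALSE)
  out <- rbind(
    r("HL", "HL", 17, 10, 7, 11, 7, 4, "covariation"),
    r("FL", "MM", 22, 14, 8, 15, 9, 6, "covariation"),
    r("DLBCL", "DLBCL", 37, 14, 23, 28, 17, 11, "covariation"),
    r("DLBCL", "CLL", 33, 11, 22, 41, 24, 17, "contravariation"),
    r("NHL-NOS", "HL", 19, 12, 7, 12, 8, 4, "covariation"),
    r("MM", "FL", 27, 15, 12, 20, 13, 7, "covariation"),
    r("MM", "MM", 88, 50, 38, 71, 44, 27, "covariation"),
    r("MM", "CLL", 58, 40, 18, 71, 41, 30, "contravariation"),
    r("MM", "ALL", 27, 11, 16, 23, 14, 9, "covariation"),
    r("MM", "CML", 33, 18, 15, 22, 14, 8, "covariation"),
    r("MM", "MF", 29, 16, 13, 12, 6, 6, "covariation"),
    r("AML", "AML", 78, 45, 33, 60, 38, 22, "covariation"),
    r("AML", "DLBCL", 47, 25, 22, 33, 20, 13, "covariation"),
    r("AML", "CLL", 28, 17, 11, 48, 28, 20, "contravariation"),
    r("AML", "MM", 73, 41, 32, 48, 30, 18, "covariation"),
    r("CML", "AML", 37, 22, 15, 27, 17, 10, "covariation"))
  out$source <- "endemic cohort observed-vs-expected table"
  out
}

#' Reference affected-relative pool sizes
#'
#' The one AR pool the source reports explicitly: 121 AR with
#' lymphoproliferative disease (68 male, 53 female) related to HL probands
#' in the endemic kindred.
#'
#' @return data.frame with columns `pc_dx`, `ar_group`, `total`, `male`,
#'   `female`.
#' @export
mbd_reference_ar_pools <- function() {
  data.frame(pc_dx = "HL", ar_group = "LPD", total = 121, male = 68,
             female = 53, source = "worked expectation example",
             stringsAsFactors = FALSE)
}

#' All reference fixtures in one list
#'
#' @return named list: `counts_continental`, `counts_faroese`, `onset`,
#'   `pairs`, `pair_list`, `obsexp`, `ar_pools`.
#' @export
fixture_tables <- function() {
  list(counts_continental = mbd_reference_counts("continental"),
       counts_faroese = mbd_reference_counts("faroese"),
       onset = mbd_reference_onset(),
       pairs = mbd_reference_pairs(),
       pair_list = mbd_reference_pair_list(),
       obsexp = mbd_reference_obsexp(),
       ar_pools = mbd_reference_ar_pools())
}
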