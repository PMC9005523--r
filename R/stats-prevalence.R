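# Prevalence tables and prevalence-based observed-vs-expected
# (co-/contravariation) statistics.
#
# Because registry incidence data are unavailable for an endemic isolate,
# all expectations are prevalence-based: the expected number of affected
# relatives (ARs) with a given diagnosis is the diagnosis's share of its
# disease group applied to the AR pool related to the proband diagnosis.
# Prevalences are carried at one decimal percent into the expectation
# (the convention of the source registry tables); `exact_prevalence = TRUE`
# disables that rounding.

#' Compute a within-group prevalence table
#'
#' Prevalence of each diagnosis label as a percentage of its disease group
#' total (LPD or MPD), reported to one decimal (half-up). Accepts either a
#' pedigree (affected members are tallied) or a pre-tallied count table with
#' columns `label`, `total`, `male`, `female` (a `group` column, if present,
#' is used to filter).
#'
#' @param x an `mbd_pedigree`, or a data.frame of counts.
#' @param group `"LPD"` or `"MPD"`.
#' @return data.frame of class `mbd_prevalence` with columns `label`,
#'   `total`, `male`, `female`, `prevalence_pct`, and attributes `group`
#'   and `group_total`.
#' @export
compute_prevalence <- function(x, group = c("LPD", "MPD")) {
  group <- match.arg(group)
  if (inherits(x, "mbd_pedigree")) {
    m <- x$members[x$members$affected, , drop = FALSE]
    m <- m[diagnosis_group(m$label) == group, , drop = FALSE]
    if (nrow(m) == 0L)
      abort_mbd(paste0("no affected members in group ", group),
                class = "mbd_usage_error")
    counts <- do.call(rbind, lapply(split(m, m$label), function(d) data.frame(
      label = d$label[1], total = nrow(d),
      male = sum(d$sex == "male"), female = sum(d$sex == "female"),
      stringsAsFactors = FALSE)))
  } else {
    counts <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!all(c("label", "total", "male", "female") %in% names(counts)))
      abort_mbd("count table needs columns label, total, male, female")
    if ("group" %in% names(counts))
      counts <- counts[counts$group == group, , drop = FALSE]
    else
      counts <- counts[diagnosis_group(counts$label) == group, , drop = FALSE]
    if (nrow(counts) == 0L)
      abort_mbd(paste0("no counts in group ", group), class = "mbd_usage_error")
  }
  counts <- counts[order(-counts$total, counts$label),
                   c("label", "total", "male", "female")]
  group_total <- sum(counts$total)
  counts$prevalence_pct <- round_half_up(100 * counts$total / group_total, 1)
  rownames(counts) <- NULL
  structure(counts, class = c("mbd_prevalence", "data.frame"),
            group = group, group_total = group_total)
}

#' @export
print.mbd_prevalence <- function(x, ...) {
  cat(sprintf("<mbd_prevalence> group %s, %d patients\n",
              attr(x, "group"), attr(x, "group_total")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Expected affected-relative counts for a diagnosis
#'
#' The expected number of ARs with diagnosis `ar_label` among an AR pool of
#' a given size is the diagnosis's within-group prevalence applied to the
#' pool total; the expected sex split follows the diagnosis's own male /
#' female case ratio in the prevalence table. By default the prevalence is
#' used at its one-decimal-percent reporting precision (so a prevalence of
#' 8.7% on a pool of 121 gives 10.53 expected, displayed as 11);
#' `exact_prevalence = TRUE` uses the unrounded ratio instead.
#'
#' @param prev an `mbd_prevalence` table.
#' @param ar_pool AR pool size: a single total, or a numeric vector whose
#'   first element (or `total` element) is used.
#' @param ar_label diagnosis label to expect.
#' @param exact_prevalence logical; bypass the one-decimal rounding.
#' @return list of class `mbd_expected` with `exp_total`, `exp_male`,
#'   `exp_female` (real-valued; male + female = total exactly) and
#'   `display` (half-up integer rounding of each).
#' @export
#' @examples
#' prev <- compute_prevalence(data.frame(
#'   label = c("HL", "CLL"), total = c(19, 200), male = c(12, 120),
#'   female = c(7, 80), group = "LPD"), "LPD")
#' expected_ar_counts(prev, 121, "HL")
expected_ar_counts <- function(prev, ar_pool, ar_label,
                               exact_prevalence = FALSE) {
  i <- match(ar_label, prev$label)
  if (is.na(i))
    abort_mbd(paste0("label not in prevalence table: ", ar_label),
              class = "mbd_usage_error")
  pool_total <- if (!is.null(names(ar_pool)) && "total" %in% names(ar_pool))
    as.numeric(ar_pool[["total"]]) else as.numeric(ar_pool[[1]])
  if (pool_total < 0) abort_mbd("AR pool must be non-negative")
  if (pool_total == 0) {
    out <- list(exp_total = 0, exp_male = 0, exp_female = 0,
                display = c(total = 0, male = 0, female = 0))
    class(out) <- "mbd_expected"
    return(out)
  }
  if (prev$total[i] == 0)
    abort_mbd(paste0("zero count for ", ar_label,
                     ": sex split undefined"), class = "mbd_usage_error")
  p <- if (exact_prevalence) 100 * prev$total[i] / attr(prev, "group_total")
       else prev$prevalence_pct[i]
  exp_total <- p / 100 * pool_total
  exp_male <- exp_total * prev$male[i] / prev$total[i]
  exp_female <- exp_total * prev$female[i] / prev$total[i]
  out <- list(exp_total = exp_total, exp_male = exp_male,
              exp_female = exp_female,
              display = c(total = round_half_up(exp_total),
                          male = round_half_up(exp_male),
                          female = round_half_up(exp_female)))
  class(out) <- "mbd_expected"
  out
}

#' @export
print.mbd_expected <- function(x, ...) {
  cat(sprintf("<mbd_expected> total %.2f (~%d): males %.2f (~%d), females %.2f (~%d)\n",
              x$exp_total, x$display["total"], x$exp_male, x$display["male"],
              x$exp_female, x$display["female"]))
  invisible(x)
}

#' Test observed against expected AR counts (co-/contravariation)
#'
#' Covariation denotes more observed ARs than expected, contravariation
#' fewer. The statistic is the Pearson chi-square over the (male, female)
#' observed-vs-expected cells, referred to a chi-square distribution with
#' `df` degrees of freedom (default 2, treating the sex cells as independent
#' counts); no continuity correction. Two classifications are returned:
#' `direction` is the sign of observed minus expected totals regardless of
#' significance, and `call` is that direction gated at `p < alpha`
#' (otherwise `"none"`).
#'
#' @param obs observed counts: numeric `c(total, male, female)` (named or in
#'   that order).
#' @param exp expected counts: same layout, or an `mbd_expected`.
#' @param df chi-square degrees of freedom (default 2).
#' @param alpha significance level for the gated call (default 0.05).
#' @return list of class `mbd_obsexp` with observed/expected components,
#'   `chi_square`, `df`, `p_value`, `direction`, `call`.
#' @export
test_cocontravariation <- function(obs, exp, df = 2L, alpha = 0.05) {
  take <- function(x, what) {
    if (inherits(x, "mbd_expected"))
      return(c(x$exp_total, x$exp_male, x$exp_female))
    x <- unlist(x)
    if (!is.null(names(x)) && all(c("total", "male", "female") %in% names(x)))
      return(as.numeric(x[c("total", "male", "female")]))
    if (length(x) < 3)
      abort_mbd(paste0(what, " must supply total, male and female counts"))
    as.numeric(x[1:3])
  }
  o <- take(obs, "obs"); e <- take(exp, "exp")
  if (any(e[2:3] <= 0))
    abort_mbd("expected sex cell is zero: pool cells before testing",
              class = "mbd_usage_error")
  chi <- sum((o[2:3] - e[2:3])^2 / e[2:3])
  p <- stats::pchisq(chi, df = df, lower.tail = FALSE)
  direction <- if (o[1] > e[1]) "covariation"
               else if (o[1] < e[1]) "contravariation" else "none"
  call <- if (p < alpha) direction else "none"
  structure(list(obs_total = o[1], obs_male = o[2], obs_female = o[3],
                 exp_total = e[1], exp_male = e[2], exp_female = e[3],
                 chi_square = chi, df = df, p_value = p,
                 direction = direction, call = call, alpha = alpha),
            class = "mbd_obsexp")
}

#' @export
print.mbd_obsexp <- function(x, ...) {
  cat(sprintf("<mbd_obsexp> OBS %g (%g, %g) vs EXP %.2f (%.2f, %.2f): X2=%.2f df=%d p=%.3g -> %s (direction %s)\n",
              x$obs_total, x$obs_male, x$obs_female, x$exp_total, x$exp_male,
              x$exp_female, x$chi_square, x$df, x$p_value, x$call, x$direction))
  invisible(x)
}

#' Full observed-vs-expected table from a pair list
#'
#' For every proband diagnosis with pairs, and every AR diagnosis observed
#' among its relatives, computes the observed AR counts (total, male,
#' female), the AR pool (all ARs in the AR diagnosis's disease group related
#' to that proband diagnosis), the prevalence-based expectation and the
#' co-/contravariation test. Combinations whose expected sex cells are zero
#' are skipped.
#'
#' @param pairs an `mbd_pairs` data.frame.
#' @param prevalence named list of `mbd_prevalence` tables by group (e.g.
#'   `list(LPD = ..., MPD = ...)`).
#' @param df,alpha passed to [test_cocontravariation()].
#' @param exact_prevalence passed to [expected_ar_counts()].
#' @return data.frame with one row per (proband diagnosis, AR diagnosis).
#' @export
cocontravariation_table <- function(pairs, prevalence, df = 2L, alpha = 0.05,
                                    exact_prevalence = FALSE) {
  rows <- list()
  for (pc_dx in sort(unique(pairs$pc_dx))) {
    rel <- pairs[pairs$pc_dx == pc_dx, , drop = FALSE]
    rel$ar_group <- diagnosis_group(rel$ar_dx)
    for (ar_dx in sort(unique(rel$ar_dx))) {
      grp <- diagnosis_group(ar_dx)
      prev <- prevalence[[grp]]
      if (is.null(prev) || !ar_dx %in% prev$label) next
      pool <- sum(rel$ar_group == grp)
      sel <- rel$ar_dx == ar_dx
      obs <- c(sum(sel), sum(sel & rel$ar_sex == "male"),
               sum(sel & rel$ar_sex == "female"))
      res <- tryCatch(
        test_cocontravariation(
          obs, expected_ar_counts(prev, pool, ar_dx,
                                  exact_prevalence = exact_prevalence),
          df = df, alpha = alpha),
        mbd_usage_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pc_dx = pc_dx, ar_dx = ar_dx, ar_pool = pool,
        obs_total = res$obs_total, obs_male = res$obs_male,
        obs_female = res$obs_female, exp_total = res$exp_total,
        exp_male = res$exp_male, exp_female = res$exp_female,
        chi_square = res$chi_square, df = res$df, p_value = res$p_value,
        direction = res$direction, call = res$call,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(pc_dx = character(0), ar_dx = character(0))
}
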