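# Birth-order effect (BOE).
#
# The Haldane-Smith rank-sum procedure compares the observed sum of birth
# ranks of the cases in their sibships with the moments of the rank sum
# under random placement (sampling m ranks from 1..s without replacement in
# each sibship): per sibship the null mean is m(s+1)/2 and the null
# variance m(s-m)(s+1)/12; sibship contributions are summed and a normal
# approximation yields a z statistic and a 95% confidence interval.
# Sibships with zero null variance (singletons, or all sibs cases) are
# uninformative and excluded. A one-sample Wilcoxon signed-rank test on the
# per-case score (number of older healthy sibs minus number of younger
# healthy sibs) serves as the control method.

#' Case birth ranks per sibship
#'
#' Extracts, for each full sibship, the sibship size and the birth ranks
#' (1..s ascending by birth order) of its cases. A case is an affected
#' member that matches the optional restriction on sex, diagnosis label and
#' parental lineage (lineage is matched against the member's vertical
#' pairs: the member must have at least one affected relative in the given
#' lineage).
#'
#' @param ped an `mbd_pedigree`.
#' @param restrict optional list with any of `sex`, `diagnosis`, `lineage`.
#' @param pairs optional precomputed [enumerate_pc_ar()] result (only used
#'   when `restrict$lineage` is given).
#' @return data.frame with columns `sibship`, `size`, `rank`, one row per
#'   case; sibships without cases are omitted (their sizes contribute
#'   nothing to the rank-sum moments).
#' @export
sibship_case_ranks <- function(ped, restrict = NULL, pairs = NULL) {
  m <- ped$members
  is_case <- stats::setNames(m$affected, m$id)
  if (!is.null(restrict$sex))
    is_case <- is_case & stats::setNames(m$sex == restrict$sex, m$id)
  if (!is.null(restrict$diagnosis))
    is_case <- is_case & stats::setNames(!is.na(m$label) &
                                           m$label == restrict$diagnosis, m$id)
  if (!is.null(restrict$lineage)) {
    if (is.null(pairs)) pairs <- enumerate_pc_ar(ped)
    in_lineage <- unique(pairs$pc_id[pairs$lineage == restrict$lineage])
    is_case <- is_case & stats::setNames(m$id %in% in_lineage, m$id)
  }
  rows <- list()
  sibs <- sibships(ped)
  for (i in seq_along(sibs)) {
    sib <- sibs[[i]]
    ranks <- which(is_case[sib$ids])
    if (!length(ranks)) next
    rows[[length(rows) + 1L]] <- data.frame(
      sibship = paste0("S", i), size = sib$size, rank = as.integer(ranks),
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(sibship = character(0), size = integer(0),
                  rank = integer(0))
}

#' Haldane-Smith birth-order-effect test
#'
#' @param x an `mbd_pedigree` or a data.frame with columns `sibship`,
#'   `size`, `rank` (one row per case, as from [sibship_case_ranks()]).
#' @param restrict,pairs passed to [sibship_case_ranks()] when `x` is a
#'   pedigree.
#' @return object of class `mbd_boe`: `rank_sum_observed`,
#'   `rank_sum_null_mean`, `rank_sum_null_variance`, `z`, `ci95`
#'   (null mean +/- 1.96 sd), `decision` (`"late_excess"` when the observed
#'   sum exceeds the upper CI bound, `"early_excess"` below the lower bound,
#'   else `"none"`), and `n_sibships_informative`.
#' @export
#' @examples
#' # one sibship of 3 with the middle child affected: symmetric, no effect
#' haldane_smith_test(data.frame(sibship = "a", size = 3, rank = 2))
haldane_smith_test <- function(x, restrict = NULL, pairs = NULL) {
  df <- if (inherits(x, "mbd_pedigree"))
    sibship_case_ranks(x, restrict = restrict, pairs = pairs)
  else as.data.frame(x)
  if (!all(c("sibship", "size", "rank") %in% names(df)))
    abort_mbd("need columns sibship, size, rank", class = "mbd_usage_error")
  if (any(df$rank < 1 | df$rank > df$size))
    abort_mbd("case rank outside 1..size", class = "mbd_usage_error")
  A <- mu <- v <- 0
  n_inf <- 0L
  for (d in split(df, df$sibship)) {
    s <- d$size[1]
    m_j <- nrow(d)
    if (s <= 1L || m_j >= s) next  # zero null variance: uninformative
    A <- A + sum(d$rank)
    mu <- mu + m_j * (s + 1) / 2
    v <- v + m_j * (s - m_j) * (s + 1) / 12
    n_inf <- n_inf + 1L
  }
  if (n_inf == 0L)
    abort_mbd("no informative sibship (need size > 1 with both cases and non-cases)",
              class = "mbd_usage_error")
  z <- (A - mu) / sqrt(v)
  ci <- c(lower = mu - 1.96 * sqrt(v), upper = mu + 1.96 * sqrt(v))
  decision <- if (A > ci["upper"]) "late_excess"
              else if (A < ci["lower"]) "early_excess" else "none"
  structure(list(rank_sum_observed = A, rank_sum_null_mean = mu,
                 rank_sum_null_variance = v, z = z, ci95 = ci,
                 decision = decision, n_sibships_informative = n_inf),
            class = "mbd_boe")
}

#' @export
print.mbd_boe <- function(x, ...) {
  cat(sprintf("<mbd_boe> rank sum %g vs null %g (var %.3g), z=%.3f, CI95 [%.2f, %.2f] -> %s (%d informative sibships)\n",
              x$rank_sum_observed, x$rank_sum_null_mean,
              x$rank_sum_null_variance, x$z, x$ci95["lower"],
              x$ci95["upper"], x$decision, x$n_sibships_informative))
  invisible(x)
}

#' Wilcoxon signed-rank control for the birth-order effect
#'
#' Per case, the score is the number of older healthy sibs minus the number
#' of younger healthy sibs in its sibship; the scores are tested against a
#' symmetric-about-zero null with a one-sample Wilcoxon signed-rank test
#' (zero scores dropped per the standard convention). A positive shift
#' indicates cases late in the sibship, concordant with a Haldane-Smith
#' late excess.
#'
#' @inheritParams haldane_smith_test
#' @return list of class `mbd_wilcoxon` with `statistic`, `p_value`,
#'   `scores` and `n_nonzero`; when every score is zero the test is
#'   undefined and `statistic`/`p_value` are `NA` with a `note`.
#' @export
wilcoxon_boe_control <- function(x, restrict = NULL, pairs = NULL) {
  df <- if (inherits(x, "mbd_pedigree"))
    sibship_case_ranks(x, restrict = restrict, pairs = pairs)
  else as.data.frame(x)
  if (nrow(df) == 0L)
    abort_mbd("no cases", class = "mbd_usage_error")
  scores <- unlist(lapply(split(df, df$sibship), function(d) {
    s <- d$size[1]
    vapply(d$rank, function(r) {
      older_healthy <- (r - 1) - sum(d$rank < r)
      younger_healthy <- (s - r) - sum(d$rank > r)
      older_healthy - younger_healthy
    }, numeric(1))
  }), use.names = FALSE)
  nz <- scores[scores != 0]
  if (length(nz) == 0L)
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          scores = scores, n_nonzero = 0L,
                          note = "all scores zero: test undefined"),
                     class = "mbd_wilcoxon"))
  wt <- suppressWarnings(stats::wilcox.test(scores, mu = 0))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 scores = scores, n_nonzero = length(nz), note = NULL),
            class = "mbd_wilcoxon")
}

#' @export
print.mbd_wilcoxon <- function(x, ...) {
  if (is.na(x$statistic))
    cat("<mbd_wilcoxon> undefined:", x$note, "\n")
  else
    cat(sprintf("<mbd_wilcoxon> V=%g, p=%.3g (%d nonzero scores, mean score %.2f)\n",
                x$statistic, x$p_value, x$n_nonzero, mean(x$scores)))
  invisible(x)
}
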