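# Anticipation: rising disease intensity and falling age at onset down the
# generations.
#
# Generation strata are defined by generation depth (maximum parent-path
# length to any founder). The onset trend across strata is assessed with a
# two-sided rank-based test (Kendall correlation of onset age with depth),
# supplemented by a least-squares estimate of the per-generation onset
# decline. Optionally, per-diagnosis familial prevalences are compared with
# reference (registry) prevalences by a chi-square goodness-of-fit test.

#' Assess anticipation in a pedigree
#'
#' @param ped an `mbd_pedigree`; affected members should carry `onset_age`.
#' @param reference optional `mbd_prevalence` table (or count table accepted
#'   by [compute_prevalence()]) giving registry prevalences; when supplied,
#'   each familial diagnosis prevalence in the reference's group is tested
#'   against it.
#' @param group disease group for the reference comparison (default
#'   `"LPD"`).
#' @param alpha significance level (default 0.05).
#' @return object of class `mbd_anticipation`: `strata` (per-generation n
#'   affected and median onset, ordered oldest to youngest), `trend`
#'   (Kendall `tau`, two-sided `p_value`, and `decline_per_generation`, the
#'   negated least-squares slope of onset on depth, in years), and
#'   `prevalence_comparison` (per-diagnosis chi-square vs the reference, or
#'   `NULL`).
#' @export
assess_anticipation <- function(ped, reference = NULL, group = "LPD",
                                alpha = 0.05) {
  m <- ped$members
  depth <- generation_depth(ped)
  aff <- m[m$affected & !is.na(m$onset_age), , drop = FALSE]
  if (nrow(aff) == 0L)
    abort_mbd("no affected members with onset age", class = "mbd_usage_error")
  d <- unname(depth[aff$id])
  strata <- do.call(rbind, lapply(sort(unique(d)), function(g) data.frame(
    generation = g, n_affected = sum(d == g),
    median_onset = stats::median(aff$onset_age[d == g]))))

  if (length(unique(d)) < 2L) {
    warning("fewer than 2 generation strata with affected members: onset trend undefined",
            call. = FALSE)
    trend <- list(tau = NA_real_, p_value = NA_real_,
                  decline_per_generation = NA_real_)
  } else if (stats::var(aff$onset_age) == 0) {
    # all onsets equal: no trend by construction
    trend <- list(tau = 0, p_value = 1, decline_per_generation = 0)
  } else {
    ct <- suppressWarnings(stats::cor.test(d, aff$onset_age,
                                           method = "kendall",
                                           alternative = "two.sided"))
    slope <- unname(stats::coef(stats::lm(aff$onset_age ~ d))[2])
    trend <- list(tau = unname(ct$estimate), p_value = ct$p.value,
                  decline_per_generation = -slope)
  }

  comparison <- NULL
  if (!is.null(reference)) {
    if (!inherits(reference, "mbd_prevalence"))
      reference <- compute_prevalence(reference, group)
    fam <- m[m$affected & diagnosis_group(m$label) == attr(reference, "group"),
             , drop = FALSE]
    n <- nrow(fam)
    if (n > 0L) {
      comparison <- do.call(rbind, lapply(
        intersect(unique(fam$label), reference$label), function(lab) {
          k <- sum(fam$label == lab)
          p <- reference$prevalence_pct[reference$label == lab] / 100
          ch <- suppressWarnings(stats::chisq.test(c(k, n - k),
                                                   p = c(p, 1 - p)))
          data.frame(label = lab, fam_count = k, fam_total = n,
                     fam_pct = round_half_up(100 * k / n, 1),
                     ref_pct = 100 * p,
                     chi_square = unname(ch$statistic),
                     p_value = ch$p.value, stringsAsFactors = FALSE)
        }))
      rownames(comparison) <- NULL
    }
  }

  structure(list(strata = strata, trend = trend,
                 prevalence_comparison = comparison, alpha = alpha),
            class = "mbd_anticipation")
}

#' @export
print.mbd_anticipation <- function(x, ...) {
  cat("<mbd_anticipation>\n  per-generation strata (oldest -> youngest):\n")
  print.data.frame(x$strata, row.names = FALSE)
  if (is.na(x$trend$tau)) {
    cat("  onset trend: undefined (<2 strata)\n")
  } else {
    cat(sprintf("  onset trend: tau=%.3f, p=%.3g; estimated decline %.2f y/generation\n",
                x$trend$tau, x$trend$p_value,
                x$trend$decline_per_generation))
  }
  if (!is.null(x$prevalence_comparison)) {
    cat("  familial vs reference prevalence:\n")
    print.data.frame(x$prevalence_comparison, row.names = FALSE)
  }
  invisible(x)
}
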