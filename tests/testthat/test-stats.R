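test_that("prevalence is the within-group share at one-decimal half-up rounding", {
  prev <- compute_prevalence(mbd_reference_counts("faroese"), "LPD")
  expect_equal(attr(prev, "group_total"), 219)
  expect_equal(prev$prevalence_pct[prev$label == "HL"], 8.7)
  expect_equal(sum(prev$prevalence_pct), 100, tolerance = 0.011)
  # single-diagnosis group -> 100.0%
  one <- compute_prevalence(data.frame(label = "CLL", total = 7, male = 4,
                                       female = 3, group = "LPD"), "LPD")
  expect_equal(one$prevalence_pct, 100.0)
  # empty group errors
  expect_error(compute_prevalence(pedigree(trio_members()), "MPD"),
               class = "mbd_usage_error")
  # pedigree and count-table routes agree
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 20,
                                             seed = 12))
  ped <- sim$pedigree
  aff <- ped$members[ped$members$affected, ]
  aff <- aff[diagnosis_group(aff$label) == "LPD", ]
  counts <- do.call(rbind, lapply(split(aff, aff$label), function(d)
    data.frame(label = d$label[1], total = nrow(d),
               male = sum(d$sex == "male"), female = sum(d$sex == "female"),
               group = "LPD")))
  expect_equal(as.data.frame(compute_prevalence(ped, "LPD")),
               as.data.frame(compute_prevalence(counts, "LPD")))
})

test_that("expected AR counts follow the one-decimal prevalence and split by the case sex ratio", {
  prev <- compute_prevalence(mbd_reference_counts("faroese"), "LPD")
  e <- expected_ar_counts(prev, 121, "HL")
  expect_equal(e$exp_total, 8.7 / 100 * 121)
  expect_equal(e$exp_male + e$exp_female, e$exp_total, tolerance = 1e-9)
  expect_equal(unname(e$display), c(11, 7, 4))
  # exact (unrounded) prevalence switch
  ex <- expected_ar_counts(prev, 121, "HL", exact_prevalence = TRUE)
  expect_equal(ex$exp_total, 19 / 219 * 121)
  # linearity in the pool size
  e2 <- expected_ar_counts(prev, 242, "HL")
  expect_equal(e2$exp_total, 2 * e$exp_total)
  # zero pool -> zeros; unknown label -> error
  expect_equal(expected_ar_counts(prev, 0, "HL")$exp_total, 0)
  expect_error(expected_ar_counts(prev, 10, "MGUS"),
               class = "mbd_usage_error")
})

test_that("co/contravariation calls follow the sign of OBS-EXP gated by the chi-square", {
  # exact agreement: zero statistic, no call
  r <- test_cocontravariation(c(20, 12, 8), c(20, 12, 8))
  expect_equal(r$chi_square, 0)
  expect_equal(r$call, "none")
  expect_equal(r$direction, "none")
  # strong excess -> covariation both as direction and as gated call
  r <- test_cocontravariation(c(60, 40, 20), c(20, 12, 8))
  expect_equal(r$direction, "covariation")
  expect_equal(r$call, "covariation")
  # deficit below significance: direction only
  r <- test_cocontravariation(c(18, 11, 7), c(20, 12, 8))
  expect_equal(r$direction, "contravariation")
  expect_equal(r$call, "none")
  # zero expected cell -> instructed to pool
  expect_error(test_cocontravariation(c(5, 5, 0), c(4, 4, 0)),
               "pool", class = "mbd_usage_error")
})

test_that("co/contravariation is invariant under swapping both sex labels", {
  set.seed(401)
  for (i in 1:20) {
    em <- runif(1, 2, 30); ef <- runif(1, 2, 30)
    om <- rpois(1, em); of <- rpois(1, ef)
    a <- test_cocontravariation(c(om + of, om, of), c(em + ef, em, ef))
    b <- test_cocontravariation(c(om + of, of, om), c(em + ef, ef, em))
    expect_equal(a$chi_square, b$chi_square)
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$call, b$call)
  }
})

test_that("Haldane-Smith moments match hand enumeration for minimal sibships", {
  # s=3, m=1, affected in the middle: symmetric center
  r <- haldane_smith_test(data.frame(sibship = "a", size = 3, rank = 2))
  expect_equal(r$rank_sum_observed, 2)
  expect_equal(r$rank_sum_null_mean, 2)
  expect_equal(r$rank_sum_null_variance, 2 / 3)
  expect_equal(r$decision, "none")
  # s=2, m=1: null places the case at rank 1 or 2 equiprobably
  r <- haldane_smith_test(data.frame(sibship = "a", size = 2, rank = 1))
  expect_equal(r$rank_sum_null_mean, 1.5)       # (1+2)/2
  expect_equal(r$rank_sum_null_variance, 0.25)  # E[A^2]-E[A]^2 over {1,2}
  expect_equal(unname(r$ci95),
               c(1.5 - 1.96 * 0.5, 1.5 + 1.96 * 0.5))
})

test_that("Haldane-Smith null moments equal exhaustive enumeration for all sibships up to size 6", {
  for (s in 2:6) {
    for (m in 1:(s - 1)) {
      sums <- combn(s, m, sum)  # all equally likely case placements
      r <- haldane_smith_test(data.frame(sibship = "x", size = s,
                                         rank = seq_len(m)))
      expect_equal(r$rank_sum_null_mean, mean(sums))
      expect_equal(r$rank_sum_null_variance,
                   mean(sums^2) - mean(sums)^2, tolerance = 1e-12)
    }
  }
})

test_that("uninformative sibships are excluded and their absence errors", {
  df <- data.frame(sibship = c("a", "a", "b", "c", "c", "c"),
                   size = c(2, 2, 1, 3, 3, 3),
                   rank = c(1, 2, 1, 1, 2, 3))
  # all three sibships are uninformative (fully affected or singleton)
  expect_error(haldane_smith_test(df), class = "mbd_usage_error")
  df2 <- rbind(df, data.frame(sibship = "d", size = 4, rank = 4))
  r <- haldane_smith_test(df2)
  expect_equal(r$n_sibships_informative, 1L)
  expect_equal(r$rank_sum_observed, 4)
  expect_equal(r$rank_sum_null_mean, 2.5)
})

test_that("Wilcoxon control scores count older minus younger healthy sibs", {
  # affected youngest of 3 (2 older healthy) -> score +2
  df <- data.frame(sibship = "a", size = 3, rank = 3)
  w <- wilcoxon_boe_control(df)
  expect_equal(w$scores, 2)
  # affected oldest -> -2; only child -> score 0, dropped
  df <- data.frame(sibship = c("a", "b"), size = c(3, 1), rank = c(1, 1))
  w <- wilcoxon_boe_control(df)
  expect_equal(sort(w$scores), c(-2, 0))
  expect_equal(w$n_nonzero, 1L)
  # single case in the middle of three: equally many healthy on each side
  df <- data.frame(sibship = "a", size = 3, rank = 2)
  w <- wilcoxon_boe_control(df)
  expect_true(is.na(w$statistic))
  expect_match(w$note, "undefined")
})

test_that("restriction filters cases by sex, diagnosis and lineage", {
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 40,
                                             seed = 77))
  ped <- sim$pedigree
  all_ranks <- sibship_case_ranks(ped)
  male_cll <- sibship_case_ranks(ped, restrict = list(sex = "male",
                                                      diagnosis = "CLL"))
  expect_lt(nrow(male_cll), nrow(all_ranks))
  pa <- sibship_case_ranks(ped, restrict = list(lineage = "PA"))
  pairs <- enumerate_pc_ar(ped)
  expect_true(nrow(pa) <= length(unique(pairs$pc_id[pairs$lineage == "PA"])))
})

test_that("anticipation reports strata medians, a null trend for flat onsets, and parameter-true decline", {
  # flat onsets: zero trend by construction
  m <- three_gen_members()
  m$onset_age[m$affected] <- 60
  a <- assess_anticipation(pedigree(m))
  expect_equal(a$trend$tau, 0)
  expect_equal(a$trend$p_value, 1)
  expect_equal(a$trend$decline_per_generation, 0)
  # gpf and pf are founders (depth 0), c1 sits two steps below gpf
  expect_equal(a$strata$generation, c(0, 2))
  # fewer than two strata: trend undefined with a warning
  expect_warning(a1 <- assess_anticipation(pedigree(trio_members())),
                 "undefined")
  expect_true(is.na(a1$trend$tau))
})

test_that("anticipation compares familial prevalence against a reference registry mix", {
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 60,
                                             anticipation_delta = 5,
                                             seed = 19))
  ref <- mbd_reference_counts("continental")
  a <- assess_anticipation(sim$pedigree, reference = ref, group = "LPD")
  cmp <- a$prevalence_comparison
  expect_true(nrow(cmp) > 0)
  expect_true(all(cmp$fam_total == cmp$fam_total[1]))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # the simulated decline shows up as a negative onset trend
  expect_lt(a$trend$tau, 0)
  expect_gt(a$trend$decline_per_generation, 0)
})
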