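test_that("generation is deterministic given a seed and leaves the RNG state alone", {
  cfg <- simulation_config("nuclear", n_families = 8, seed = 123)
  a <- generate_pedigree(cfg)
  set.seed(999)
  before <- .Random.seed
  b <- generate_pedigree(cfg)
  expect_identical(a$pedigree$members, b$pedigree$members)
  expect_identical(a$truth, b$truth)
  expect_identical(before, .Random.seed)  # caller RNG restored
  # different seed, different pedigree
  c <- generate_pedigree(cfg, seed = 124)
  expect_false(identical(a$pedigree$members, c$pedigree$members))
})

test_that("infeasible configurations error before sampling", {
  expect_error(simulation_config(mixture = data.frame(label = character(0),
                                                      weight = numeric(0))),
               class = "mbd_config_error")
  expect_error(simulation_config(maternal_drive = 1.3),
               class = "mbd_config_error")
  expect_error(simulation_config(transmit_rate = 0.9, maternal_drive = 0.8),
               "infeasible", class = "mbd_config_error")
  expect_error(simulation_config(birth_order_enhancement = 0.5),
               class = "mbd_config_error")
  expect_error(generate_pedigree(simulation_config("nuclear", n_families = 2)),
               "seed", class = "mbd_config_error")
})

test_that("nuclear ascertainment yields only families with two or more affected", {
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 30,
                                             seed = 55))
  per_family <- tapply(sim$pedigree$members$affected,
                       sub("\\..*$", "", sim$pedigree$members$id), sum)
  expect_true(all(per_family >= 2))
  expect_equal(sim$mean_cases_per_family, mean(per_family))
  # realized case load sits near the configured continental average
  expect_gt(sim$mean_cases_per_family, 2)
  expect_lt(sim$mean_cases_per_family, 4)
})

test_that("non-carriers never have affected descendants through their line", {
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 25,
                                             seed = 14))
  ped <- sim$pedigree
  carrier <- setNames(sim$truth$carrier_state != "non-carrier", sim$truth$id)
  m <- ped$members
  for (i in which(m$affected)) {
    expect_true(carrier[[m$id[i]]])  # affected are carriers
    f <- m$father_id[i]; mo <- m$mother_id[i]
    if (!is.na(f) || !is.na(mo)) {
      # at least one parent of an affected non-founder is a carrier
      expect_true(any(carrier[stats::na.omit(c(f, mo))]))
    }
  }
})

test_that("the symmetric null is balanced: PA/MA near 50/50 and no birth-order excess", {
  # pairs pooled over several independent null simulations
  n_pa <- n_ma <- 0
  hs_reject <- 0
  reps <- 25
  for (seed in seq_len(reps)) {
    sim <- generate_pedigree(simulation_config("nuclear", n_families = 30,
                                               seed = 3000 + seed))
    pt <- extract_vertical_pairs(enumerate_pc_ar(sim$pedigree))
    sh <- lineage_shares(pt)
    n_pa <- n_pa + sh$n[sh$lineage == "PA"]
    n_ma <- n_ma + sh$n[sh$lineage == "MA"]
    hs <- haldane_smith_test(sim$pedigree)
    if (hs$decision != "none") hs_reject <- hs_reject + 1
  }
  frac_pa <- n_pa / (n_pa + n_ma)
  expect_gt(n_pa + n_ma, 700)
  expect_gt(frac_pa, 0.44)
  expect_lt(frac_pa, 0.56)
  # ~5% nominal rejection rate: with 25 draws, >7 rejections would be
  # astronomically unlikely (P < 1e-5 at p = 0.05)
  expect_lte(hs_reject, 7)
})

test_that("raising the birth-order enhancement raises the mean rank-sum z", {
  mean_z <- function(beta) {
    zs <- vapply(1:6, function(seed) {
      sim <- generate_pedigree(simulation_config(
        "nuclear", n_families = 25, birth_order_enhancement = beta,
        mixture = data.frame(label = "CLL", weight = 1),
        seed = 6000 + seed))
      hs <- haldane_smith_test(
        sim$pedigree,
        restrict = list(sex = "male", diagnosis = "CLL", lineage = "PA"))
      hs$z
    }, numeric(1))
    mean(zs)
  }
  expect_gt(mean_z(4), mean_z(1))
})

test_that("raising the maternal drive raises the maternal pair fraction", {
  ma_frac <- function(drive, seed) {
    sim <- generate_pedigree(simulation_config(
      "nuclear", n_families = 120, maternal_drive = drive, seed = seed))
    sh <- lineage_shares(extract_vertical_pairs(enumerate_pc_ar(sim$pedigree)))
    sh$n[sh$lineage == "MA"] / sum(sh$n)
  }
  expect_gt(ma_frac(0.75, 21), ma_frac(0.5, 21))
  expect_gt(ma_frac(0.5, 22), ma_frac(0.25, 22))
})

test_that("endemic mode produces one connected deep kindred with loops available", {
  sim <- generate_pedigree(simulation_config("endemic", loop_rate = 0.5,
                                             seed = 4))
  ped <- sim$pedigree
  expect_equal(ped$kindred_mode, "endemic")
  expect_gte(max(generation_depth(ped)), 4L)
  # connectivity over the parent-child graph (marriages bind via children)
  m <- ped$members
  edges <- rbind(
    cbind(m$id, m$father_id)[!is.na(m$father_id), , drop = FALSE],
    cbind(m$id, m$mother_id)[!is.na(m$mother_id), , drop = FALSE])
  comp <- setNames(seq_len(nrow(m)), m$id)
  repeat {
    before <- comp
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      mn <- min(comp[[a]], comp[[b]])
      comp[[a]] <- mn; comp[[b]] <- mn
    }
    if (identical(before, comp)) break
  }
  main <- max(table(comp)) / nrow(m)
  expect_gt(main, 0.95)  # essentially one connected kindred
})

test_that("the null configuration leaves anticipation undetected at the nominal rate", {
  rejections <- 0
  reps <- 20
  for (seed in seq_len(reps)) {
    sim <- generate_pedigree(simulation_config("nuclear", n_families = 20,
                                               seed = 7000 + seed))
    a <- assess_anticipation(sim$pedigree)
    if (!is.na(a$trend$p_value) && a$trend$p_value < 0.05)
      rejections <- rejections + 1
  }
  # with 20 draws at a true rate of 0.05, >6 rejections has P < 1e-4
  expect_lte(rejections, 6)
})
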