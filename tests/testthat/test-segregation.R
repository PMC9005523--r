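test_that("lineage follows the first ancestral step", {
  ped <- pedigree(three_gen_members())
  expect_equal(classify_lineage(ped, "c1", "pf"), "PA")    # father
  expect_equal(classify_lineage(ped, "c1", "gpf"), "MA")   # maternal grandfather
  expect_error(classify_lineage(ped, "c1", "c2"),
               class = "mbd_relation_error")                # a sib, not an ancestor
  expect_error(classify_lineage(ped, "pf", "c1"),
               class = "mbd_relation_error")                # descendant, not ancestor
})

test_that("consanguinity loops signal ambiguity and duplicate the pair per first edge", {
  ped <- pedigree(consanguineous_members())
  expect_warning(lin <- classify_lineage(ped, "P", "A"),
                 class = "mbd_lineage_ambiguity")
  expect_setequal(lin, c("PA", "MA"))
  pairs <- enumerate_pc_ar(ped)
  pa <- pairs[pairs$pc_id == "P" & pairs$ar_id == "A", ]
  expect_equal(nrow(pa), 2L)
  expect_setequal(pa$lineage, c("PA", "MA"))
  expect_true(all(pa$consanguineous))
  expect_true(all(pa$generation_gap == 3L))
  expect_true(all(pa$healthy_intermediates == 2L))
  # matches the brute-force path-enumeration oracle
  expect_equal(sorted_pairs(pairs), sorted_pairs(brute_force_pairs(ped)))
})

test_that("affected parent-child chain yields one pair with the child as proband", {
  ped <- pedigree(three_gen_members())
  pairs <- enumerate_pc_ar(ped)
  # affected: gpf, pf, c1. Vertical links: c1-pf (PA gap 1), c1-gpf (MA gap 2)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(paste(pairs$pc_id, pairs$ar_id),
                  c("c1 pf", "c1 gpf"))
  expect_equal(pairs$healthy_intermediates[pairs$ar_id == "gpf"], 1L)
})

test_that("generation and healthy-intermediate caps bound the enumeration", {
  # gap 6 ancestor: excluded at the default cap, included when raised
  deep <- pedigree(chain_members(5))    # 5 healthy links -> gap 6
  expect_equal(nrow(enumerate_pc_ar(deep)), 0L)
  expect_equal(nrow(enumerate_pc_ar(deep, max_generations = 6)), 1L)

  # healthy cap in isolation (generation cap relaxed):
  # 6 healthy intermediates -> no pair; 5 healthy -> pair
  six <- pedigree(chain_members(6))
  expect_equal(nrow(enumerate_pc_ar(six, max_generations = 10)), 0L)
  five <- pedigree(chain_members(5))
  got <- enumerate_pc_ar(five, max_generations = 10)
  expect_equal(nrow(got), 1L)
  expect_equal(got$healthy_intermediates, 5L)

  # affected intermediates do not count against the healthy cap
  m <- chain_members(6)
  m$affected[m$id == "i4"] <- TRUE
  m$icd10[m$id == "i4"] <- "C90"
  got <- enumerate_pc_ar(pedigree(m), max_generations = 10)
  expect_equal(sum(got$pc_id == "i8" & got$ar_id == "i1"), 1L)
})

test_that("enumeration is monotone in both caps", {
  sim <- generate_pedigree(simulation_config("endemic", n_generations = 5,
                                             seed = 9))
  ped <- sim$pedigree
  key <- function(p) paste(p$pc_id, p$ar_id, p$lineage)
  for (g in 1:4) {
    a <- enumerate_pc_ar(ped, max_generations = g)
    b <- enumerate_pc_ar(ped, max_generations = g + 1)
    expect_true(all(key(a) %in% key(b)))
  }
  for (h in 0:4) {
    a <- enumerate_pc_ar(ped, max_healthy_intermediates = h)
    b <- enumerate_pc_ar(ped, max_healthy_intermediates = h + 1)
    expect_true(all(key(a) %in% key(b)))
  }
})

test_that("pair enumeration equals the brute-force oracle on random pedigrees", {
  for (seed in c(5, 17)) {
    for (mode in c("nuclear", "endemic")) {
      sim <- generate_pedigree(simulation_config(
        mode, n_families = 8, n_generations = 4, seed = seed))
      got <- sorted_pairs(enumerate_pc_ar(sim$pedigree))
      want <- sorted_pairs(brute_force_pairs(sim$pedigree))
      expect_equal(got, want)
      # lineage of every pair agrees with classify_lineage
      for (i in seq_len(nrow(got))) {
        lin <- suppressWarnings(classify_lineage(sim$pedigree, got$pc_id[i],
                                                 got$ar_id[i]))
        expect_true(got$lineage[i] %in% lin)
      }
    }
  }
})

test_that("no lineage ambiguity ever arises in loop-free nuclear pedigrees", {
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 25,
                                             seed = 31))
  pairs <- enumerate_pc_ar(sim$pedigree)
  expect_false(any(pairs$consanguineous))
  expect_warning(
    for (i in seq_len(nrow(pairs)))
      classify_lineage(sim$pedigree, pairs$pc_id[i], pairs$ar_id[i]),
    NA)
})

test_that("true transmission lineage is recovered for parent-offspring pairs", {
  sim <- generate_pedigree(simulation_config("nuclear", n_families = 30,
                                             seed = 8))
  pairs <- enumerate_pc_ar(sim$pedigree)
  po <- pairs[pairs$generation_gap == 1L, ]
  truth <- setNames(sim$truth$lineage, sim$truth$id)
  # the affected parent of an affected child is its transmitting carrier,
  # so the pair lineage must equal the child's true lineage
  expect_true(all(po$lineage == truth[po$pc_id]))
})

test_that("vertical extraction drops oblique and deep pairs and keeps marginals consistent", {
  pairs <- enumerate_pc_ar(pedigree(chain_members(2)), max_generations = 5)
  expect_equal(nrow(pairs), 1L)          # gap 3 pair exists
  pt <- extract_vertical_pairs(pairs)    # but exceeds the default gap cap
  expect_equal(nrow(pt$pairs), 0L)

  # a hand-made oblique pair never enters
  obl <- pairs
  obl$relation_class <- "oblique"
  obl$generation_gap <- 2L
  expect_equal(nrow(extract_vertical_pairs(obl)$pairs), 0L)

  # PA + MA counts equal total pairs (consanguineous duplicates counted
  # once per first edge)
  sim <- generate_pedigree(simulation_config("endemic", seed = 2))
  pt <- extract_vertical_pairs(enumerate_pc_ar(sim$pedigree))
  sh <- lineage_shares(pt)
  expect_equal(sum(sh$n), nrow(pt$pairs))
  expect_equal(sum(pt$xtab), nrow(pt$pairs))
})

test_that("pair percentages use half-up rounding and mark empty strata undefined", {
  pairs <- mbd_reference_pair_list()
  pt <- extract_vertical_pairs(pairs)
  pp <- pair_percentages(pt)
  # single-sex stratum
  one <- pairs[1, , drop = FALSE]
  one$pc_sex <- "male"
  pp1 <- pair_percentages(extract_vertical_pairs(one))
  expect_equal(pp1$pct_male[pp1$pair_group == "CLL-CLL" & pp1$lineage == "PA"], 100L)
  expect_true(is.na(pp1$pct_male[pp1$lineage == "MA" & pp1$pair_group == "CLL-CLL"]))
  # half-up: mixed-pair MA CLL offspring 10/16 -> 63%, 6/16 -> 38%
  mixed <- pp[pp$pair_group == "nonCLL-CLL" & pp$lineage == "MA", ]
  expect_equal(mixed$pct_male, 63L)
  expect_equal(mixed$pct_female, 38L)
})

test_that("horizontal sibling pairs are enumerated separately and never enter the table", {
  m <- three_gen_members()
  m$affected[m$id == "c2"] <- TRUE
  m$icd10[m$id == "c2"] <- "C90"
  ped <- pedigree(m)
  hp <- horizontal_pairs(ped)
  expect_equal(nrow(hp), 1L)
  expect_setequal(c(hp$id1, hp$id2), c("c1", "c2"))
  pt <- extract_vertical_pairs(enumerate_pc_ar(ped))
  expect_false(any(paste(pt$pairs$pc_id, pt$pairs$ar_id) %in%
                     c("c1 c2", "c2 c1")))
})
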