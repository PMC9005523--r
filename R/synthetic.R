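# Synthetic pedigree generator.
#
# The generator implements a two-state carrier process with
# sex-of-parent x sex-of-child transmission weights: a carrier parent
# transmits susceptibility to each child with a base rate, tilted towards
# daughters by `maternal_drive` so that the fraction of transmissions
# through mothers (and hence of maternal-line affected pairs) equals the
# drive. Carriers receive a "destined" diagnosis drawn from a configurable
# prevalence mixture and become affected with a penetrance whose odds can
# be multiplied by `birth_order_enhancement` per birth rank for a
# configurable scope (by default male CLL carriers in paternal lines,
# the one group with a reported late-birth excess). Age at onset declines
# by `anticipation_delta` years per generation around a configurable
# median with Gaussian noise. Non-carriers never become affected, so a
# non-carrier line produces affected descendants only through a second
# carrier founder (which nuclear mode never introduces).
#
# Two kindred modes:
#  * nuclear: independent three-generation families, each re-drawn until it
#    contains at least `min_affected_per_family` affected members
#    (the ascertainment rule for the continental series);
#  * endemic: one deep connected family in which children marry within the
#    pedigree with probability `loop_rate`, creating consanguinity loops.

#' Simulation configuration
#'
#' @param mode `"nuclear"` or `"endemic"`.
#' @param n_families number of independent families (nuclear mode).
#' @param n_generations pedigree depth in generations (default 3 nuclear,
#'   5 endemic).
#' @param mean_sibship mean number of children per couple (sibship size is
#'   `1 + Poisson(mean_sibship - 1)`); defaults to 3 in nuclear mode and 5
#'   in endemic mode (a high-parity isolate).
#' @param transmit_rate base probability that a carrier parent transmits to
#'   a child (before the drive tilt); must satisfy
#'   `2 * transmit_rate * max(maternal_drive, 1 - maternal_drive) <= 1`.
#'   Defaults to 0.5 in nuclear mode and 0.85 in endemic mode (where the
#'   susceptibility persists through many generations).
#' @param maternal_drive probability that a transmission passes through a
#'   mother; 0.5 is the symmetric null.
#' @param penetrance probability that a carrier becomes affected.
#' @param birth_order_enhancement multiplier `beta >= 1` applied to the
#'   penetrance odds per birth rank (`odds * beta^(rank-1)`) for carriers
#'   matching `boe_scope`; 1 disables the effect.
#' @param boe_scope list with `sex`, `diagnosis`, `lineage` restricting the
#'   birth-order enhancement (default male, CLL, PA).
#' @param anticipation_delta onset-age decrement per generation, years.
#' @param onset_median,onset_sd baseline onset distribution (years): onset
#'   is `onset_median - depth * anticipation_delta + N(0, onset_sd)`,
#'   truncated at 0.
#' @param mixture diagnosis mixture: data.frame with `label` and `weight`
#'   (defaults to the continental familial MBD case mix).
#' @param min_affected_per_family ascertainment threshold (nuclear mode).
#' @param loop_rate probability of a within-pedigree marriage (endemic).
#' @param max_reproducers cap on children who marry per generation
#'   (endemic mode; bounds pedigree growth).
#' @param max_attempts resampling cap per family for ascertainment.
#' @param seed default seed used by [generate_pedigree()].
#' @return validated list of class `mbd_sim_config`.
#' @export
simulation_config <- function(mode = c("nuclear", "endemic"),
                              n_families = 112L,
                              n_generations = NULL,
                              mean_sibship = NULL,
                              transmit_rate = NULL,
                              maternal_drive = 0.5,
                              penetrance = 0.3,
                              birth_order_enhancement = 1,
                              boe_scope = list(sex = "male",
                                               diagnosis = "CLL",
                                               lineage = "PA"),
                              anticipation_delta = 0,
                              onset_median = 67,
                              onset_sd = 10,
                              mixture = NULL,
                              min_affected_per_family = 2L,
                              loop_rate = 0.3,
                              max_reproducers = 60L,
                              max_attempts = 500L,
                              seed = NULL) {
  mode <- match.arg(mode)
  n_generations <- n_generations %||% if (mode == "nuclear") 3L else 5L
  mean_sibship <- mean_sibship %||% if (mode == "nuclear") 3 else 5
  transmit_rate <- transmit_rate %||% if (mode == "nuclear") 0.5 else 0.85
  mixture <- mixture %||% default_diagnosis_mixture()
  mixture <- as.data.frame(mixture, stringsAsFactors = FALSE)
  if (!all(c("label", "weight") %in% names(mixture)) ||
      nrow(mixture) == 0L || sum(mixture$weight) <= 0)
    abort_mbd("mixture must have labels with positive total weight",
              class = "mbd_config_error")
  probs <- c(transmit_rate = transmit_rate, maternal_drive = maternal_drive,
             penetrance = penetrance, loop_rate = loop_rate)
  if (any(probs < 0 | probs > 1))
    abort_mbd("probabilities must lie in [0, 1]", class = "mbd_config_error")
  if (2 * transmit_rate * max(maternal_drive, 1 - maternal_drive) > 1 + 1e-12)
    abort_mbd("infeasible drive tilt: need 2*transmit_rate*max(drive, 1-drive) <= 1",
              class = "mbd_config_error")
  if (birth_order_enhancement < 1)
    abort_mbd("birth_order_enhancement must be >= 1", class = "mbd_config_error")
  if (mean_sibship < 1)
    abort_mbd("mean_sibship must be >= 1", class = "mbd_config_error")
  if (n_generations < 2)
    abort_mbd("need at least 2 generations", class = "mbd_config_error")
  if (anticipation_delta < 0 || onset_sd < 0)
    abort_mbd("anticipation_delta and onset_sd must be non-negative",
              class = "mbd_config_error")
  structure(list(mode = mode, n_families = as.integer(n_families),
                 n_generations = as.integer(n_generations),
                 mean_sibship = mean_sibship, transmit_rate = transmit_rate,
                 maternal_drive = maternal_drive, penetrance = penetrance,
                 birth_order_enhancement = birth_order_enhancement,
                 boe_scope = boe_scope,
                 anticipation_delta = anticipation_delta,
                 onset_median = onset_median, onset_sd = onset_sd,
                 mixture = mixture,
                 min_affected_per_family = as.integer(min_affected_per_family),
                 loop_rate = loop_rate,
                 max_reproducers = as.integer(max_reproducers),
                 max_attempts = as.integer(max_attempts), seed = seed),
            class = "mbd_sim_config")
}

#' Default diagnosis mixture
#'
#' The continental familial MBD case mix (all diagnosis labels weighted by
#' their familial case counts).
#'
#' @return data.frame with columns `label`, `weight`.
#' @export
default_diagnosis_mixture <- function() {
  counts <- mbd_reference_counts("continental")
  data.frame(label = counts$label, weight = counts$total,
             stringsAsFactors = FALSE)
}

# accumulator for individuals of one simulated kindred
new_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$add <- function(id, father, mother, sex, birth_order, birth_year,
                    affected, icd10, onset_age, carrier, lineage, destined,
                    depth, family) {
    e$rows[[length(e$rows) + 1L]] <- list(
      id = id, father_id = father, mother_id = mother, sex = sex,
      birth_order = birth_order, birth_year = birth_year,
      affected = affected, icd10 = icd10, onset_age = onset_age,
      carrier = carrier, lineage = lineage, destined = destined,
      depth = depth, family = family)
  }
  e
}

acc_frame <- function(acc) {
  cols <- names(acc$rows[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(acc$rows, function(r) {
    v <- r[[cn]]
    if (is.null(v)) NA else v
  })))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

sample_label <- function(mixture) {
  if (nrow(mixture) == 1L) return(mixture$label)
  sample(mixture$label, 1L, prob = mixture$weight)
}

scope_matches <- function(scope, sex, destined, lineage) {
  ok <- TRUE
  if (!is.null(scope$sex)) ok <- ok && identical(sex, scope$sex)
  if (!is.null(scope$diagnosis)) ok <- ok && identical(destined, scope$diagnosis)
  if (!is.null(scope$lineage)) ok <- ok && identical(lineage, scope$lineage)
  ok
}

# draw affection for a carrier, applying the birth-order enhancement
draw_affected <- function(cfg, sex, destined, lineage, rank) {
  p <- cfg$penetrance
  if (cfg$birth_order_enhancement > 1 && !is.na(lineage) &&
      scope_matches(cfg$boe_scope, sex, destined, lineage)) {
    o <- p / (1 - p) * cfg$birth_order_enhancement^(rank - 1)
    p <- o / (1 + o)
  }
  stats::runif(1) < p
}

draw_onset <- function(cfg, depth) {
  max(0, cfg$onset_median - depth * cfg$anticipation_delta +
        stats::rnorm(1, 0, cfg$onset_sd))
}

# one nuclear family draw (without ascertainment)
gen_family_once <- function(fid, cfg) {
  acc <- new_acc()
  n <- 0L
  next_id <- function() {
    n <<- n + 1L
    sprintf("%s.%02d", fid, n)
  }
  f0 <- next_id(); m0 <- next_id()
  carrier_is_mother <- stats::runif(1) < cfg$maternal_drive
  g0 <- list(
    list(id = f0, sex = "male", carrier = !carrier_is_mother),
    list(id = m0, sex = "female", carrier = carrier_is_mother))
  carrier_id <- if (carrier_is_mother) m0 else f0
  for (p in g0) {
    destined <- if (p$carrier) sample_label(cfg$mixture) else NA_character_
    affected <- p$carrier && draw_affected(cfg, p$sex, destined, NA_character_, 1L)
    acc$add(p$id, NA_character_, NA_character_, p$sex, NA_integer_, 1880L,
            affected, if (affected) icd10_for_label(destined) else NA_character_,
            if (affected) draw_onset(cfg, 0L) else NA_real_,
            p$carrier, NA_character_, destined, 0L, fid)
  }
  couples <- list(list(f = f0, m = m0,
                       carrier_sex = if (carrier_is_mother) "female" else "male",
                       has_carrier = TRUE))
  for (g in seq_len(cfg$n_generations - 1L)) {
    next_couples <- list()
    for (cp in couples) {
      k <- 1L + stats::rpois(1, max(cfg$mean_sibship - 1, 0))
      for (r in seq_len(k)) {
        cid <- next_id()
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        carrier <- FALSE
        lineage <- NA_character_
        destined <- NA_character_
        if (cp$has_carrier) {
          tilt <- if (sex == "female") cfg$maternal_drive else 1 - cfg$maternal_drive
          if (stats::runif(1) < 2 * cfg$transmit_rate * tilt) {
            carrier <- TRUE
            lineage <- if (cp$carrier_sex == "male") "PA" else "MA"
            destined <- sample_label(cfg$mixture)
          }
        }
        affected <- carrier && draw_affected(cfg, sex, destined, lineage, r)
        acc$add(cid, cp$f, cp$m, sex, r, 1880L + 28L * g + 2L * (r - 1L),
                affected,
                if (affected) icd10_for_label(destined) else NA_character_,
                if (affected) draw_onset(cfg, g) else NA_real_,
                carrier, lineage, destined, g, fid)
        if (g < cfg$n_generations - 1L) {
          sid <- next_id()
          ssex <- if (sex == "male") "female" else "male"
          acc$add(sid, NA_character_, NA_character_, ssex, NA_integer_,
                  1880L + 28L * g, FALSE, NA_character_, NA_real_,
                  FALSE, NA_character_, NA_character_, 0L, fid)
          next_couples[[length(next_couples) + 1L]] <- list(
            f = if (sex == "male") cid else sid,
            m = if (sex == "male") sid else cid,
            carrier_sex = sex, has_carrier = carrier)
        }
      }
    }
    couples <- next_couples
  }
  acc_frame(acc)
}

gen_family <- function(fid, cfg) {
  for (attempt in seq_len(cfg$max_attempts)) {
    fam <- gen_family_once(fid, cfg)
    if (sum(fam$affected) >= cfg$min_affected_per_family) return(fam)
  }
  abort_mbd(sprintf("could not ascertain a family with >= %d affected in %d attempts; raise penetrance/transmission",
                    cfg$min_affected_per_family, cfg$max_attempts),
            class = "mbd_config_error")
}

# one deep endemic kindred with within-pedigree marriages
gen_endemic <- function(cfg) {
  acc <- new_acc()
  n <- 0L
  fid <- "E1"
  next_id <- function() {
    n <<- n + 1L
    sprintf("%s.%04d", fid, n)
  }
  f0 <- next_id(); m0 <- next_id()
  carrier_is_mother <- stats::runif(1) < cfg$maternal_drive
  for (p in list(list(id = f0, sex = "male", carrier = !carrier_is_mother),
                 list(id = m0, sex = "female", carrier = carrier_is_mother))) {
    destined <- if (p$carrier) sample_label(cfg$mixture) else NA_character_
    affected <- p$carrier && draw_affected(cfg, p$sex, destined, NA_character_, 1L)
    acc$add(p$id, NA_character_, NA_character_, p$sex, NA_integer_, 1880L,
            affected, if (affected) icd10_for_label(destined) else NA_character_,
            if (affected) draw_onset(cfg, 0L) else NA_real_,
            p$carrier, NA_character_, destined, 0L, fid)
  }
  couples <- list(list(f = f0, m = m0,
                       carrier_sex = if (carrier_is_mother) "female" else "male",
                       has_carrier = TRUE))
  for (g in seq_len(cfg$n_generations - 1L)) {
    children <- list()
    for (ci in seq_along(couples)) {
      cp <- couples[[ci]]
      k <- 1L + stats::rpois(1, max(cfg$mean_sibship - 1, 0))
      for (r in seq_len(k)) {
        cid <- next_id()
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        carrier <- FALSE
        lineage <- NA_character_
        destined <- NA_character_
        if (cp$has_carrier) {
          tilt <- if (sex == "female") cfg$maternal_drive else 1 - cfg$maternal_drive
          if (stats::runif(1) < 2 * cfg$transmit_rate * tilt) {
            carrier <- TRUE
            lineage <- if (cp$carrier_sex == "male") "PA" else "MA"
            destined <- sample_label(cfg$mixture)
          }
        }
        affected <- carrier && draw_affected(cfg, sex, destined, lineage, r)
        acc$add(cid, cp$f, cp$m, sex, r, 1880L + 28L * g + 2L * (r - 1L),
                affected,
                if (affected) icd10_for_label(destined) else NA_character_,
                if (affected) draw_onset(cfg, g) else NA_real_,
                carrier, lineage, destined, g, fid)
        children[[length(children) + 1L]] <- list(id = cid, sex = sex,
                                                  carrier = carrier,
                                                  couple = ci)
      }
    }
    if (g == cfg$n_generations - 1L) break
    # marriages: within the pedigree with probability loop_rate (different
    # parental couple required), otherwise to a new marry-in founder
    if (length(children) > cfg$max_reproducers)
      children <- children[sort(sample.int(length(children),
                                           cfg$max_reproducers))]
    unmatched <- children[sample.int(length(children))]
    couples <- list()
    while (length(unmatched) > 0L) {
      a <- unmatched[[1]]
      unmatched <- unmatched[-1]
      partner <- NULL
      if (length(unmatched) > 0L && stats::runif(1) < cfg$loop_rate) {
        ok <- which(vapply(unmatched, function(b)
          b$sex != a$sex && b$couple != a$couple, logical(1)))
        if (length(ok)) {
          partner <- unmatched[[ok[1]]]
          unmatched <- unmatched[-ok[1]]
        }
      }
      if (is.null(partner)) {
        sid <- next_id()
        ssex <- if (a$sex == "male") "female" else "male"
        acc$add(sid, NA_character_, NA_character_, ssex, NA_integer_,
                1880L + 28L * g, FALSE, NA_character_, NA_real_,
                FALSE, NA_character_, NA_character_, 0L, fid)
        partner <- list(id = sid, sex = ssex, carrier = FALSE, couple = 0L)
      }
      carriers <- c(if (a$carrier) list(a), if (partner$carrier) list(partner))
      designated <- if (length(carriers))
        carriers[[sample.int(length(carriers), 1L)]] else NULL
      couples[[length(couples) + 1L]] <- list(
        f = if (a$sex == "male") a$id else partner$id,
        m = if (a$sex == "male") partner$id else a$id,
        carrier_sex = if (is.null(designated)) NA_character_ else designated$sex,
        has_carrier = !is.null(designated))
    }
  }
  acc_frame(acc)
}

#' Generate a synthetic pedigree with ground truth
#'
#' Reproducible given `seed` (the caller's RNG state is restored
#' afterwards). In nuclear mode each family is re-drawn until it contains
#' the ascertainment minimum of affected members; in endemic mode one
#' connected multi-generation pedigree is produced.
#'
#' @param cfg an [simulation_config()] object.
#' @param seed integer seed (defaults to `cfg$seed`); an error is raised if
#'   neither is given, since unseeded simulations are not reproducible.
#' @return list of class `mbd_simulation`: `pedigree` (an `mbd_pedigree`),
#'   `truth` (per-individual ground truth: `carrier_state` in
#'   affected-susceptible / silent-carrier / non-carrier, true transmission
#'   `lineage`, `destined` diagnosis, generation `depth`, `family`), and
#'   `mean_cases_per_family` (nuclear mode).
#' @export
generate_pedigree <- function(cfg, seed = cfg$seed) {
  if (!inherits(cfg, "mbd_sim_config"))
    abort_mbd("cfg must come from simulation_config()",
              class = "mbd_config_error")
  if (is.null(seed))
    abort_mbd("a seed is required for reproducible generation",
              class = "mbd_config_error")
  with_seed(seed, {
    frames <- if (cfg$mode == "nuclear") {
      lapply(seq_len(cfg$n_families), function(i)
        gen_family(sprintf("F%04d", i), cfg))
    } else {
      list(gen_endemic(cfg))
    }
    all <- do.call(rbind, frames)
    ped <- pedigree(all[, MEMBER_COLUMNS],
                    family_id = if (cfg$mode == "nuclear") "SIM" else "E1",
                    kindred_mode = cfg$mode)
    truth <- data.frame(
      id = all$id, family = all$family,
      carrier_state = ifelse(!all$carrier, "non-carrier",
                             ifelse(all$affected, "affected-susceptible",
                                    "silent-carrier")),
      lineage = all$lineage, destined = all$destined, depth = all$depth,
      stringsAsFactors = FALSE)
    mean_cases <- if (cfg$mode == "nuclear")
      mean(tapply(all$affected, all$family, sum)) else NA_real_
    structure(list(pedigree = ped, truth = truth,
                   mean_cases_per_family = mean_cases, config = cfg),
              class = "mbd_simulation")
  })
}

#' @export
print.mbd_simulation <- function(x, ...) {
  cat(sprintf("<mbd_simulation> mode %s: %d members, %d affected",
              x$config$mode, nrow(x$pedigree$members),
              sum(x$pedigree$members$affected)))
  if (!is.na(x$mean_cases_per_family))
    cat(sprintf(", %.2f cases/family", x$mean_cases_per_family))
  cat("\n")
  invisible(x)
}
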