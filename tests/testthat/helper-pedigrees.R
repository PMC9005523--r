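# Small pedigrees built in code, shared across test files.

# founder couple with one affected CLL child
trio_members <- function() {
  data.frame(
    id = c("f", "m", "c"),
    father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"),
    sex = c("male", "female", "male"),
    birth_order = c(NA, NA, 1),
    affected = c(FALSE, FALSE, TRUE),
    icd10 = c(NA, NA, "C91.1"),
    onset_age = c(NA, NA, 60),
    stringsAsFactors = FALSE)
}

# three generations: affected maternal grandfather, unaffected parents,
# affected grandchild; plus an affected father on the paternal side
three_gen_members <- function() {
  data.frame(
    id =        c("gpf", "gpm", "pf",    "pm",  "c1", "c2"),
    father_id = c(NA,    NA,    NA,      "gpf", "pf", "pf"),
    mother_id = c(NA,    NA,    NA,      "gpm", "pm", "pm"),
    sex = c("male", "female", "male", "female", "male", "female"),
    birth_order = c(NA, NA, NA, 1, 1, 2),
    affected = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    icd10 = c("C91.1", NA, "C90", NA, "C91.1", NA),
    onset_age = c(70, NA, 65, NA, 55, NA),
    stringsAsFactors = FALSE)
}

# cousin marriage: founder couple A,B; sibs C,D; C x E -> G; D x F -> H;
# G x H -> P. A and P affected, so A (great-grandparent of P) is reachable
# through P's father H (PA) and P's mother G (MA).
consanguineous_members <- function() {
  data.frame(
    id =        c("A", "B",  "C", "D", "E", "F", "G", "H", "P"),
    father_id = c(NA,  NA,   "A", "A", NA,  NA,  "C", "F", "H"),
    mother_id = c(NA,  NA,   "B", "B", NA,  NA,  "E", "D", "G"),
    sex = c("male", "female", "male", "female", "female", "male",
            "female", "male", "male"),
    birth_order = c(NA, NA, 1, 2, NA, NA, 1, 1, 1),
    affected = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    icd10 = c("C90", NA, NA, NA, NA, NA, NA, NA, "C91.1"),
    onset_age = c(72, NA, NA, NA, NA, NA, NA, NA, 48),
    stringsAsFactors = FALSE)
}

# straight descent chain: affected top ancestor, n_healthy unaffected
# links, affected bottom proband (generation gap = n_healthy + 1)
chain_members <- function(n_healthy) {
  n <- n_healthy + 2L
  ids <- paste0("i", seq_len(n))
  spouses <- paste0("s", seq_len(n - 1L))
  rows <- data.frame(
    id = c(ids, spouses),
    father_id = c(NA, ids[-n], rep(NA, n - 1L)),
    mother_id = c(NA, spouses, rep(NA, n - 1L)),
    sex = c(rep("male", n), rep("female", n - 1L)),
    birth_order = c(NA, rep(1, n - 1L), rep(NA, n - 1L)),
    affected = c(TRUE, rep(FALSE, n - 2L), TRUE, rep(FALSE, n - 1L)),
    icd10 = c("C91.1", rep(NA, n - 2L), "C91.1", rep(NA, n - 1L)),
    stringsAsFactors = FALSE)
  rows
}

# independent brute-force ancestry oracle: enumerate every parent path
# from `from` upward and return data.frame(ancestor, first_edge, gap,
# healthy) for all paths (not only shortest)
all_ancestor_paths <- function(ped, from) {
  m <- ped$members
  father <- setNames(m$father_id, m$id)
  mother <- setNames(m$mother_id, m$id)
  affected <- setNames(m$affected, m$id)
  out <- list()
  recurse <- function(id, edge, gap, path) {
    healthy <- if (length(path)) sum(!affected[path]) else 0L
    out[[length(out) + 1L]] <<- data.frame(
      ancestor = id, first_edge = edge, gap = gap, healthy = healthy,
      stringsAsFactors = FALSE)
    f <- father[[id]]; mo <- mother[[id]]
    if (!is.na(f)) recurse(f, edge, gap + 1L, c(path, id))
    if (!is.na(mo)) recurse(mo, edge, gap + 1L, c(path, id))
  }
  f <- father[[from]]; mo <- mother[[from]]
  if (!is.na(f)) recurse(f, "PA", 1L, character(0))
  if (!is.na(mo)) recurse(mo, "MA", 1L, character(0))
  if (length(out)) do.call(rbind, out)
  else data.frame(ancestor = character(0), first_edge = character(0),
                  gap = integer(0), healthy = integer(0))
}

# brute-force pair oracle built on all_ancestor_paths: for each affected
# proband and (affected ancestor, first edge), the shortest path's gap and
# its healthy count, subject to the caps
brute_force_pairs <- function(ped, max_gap = 5L, max_healthy = 5L) {
  m <- ped$members
  affected_ids <- m$id[m$affected]
  rows <- list()
  for (pc in affected_ids) {
    paths <- all_ancestor_paths(ped, pc)
    paths <- paths[paths$ancestor %in% affected_ids & paths$gap <= max_gap, ,
                   drop = FALSE]
    if (!nrow(paths)) next
    for (key in unique(paste(paths$ancestor, paths$first_edge))) {
      sel <- paths[paste(paths$ancestor, paths$first_edge) == key, ,
                   drop = FALSE]
      best <- sel[order(sel$gap, sel$healthy), ][1, ]
      if (best$healthy > max_healthy) next
      rows[[length(rows) + 1L]] <- data.frame(
        pc_id = pc, ar_id = best$ancestor, lineage = best$first_edge,
        generation_gap = best$gap, healthy_intermediates = best$healthy,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(pc_id = character(0), ar_id = character(0),
                  lineage = character(0), generation_gap = integer(0),
                  healthy_intermediates = integer(0))
}

sorted_pairs <- function(df) {
  df <- as.data.frame(df)[, c("pc_id", "ar_id", "lineage", "generation_gap",
                              "healthy_intermediates")]
  df <- df[order(df$pc_id, df$ar_id, df$lineage), ]
  rownames(df) <- NULL
  df
}
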