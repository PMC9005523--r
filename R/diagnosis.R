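# Diagnosis vocabulary for malignant blood disorders (MBD).
#
# Two disease groups are used throughout: lymphoproliferative disorders (LPD)
# and myeloproliferative disorders (MPD); leukemia-NOS and malignant
# histiocytosis fall outside both ("OTHER"). CLL is singled out because its
# segregation is analysed separately from all other diagnoses ("nonCLL").

#' Canonical diagnosis table for malignant blood disorders
#'
#' Returns the diagnosis vocabulary used by the package: short label,
#' representative ICD-10 code, lineage group (`LPD`, `MPD` or `OTHER`) and
#' whether the label is chronic lymphocytic leukemia. The grouping follows
#' the standard clinical partition of MBD: CLL, ALL, other leukemias, MM,
#' MGUS, HL, DLBCL, FL and other lymphomas are lymphoproliferative; AML, CML
#' and other MPD are myeloproliferative; leukemia NOS and malignant
#' histiocytosis are grouped as other MBD.
#'
#' @param aliases logical; if `TRUE`, also include the auxiliary labels
#'   `NHL-NOS` (LPD) and `MF` (myelofibrosis, MPD) that occur as separate
#'   strata in observed-vs-expected reporting.
#' @return data.frame with columns `label`, `icd10`, `lineage_group`,
#'   `is_cll`.
#' @export
#' @examples
#' diagnosis_table()
diagnosis_table <- function(aliases = FALSE) {
  core <- data.frame(
    label = c("CLL", "ALL", "other-leukemia", "MM", "MGUS", "HL", "DLBCL",
              "FL", "other-lymphoma", "AML", "CML", "other-MPD", "L-NOS",
              "MH"),
    icd10 = c("C91.1", "C91.0", "C94.7", "C90", "D47.2", "C81.1", "C83.3",
              "C82", "C85.7", "C92.0", "C92.1", "D47.1", "C95.9", "C96.1"),
    lineage_group = c(rep("LPD", 9L), rep("MPD", 3L), "OTHER", "OTHER"),
    stringsAsFactors = FALSE)
  if (aliases) {
    core <- rbind(core, data.frame(
      label = c("NHL-NOS", "MF"),
      icd10 = c("C85.9", "D47.4"),
      lineage_group = c("LPD", "MPD"),
      stringsAsFactors = FALSE))
  }
  core$is_cll <- core$label == "CLL"
  core
}

#' Map ICD-10 codes to diagnosis labels
#'
#' Classifies ICD-10 codes of hematologic malignancies into the package's
#' label vocabulary (see [diagnosis_table()]). Codes not covered by the
#' built-in rules can be supplied through `mapping`; any code that still
#' fails to classify yields `NA` with a warning (its lineage group is then
#' `OTHER`).
#'
#' @param code character vector of ICD-10 codes (e.g. `"C91.1"`).
#' @param mapping optional data.frame with columns `icd10`, `label` consulted
#'   before the built-in rules; this is how site-specific codes are grouped.
#' @return character vector of labels (possibly `NA`).
#' @export
#' @examples
#' classify_icd10(c("C91.1", "C90.0", "C92.5"))
classify_icd10 <- function(code, mapping = NULL) {
  rule <- function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    if (!is.null(mapping)) {
      hit <- match(x, mapping$icd10)
      if (!is.na(hit)) return(mapping$label[hit])
    }
    if (x == "C91.1") return("CLL")
    if (x == "C91.0") return("ALL")
    if (x == "C90" || startsWith(x, "C90.")) return("MM")
    if (x == "D47.2") return("MGUS")
    if (x == "C81" || startsWith(x, "C81.")) return("HL")
    if (x == "C83.3") return("DLBCL")
    if (x == "C82" || startsWith(x, "C82.")) return("FL")
    if (x == "C85.9") return("NHL-NOS")
    if (startsWith(x, "C83") || startsWith(x, "C84") || startsWith(x, "C85"))
      return("other-lymphoma")
    if (x == "C92.1") return("CML")
    if (x == "C92" || startsWith(x, "C92.")) return("AML")
    if (x == "C95.9") return("L-NOS")
    if (startsWith(x, "C91") || startsWith(x, "C93") ||
        startsWith(x, "C94") || startsWith(x, "C95"))
      return("other-leukemia")
    if (startsWith(x, "C96")) return("MH")
    if (x == "D47.4") return("MF")
    if (startsWith(x, "D45") || startsWith(x, "D46") || startsWith(x, "D47"))
      return("other-MPD")
    NA_character_
  }
  out <- vapply(toupper(trimws(as.character(code))), rule, character(1),
                USE.NAMES = FALSE)
  bad <- !is.na(code) & nzchar(trimws(as.character(code))) & is.na(out)
  if (any(bad)) {
    warning(sprintf("unrecognised ICD-10 code(s): %s; label set to NA (group OTHER)",
                    paste(unique(code[bad]), collapse = ", ")),
            call. = FALSE)
  }
  out
}

#' Lineage group of a diagnosis label
#'
#' @param label character vector of diagnosis labels.
#' @return character vector: `"LPD"`, `"MPD"` or `"OTHER"`.
#' @export
diagnosis_group <- function(label) {
  tab <- diagnosis_table(aliases = TRUE)
  grp <- tab$lineage_group[match(label, tab$label)]
  grp[is.na(grp)] <- "OTHER"
  grp
}

# Representative ICD-10 code for a label (inverse lookup; used by the
# simulator when it assigns diagnoses from a mixture of labels).
icd10_for_label <- function(label) {
  tab <- diagnosis_table(aliases = TRUE)
  tab$icd10[match(label, tab$label)]
}
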