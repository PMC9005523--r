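# Pedigree file I/O.
#
# Two formats:
#  * CSV dialect: UTF-8, comma separated, header row with the exact columns
#    id,father_id,mother_id,sex,birth_order,birth_year,affected,icd10,onset_age
#    (empty cell = missing). An optional `uncertain` column flags members
#    whose position in the family tree is unreliable; they are excluded at
#    read time and references to them are severed.
#  * Standard 6-column PED (FID IID PAT MAT SEX PHENO; SEX 1=male 2=female;
#    PHENO 2=affected, 1=unaffected, 0/-9=missing -> treated as unaffected,
#    with a message) plus a CSV sidecar keyed by id carrying what PED's
#    single phenotype column cannot: icd10, onset_age, birth_order,
#    birth_year. PED is supported for interoperability; the CSV dialect is
#    the lossless native format.

#' Read a pedigree from disk
#'
#' @param path path to the pedigree file.
#' @param format `"csv"` or `"ped"`.
#' @param sidecar path to the phenotype sidecar CSV (required for
#'   `format = "ped"`); defaults to `<path>.info.csv`.
#' @param family_id kindred identifier; defaults to the file name (CSV) or
#'   the PED family id.
#' @param kindred_mode `"nuclear"` or `"endemic"`.
#' @param mapping optional ICD-10 mapping table (see [classify_icd10()]).
#' @return a validated [pedigree()].
#' @export
read_pedigree <- function(path, format = c("csv", "ped"), sidecar = NULL,
                          family_id = NULL,
                          kindred_mode = c("nuclear", "endemic"),
                          mapping = NULL) {
  format <- match.arg(format)
  kindred_mode <- match.arg(kindred_mode)
  if (!file.exists(path))
    abort_mbd(paste0("file not found: ", path), class = "mbd_io_error")
  if (format == "csv") {
    m <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), stringsAsFactors = FALSE)
    need <- c("id", "father_id", "mother_id", "sex", "affected")
    miss <- setdiff(need, names(m))
    if (length(miss))
      abort_mbd(paste0("pedigree CSV lacks column(s): ",
                       paste(miss, collapse = ", ")))
    if ("uncertain" %in% names(m)) {
      drop <- !is.na(m$uncertain) &
        tolower(m$uncertain) %in% c("true", "t", "1", "yes")
      if (any(drop)) {
        dropped <- m$id[drop]
        message(sprintf("excluding %d member(s) with uncertain pedigree position: %s",
                        length(dropped), paste(dropped, collapse = ", ")))
        m <- m[!drop, , drop = FALSE]
        m$father_id[m$father_id %in% dropped] <- NA
        m$mother_id[m$mother_id %in% dropped] <- NA
      }
      m$uncertain <- NULL
    }
    fam <- family_id %||% sub("\\.[^.]*$", "", basename(path))
    return(pedigree(m, family_id = fam, kindred_mode = kindred_mode,
                    mapping = mapping))
  }

  # PED + sidecar
  sidecar <- sidecar %||% paste0(path, ".info.csv")
  if (!file.exists(sidecar))
    abort_mbd(paste0("PED phenotype sidecar not found: ", sidecar),
              class = "mbd_io_error")
  ped6 <- utils::read.table(path, header = FALSE, colClasses = "character",
                            col.names = c("fid", "iid", "pat", "mat",
                                          "sex", "pheno"))
  fids <- unique(ped6$fid)
  if (length(fids) != 1L)
    abort_mbd("PED file must contain a single family id per pedigree",
              class = "mbd_io_error")
  if (any(ped6$pheno %in% c("0", "-9")))
    message("PED phenotype 0/-9 (missing) treated as unaffected")
  info <- utils::read.csv(sidecar, colClasses = "character",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (!"id" %in% names(info))
    abort_mbd("sidecar must have an 'id' column", class = "mbd_io_error")
  m <- data.frame(id = ped6$iid,
                  father_id = ped6$pat, mother_id = ped6$mat,
                  sex = ped6$sex,
                  affected = ped6$pheno == "2",
                  stringsAsFactors = FALSE)
  for (col in c("icd10", "onset_age", "birth_order", "birth_year")) {
    m[[col]] <- if (col %in% names(info)) info[[col]][match(m$id, info$id)] else NA
  }
  pedigree(m, family_id = family_id %||% fids, kindred_mode = kindred_mode,
           mapping = mapping)
}

#' Write a pedigree to disk
#'
#' `read_pedigree(write_pedigree(p))` reproduces `p` field for field (for
#' PED, via the sidecar).
#'
#' @param ped an `mbd_pedigree`.
#' @param path output path.
#' @param format `"csv"` or `"ped"`.
#' @param sidecar sidecar path for `format = "ped"`; defaults to
#'   `<path>.info.csv`.
#' @return invisibly, `path`.
#' @export
write_pedigree <- function(ped, path, format = c("csv", "ped"),
                           sidecar = NULL) {
  format <- match.arg(format)
  validate_pedigree(ped)
  m <- ped$members
  dir <- dirname(path)
  if (!dir.exists(dir))
    abort_mbd(paste0("directory does not exist: ", dir),
              class = "mbd_io_error")
  if (format == "csv") {
    out <- m[, MEMBER_COLUMNS, drop = FALSE]
    out$affected <- ifelse(out$affected, "TRUE", "FALSE")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(path))
  }
  sidecar <- sidecar %||% paste0(path, ".info.csv")
  ped6 <- data.frame(fid = ped$family_id,
                     iid = m$id,
                     pat = ifelse(is.na(m$father_id), "0", m$father_id),
                     mat = ifelse(is.na(m$mother_id), "0", m$mother_id),
                     sex = ifelse(m$sex == "male", "1", "2"),
                     pheno = ifelse(m$affected, "2", "1"))
  utils::write.table(ped6, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  info <- m[, c("id", "icd10", "onset_age", "birth_order", "birth_year")]
  utils::write.csv(info, sidecar, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
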