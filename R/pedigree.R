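#' Read trio pedigrees from a 6-column PED file
#'
#' Parses a standard PED file (family, individual, father, mother, sex,
#' phenotype; whitespace separated, gzip transparent) and returns one
#' [TrioPedigree-class] per family whose affected child (phenotype code 2)
#' has both parents listed in the file. Sex codes are mapped 1 to male and
#' 2 to female; 0/unknown is an error because the X-linked model needs the
#' proband sex.
#'
#' @param path path to the PED file.
#' @return list of [TrioPedigree-class], in file order.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("FAM1 F1 0 0 1 1", "FAM1 M1 0 0 2 1", "FAM1 P1 F1 M1 1 2"), ped)
#' readPedigree(ped)
#' @export
readPedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#",
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "phenotype"))
  tab[] <- lapply(tab, as.character)
  kids <- tab[tab$phenotype == "2", , drop = FALSE]
  if (nrow(kids) == 0)
    stop("no affected individual (phenotype 2) found in PED file")
  out <- list()
  for (i in seq_len(nrow(kids))) {
    k <- kids[i, ]
    if (k$father == "0" || k$mother == "0")
      stop(sprintf("incomplete trio in family %s: affected child %s is missing a parent id",
                   k$family, k$individual))
    if (!k$father %in% tab$individual || !k$mother %in% tab$individual)
      stop(sprintf("incomplete trio in family %s: parent of %s not present among PED samples",
                   k$family, k$individual))
    sex <- switch(k$sex, "1" = "male", "2" = "female",
                  stop(sprintf("family %s: sex code '%s' for proband %s; the X-linked model requires male (1) or female (2)",
                               k$family, k$sex, k$individual)))
    out[[length(out) + 1L]] <- TrioPedigree(k$family, k$individual,
                                            k$father, k$mother, sex)
  }
  out
}

#' Write a cohort PED file
#'
#' Inverse of [readPedigree()]: one affected child plus two unaffected
#' parents per family.
#'
#' @param pedigrees list of [TrioPedigree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(pedigrees, path) {
  rows <- lapply(pedigrees, function(p) {
    sex <- if (p@probandSex == "male") "1" else "2"
    c(paste(p@familyId, p@fatherId, "0", "0", "1", "1"),
      paste(p@familyId, p@motherId, "0", "0", "2", "1"),
      paste(p@familyId, p@probandId, p@fatherId, p@motherId, sex, "2"))
  })
  lines <- unlist(rows)
  writeLines(if (is.null(lines)) character(0) else lines, path)
  invisible(path)
}
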