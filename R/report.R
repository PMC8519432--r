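# Cohort-level reporting: diagnostic yield, phenotype-matrix summaries and
# the candidate table renderer.

#' Diagnostic yield of a classified cohort
#'
#' A proband counts as diagnosed when it carries at least one candidate
#' classified pathogenic or likely pathogenic. The yield percentage is
#' truncated (not rounded) to one decimal: 11 of 14 gives 78.5, although
#' 11/14 = 78.57...%.
#'
#' @param candidates data.frame with columns `probandId` and
#'   `classification` (e.g. from [classifyCandidates()]).
#' @param cohort list of [TrioPedigree-class], or a character vector of
#'   proband ids, defining the denominator.
#' @return list of class `"CohortSummary"`: `nProbands`, `nDiagnosed`,
#'   `yieldPercent`, `perModelCounts`, `perGeneCounts`.
#' @examples
#' cands <- data.frame(probandId = c("P1", "P2"),
#'                     classification = c("pathogenic", "uncertain_significance"),
#'                     model = c("de_novo", "de_novo"), gene = c("G1", "G2"))
#' computeDiagnosticYield(cands, paste0("P", 1:4))
#' @export
computeDiagnosticYield <- function(candidates, cohort) {
  probands <- if (is.list(cohort)) vapply(cohort, probandId, character(1))
              else as.character(cohort)
  probands <- unique(probands)
  if (length(probands) == 0) stop("empty cohort")
  plp <- candidates$classification %in% c("pathogenic", "likely_pathogenic")
  diagnosed <- unique(candidates$probandId[plp])
  diagnosed <- intersect(diagnosed, probands)
  nD <- length(diagnosed); nP <- length(probands)
  yield <- floor(1000 * nD / nP) / 10
  perModel <- if (!is.null(candidates$model))
    table(candidates$model[plp & candidates$probandId %in% probands])
  else table(character(0))
  perGene <- if (!is.null(candidates$gene))
    table(candidates$gene[plp & candidates$probandId %in% probands])
  else table(character(0))
  structure(list(nProbands = nP, nDiagnosed = nD, yieldPercent = yield,
                 perModelCounts = perModel, perGeneCounts = perGene),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("CohortSummary: %d/%d probands diagnosed (yield %.1f%%)\n",
              x$nDiagnosed, x$nProbands, x$yieldPercent))
  if (length(x$perModelCounts)) {
    cat("per model:",
        paste(names(x$perModelCounts), x$perModelCounts, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a phenotype matrix
#'
#' TSV with a `patient` column and one column per clinical feature; cells
#' hold raw strings where a leading `+` means present (qualifiers such as
#' `"+ (Relative)"` are preserved and still count as present), `-` means
#' absent, and `NA`/empty means not available.
#'
#' @param path TSV path.
#' @return data.frame with `patient` as character.
#' @export
readPhenotypeMatrix <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = "character")
  if (!"patient" %in% names(pm)) stop("phenotype matrix needs a 'patient' column")
  pm
}

#' Per-feature phenotype counts
#'
#' For each requested feature column, counts patients in whom the feature
#' is present (cell starts with `+`; qualifiers count as present), absent
#' (`-`), or not available (`NA`). Not-available cells are excluded from
#' the denominator and reported separately.
#'
#' @param matrix data.frame from [readPhenotypeMatrix()].
#' @param features character vector of feature column names; default: all
#'   columns except `patient` and obvious metadata columns.
#' @return data.frame with columns `feature`, `present`, `absent`,
#'   `notAvailable`, `denominator`.
#' @export
summarizePhenotypes <- function(matrix,
                                features = setdiff(names(matrix),
                                                   c("patient", "gender",
                                                     "age_years"))) {
  if (nrow(matrix) == 0 || length(features) == 0)
    return(data.frame(feature = character(), present = integer(),
                      absent = integer(), notAvailable = integer(),
                      denominator = integer(), stringsAsFactors = FALSE))
  rows <- lapply(features, function(f) {
    v <- matrix[[f]]
    pres <- !is.na(v) & startsWith(trimws(v), "+")
    abs_ <- !is.na(v) & startsWith(trimws(v), "-")
    na_ <- is.na(v) | (!pres & !abs_)
    data.frame(feature = f, present = sum(pres), absent = sum(abs_),
               notAvailable = sum(na_), denominator = sum(pres) + sum(abs_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Render a candidate table as TSV
#'
#' Deterministic column order (patient, gene, transcript, c., p., variant
#' type, inheritance, classification), stable sort by patient then model
#' priority (de novo before X-linked before autosomal recessive), then
#' consequence severity.
#'
#' @param candidates classified candidate data.frame (needs `probandId`,
#'   `gene`, `transcriptId`, `cdnaChange`, `proteinChange`, `consequence`,
#'   `model`, `classification`).
#' @param path optional output TSV path; when `NULL` the table is only
#'   returned.
#' @return the rendered data.frame (invisibly when `path` is given).
#' @export
renderCandidateTable <- function(candidates, path = NULL) {
  typeLabel <- c(nonsense = "Nonsense", frameshift = "Frameshift",
                 missense = "Missense", in_frame = "In-frame",
                 splice_site = "Splice site", synonymous = "Synonymous",
                 unknown = "Unknown")
  modelLabel <- c(de_novo = "De novo", x_linked = "X-linked",
                  ar_homozygous = "Autosomal recessive",
                  ar_compound_het = "Autosomal recessive (compound het)")
  modelRank <- c(de_novo = 1L, x_linked = 2L, ar_homozygous = 3L,
                 ar_compound_het = 3L)
  out <- data.frame(
    patient = candidates$probandId,
    gene = candidates$gene,
    transcript = candidates$transcriptId,
    nucleotide_change = candidates$cdnaChange,
    amino_acid_change = candidates$proteinChange,
    variant_type = unname(typeLabel[candidates$consequence]),
    inheritance = unname(modelLabel[candidates$model]),
    classification = candidates$classification,
    stringsAsFactors = FALSE)
  sev <- .severityRank(candidates$consequence, candidates$predictorDeleterious)
  o <- order(out$patient, modelRank[candidates$model], sev, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

## ------------------------------------------------------------------ ##
##  Packaged cohort fixtures                                          ##
## ------------------------------------------------------------------ ##

#' Packaged diagnostic-variant table fixture
#'
#' The packaged table of eleven confirmed diagnostic variants (patients
#' with a molecular diagnosis in a 14-proband cohort), with their genes,
#' transcripts, c./p. descriptions, variant types, inheritance patterns
#' and confirmed classifications. Returned both in its raw printed form
#' and mapped onto the package's candidate-table conventions.
#'
#' @return data.frame with raw columns plus `probandId`, `consequence`,
#'   `model`, `populationAf`, `predictorDeleterious`, `classification`.
#' @export
loadTable1Candidates <- function() {
  path <- system.file("extdata", "table1_variants.tsv", package = "TrioExome",
                      mustWork = TRUE)
  t1 <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  consMap <- c("Nonsense" = "nonsense", "Frameshift" = "frameshift",
               "Missense" = "missense", "In-frame" = "in_frame",
               "Splice site" = "splice_site")
  modelMap <- c("De novo" = "de_novo", "X-linked" = "x_linked")
  clsMap <- c("Pathogenic" = "pathogenic",
              "Likely pathogenic" = "likely_pathogenic")
  t1$probandId <- paste0("patient_", t1$patient)
  t1$consequence <- unname(consMap[t1$variant_type])
  t1$model <- unname(modelMap[t1$inheritance])
  t1$populationAf <- 0          # all absent from the population database
  # predictor consensus applies to missense/in-frame variants
  t1$predictorDeleterious <- ifelse(t1$consequence %in% c("missense", "in_frame"),
                                    TRUE, NA)
  t1$classification <- unname(clsMap[t1$acmg_classification])
  t1$proteinChange <- t1$amino_acid_change
  t1$transcriptId <- t1$transcript
  t1$cdnaChange <- t1$nucleotide_change
  t1
}

#' Packaged phenotype-matrix fixture
#'
#' The packaged 14-patient clinical re-evaluation matrix (consistent,
#' frequent and associated feature groups), with raw cell strings
#' preserved (qualifiers such as `"+ (Relative)"` and word-count notes).
#'
#' @return data.frame as from [readPhenotypeMatrix()].
#' @export
loadTable2Phenotypes <- function() {
  readPhenotypeMatrix(system.file("extdata", "table2_phenotypes.tsv",
                                  package = "TrioExome", mustWork = TRUE))
}

#' Packaged gene-constraint fixture
#'
#' Per-gene LoF-intolerance flags and previously established pathogenic
#' protein changes for the genes of the packaged diagnostic-variant table.
#'
#' @return data.frame as from [readGeneConstraints()].
#' @export
loadGeneConstraints <- function() {
  readGeneConstraints(system.file("extdata", "gene_constraints.tsv",
                                  package = "TrioExome", mustWork = TRUE))
}
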