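# Reduced ACMG/AMP classification: the minimal evidence-code subset needed
# for trio-prioritized candidates (PVS1, PS1, PS2, PM2, PM4, PP3) plus the
# published combining rules restricted to those codes. Benign-side codes
# and the remaining pathogenic codes are deliberately out of scope.

.ACMG_CODES <- c("PVS1", "PS1", "PS2", "PM2", "PM4", "PP3")

#' Read a gene-constraint table
#'
#' TSV with columns `gene`, `lof_intolerant` (TRUE/FALSE: whether the
#' null-variant argument applies to loss-of-function variants in this
#' gene) and `known_pathogenic_changes` (comma-separated protein changes
#' previously established as pathogenic, e.g. `p.Arg230Cys`; empty when
#' none). An optional `transcript_id` column records the transcript the
#' changes refer to.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readGeneConstraints <- function(path) {
  gc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", fill = TRUE,
                          na.strings = c("NA", ""))
  if (!all(c("gene", "lof_intolerant") %in% names(gc)))
    stop("gene constraint table needs columns gene, lof_intolerant")
  gc$lof_intolerant <- as.logical(gc$lof_intolerant)
  if (is.null(gc$known_pathogenic_changes)) gc$known_pathogenic_changes <- NA_character_
  gc
}

#' Assign the reduced ACMG/AMP evidence set to a candidate
#'
#' Code semantics as implemented here:
#' * `PVS1` -- null variant (nonsense, frameshift or canonical splice
#'   site) in a gene flagged LoF-intolerant;
#' * `PS1` -- the identical protein change was previously established as
#'   pathogenic; applied only when the protein change is directly observed
#'   (not to splice-site variants, whose p. description is a prediction of
#'   transcript effect);
#' * `PS2` -- trio-confirmed de novo (candidate model `de_novo`);
#' * `PM2` -- absent from the population database (allele frequency 0);
#' * `PM4` -- protein length change from an in-frame indel;
#' * `PP3` -- concordant deleterious in-silico predictions.
#'
#' @param consequence one of `nonsense`, `frameshift`, `splice_site`,
#'   `missense`, `in_frame`, `synonymous`, `unknown`.
#' @param model inheritance model label (`de_novo`, `x_linked`,
#'   `ar_homozygous`, `ar_compound_het`).
#' @param populationAf population allele frequency.
#' @param predictorDeleterious `TRUE`/`FALSE`/`NA`.
#' @param proteinChange HGVS-lite p. string or `NA`.
#' @param gene gene symbol.
#' @param constraints data.frame from [readGeneConstraints()], or `NULL`.
#' @return character vector of evidence codes (subset of
#'   `PVS1, PS1, PS2, PM2, PM4, PP3`).
#' @examples
#' assignEvidence("nonsense", "de_novo", 0, NA, "p.Arg621*", "SYNGAP1",
#'                data.frame(gene = "SYNGAP1", lof_intolerant = TRUE,
#'                           known_pathogenic_changes = NA))
#' @export
assignEvidence <- function(consequence, model, populationAf,
                           predictorDeleterious, proteinChange, gene,
                           constraints = NULL) {
  lofIntolerant <- FALSE
  knownChanges <- character(0)
  if (!is.null(constraints) && !is.na(gene)) {
    row <- constraints[constraints$gene == gene, , drop = FALSE]
    if (nrow(row)) {
      lofIntolerant <- isTRUE(row$lof_intolerant[1])
      kc <- row$known_pathogenic_changes[1]
      if (!is.na(kc) && nzchar(kc))
        knownChanges <- trimws(strsplit(kc, ",", fixed = TRUE)[[1]])
    }
  }
  ev <- character(0)
  if (consequence %in% c("nonsense", "frameshift", "splice_site") && lofIntolerant)
    ev <- c(ev, "PVS1")
  if (!is.na(proteinChange) && proteinChange %in% knownChanges &&
      consequence != "splice_site")
    ev <- c(ev, "PS1")
  if (model == "de_novo") ev <- c(ev, "PS2")
  if (!is.na(populationAf) && populationAf == 0) ev <- c(ev, "PM2")
  if (consequence == "in_frame") ev <- c(ev, "PM4")
  if (isTRUE(predictorDeleterious)) ev <- c(ev, "PP3")
  ev
}

#' Combine ACMG/AMP evidence codes into a classification
#'
#' Implements the published combining rules restricted to the code subset
#' used here (PVS1 very strong; PS1/PS2 strong; PM2/PM4 moderate; PP3
#' supporting):
#'
#' Pathogenic: PVS1 with at least one strong, or with at least two
#' moderate, or with one moderate plus one supporting, or with at least
#' two supporting; at least two strong; one strong with at least three
#' moderate, or with two moderate plus at least two supporting, or with
#' one moderate plus at least four supporting.
#'
#' Likely pathogenic: PVS1 with one moderate; one strong with one or two
#' moderate; one strong with at least two supporting; at least three
#' moderate; two moderate with at least two supporting; one moderate with
#' at least four supporting.
#'
#' Anything else: uncertain significance. Adding evidence can never
#' downgrade a classification (the rule set is monotone).
#'
#' @param evidence character vector of codes (subset of
#'   `PVS1, PS1, PS2, PM2, PM4, PP3`).
#' @return one of `"pathogenic"`, `"likely_pathogenic"`,
#'   `"uncertain_significance"`.
#' @examples
#' combineEvidence(c("PVS1", "PS2", "PM2"))  # pathogenic
#' combineEvidence(c("PS2", "PM2", "PP3"))   # likely_pathogenic
#' @export
combineEvidence <- function(evidence) {
  bad <- setdiff(evidence, .ACMG_CODES)
  if (length(bad))
    stop(sprintf("unsupported evidence code(s): %s (implemented subset: %s)",
                 paste(bad, collapse = ", "), paste(.ACMG_CODES, collapse = ", ")))
  vs <- "PVS1" %in% evidence
  ns <- sum(c("PS1", "PS2") %in% evidence)
  nm <- sum(c("PM2", "PM4") %in% evidence)
  np <- sum("PP3" %in% evidence)
  pathogenic <-
    (vs && (ns >= 1 || nm >= 2 || (nm == 1 && np >= 1) || np >= 2)) ||
    (ns >= 2) ||
    (ns == 1 && (nm >= 3 || (nm == 2 && np >= 2) || (nm == 1 && np >= 4)))
  if (pathogenic) return("pathogenic")
  likely <-
    (vs && nm == 1) ||
    (ns == 1 && nm >= 1 && nm <= 2) ||
    (ns == 1 && np >= 2) ||
    (nm >= 3) ||
    (nm == 2 && np >= 2) ||
    (nm == 1 && np >= 4)
  if (likely) return("likely_pathogenic")
  "uncertain_significance"
}

#' Classify a table of candidate variants
#'
#' Applies [assignEvidence()] and [combineEvidence()] to each row of a
#' candidate table (e.g. from [prioritizeTrio()]).
#'
#' @param candidates data.frame with columns `consequence`, `model`,
#'   `populationAf`, `predictorDeleterious`, `proteinChange`, `gene`.
#' @param constraints data.frame from [readGeneConstraints()], or `NULL`.
#' @return `candidates` with added columns `evidence` (comma-separated
#'   codes) and `classification`.
#' @export
classifyCandidates <- function(candidates, constraints = NULL) {
  n <- nrow(candidates)
  ev <- character(n); cls <- character(n)
  for (i in seq_len(n)) {
    e <- assignEvidence(candidates$consequence[i], candidates$model[i],
                        candidates$populationAf[i],
                        candidates$predictorDeleterious[i],
                        candidates$proteinChange[i], candidates$gene[i],
                        constraints)
    ev[i] <- paste(e, collapse = ",")
    cls[i] <- combineEvidence(e)
  }
  candidates$evidence <- ev
  candidates$classification <- cls
  candidates
}
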