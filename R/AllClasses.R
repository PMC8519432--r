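#' @import methods
NULL

## ------------------------------------------------------------------ ##
##  TrioPedigree                                                      ##
## ------------------------------------------------------------------ ##

#' Parent-offspring trio pedigree
#'
#' One affected proband and both parents. The proband sex is mandatory
#' because the X-linked inheritance model is sex-aware (hemizygous male
#' probands with carrier mothers).
#'
#' @slot familyId family identifier.
#' @slot probandId,fatherId,motherId sample identifiers; must be distinct.
#' @slot probandSex `"male"` or `"female"`.
#'
#' @examples
#' TrioPedigree("FAM1", "P1", "F1", "M1", "male")
#' @export
setClass("TrioPedigree",
  representation(
    familyId   = "character",
    probandId  = "character",
    fatherId   = "character",
    motherId   = "character",
    probandSex = "character"
  )
)

setValidity("TrioPedigree", function(object) {
  ids <- c(object@probandId, object@fatherId, object@motherId)
  if (anyDuplicated(ids))
    return("proband, father and mother ids must be distinct")
  if (!object@probandSex %in% c("male", "female"))
    return("probandSex must be 'male' or 'female' (required by the X-linked model)")
  TRUE
})

#' @param familyId,probandId,fatherId,motherId,probandSex see slots.
#' @rdname TrioPedigree-class
#' @export
TrioPedigree <- function(familyId, probandId, fatherId, motherId, probandSex) {
  new("TrioPedigree", familyId = as.character(familyId),
      probandId = as.character(probandId), fatherId = as.character(fatherId),
      motherId = as.character(motherId), probandSex = as.character(probandSex))
}

setMethod("show", "TrioPedigree", function(object) {
  cat("TrioPedigree", object@familyId, ": proband", object@probandId,
      paste0("(", object@probandSex, ")"),
      "father", object@fatherId, "mother", object@motherId, "\n")
})

#' Accessors for TrioPedigree
#' @param x a [TrioPedigree-class] object.
#' @return a character scalar.
#' @export
probandId <- function(x) x@probandId
#' @rdname probandId
#' @export
fatherId <- function(x) x@fatherId
#' @rdname probandId
#' @export
motherId <- function(x) x@motherId
#' @rdname probandId
#' @export
probandSex <- function(x) x@probandSex
#' @rdname probandId
#' @export
familyId <- function(x) x@familyId

## ------------------------------------------------------------------ ##
##  TrioCalls                                                         ##
## ------------------------------------------------------------------ ##

#' Normalized biallelic variant sites with per-sample genotype calls
#'
#' The central genotype container: one row per biallelic site (after
#' multiallelic splitting and parsimony trimming), with parallel matrices
#' of per-sample GT strings, per-allele read depths (AD), total depth (DP)
#' and Phred-scaled genotype quality (GQ). Missing FORMAT values are `NA`,
#' never fabricated zeros, so downstream filters that need read evidence
#' fail on its absence.
#'
#' @slot sites `data.frame` with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (exactly one alternate allele per row), `id`.
#' @slot gt character matrix (sites x samples) of VCF genotype strings.
#' @slot adRef,adAlt,dp,gq integer matrices (sites x samples).
#' @export
setClass("TrioCalls",
  representation(
    sites = "data.frame",
    gt    = "matrix",
    adRef = "matrix",
    adAlt = "matrix",
    dp    = "matrix",
    gq    = "matrix"
  )
)

setValidity("TrioCalls", function(object) {
  s <- object@sites
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(s)))
    return("sites must have columns chrom, pos, ref, alt")
  n <- nrow(s)
  for (nm in c("gt", "adRef", "adAlt", "dp", "gq")) {
    m <- slot(object, nm)
    if (nrow(m) != n) return(sprintf("slot '%s' has %d rows; expected %d", nm, nrow(m), n))
    if (!identical(colnames(m), colnames(object@gt)))
      return("all genotype matrices must share the same sample columns")
  }
  if (n > 0) {
    if (any(s$pos < 1)) return("pos must be >= 1")
    if (any(grepl(",", s$alt, fixed = TRUE)))
      return("alt must hold exactly one allele per row (split multiallelics first)")
    if (any(s$ref == s$alt)) return("ref and alt must differ")
    bad <- !is.na(object@adRef) & object@adRef < 0 |
           !is.na(object@adAlt) & object@adAlt < 0
    if (any(bad)) return("allele depths must be non-negative")
    if (any(!is.na(object@gq) & object@gq < 0)) return("GQ must be non-negative")
  }
  TRUE
})

#' @param sites,gt,adRef,adAlt,dp,gq see slots.
#' @rdname TrioCalls-class
#' @export
TrioCalls <- function(sites, gt, adRef, adAlt, dp, gq) {
  sites$chrom <- as.character(sites$chrom)
  sites$pos   <- as.integer(sites$pos)
  sites$ref   <- as.character(sites$ref)
  sites$alt   <- as.character(sites$alt)
  if (is.null(sites$id)) sites$id <- NA_character_
  rownames(sites) <- NULL
  toInt <- function(m) { storage.mode(m) <- "integer"; m }
  new("TrioCalls", sites = sites, gt = as.matrix(gt),
      adRef = toInt(as.matrix(adRef)), adAlt = toInt(as.matrix(adAlt)),
      dp = toInt(as.matrix(dp)), gq = toInt(as.matrix(gq)))
}

setMethod("show", "TrioCalls", function(object) {
  cat("TrioCalls with", nrow(object@sites), "sites x",
      ncol(object@gt), "samples\n")
  if (ncol(object@gt)) cat("samples:", paste(colnames(object@gt), collapse = ", "), "\n")
  if (nrow(object@sites)) {
    cat("first sites:\n")
    print(utils::head(object@sites, 3))
  }
})

#' Accessors for TrioCalls
#'
#' `variantSites()` returns the site table; `sampleNames()` the sample ids;
#' `genoField()` one of the genotype matrices (`"GT"`, `"AD_REF"`,
#' `"AD_ALT"`, `"DP"`, `"GQ"`); `nSites()` the number of sites.
#'
#' @param x a [TrioCalls-class] object.
#' @param field matrix name for `genoField`.
#' @export
variantSites <- function(x) x@sites
#' @rdname variantSites
#' @export
sampleNames <- function(x) colnames(x@gt)
#' @rdname variantSites
#' @export
nSites <- function(x) nrow(x@sites)
#' @rdname variantSites
#' @export
genoField <- function(x, field = c("GT", "AD_REF", "AD_ALT", "DP", "GQ")) {
  switch(match.arg(field),
         GT = x@gt, AD_REF = x@adRef, AD_ALT = x@adAlt, DP = x@dp, GQ = x@gq)
}

#' @export
setMethod("[", "TrioCalls", function(x, i, j, ..., drop = FALSE) {
  TrioCalls(x@sites[i, , drop = FALSE],
            x@gt[i, , drop = FALSE], x@adRef[i, , drop = FALSE],
            x@adAlt[i, , drop = FALSE], x@dp[i, , drop = FALSE],
            x@gq[i, , drop = FALSE])
})

## ------------------------------------------------------------------ ##
##  FilterThresholds                                                  ##
## ------------------------------------------------------------------ ##

#' Inheritance-model filter thresholds
#'
#' Defaults implement the trio filtering rules used throughout the package:
#' genotype quality at least 20 in all trio members; read depth at least 5
#' in each parent and 10 in the proband; a de novo call requires the
#' alternate allele in strictly more than 10% of the proband's reads;
#' autosomal-recessive candidates require population allele frequency
#' strictly below 0.02; X-linked candidates strictly below 0.001.
#'
#' @slot minGqTrio Phred GQ required in all three members (default 20).
#' @slot minDpParent minimum parental depth (default 5).
#' @slot minDpProband minimum proband depth (default 10).
#' @slot minAltFractionDeNovo proband allele-fraction bound, strict `>`
#'   (default 0.10).
#' @slot maxAfRecessive population AF bound for the recessive model,
#'   strict `<` (default 0.02).
#' @slot maxAfXlinked population AF bound for the X-linked model, strict
#'   `<` (default 0.001).
#' @export
setClass("FilterThresholds",
  representation(
    minGqTrio            = "numeric",
    minDpParent          = "numeric",
    minDpProband         = "numeric",
    minAltFractionDeNovo = "numeric",
    maxAfRecessive       = "numeric",
    maxAfXlinked         = "numeric"
  ),
  prototype(
    minGqTrio = 20, minDpParent = 5, minDpProband = 10,
    minAltFractionDeNovo = 0.10, maxAfRecessive = 0.02, maxAfXlinked = 0.001
  )
)

setValidity("FilterThresholds", function(object) {
  v <- c(object@minGqTrio, object@minDpParent, object@minDpProband,
         object@minAltFractionDeNovo, object@maxAfRecessive, object@maxAfXlinked)
  if (any(v < 0)) return("thresholds must be non-negative")
  f <- c(object@minAltFractionDeNovo, object@maxAfRecessive, object@maxAfXlinked)
  if (any(f > 1)) return("fraction thresholds must lie in [0, 1]")
  TRUE
})

#' @param minGqTrio,minDpParent,minDpProband,minAltFractionDeNovo,maxAfRecessive,maxAfXlinked
#'   see slots.
#' @rdname FilterThresholds-class
#' @export
filterThresholds <- function(minGqTrio = 20, minDpParent = 5, minDpProband = 10,
                             minAltFractionDeNovo = 0.10,
                             maxAfRecessive = 0.02, maxAfXlinked = 0.001) {
  new("FilterThresholds", minGqTrio = minGqTrio, minDpParent = minDpParent,
      minDpProband = minDpProband, minAltFractionDeNovo = minAltFractionDeNovo,
      maxAfRecessive = maxAfRecessive, maxAfXlinked = maxAfXlinked)
}

setMethod("show", "FilterThresholds", function(object) {
  cat("FilterThresholds: GQ>=", object@minGqTrio,
      " DP parents>=", object@minDpParent, " proband>=", object@minDpProband,
      " de novo alt fraction>", object@minAltFractionDeNovo,
      " AF(recessive)<", object@maxAfRecessive,
      " AF(X-linked)<", object@maxAfXlinked, "\n", sep = "")
})

## ------------------------------------------------------------------ ##
##  TranscriptModel                                                   ##
## ------------------------------------------------------------------ ##

#' Coding transcript model
#'
#' A gene's coding structure: ordered, non-overlapping CDS exons in
#' genomic coordinates plus the spliced CDS nucleotide sequence (coding
#' strand, beginning with ATG, length a multiple of 3, no internal stop;
#' the terminal stop codon is included).
#'
#' @slot gene gene symbol.
#' @slot txId transcript identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons integer matrix with columns `start`, `end` (1-based,
#'   inclusive, sorted by genomic position); these are CDS segments, so
#'   their total width equals `nchar(cds)`.
#' @slot cds CDS sequence as a character scalar.
#' @export
setClass("TranscriptModel",
  representation(
    gene   = "character",
    txId   = "character",
    chrom  = "character",
    strand = "character",
    exons  = "matrix",
    cds    = "character"
  )
)

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (ncol(ex) != 2) return("exons must be a 2-column (start, end) matrix")
  if (nrow(ex) == 0) return("at least one exon required")
  if (any(ex[, 2] < ex[, 1])) return("exon end < start")
  if (nrow(ex) > 1) {
    o <- order(ex[, 1])
    if (any(ex[o, 1][-1] <= ex[o, 2][-nrow(ex)]))
      return("exons must be non-overlapping")
  }
  n <- nchar(object@cds)
  if (n %% 3 != 0) return("CDS length must be a multiple of 3")
  if (substr(object@cds, 1, 3) != "ATG") return("CDS must begin with ATG")
  if (sum(ex[, 2] - ex[, 1] + 1) != n)
    return("sum of exon widths must equal CDS length")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  aa <- translateCds(object@cds)
  if (any(aa[-length(aa)] == "*")) return("CDS translation contains an internal stop")
  TRUE
})

#' @param gene,txId,chrom,strand,exons,cds see slots. `exons` may be given
#'   as a 2-column matrix or a data.frame with `start`/`end` columns.
#' @rdname TranscriptModel-class
#' @export
transcriptModel <- function(gene, txId, chrom, strand, exons, cds) {
  ex <- as.matrix(as.data.frame(exons)[, 1:2])
  colnames(ex) <- c("start", "end")
  storage.mode(ex) <- "integer"
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  new("TranscriptModel", gene = gene, txId = txId, chrom = chrom,
      strand = strand, exons = ex, cds = toupper(as.character(cds)))
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@txId, paste0("(", object@gene, ")"),
      object@chrom, object@strand, ":", nrow(object@exons), "CDS exon(s),",
      nchar(object@cds), "nt CDS\n")
})

#' Accessors for TranscriptModel
#' @param x a [TranscriptModel-class].
#' @export
txGene <- function(x) x@gene
#' @rdname txGene
#' @export
txId <- function(x) x@txId
#' @rdname txGene
#' @export
txChrom <- function(x) x@chrom
#' @rdname txGene
#' @export
txStrand <- function(x) x@strand
#' @rdname txGene
#' @export
txExons <- function(x) x@exons
#' @rdname txGene
#' @export
txCds <- function(x) x@cds
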