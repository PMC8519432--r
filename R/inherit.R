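# Inheritance-model filters: trio quality gate, de novo, X-linked and
# autosomal-recessive models, and the model-ordered prioritization that
# produces candidate variants per trio.

# consequence severity used for within-model ordering (lower = more severe)
.severityRank <- function(consequence, deleterious) {
  r <- rep(4L, length(consequence))
  r[consequence %in% c("nonsense", "frameshift", "splice_site")] <- 1L
  r[consequence == "missense" & !is.na(deleterious) & deleterious] <- 2L
  r[consequence == "in_frame"] <- 3L
  r
}

# "Predicted impact on the protein": protein-altering consequences; a
# missense counts only with a deleterious predictor consensus.
.isImpactful <- function(consequence, deleterious) {
  consequence %in% c("nonsense", "frameshift", "splice_site", "in_frame") |
    (consequence == "missense" & !is.na(deleterious) & deleterious)
}

.trioCols <- function(calls, ped) {
  sn <- sampleNames(calls)
  need <- c(ped@probandId, ped@fatherId, ped@motherId)
  miss <- setdiff(need, sn)
  if (length(miss))
    stop(sprintf("trio sample(s) %s not present in calls",
                 paste(miss, collapse = ", ")))
  match(need, sn)   # proband, father, mother column indices
}

#' Trio-wide genotype quality gate
#'
#' A site passes when all three trio members have a valid (non-missing)
#' genotype with GQ at or above the trio threshold, both parents have
#' depth at or above the parental minimum, and the proband depth is at or
#' above the proband minimum. Missing values fail (they are absence of
#' evidence, not evidence).
#'
#' @param calls a [TrioCalls-class].
#' @param ped a [TrioPedigree-class].
#' @param th a [FilterThresholds-class].
#' @return logical vector, one element per site.
#' @export
trioQualityPass <- function(calls, ped, th = filterThresholds()) {
  ix <- .trioCols(calls, ped)
  gq <- calls@gq[, ix, drop = FALSE]
  dp <- calls@dp[, ix, drop = FALSE]
  gtOk <- matrix(gtIsValid(calls@gt[, ix]), ncol = 3)
  pass <- gtOk[, 1] & gtOk[, 2] & gtOk[, 3] &
    !is.na(gq[, 1]) & gq[, 1] >= th@minGqTrio &
    !is.na(gq[, 2]) & gq[, 2] >= th@minGqTrio &
    !is.na(gq[, 3]) & gq[, 3] >= th@minGqTrio &
    !is.na(dp[, 1]) & dp[, 1] >= th@minDpProband &
    !is.na(dp[, 2]) & dp[, 2] >= th@minDpParent &
    !is.na(dp[, 3]) & dp[, 3] >= th@minDpParent
  pass & !is.na(pass)
}

#' De novo variant calls
#'
#' A site is called de novo when it passes [trioQualityPass()], the
#' proband is heterozygous while both parents are homozygous for the
#' reference allele, and the alternate allele is seen in strictly more
#' than the configured fraction of the proband's informative reads
#' (default: more than 10%). A missing allele fraction fails.
#'
#' @inheritParams trioQualityPass
#' @param qualityPass optional precomputed [trioQualityPass()] vector.
#' @return logical vector, one element per site.
#' @export
callDeNovo <- function(calls, ped, th = filterThresholds(), qualityPass = NULL) {
  ix <- .trioCols(calls, ped)
  if (is.null(qualityPass)) qualityPass <- trioQualityPass(calls, ped, th)
  gtP <- calls@gt[, ix[1]]; gtF <- calls@gt[, ix[2]]; gtM <- calls@gt[, ix[3]]
  af <- alleleFraction(calls@adRef[, ix[1]], calls@adAlt[, ix[1]])
  dn <- qualityPass & gtIsHet(gtP) & gtIsHomRef(gtF) & gtIsHomRef(gtM) &
    !is.na(af) & af > th@minAltFractionDeNovo
  dn & !is.na(dn)
}

#' X-linked recessive candidate calls
#'
#' The carrier-mother pattern on the X chromosome: a male proband
#' hemizygous (or reported homozygous) for the alternate allele, a
#' heterozygous mother and a reference-homozygous father, with population
#' allele frequency strictly below the X-linked threshold (default 0.001)
#' and a protein-impactful consequence. Female probands are not handled by
#' this model (a dominant de novo X variant is caught by the de novo
#' model). Sites off the X chromosome return `FALSE`.
#'
#' @inheritParams callDeNovo
#' @param ann annotation data.frame from [annotateVariants()], parallel to
#'   the sites in `calls`.
#' @return logical vector, one element per site.
#' @export
callXLinked <- function(calls, ann, ped, th = filterThresholds(),
                        qualityPass = NULL) {
  n <- nSites(calls)
  if (ped@probandSex != "male") return(rep(FALSE, n))
  ix <- .trioCols(calls, ped)
  if (is.null(qualityPass)) qualityPass <- trioQualityPass(calls, ped, th)
  onX <- isChrX(calls@sites$chrom)
  gtP <- calls@gt[, ix[1]]; gtF <- calls@gt[, ix[2]]; gtM <- calls@gt[, ix[3]]
  xl <- qualityPass & onX &
    gtIsAltOnly(gtP) &          # hemizygous "1" or "1/1" dialects
    gtIsHet(gtM) & gtIsHomRef(gtF) &
    ann$populationAf < th@maxAfXlinked &
    .isImpactful(ann$consequence, ann$predictorDeleterious)
  xl & !is.na(xl)
}

#' Autosomal-recessive candidates within one gene
#'
#' Two configurations qualify, each requiring every involved site to pass
#' the quality gate, have population allele frequency strictly below the
#' recessive threshold (default 0.02) and a protein-impactful consequence:
#'
#' * homozygous: proband homozygous alternate with both parents
#'   heterozygous (`ar_homozygous`);
#' * compound heterozygous: the proband heterozygous at two distinct
#'   sites, one transmitted exclusively by the father and one exclusively
#'   by the mother (trans configuration by transmission phasing;
#'   `ar_compound_het`). Two proband-het sites carried by the same parent
#'   are in cis and do not qualify.
#'
#' @param calls a [TrioCalls-class] restricted (by `idx`) to one gene's
#'   sites on an autosome.
#' @param ann annotation data.frame parallel to `calls` sites.
#' @param ped a [TrioPedigree-class].
#' @param th a [FilterThresholds-class].
#' @param idx integer indices of the gene's sites within `calls`.
#' @param qualityPass optional precomputed quality vector (full length).
#' @return data.frame of candidates with columns `siteIdx`, `model`,
#'   `partnerIdx` (NA for homozygous candidates).
#' @export
callAutosomalRecessive <- function(calls, ann, ped, th = filterThresholds(),
                                   idx = seq_len(nSites(calls)),
                                   qualityPass = NULL) {
  ix <- .trioCols(calls, ped)
  if (is.null(qualityPass)) qualityPass <- trioQualityPass(calls, ped, th)
  out <- data.frame(siteIdx = integer(), model = character(),
                    partnerIdx = integer(), stringsAsFactors = FALSE)
  idx <- idx[qualityPass[idx] & !isChrX(calls@sites$chrom[idx]) &
             ann$populationAf[idx] < th@maxAfRecessive &
             .isImpactful(ann$consequence[idx], ann$predictorDeleterious[idx])]
  if (!length(idx)) return(out)
  gtP <- calls@gt[idx, ix[1]]; gtF <- calls@gt[idx, ix[2]]; gtM <- calls@gt[idx, ix[3]]
  # homozygous-recessive: proband 1/1, both parents carriers (het)
  hom <- gtIsAltOnly(gtP) & gtPloidy(gtP) == 2L & gtIsHet(gtF) & gtIsHet(gtM)
  if (any(hom))
    out <- rbind(out, data.frame(siteIdx = idx[hom], model = "ar_homozygous",
                                 partnerIdx = NA_integer_,
                                 stringsAsFactors = FALSE))
  # compound het by transmission: paternal-only x maternal-only
  het <- gtIsHet(gtP)
  pat <- het & gtAltCount(gtF) >= 1L & gtIsHomRef(gtM)
  mat <- het & gtAltCount(gtM) >= 1L & gtIsHomRef(gtF)
  pat[is.na(pat)] <- FALSE; mat[is.na(mat)] <- FALSE
  if (any(pat) && any(mat)) {
    pairs <- expand.grid(p = idx[pat], m = idx[mat])
    out <- rbind(out, data.frame(siteIdx = pairs$p, model = "ar_compound_het",
                                 partnerIdx = pairs$m, stringsAsFactors = FALSE))
  }
  out
}

#' Prioritize candidate variants for one trio
#'
#' Runs the inheritance models in fixed order -- de novo first, then
#' X-linked, then autosomal recessive -- over annotated, normalized sites.
#' A site is assigned to the first model it matches. Within a model group,
#' candidates are ordered by consequence severity (nonsense / frameshift /
#' splice site before deleterious missense before in-frame) and then by
#' ascending population allele frequency.
#'
#' @param calls a [TrioCalls-class] for the trio.
#' @param ann annotation data.frame from [annotateVariants()], parallel to
#'   the sites in `calls`.
#' @param ped a [TrioPedigree-class].
#' @param th a [FilterThresholds-class].
#' @return data.frame of candidates: `probandId`, `chrom`, `pos`, `ref`,
#'   `alt`, `gene`, `transcriptId`, `cdnaChange`, `proteinChange`,
#'   `consequence`, `model`, `populationAf`, `predictorDeleterious`,
#'   `partnerKey` (the paired site of a compound-het candidate, else NA).
#' @export
prioritizeTrio <- function(calls, ann, ped, th = filterThresholds()) {
  stopifnot(nrow(ann) == nSites(calls))
  qp <- trioQualityPass(calls, ped, th)
  s <- calls@sites
  key <- siteKey(s$chrom, s$pos, s$ref, s$alt)

  dn <- which(callDeNovo(calls, ped, th, qualityPass = qp))
  xl <- which(callXLinked(calls, ann, ped, th, qualityPass = qp))
  xl <- setdiff(xl, dn)
  taken <- c(dn, xl)

  arRows <- data.frame(siteIdx = integer(), model = character(),
                       partnerIdx = integer(), stringsAsFactors = FALSE)
  candGene <- !is.na(ann$gene) & qp & !isChrX(s$chrom) &
    ann$populationAf < th@maxAfRecessive &
    .isImpactful(ann$consequence, ann$predictorDeleterious)
  for (g in unique(ann$gene[candGene])) {
    idx <- setdiff(which(candGene & ann$gene == g), taken)
    if (length(idx) == 0) next
    arRows <- rbind(arRows,
                    callAutosomalRecessive(calls, ann, ped, th, idx = idx,
                                           qualityPass = qp))
  }

  build <- function(idx, model, partnerIdx = rep(NA_integer_, length(idx))) {
    if (!length(idx)) return(NULL)
    data.frame(probandId = ped@probandId,
               chrom = s$chrom[idx], pos = s$pos[idx], ref = s$ref[idx],
               alt = s$alt[idx], gene = ann$gene[idx],
               transcriptId = ann$transcriptId[idx],
               cdnaChange = ann$cdnaChange[idx],
               proteinChange = ann$proteinChange[idx],
               consequence = ann$consequence[idx], model = model,
               populationAf = ann$populationAf[idx],
               predictorDeleterious = ann$predictorDeleterious[idx],
               partnerKey = ifelse(is.na(partnerIdx), NA_character_,
                                   key[partnerIdx]),
               stringsAsFactors = FALSE)
  }
  orderGroup <- function(df) {
    if (is.null(df)) return(NULL)
    r <- .severityRank(df$consequence, df$predictorDeleterious)
    df[order(r, df$populationAf, df$chrom, df$pos), , drop = FALSE]
  }
  out <- rbind(
    orderGroup(build(dn, "de_novo")),
    orderGroup(build(xl, "x_linked")),
    orderGroup(build(arRows$siteIdx,
                     arRows$model,
                     arRows$partnerIdx)))
  if (is.null(out))
    out <- build(integer(0), character(0))
  if (is.null(out))   # still NULL: produce an empty typed frame
    out <- data.frame(probandId = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), transcriptId = character(),
                      cdnaChange = character(), proteinChange = character(),
                      consequence = character(), model = character(),
                      populationAf = numeric(), predictorDeleterious = logical(),
                      partnerKey = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
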