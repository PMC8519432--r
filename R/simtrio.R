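# Synthetic trio-exome simulator. Generates multi-sample VCFs with the
# statistical structure the prioritization pipeline assumes: a background
# panel of exonic variants calibrated so the expected per-individual
# variant-class counts match the configured averages, Hardy-Weinberg
# founder genotypes, Mendelian transmission to the proband, Poisson read
# depths, binomial allele depths, a likelihood-ratio GQ model, optional
# genotyping error, and spiked causal variants with a ground-truth table.

#' Simulator configuration
#'
#' Defaults encode the study conditions the simulator emulates: on average
#' 21,170 exonic variants per individual, of which 9,570 missense, 351
#' loss-of-function, 237 non-frameshift (in-frame) and 10,606 synonymous
#' (the remainder, about 406, unclassifiable); mean site depth 67x.
#' Population allele frequencies are drawn from a Beta distribution
#' (default Beta(0.8, 0.8), a computationally compact stand-in for an
#' exome site-frequency spectrum; see the vignette).
#'
#' @slot nTrios number of families.
#' @slot meanExonicPerIndividual expected exonic variants per individual.
#' @slot classMix named expected per-individual counts for `missense`,
#'   `lof`, `non_frameshift`, `synonymous`; the remainder up to
#'   `meanExonicPerIndividual` is emitted as unclassifiable (`unknown`).
#' @slot meanDepth expected sequencing depth (x coverage).
#' @slot genotypingErrorRate per-genotype miscall probability; also used
#'   as the read-level noise rate (default 0, a clean surrogate for the
#'   upstream caller's output).
#' @slot afAlpha,afBeta Beta parameters of the background AF distribution.
#' @slot spikePlan data.frame with columns `trio`, `model`
#'   (`de_novo`, `x_linked`, `ar_homozygous`, `ar_compound_het`) and
#'   `consequence`; default: one de novo coding missense per trio.
#' @slot seed integer seed; the whole cohort is reproducible from it.
#' @export
setClass("SimConfig",
  representation(
    nTrios = "numeric",
    meanExonicPerIndividual = "numeric",
    classMix = "numeric",
    meanDepth = "numeric",
    genotypingErrorRate = "numeric",
    afAlpha = "numeric",
    afBeta = "numeric",
    spikePlan = "data.frame",
    seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  cm <- object@classMix
  need <- c("missense", "lof", "non_frameshift", "synonymous")
  if (!all(need %in% names(cm)))
    return("classMix needs components missense, lof, non_frameshift, synonymous")
  if (sum(cm[need]) > object@meanExonicPerIndividual)
    return("classMix components must sum to at most meanExonicPerIndividual")
  if (object@genotypingErrorRate < 0 || object@genotypingErrorRate > 1)
    return("genotypingErrorRate must lie in [0, 1]")
  if (object@meanDepth <= 0) return("meanDepth must be positive")
  if (nrow(object@spikePlan)) {
    if (!all(c("trio", "model", "consequence") %in% names(object@spikePlan)))
      return("spikePlan needs columns trio, model, consequence")
    if (any(!object@spikePlan$model %in%
            c("de_novo", "x_linked", "ar_homozygous", "ar_compound_het")))
      return("unknown spikePlan model")
  }
  TRUE
})

#' @param nTrios,meanExonicPerIndividual,classMix,meanDepth,genotypingErrorRate,afAlpha,afBeta,spikePlan,seed
#'   see slots; `spikePlan = NULL` installs the default one-de-novo-per-trio
#'   plan, `spikePlan = "none"` disables spiking.
#' @rdname SimConfig-class
#' @export
simConfig <- function(nTrios = 1,
                      meanExonicPerIndividual = 21170,
                      classMix = c(missense = 9570, lof = 351,
                                   non_frameshift = 237, synonymous = 10606),
                      meanDepth = 67,
                      genotypingErrorRate = 0,
                      afAlpha = 0.8, afBeta = 0.8,
                      spikePlan = NULL, seed = 1L) {
  if (is.null(spikePlan)) {
    spikePlan <- if (nTrios > 0)
      data.frame(trio = seq_len(nTrios), model = "de_novo",
                 consequence = "missense", stringsAsFactors = FALSE)
    else data.frame(trio = integer(), model = character(),
                    consequence = character(), stringsAsFactors = FALSE)
  } else if (identical(spikePlan, "none")) {
    spikePlan <- data.frame(trio = integer(), model = character(),
                            consequence = character(), stringsAsFactors = FALSE)
  }
  new("SimConfig", nTrios = nTrios,
      meanExonicPerIndividual = meanExonicPerIndividual,
      classMix = classMix, meanDepth = meanDepth,
      genotypingErrorRate = genotypingErrorRate,
      afAlpha = afAlpha, afBeta = afBeta,
      spikePlan = spikePlan, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nTrios, "trio(s),",
      object@meanExonicPerIndividual, "exonic variants/individual,",
      object@meanDepth, "x depth, error rate",
      object@genotypingErrorRate, ", seed", object@seed, "\n")
  cat("class mix:", paste(names(object@classMix), object@classMix,
                          sep = "=", collapse = ", "), "\n")
  if (nrow(object@spikePlan)) {
    cat("spikes:\n"); print(object@spikePlan)
  }
})

## ------------------------------------------------------------------ ##
##  Synthetic exome coordinate map                                    ##
## ------------------------------------------------------------------ ##

#' Synthetic exome coordinate map
#'
#' Builds a deterministic (given the RNG state) set of synthetic
#' plus-strand transcript models spread over synthetic autosomes plus two
#' X-chromosome genes, and a set of "dark" intervals carrying no
#' annotation (used for unclassifiable background variants). Background
#' panel sites are drawn from the single-exon transcripts; multi-exon
#' transcripts host splice-site spikes.
#'
#' @param nGenes number of autosomal genes.
#' @param nChrom number of synthetic autosomes.
#' @return list with elements `txs` (named list of
#'   [TranscriptModel-class]), `dark` (data.frame of unannotated
#'   intervals).
#' @export
makeSyntheticExomeMap <- function(nGenes = 160, nChrom = 6) {
  chroms <- paste0("chr", seq_len(nChrom))
  txs <- list()
  cursor <- stats::setNames(rep(10000L, nChrom + 1L), c(chroms, "chrX"))
  mkGene <- function(gene, id, chrom, nCodons, multi) {
    exonLens <- NULL
    len <- nCodons * 3L
    if (multi) {
      nEx <- sample(2:4, 1)
      cuts <- sort(sample(seq(30L, len - 30L, by = 3L), nEx - 1L))
      exonLens <- diff(c(0L, cuts, len))
    }
    tx <- .buildTx(gene, id, chrom, "+", nCodons, exonLens = exonLens,
                   gStart = cursor[[chrom]])
    cursor[[chrom]] <<- max(tx@exons[, 2]) + 10000L
    tx
  }
  for (i in seq_len(nGenes)) {
    gene <- sprintf("SG%04d", i)
    id <- sprintf("SGT%04d", i)
    chrom <- chroms[(i - 1L) %% nChrom + 1L]
    nCodons <- sample(150:900, 1)
    multi <- stats::runif(1) < 0.3
    txs[[id]] <- mkGene(gene, id, chrom, nCodons, multi)
  }
  for (i in 1:2) {
    id <- sprintf("SGTX%02d", i)
    txs[[id]] <- mkGene(sprintf("SGX%02d", i), id, "chrX",
                        sample(300:700, 1), multi = FALSE)
  }
  dark <- data.frame(chrom = chroms,
                     start = unname(cursor[chroms]) + 50000L,
                     end = unname(cursor[chroms]) + 70000L,
                     stringsAsFactors = FALSE)
  list(txs = txs, dark = dark)
}

## ------------------------------------------------------------------ ##
##  Background panel                                                  ##
## ------------------------------------------------------------------ ##

# Draw background sites class by class until the cumulative expected
# per-individual carrier mass sum(1 - (1-p)^2) reaches each class target,
# so that the expected per-individual yield equals the configured means
# by construction.
.buildBackgroundPanel <- function(cfg, map) {
  txs <- map$txs
  single <- Filter(function(tx) nrow(tx@exons) == 1L && tx@chrom != "chrX", txs)
  cdsStr <- vapply(single, txCds, character(1))
  lens <- nchar(cdsStr)
  starts <- vapply(single, function(tx) tx@exons[1, 1], integer(1))
  chr <- vapply(single, txChrom, character(1))
  genes <- vapply(single, txGene, character(1))
  ids <- vapply(single, txId, character(1))
  bases <- c("A", "C", "G", "T")

  targets <- c(synonymous = unname(cfg@classMix["synonymous"]),
               missense = unname(cfg@classMix["missense"]),
               nonsense = 0.4 * unname(cfg@classMix["lof"]),
               frameshift = 0.6 * unname(cfg@classMix["lof"]),
               non_frameshift = unname(cfg@classMix["non_frameshift"]),
               unknown = cfg@meanExonicPerIndividual - sum(cfg@classMix))
  got <- stats::setNames(numeric(length(targets)), names(targets))
  pools <- stats::setNames(vector("list", length(targets)), names(targets))
  usedKeys <- character(0)

  snvBatch <- function(k) {
    ti <- sample(length(single), k, replace = TRUE, prob = lens)
    pos <- 4L + floor(stats::runif(k) * (lens[ti] - 6L))
    refB <- substr(cdsStr[ti], pos, pos)
    refI <- match(refB, bases)
    altI <- (refI - 1L + sample(1:3, k, replace = TRUE)) %% 4L + 1L
    altB <- bases[altI]
    ci <- ceiling(pos / 3)
    a <- (ci - 1L) * 3L + 1L
    oldCod <- substr(cdsStr[ti], a, a + 2L)
    off <- pos - a + 1L
    newCod <- oldCod
    substr(newCod, off, off) <- altB
    aaOld <- unname(Biostrings::GENETIC_CODE[oldCod])
    aaNew <- unname(Biostrings::GENETIC_CODE[newCod])
    cls <- ifelse(aaOld == aaNew, "synonymous",
           ifelse(aaNew == "*", "nonsense", "missense"))
    data.frame(chrom = chr[ti], pos = starts[ti] + pos - 1L,
               ref = refB, alt = altB, class = cls,
               gene = genes[ti], txid = ids[ti], stringsAsFactors = FALSE)
  }
  delBatch <- function(k, L, cls) {
    ti <- sample(length(single), k, replace = TRUE, prob = lens)
    pos <- 10L + floor(stats::runif(k) * (lens[ti] - 200L))   # event start
    anchor <- pos - 1L
    ref <- substr(cdsStr[ti], anchor, anchor + L)
    alt <- substr(cdsStr[ti], anchor, anchor)
    data.frame(chrom = chr[ti], pos = starts[ti] + anchor - 1L,
               ref = ref, alt = alt, class = cls,
               gene = genes[ti], txid = ids[ti], stringsAsFactors = FALSE)
  }
  darkBatch <- function(k) {
    di <- sample(nrow(map$dark), k, replace = TRUE)
    pos <- map$dark$start[di] +
      floor(stats::runif(k) * (map$dark$end[di] - map$dark$start[di] + 1L))
    refB <- bases[sample(4L, k, replace = TRUE)]
    altB <- bases[(match(refB, bases) - 1L + sample(1:3, k, TRUE)) %% 4L + 1L]
    data.frame(chrom = map$dark$chrom[di], pos = as.integer(pos),
               ref = refB, alt = altB, class = "unknown",
               gene = NA_character_, txid = NA_character_,
               stringsAsFactors = FALSE)
  }
  takeInto <- function(batch) {
    key <- paste(batch$chrom, batch$pos)
    keep <- !duplicated(key) & !(key %in% usedKeys)
    batch <- batch[keep, , drop = FALSE]
    key <- key[keep]
    sel <- logical(nrow(batch))
    for (cl in unique(batch$class)) {
      if (!cl %in% names(targets)) next
      if (got[cl] >= targets[cl]) next
      ii <- which(batch$class == cl)
      af <- stats::rbeta(length(ii), cfg@afAlpha, cfg@afBeta)
      mass <- 1 - (1 - af)^2
      cum <- got[cl] + cumsum(mass)
      nTake <- min(length(ii), sum(cum < targets[cl]) + 1L)
      loc <- seq_len(nTake)
      b <- batch[ii[loc], , drop = FALSE]
      b$af <- af[loc]
      pools[[cl]] <<- c(pools[[cl]], list(b))
      got[cl] <<- got[cl] + sum(1 - (1 - b$af)^2)
      sel[ii[loc]] <- TRUE
    }
    usedKeys <<- c(usedKeys, key[sel])
  }
  # SNV classes (synonymous / missense / nonsense byproduct)
  while (got["synonymous"] < targets["synonymous"] ||
         got["missense"] < targets["missense"] ||
         got["nonsense"] < targets["nonsense"]) {
    takeInto(snvBatch(20000L))
  }
  while (got["frameshift"] < targets["frameshift"])
    takeInto(delBatch(2000L, 1L, "frameshift"))
  while (got["non_frameshift"] < targets["non_frameshift"])
    takeInto(delBatch(2000L, 3L, "non_frameshift"))
  while (got["unknown"] < targets["unknown"])
    takeInto(darkBatch(2000L))

  panel <- do.call(rbind, unlist(pools, recursive = FALSE))
  panel <- panel[order(panel$chrom, panel$pos, method = "radix"), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

## ------------------------------------------------------------------ ##
##  Mendelian transmission                                            ##
## ------------------------------------------------------------------ ##

#' Transmit parental genotypes to a proband
#'
#' Autosomal model: each proband allele is drawn uniformly from the
#' corresponding parent's two alleles. X chromosome: a son receives his
#' single X allele from the mother only (the father contributes Y); a
#' daughter receives the paternal X allele plus one maternal allele.
#'
#' @param fatherGt,motherGt integer vectors of parental alternate-allele
#'   counts (0/1/2 autosomal diploid; for the X in males, the father is
#'   hemizygous 0/1).
#' @param chromX logical scalar or vector: is the site on the X?
#' @param probandSex `"male"` or `"female"`.
#' @return integer vector of proband alternate-allele counts (on the X,
#'   hemizygous 0/1 for males).
#' @export
transmitGenotypes <- function(fatherGt, motherGt, chromX = FALSE,
                              probandSex = "female") {
  n <- length(fatherGt)
  chromX <- rep_len(chromX, n)
  pat <- stats::rbinom(n, 1L, fatherGt / 2)
  mat <- stats::rbinom(n, 1L, motherGt / 2)
  out <- pat + mat
  if (any(chromX)) {
    i <- which(chromX)
    matX <- stats::rbinom(length(i), 1L, motherGt[i] / 2)
    if (probandSex == "male") {
      out[i] <- matX                        # hemizygous: maternal X only
    } else {
      out[i] <- fatherGt[i] + matX          # paternal X is transmitted whole
    }
  }
  as.integer(out)
}

## ------------------------------------------------------------------ ##
##  Spiked causal variants                                            ##
## ------------------------------------------------------------------ ##

# Find a CDS position on tx realizing the requested SNV consequence.
.findSnvSite <- function(tx, consequence, maxTries = 5000L) {
  cds <- tx@cds
  len <- nchar(cds)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(maxTries)) {
    pos <- sample(4:(len - 3L), 1)
    refB <- substr(cds, pos, pos)
    for (altB in setdiff(bases, refB)) {
      cl <- classifyCodingChange(tx, pos, refB, altB)$consequence
      if (cl == consequence)
        return(list(cdsPos = pos, ref = refB, alt = altB))
    }
  }
  stop(sprintf("could not realize a %s SNV on %s", consequence, tx@txId))
}

# Construct one spiked variant site for a trio. Returns site fields plus
# per-member alternate allele counts.
.makeSpike <- function(map, model, consequence, probandSex, usedKeys) {
  txs <- map$txs
  onX <- model == "x_linked"
  if (onX && probandSex != "male")
    stop("impossible spike: X-linked hemizygous plan requires a male proband")
  pool <- Filter(function(tx) {
    if (onX) tx@chrom == "chrX" else tx@chrom != "chrX"
  }, txs)
  if (consequence == "splice_site")
    pool <- Filter(function(tx) nrow(tx@exons) > 1L, pool)
  else
    pool <- Filter(function(tx) nrow(tx@exons) == 1L, pool)
  repeat {
    tx <- pool[[sample(length(pool), 1)]]
    if (consequence == "splice_site") {
      ex <- tx@exons
      donorEnd <- ex[sample(nrow(ex) - 1L, 1), 2]
      site <- list(chrom = tx@chrom, pos = donorEnd + 1L, ref = "G", alt = "T")
    } else if (consequence %in% c("frameshift", "non_frameshift", "in_frame")) {
      L <- if (consequence == "frameshift") 1L else 3L
      pos <- sample(10:(nchar(tx@cds) - 200L), 1)
      anchor <- pos - 1L
      site <- list(chrom = tx@chrom,
                   pos = tx@exons[1, 1] + anchor - 1L,
                   ref = substr(tx@cds, anchor, anchor + L),
                   alt = substr(tx@cds, anchor, anchor))
    } else {
      s <- .findSnvSite(tx, consequence)
      site <- list(chrom = tx@chrom,
                   pos = tx@exons[1, 1] + s$cdsPos - 1L,
                   ref = s$ref, alt = s$alt)
    }
    key <- paste(site$chrom, site$pos)
    if (!key %in% usedKeys) {
      site$gene <- tx@gene; site$txid <- tx@txId
      return(site)
    }
  }
}

# Per-member alternate allele counts for a spiked model (autosomal sites;
# X handled separately because of hemizygosity).
.spikeCounts <- function(model) {
  switch(model,
    de_novo       = list(fa = 0L, mo = 0L, pb = 1L),
    ar_homozygous = list(fa = 1L, mo = 1L, pb = 2L),
    stop("unhandled spike model"))
}

## ------------------------------------------------------------------ ##
##  Cohort simulation                                                 ##
## ------------------------------------------------------------------ ##

#' Simulate a cohort of trio exomes
#'
#' Writes, per trio, a multi-sample VCF (proband, father, mother) of
#' background and spiked variants; plus one cohort PED file, a population
#' allele-frequency table, an in-silico predictor call table, a
#' gene-constraint table for the synthetic map, the transcript models
#' (GFF3 + CDS FASTA), a ground-truth table of spiked variants, and a JSON
#' run manifest. Fully reproducible from `cfg@seed`.
#'
#' Founder genotypes are Hardy-Weinberg draws from each site's population
#' allele frequency; proband genotypes follow Mendelian transmission
#' ([transmitGenotypes()]). Depth is Poisson(meanDepth); heterozygous
#' allele depths are Binomial(DP, 1/2); homozygous genotypes show alt
#' reads at the configured error rate; GQ is the Phred-scaled likelihood
#' ratio between the best and second-best genotype, capped at 99. With
#' `genotypingErrorRate > 0`, each genotype is independently replaced by a
#' uniformly random other genotype with that probability before read
#' simulation.
#'
#' @param cfg a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param probandSexes optional character vector (`"male"`/`"female"`, one
#'   per trio). Default: alternating, with trios that receive an X-linked
#'   spike forced male. An X-linked spike planned for an explicitly female
#'   proband is an error.
#' @return invisibly, a list: `dir`, `pedPath`, `vcfPaths` (named by
#'   family), `freqPath`, `predictorPath`, `constraintPath`, `gffPath`,
#'   `fastaPath`, `truthPath`, `manifestPath`, `pedigrees`, `truth`
#'   (data.frame), `map`.
#' @export
simulateCohort <- function(cfg, outDir, probandSexes = NULL) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg@seed)

  map <- makeSyntheticExomeMap()
  panel <- .buildBackgroundPanel(cfg, map)
  M <- nrow(panel)

  nT <- cfg@nTrios
  famIds <- sprintf("FAM%02d", seq_len(nT))
  if (is.null(probandSexes)) {
    sexes <- rep(c("male", "female"), length.out = max(nT, 1L))[seq_len(nT)]
    # X-linked hemizygous spikes need a male proband; with auto-assigned
    # sexes the planned trios are made male (explicit sexes are honoured
    # as given, and an impossible plan raises an error)
    if (nrow(cfg@spikePlan)) {
      needMale <- unique(cfg@spikePlan$trio[cfg@spikePlan$model == "x_linked"])
      sexes[needMale] <- "male"
    }
  } else {
    stopifnot(length(probandSexes) == nT,
              all(probandSexes %in% c("male", "female")))
    sexes <- probandSexes
  }
  peds <- lapply(seq_len(nT), function(i)
    TrioPedigree(famIds[i],
                 paste0(famIds[i], "_PB"), paste0(famIds[i], "_FA"),
                 paste0(famIds[i], "_MO"), sexes[i]))

  err <- cfg@genotypingErrorRate
  usedKeys <- paste(panel$chrom, panel$pos)
  truth <- list()
  spikeSites <- list()     # cohort-wide spiked site records (for AF table)
  vcfPaths <- character(0)

  simulateReads <- function(dose, ploidy) {
    # dose: expected alt fraction (0, .5, 1); ploidy 1 or 2
    n <- length(dose)
    dp <- stats::rpois(n, cfg@meanDepth)
    pAlt <- ifelse(dose == 0, err, ifelse(dose == 1, 1 - err, 0.5))
    adAlt <- stats::rbinom(n, dp, pAlt)
    adRef <- dp - adAlt
    e2 <- max(err, 1e-3)
    ll <- function(p) adAlt * log10(p) + adRef * log10(1 - p)
    l0 <- ll(e2); l1 <- ll(0.5); l2 <- ll(1 - e2)
    # Phred LR between best and second-best genotype, vectorized
    best <- pmax(l0, l1, l2)
    worst <- pmin(l0, l1, l2)
    second <- l0 + l1 + l2 - best - worst
    hap <- ploidy == 1L                      # haploid: het not a candidate
    if (any(hap)) {
      best[hap] <- pmax(l0[hap], l2[hap])
      second[hap] <- pmin(l0[hap], l2[hap])
    }
    gq <- pmin(99L, pmax(0L, as.integer(round(10 * (best - second)))))
    list(dp = dp, adRef = adRef, adAlt = adAlt, gq = gq)
  }

  for (t in seq_len(nT)) {
    ped <- peds[[t]]
    fa <- stats::rbinom(M, 2L, panel$af)
    mo <- stats::rbinom(M, 2L, panel$af)
    pb <- transmitGenotypes(fa, mo, chromX = FALSE, probandSex = ped@probandSex)
    if (err > 0) {
      flip <- function(g) {
        hit <- stats::runif(M) < err
        g[hit] <- (g[hit] + sample(1:2, sum(hit), replace = TRUE)) %% 3L
        g
      }
      fa <- flip(fa); mo <- flip(mo); pb <- flip(pb)
    }
    ploidy <- rep(2L, M)
    chromX <- rep(FALSE, M)

    # spikes for this trio
    plan <- cfg@spikePlan[cfg@spikePlan$trio == t, , drop = FALSE]
    sChrom <- character(0); sPos <- integer(0); sRef <- character(0)
    sAlt <- character(0); sFa <- integer(0); sMo <- integer(0)
    sPb <- integer(0); sPloidyPb <- integer(0); sPloidyFa <- integer(0)
    sX <- logical(0)
    addSpike <- function(site, faC, moC, pbC, model, consequence, onX) {
      sChrom <<- c(sChrom, site$chrom); sPos <<- c(sPos, site$pos)
      sRef <<- c(sRef, site$ref); sAlt <<- c(sAlt, site$alt)
      sFa <<- c(sFa, faC); sMo <<- c(sMo, moC); sPb <<- c(sPb, pbC)
      sX <<- c(sX, onX)
      usedKeys <<- c(usedKeys, paste(site$chrom, site$pos))
      truth[[length(truth) + 1L]] <<- data.frame(
        trioId = ped@familyId, probandId = ped@probandId,
        chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
        model = model, gene = site$gene, consequence = consequence,
        expectedCandidate = TRUE, stringsAsFactors = FALSE)
      spikeSites[[length(spikeSites) + 1L]] <<- data.frame(
        chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
        consequence = consequence, gene = site$gene,
        lofSpike = consequence %in% c("nonsense", "frameshift", "splice_site"),
        stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(plan))) {
      model <- plan$model[r]; consequence <- plan$consequence[r]
      if (model == "ar_compound_het") {
        s1 <- .makeSpike(map, model = "de_novo", consequence, ped@probandSex,
                         usedKeys)
        # second site in the same gene
        tx <- map$txs[[s1$txid]]
        repeat {
          s2 <- .findSnvSite(tx, consequence)
          s2 <- list(chrom = tx@chrom, pos = tx@exons[1, 1] + s2$cdsPos - 1L,
                     ref = s2$ref, alt = s2$alt, gene = tx@gene, txid = tx@txId)
          if (!paste(s2$chrom, s2$pos) %in% c(usedKeys, paste(s1$chrom, s1$pos)))
            break
        }
        addSpike(s1, 1L, 0L, 1L, model, consequence, FALSE)
        addSpike(s2, 0L, 1L, 1L, model, consequence, FALSE)
      } else if (model == "x_linked") {
        site <- .makeSpike(map, model, consequence, ped@probandSex, usedKeys)
        addSpike(site, 0L, 1L, 1L, model, consequence, TRUE)
      } else {
        site <- .makeSpike(map, "autosomal", consequence, ped@probandSex,
                           usedKeys)
        cnt <- .spikeCounts(model)
        addSpike(site, cnt$fa, cnt$mo, cnt$pb, model, consequence, FALSE)
      }
    }

    chrom <- c(panel$chrom, sChrom); pos <- c(panel$pos, sPos)
    ref <- c(panel$ref, sRef); alt <- c(panel$alt, sAlt)
    fa <- c(fa, sFa); mo <- c(mo, sMo); pb <- c(pb, sPb)
    chromX <- c(chromX, sX)
    present <- (fa + mo + pb) > 0
    idx <- which(present)

    faP <- fa[idx]; moP <- mo[idx]; pbP <- pb[idx]; xP <- chromX[idx]
    # ploidy: X sites are hemizygous in males (proband and father)
    male <- ped@probandSex == "male"
    plPb <- ifelse(xP & male, 1L, 2L)
    plFa <- ifelse(xP, 1L, 2L)
    plMo <- rep(2L, length(idx))
    dosePb <- pbP / plPb; doseFa <- faP / plFa; doseMo <- moP / plMo

    rPb <- simulateReads(dosePb, plPb)
    rFa <- simulateReads(doseFa, plFa)
    rMo <- simulateReads(doseMo, plMo)
    # spiked de novo variants must show the alt in >10% of proband reads
    dnSpike <- which(idx > M)   # all spiked rows sit after the panel
    for (k in dnSpike) {
      if (dosePb[k] == 0.5 && plPb[k] == 2L) {
        tries <- 0
        while ((rPb$adAlt[k] / max(1, rPb$dp[k])) <= 0.10 && tries < 100) {
          rPb$dp[k] <- stats::rpois(1, cfg@meanDepth)
          rPb$adAlt[k] <- stats::rbinom(1, rPb$dp[k], 0.5)
          rPb$adRef[k] <- rPb$dp[k] - rPb$adAlt[k]
          tries <- tries + 1
        }
      }
    }

    gtStr <- function(count, pl) {
      ifelse(pl == 1L, as.character(count),
             c("0/0", "0/1", "1/1")[count + 1L])
    }
    sites <- data.frame(chrom = chrom[idx], pos = pos[idx], ref = ref[idx],
                        alt = alt[idx], id = NA_character_,
                        stringsAsFactors = FALSE)
    o <- order(sites$chrom, sites$pos, method = "radix")
    mk <- function(v) matrix(v[o], ncol = 1)
    samples <- c(ped@probandId, ped@fatherId, ped@motherId)
    calls <- TrioCalls(sites[o, , drop = FALSE],
      gt    = cbind(mk(gtStr(pbP, plPb)), mk(gtStr(faP, plFa)), mk(gtStr(moP, plMo))),
      adRef = cbind(mk(rPb$adRef), mk(rFa$adRef), mk(rMo$adRef)),
      adAlt = cbind(mk(rPb$adAlt), mk(rFa$adAlt), mk(rMo$adAlt)),
      dp    = cbind(mk(rPb$dp), mk(rFa$dp), mk(rMo$dp)),
      gq    = cbind(mk(rPb$gq), mk(rFa$gq), mk(rMo$gq)))
    colnames(calls@gt) <- colnames(calls@adRef) <- colnames(calls@adAlt) <-
      colnames(calls@dp) <- colnames(calls@gq) <- samples
    p <- file.path(outDir, paste0(ped@familyId, ".vcf"))
    writeTrioVcf(calls, p, source = "TrioExome::simulateCohort")
    vcfPaths[ped@familyId] <- p
  }

  ## cohort-level outputs
  pedPath <- file.path(outDir, "cohort.ped")
  writePedigree(peds, pedPath)

  spikeDf <- if (length(spikeSites)) do.call(rbind, spikeSites) else NULL
  freq <- panel[, c("chrom", "pos", "ref", "alt", "af")]
  if (!is.null(spikeDf))
    freq <- rbind(freq, data.frame(chrom = spikeDf$chrom, pos = spikeDf$pos,
                                   ref = spikeDf$ref, alt = spikeDf$alt,
                                   af = 0))
  freqPath <- file.path(outDir, "population_af.tsv")
  utils::write.table(freq, freqPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # predictor calls: background missense / in-frame sites plus all spikes
  predRows <- panel[panel$class %in% c("missense", "non_frameshift"),
                    c("chrom", "pos", "ref", "alt", "class")]
  predRows$damaging <- stats::runif(nrow(predRows)) < 0.25
  if (!is.null(spikeDf)) {
    sp <- spikeDf[spikeDf$consequence %in%
                    c("missense", "in_frame", "non_frameshift", "splice_site"),
                  c("chrom", "pos", "ref", "alt")]
    if (nrow(sp)) {
      sp$class <- "spike"; sp$damaging <- TRUE
      predRows <- rbind(predRows, sp)
    }
  }
  drawCalls <- function(damaging, n) {
    from <- if (damaging) c("D", "Prob. DA", "H") else c("tolerated", "neutral", "B")
    sample(from, n, replace = TRUE)
  }
  npr <- nrow(predRows)
  pred <- data.frame(chrom = predRows$chrom, pos = predRows$pos,
                     ref = predRows$ref, alt = predRows$alt,
                     SIFT = character(npr), PolyPhen2 = character(npr),
                     MutationTaster = character(npr),
                     stringsAsFactors = FALSE)
  dmg <- predRows$damaging
  for (col in c("SIFT", "PolyPhen2", "MutationTaster")) {
    v <- character(npr)
    v[dmg] <- drawCalls(TRUE, sum(dmg))
    v[!dmg] <- drawCalls(FALSE, sum(!dmg))
    pred[[col]] <- v
  }
  predictorPath <- file.path(outDir, "predictors.tsv")
  utils::write.table(pred, predictorPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # gene constraints: LoF-spiked genes are flagged intolerant
  allGenes <- vapply(map$txs, txGene, character(1))
  lofGenes <- if (!is.null(spikeDf)) unique(spikeDf$gene[spikeDf$lofSpike]) else character(0)
  gc <- data.frame(gene = unname(allGenes),
                   transcript_id = names(allGenes),
                   lof_intolerant = unname(allGenes) %in% lofGenes |
                     stats::runif(length(allGenes)) < 0.15,
                   known_pathogenic_changes = NA_character_,
                   stringsAsFactors = FALSE)
  gc$lof_intolerant[gc$gene %in% lofGenes] <- TRUE
  constraintPath <- file.path(outDir, "gene_constraints.tsv")
  utils::write.table(gc, constraintPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gffPath <- file.path(outDir, "transcripts.gff3")
  fastaPath <- file.path(outDir, "transcripts.fa")
  writeTranscriptModels(map$txs, gffPath, fastaPath)

  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(trioId = character(), probandId = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), model = character(), gene = character(),
               consequence = character(), expectedCandidate = logical(),
               stringsAsFactors = FALSE)
  rownames(truthDf) <- NULL
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(truthDf, truthPath, dataframe = "rows", auto_unbox = TRUE)

  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(list(
    seed = cfg@seed, nTrios = cfg@nTrios,
    meanExonicPerIndividual = cfg@meanExonicPerIndividual,
    classMix = as.list(cfg@classMix), meanDepth = cfg@meanDepth,
    genotypingErrorRate = cfg@genotypingErrorRate,
    afAlpha = cfg@afAlpha, afBeta = cfg@afBeta,
    files = list(ped = pedPath, vcf = as.list(vcfPaths), freq = freqPath,
                 predictors = predictorPath, constraints = constraintPath,
                 gff = gffPath, fasta = fastaPath, truth = truthPath)),
    manifestPath, auto_unbox = TRUE)

  invisible(list(dir = outDir, pedPath = pedPath, vcfPaths = vcfPaths,
                 freqPath = freqPath, predictorPath = predictorPath,
                 constraintPath = constraintPath, gffPath = gffPath,
                 fastaPath = fastaPath, truthPath = truthPath,
                 manifestPath = manifestPath, pedigrees = peds,
                 truth = truthDf, map = map))
}
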