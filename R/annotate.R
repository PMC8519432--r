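# Coding-consequence annotation: codon arithmetic, protein-level naming
# (HGVS-lite), canonical splice-site calls, population allele-frequency
# lookup and in-silico predictor consensus.

.AA3 <- local({
  a <- Biostrings::AMINO_ACID_CODE
  function(aa1) ifelse(aa1 == "*", "*", unname(a[aa1]))
})

#' Codon index and within-codon offset of a CDS position
#'
#' `codon = ceiling(cdsPos/3)`, `offset = cdsPos - 3*(codon-1)` (1..3).
#' The codon index equals the residue number of HGVS protein notation, so
#' e.g. CDS position 1861 falls in codon 621.
#'
#' @param cdsPos integer vector of 1-based CDS positions.
#' @return data.frame with columns `codon` and `offset`.
#' @examples
#' cdsCodonIndex(1861)  # codon 621, offset 1
#' @export
cdsCodonIndex <- function(cdsPos) {
  if (any(cdsPos < 1)) stop("cdsPos must be >= 1")
  codon <- ceiling(cdsPos / 3)
  data.frame(codon = as.integer(codon),
             offset = as.integer(cdsPos - 3 * (codon - 1)))
}

# Longest common prefix / suffix lengths of two character vectors.
.lcpLen <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d) == 0) n else d[1] - 1L
}
.lcsLen <- function(a, b, skip) {
  # common suffix length, not overlapping the first `skip` elements
  n <- min(length(a), length(b)) - skip
  if (n <= 0) return(0L)
  ra <- rev(a); rb <- rev(b)
  d <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(d) == 0) n else d[1] - 1L
}

# Name an in-frame protein difference between refP and mutP (aa vectors).
.inFrameProteinName <- function(refP, mutP) {
  lcp <- .lcpLen(refP, mutP)
  lcs <- .lcsLen(refP, mutP, lcp)
  del <- refP[seq_len(length(refP) - lcs)][-seq_len(lcp)]
  ins <- mutP[seq_len(length(mutP) - lcs)][-seq_len(lcp)]
  if (length(del) == 0 && length(ins) == 0) return(list(name = "p.=", firstCodon = NA_integer_))
  if (length(ins) == 0) {                      # clean deletion
    s <- lcp + 1L; e <- lcp + length(del)
    nm <- if (s == e) sprintf("p.%s%ddel", .AA3(refP[s]), s)
          else sprintf("p.%s%d_%s%ddel", .AA3(refP[s]), s, .AA3(refP[e]), e)
    return(list(name = nm, firstCodon = s))
  }
  if (length(del) == 0) {                      # insertion; check duplication
    L <- length(ins)
    if (lcp >= L && identical(mutP[(lcp - L + 1L):lcp], ins)) {
      s <- lcp - L + 1L; e <- lcp
      nm <- if (s == e) sprintf("p.%s%ddup", .AA3(refP[s]), s)
            else sprintf("p.%s%d_%s%ddup", .AA3(refP[s]), s, .AA3(refP[e]), e)
      return(list(name = nm, firstCodon = s))
    }
    nm <- sprintf("p.%s%d_%s%dins%s", .AA3(refP[lcp]), lcp,
                  .AA3(refP[lcp + 1L]), lcp + 1L,
                  paste(.AA3(ins), collapse = ""))
    return(list(name = nm, firstCodon = lcp + 1L))
  }
  s <- lcp + 1L; e <- lcp + length(del)        # delins
  nm <- if (s == e) sprintf("p.%s%ddelins%s", .AA3(refP[s]), s,
                            paste(.AA3(ins), collapse = ""))
        else sprintf("p.%s%d_%s%ddelins%s", .AA3(refP[s]), s, .AA3(refP[e]), e,
                     paste(.AA3(ins), collapse = ""))
  list(name = nm, firstCodon = s)
}

# HGVS-lite c. description. ref/alt are pure event alleles ("" allowed);
# for an insertion cdsPos is the position the sequence is inserted BEFORE.
.cdnaName <- function(cds, cdsPos, ref, alt) {
  if (nchar(ref) == 1 && nchar(alt) == 1)
    return(sprintf("c.%d%s>%s", cdsPos, ref, alt))
  if (nchar(alt) == 0) {                       # deletion
    e <- cdsPos + nchar(ref) - 1L
    if (cdsPos == e) return(sprintf("c.%ddel%s", cdsPos, ref))
    return(sprintf("c.%d_%ddel%s", cdsPos, e, ref))
  }
  if (nchar(ref) == 0) {                       # insertion / duplication
    L <- nchar(alt)
    if (cdsPos - L >= 1 && substr(cds, cdsPos - L, cdsPos - 1L) == alt) {
      s <- cdsPos - L
      if (L == 1) return(sprintf("c.%ddup%s", s, alt))
      return(sprintf("c.%d_%ddup%s", s, cdsPos - 1L, alt))
    }
    return(sprintf("c.%d_%dins%s", cdsPos - 1L, cdsPos, alt))
  }
  e <- cdsPos + nchar(ref) - 1L
  if (cdsPos == e) return(sprintf("c.%ddelins%s", cdsPos, alt))
  sprintf("c.%d_%ddelins%s", cdsPos, e, alt)
}

#' Classify a coding change on a transcript
#'
#' Works in CDS space. For SNVs the affected codon is translated before
#' and after the substitution (standard genetic code): same residue gives
#' `synonymous`, a gained stop gives `nonsense` (`p.Xxx<n>*`), otherwise
#' `missense` (`p.Xxx<n>Yyy`). Indels with length difference not a
#' multiple of 3 are `frameshift`; the protein change names the first
#' altered residue and, when a downstream stop lies within the supplied
#' CDS, the stop offset (`p.Xxx<n>Yyyfs*<m>`). In-frame indels are
#' `in_frame`, with deletion/duplication/insertion naming derived from a
#' prefix/suffix alignment of the reference and mutant proteins.
#'
#' @param tx a [TranscriptModel-class].
#' @param cdsPos 1-based CDS position of the first changed base (for pure
#'   insertions: the position the sequence is inserted before).
#' @param ref,alt event alleles in coding-strand orientation; `""` for the
#'   empty side of a pure insertion/deletion. `ref` must match the CDS.
#' @return one-row data.frame: `consequence`, `proteinChange`,
#'   `cdnaChange`, `codon` (first affected codon index, NA for `p.=`).
#' @examples
#' tx <- exampleTranscripts()[["NM_006772.2"]]  # codon 621 is CGA
#' classifyCodingChange(tx, 1861, "C", "T")     # nonsense p.Arg621*
#' @export
classifyCodingChange <- function(tx, cdsPos, ref, alt) {
  cds <- tx@cds
  ref <- toupper(ref); alt <- toupper(alt)
  cdsPos <- as.integer(cdsPos)
  if (nzchar(ref)) {
    have <- substr(cds, cdsPos, cdsPos + nchar(ref) - 1L)
    if (have != ref)
      stop(sprintf("transcript/variant inconsistency: %s CDS %d has '%s', variant says '%s'",
                   tx@txId, cdsPos, have, ref))
  } else if (cdsPos < 1L || cdsPos > nchar(cds) + 1L) {
    stop("insertion point outside CDS")
  }
  mut <- paste0(substr(cds, 1, cdsPos - 1L), alt,
                substr(cds, cdsPos + nchar(ref), nchar(cds)))
  cdna <- .cdnaName(cds, cdsPos, ref, alt)
  res <- function(consequence, proteinChange, codon)
    data.frame(consequence = consequence, proteinChange = proteinChange,
               cdnaChange = cdna, codon = as.integer(codon),
               stringsAsFactors = FALSE)

  if (nchar(ref) == 1 && nchar(alt) == 1) {
    ci <- cdsCodonIndex(cdsPos)
    a <- (ci$codon - 1L) * 3L + 1L
    oldCodon <- substr(cds, a, a + 2L)
    newCodon <- substr(mut, a, a + 2L)
    aaOld <- unname(Biostrings::GENETIC_CODE[oldCodon])
    aaNew <- unname(Biostrings::GENETIC_CODE[newCodon])
    if (aaOld == aaNew)
      return(res("synonymous", "p.=", ci$codon))
    if (aaNew == "*")
      return(res("nonsense", sprintf("p.%s%d*", .AA3(aaOld), ci$codon), ci$codon))
    if (aaOld == "*")   # stop-lost; outside the five-class scheme
      return(res("unknown", sprintf("p.*%d%sext", ci$codon, .AA3(aaNew)), ci$codon))
    return(res("missense", sprintf("p.%s%d%s%s", .AA3(aaOld), ci$codon, .AA3(aaNew), ""),
               ci$codon))
  }

  d <- nchar(alt) - nchar(ref)
  refP <- proteinOf(cds)
  mutP <- proteinOf(mut)
  if (d %% 3 != 0) {                           # frameshift
    firstCodon <- cdsCodonIndex(cdsPos)$codon
    lcp <- .lcpLen(refP, mutP)
    k <- lcp + 1L
    if (k > length(refP)) k <- length(refP)    # shift at the very end
    aaRef <- if (k <= length(refP)) refP[k] else "*"
    if (k > length(mutP)) {
      # mutant protein truncates exactly before k: a stop replaces aaRef
      pc <- sprintf("p.%s%d*", .AA3(aaRef), k)
      return(res("frameshift", pc, k))
    }
    aaMut <- mutP[k]
    # stop offset within the new reading frame, if the CDS extends that far
    mutAA <- translateCds(substr(mut, 1, nchar(mut) - nchar(mut) %% 3))
    stopAt <- which(mutAA == "*")
    stopAt <- stopAt[stopAt >= k][1]
    pc <- if (!is.na(stopAt))
      sprintf("p.%s%d%sfs*%d", .AA3(aaRef), k, .AA3(aaMut), stopAt - k + 1L)
    else sprintf("p.%s%d%sfs", .AA3(aaRef), k, .AA3(aaMut))
    return(res("frameshift", pc, k))
  }
  nm <- .inFrameProteinName(refP, mutP)
  codon <- if (is.na(nm$firstCodon)) cdsCodonIndex(cdsPos)$codon else nm$firstCodon
  res("in_frame", nm$name, codon)
}

#' Classify a genomic position relative to a transcript's exon structure
#'
#' Intronic positions within 1-2 nt of an exon/intron boundary (the
#' canonical donor +1/+2 and acceptor -1/-2 dinucleotides) are
#' `splice_site`; other intronic positions are `intronic`; exonic
#' positions are `coding`; positions outside the transcript span are
#' `other`. This is a binary canonical-site rule, not a splice-strength
#' score.
#'
#' @param tx a [TranscriptModel-class].
#' @param gpos integer vector of genomic positions.
#' @return character vector in `{coding, splice_site, intronic, other}`.
#' @export
classifySpliceProximity <- function(tx, gpos) {
  ex <- tx@exons
  span <- c(min(ex[, 1]), max(ex[, 2]))
  out <- rep("other", length(gpos))
  inSpan <- !is.na(gpos) & gpos >= span[1] & gpos <= span[2]
  exonic <- !is.na(genomicToCds(tx, gpos))
  out[inSpan] <- "intronic"
  out[exonic] <- "coding"
  intr <- which(inSpan & !exonic)
  if (length(intr)) {
    bounds <- c(ex[, 1], ex[, 2])
    d <- vapply(gpos[intr], function(p) min(abs(p - bounds)), numeric(1))
    out[intr][d <= 2] <- "splice_site"
  }
  out
}

# c. notation for an intronic position near an exon boundary, e.g.
# "c.237+1" (donor) or "c.238-2" (acceptor), strand-aware.
.intronicCdsName <- function(tx, gpos) {
  ex <- tx@exons
  bounds <- data.frame(gp = c(ex[, 1] - 1L, ex[, 2] + 1L),
                       edge = c(ex[, 1], ex[, 2]))   # nearest exon base
  # nearest exon edge to gpos
  allEdges <- c(ex[, 1], ex[, 2])
  edge <- allEdges[which.min(abs(gpos - allEdges))]
  off <- gpos - edge                                  # genomic offset
  cdsEdge <- genomicToCds(tx, edge)
  if (tx@strand == "-") off <- -off
  if (off > 0) sprintf("c.%d+%d", cdsEdge, off) else sprintf("c.%d%d", cdsEdge, off)
}

#' Read a population allele-frequency table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `af` (normalized
#' biallelic keys; frequencies in `[0, 1]`).
#'
#' @param path TSV path.
#' @return data.frame with an attached lookup key.
#' @export
readFrequencyTable <- function(path) {
  ft <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(need %in% names(ft)))
    stop("frequency table needs columns chrom, pos, ref, alt, af")
  if (any(ft$af < 0 | ft$af > 1)) stop("allele frequencies must lie in [0, 1]")
  ft
}

#' Look up population allele frequencies for variant sites
#'
#' Exact (chrom, pos, ref, alt) matching on canonical chromosome names;
#' absent keys return 0 (absence from the population database is treated
#' as novel). No cross-allele matching.
#'
#' @param chrom,pos,ref,alt vectors describing normalized biallelic sites.
#' @param freqTable data.frame from [readFrequencyTable()].
#' @return numeric vector of allele frequencies.
#' @export
lookupPopulationAF <- function(chrom, pos, ref, alt, freqTable) {
  if (is.null(freqTable) || nrow(freqTable) == 0)
    return(rep(0, length(pos)))
  key <- siteKey(chrom, pos, ref, alt)
  tabKey <- siteKey(freqTable$chrom, freqTable$pos, freqTable$ref, freqTable$alt)
  af <- freqTable$af[match(key, tabKey)]
  af[is.na(af)] <- 0
  af
}

.DAMAGING_LABELS <- c("D", "Deleterious", "deleterious",
                      "Prob. DA", "Probably Damaging", "probably_damaging",
                      "Pos. DA", "Possibly Damaging", "possibly_damaging",
                      "M", "Medium", "H", "High")
.BENIGN_LABELS <- c("T", "tolerated", "Tolerated", "B", "Benign", "benign",
                    "N", "neutral", "Neutral", "L", "Low", "P", "Polymorphism")

#' Consensus of in-silico predictor calls
#'
#' Counts damaging-class calls (Probably/Possibly Damaging, Deleterious,
#' Medium, High and their abbreviations); a variant is deemed deleterious
#' when damaging calls make up at least half of the available (non-NA)
#' calls. An empty or all-NA call set returns `NA` (not applicable).
#' Unknown category labels are an error.
#'
#' @param calls named character vector (predictor -> categorical call),
#'   possibly empty; `NA` entries are ignored.
#' @return `TRUE`, `FALSE` or `NA`.
#' @examples
#' predictorConsensus(c(P1 = "D", P2 = "Prob. DA", P3 = "tolerated"))  # TRUE
#' @export
predictorConsensus <- function(calls) {
  calls <- calls[!is.na(calls) & calls != "NA" & calls != ""]
  if (length(calls) == 0) return(NA)
  known <- c(.DAMAGING_LABELS, .BENIGN_LABELS)
  bad <- setdiff(unique(calls), known)
  if (length(bad))
    stop(sprintf("unknown predictor category '%s'; accepted labels: %s",
                 bad[1], paste(known, collapse = ", ")))
  sum(calls %in% .DAMAGING_LABELS) >= length(calls) / 2
}

#' Read per-variant predictor calls
#'
#' TSV keyed by `chrom`, `pos`, `ref`, `alt` with one column per
#' predictor; cells are categorical calls (or `NA`).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readPredictorCalls <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"), check.names = FALSE)
}

#' Annotate variant sites against transcript models
#'
#' For each normalized biallelic site: locates the containing transcript,
#' classifies the region (`coding` / `splice_site` / `intronic` / `other`),
#' derives the coding consequence and HGVS-lite c./p. descriptions
#' (strand-aware; alleles on minus-strand transcripts are
#' reverse-complemented before CDS mapping), attaches the population
#' allele frequency (0 when absent from the table) and the in-silico
#' predictor consensus. SNVs take a vectorized fast path.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (VCF-anchored alleles), or a [TrioCalls-class].
#' @param txs named list of [TranscriptModel-class].
#' @param freqTable optional data.frame from [readFrequencyTable()].
#' @param predictorCalls optional data.frame from [readPredictorCalls()].
#' @return data.frame with one row per site: `gene`, `transcriptId`,
#'   `region`, `consequence`, `cdnaChange`, `proteinChange`, `codon`,
#'   `populationAf`, `predictorDeleterious`.
#' @export
annotateVariants <- function(sites, txs, freqTable = NULL, predictorCalls = NULL) {
  if (is(sites, "TrioCalls")) sites <- variantSites(sites)
  n <- nrow(sites)
  ann <- data.frame(gene = rep(NA_character_, n), transcriptId = NA_character_,
                    region = "other", consequence = "unknown",
                    cdnaChange = NA_character_, proteinChange = NA_character_,
                    codon = NA_integer_, populationAf = 0,
                    predictorDeleterious = NA, stringsAsFactors = FALSE)
  if (n == 0) return(ann)

  # --- map sites to transcripts (exonic hit, else span hit) ---
  exTab <- do.call(rbind, lapply(seq_along(txs), function(i) {
    tx <- txs[[i]]
    data.frame(chrom = canonChrom(tx@chrom), start = tx@exons[, 1],
               end = tx@exons[, 2], txi = i, stringsAsFactors = FALSE)
  }))
  spanTab <- do.call(rbind, lapply(seq_along(txs), function(i) {
    tx <- txs[[i]]
    data.frame(chrom = canonChrom(tx@chrom), start = min(tx@exons[, 1]),
               end = max(tx@exons[, 2]), txi = i, stringsAsFactors = FALSE)
  }))
  mapHits <- function(tab) {
    hit <- rep(NA_integer_, n)
    sc <- canonChrom(sites$chrom)
    for (ch in unique(tab$chrom)) {
      q <- which(sc == ch)
      s <- which(tab$chrom == ch)
      if (!length(q) || !length(s)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(sites$pos[q], sites$pos[q]),
        IRanges::IRanges(tab$start[s], tab$end[s]), select = "first")
      hit[q] <- tab$txi[s][ov]
    }
    hit
  }
  exHit <- mapHits(exTab)
  spHit <- mapHits(spanTab)

  # --- intronic / splice-site sites ---
  intr <- which(is.na(exHit) & !is.na(spHit))
  for (i in intr) {
    tx <- txs[[spHit[i]]]
    reg <- classifySpliceProximity(tx, sites$pos[i])
    ann$gene[i] <- tx@gene; ann$transcriptId[i] <- tx@txId
    ann$region[i] <- reg
    ann$consequence[i] <- if (reg == "splice_site") "splice_site" else "unknown"
    if (reg == "splice_site")
      ann$cdnaChange[i] <- paste0(.intronicCdsName(tx, sites$pos[i]),
                                  sites$ref[i], ">", sites$alt[i])
  }

  # --- exonic sites ---
  exo <- which(!is.na(exHit))
  if (length(exo)) {
    ann$region[exo] <- "coding"
    isSnv <- nchar(sites$ref[exo]) == 1 & nchar(sites$alt[exo]) == 1
    # vectorized SNV path, per transcript
    snvIdx <- exo[isSnv]
    for (ti in unique(exHit[snvIdx])) {
      ii <- snvIdx[exHit[snvIdx] == ti]
      tx <- txs[[ti]]
      cp <- genomicToCds(tx, sites$pos[ii])
      refC <- sites$ref[ii]; altC <- sites$alt[ii]
      if (tx@strand == "-") {
        refC <- chartr("ACGT", "TGCA", refC); altC <- chartr("ACGT", "TGCA", altC)
      }
      ok <- !is.na(cp) & substr(rep(tx@cds, length(ii)), cp, cp) == refC
      ci <- ceiling(cp / 3)
      a <- (ci - 1L) * 3L + 1L
      oldCod <- substring(tx@cds, a, a + 2L)
      off <- cp - a + 1L
      newCod <- oldCod
      substr(newCod, off, off) <- altC
      aaOld <- unname(Biostrings::GENETIC_CODE[oldCod])
      aaNew <- unname(Biostrings::GENETIC_CODE[newCod])
      cons <- ifelse(aaOld == aaNew, "synonymous",
              ifelse(aaNew == "*", "nonsense",
              ifelse(aaOld == "*", "unknown", "missense")))
      pch <- ifelse(cons == "synonymous", "p.=",
             ifelse(cons == "nonsense", sprintf("p.%s%d*", .AA3(aaOld), ci),
             ifelse(cons == "missense",
                    sprintf("p.%s%d%s", .AA3(aaOld), ci, .AA3(aaNew)),
                    NA_character_)))
      ann$gene[ii] <- tx@gene; ann$transcriptId[ii] <- tx@txId
      ann$consequence[ii] <- ifelse(ok, cons, "unknown")
      ann$proteinChange[ii] <- ifelse(ok, pch, NA_character_)
      ann$cdnaChange[ii] <- ifelse(ok, sprintf("c.%d%s>%s", cp, refC, altC),
                                   NA_character_)
      ann$codon[ii] <- ifelse(ok, ci, NA_integer_)
    }
    # indels and MNVs, one by one
    for (i in exo[!isSnv]) {
      tx <- txs[[exHit[i]]]
      ann$gene[i] <- tx@gene; ann$transcriptId[i] <- tx@txId
      ref <- sites$ref[i]; alt <- sites$alt[i]
      res <- tryCatch({
        if (tx@strand == "+") {
          cp <- genomicToCds(tx, sites$pos[i])
          if (is.na(cp)) stop("edge")
          refC <- ref; altC <- alt
        } else {
          cp <- genomicToCds(tx, sites$pos[i] + nchar(ref) - 1L)
          if (is.na(cp)) stop("edge")
          refC <- revcompChar(ref); altC <- revcompChar(alt)
        }
        # reduce the anchored representation to the pure event
        while (nchar(refC) > 0 && nchar(altC) > 0 &&
               substr(refC, 1, 1) == substr(altC, 1, 1)) {
          refC <- substr(refC, 2, nchar(refC)); altC <- substr(altC, 2, nchar(altC))
          cp <- cp + 1L
        }
        while (nchar(refC) > 0 && nchar(altC) > 0 &&
               substr(refC, nchar(refC), nchar(refC)) ==
               substr(altC, nchar(altC), nchar(altC))) {
          refC <- substr(refC, 1, nchar(refC) - 1L)
          altC <- substr(altC, 1, nchar(altC) - 1L)
        }
        classifyCodingChange(tx, cp, refC, altC)
      }, error = function(e) NULL)
      if (is.null(res)) { ann$consequence[i] <- "unknown"; next }
      ann$consequence[i] <- res$consequence
      ann$proteinChange[i] <- res$proteinChange
      ann$cdnaChange[i] <- res$cdnaChange
      ann$codon[i] <- res$codon
    }
  }

  ann$populationAf <- lookupPopulationAF(sites$chrom, sites$pos, sites$ref,
                                         sites$alt, freqTable)
  if (!is.null(predictorCalls) && nrow(predictorCalls) > 0) {
    key <- siteKey(sites$chrom, sites$pos, sites$ref, sites$alt)
    pk <- siteKey(predictorCalls$chrom, predictorCalls$pos,
                  predictorCalls$ref, predictorCalls$alt)
    predCols <- setdiff(names(predictorCalls), c("chrom", "pos", "ref", "alt"))
    m <- match(key, pk)
    hit <- which(!is.na(m))
    for (i in hit) {
      calls <- unlist(predictorCalls[m[i], predCols, drop = TRUE])
      ann$predictorDeleterious[i] <- predictorConsensus(calls)
    }
  }
  ann
}
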