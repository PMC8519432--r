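# Multi-sample VCF input/output built on vcfR. Records are split into
# biallelic representations and parsimony-trimmed on the way in, so that
# downstream frequency lookups match on exact (chrom, pos, ref, alt).

#' Read a multi-sample VCF into a TrioCalls object
#'
#' Reads a VCF (v4.2; plain or gzipped) with GT, AD, DP and GQ FORMAT
#' fields, splits multiallelic records into biallelic sites (projecting
#' per-alt allele depths), parsimony-trims alleles, and returns a
#' [TrioCalls-class]. Missing FORMAT values become `NA`, never fabricated
#' zeros. Biallelic records take a vectorized fast path; only multiallelic
#' records are processed one by one.
#'
#' @param path VCF path.
#' @param pedigree optional [TrioPedigree-class]; when supplied, all three
#'   trio samples must be present in the VCF header or an error is raised.
#' @return a [TrioCalls-class] with one row per record-alt.
#' @export
readTrioVcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (!is.null(pedigree)) {
    need <- c(pedigree@probandId, pedigree@fatherId, pedigree@motherId)
    miss <- setdiff(need, samples)
    if (length(miss))
      stop(sprintf("sample not in VCF: %s (file %s)",
                   paste(miss, collapse = ", "), path))
  }
  fix <- v@fix
  n <- nrow(fix)
  emptyCalls <- function() {
    e <- matrix(NA_integer_, 0, length(samples), dimnames = list(NULL, samples))
    g <- matrix(NA_character_, 0, length(samples), dimnames = list(NULL, samples))
    TrioCalls(data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         id = character()), g, e, e, e, e)
  }
  if (n == 0) return(emptyCalls())

  gtm <- vcfR::extract.gt(v, element = "GT")
  adm <- vcfR::extract.gt(v, element = "AD")
  dpm <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gqm <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  fixDim <- function(m, proto) {
    if (is.null(m)) m <- matrix(proto, n, length(samples))
    colnames(m) <- samples
    m
  }
  gtm <- fixDim(gtm, NA_character_); adm <- fixDim(adm, NA_character_)
  dpm <- fixDim(dpm, NA_real_);      gqm <- fixDim(gqm, NA_real_)
  badGt <- !is.na(gtm) & !grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))*$", gtm)
  if (any(badGt)) {
    w <- which(badGt, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed GT '%s' for sample %s at %s:%s in %s",
                 gtm[w[1], w[2]], samples[w[2]],
                 fix[w[1], "CHROM"], fix[w[1], "POS"], path))
  }
  # canonical missing genotype is NA (any all-missing dialect: ".", "./.")
  gtm[!is.na(gtm) & grepl("^\\.([/|]\\.)*$", gtm)] <- NA_character_

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)

  blocks <- list()
  if (any(!multi)) {
    i <- which(!multi)
    adRef <- suppressWarnings(
      matrix(as.integer(sub(",.*$", "", adm[i, , drop = FALSE])),
             nrow = length(i)))
    # second AD field (alt depth); "." or absent -> NA
    altField <- sub("^[^,]*", "", adm[i, , drop = FALSE])   # ",a" or ""
    altField <- sub("^,", "", altField)
    altField[altField == ""] <- NA_character_
    adAlt <- suppressWarnings(matrix(as.integer(sub(",.*$", "", altField)),
                                     nrow = length(i)))
    colnames(adRef) <- colnames(adAlt) <- samples
    pos0 <- as.integer(fix[i, "POS"])
    ref0 <- fix[i, "REF"]; alt0 <- fix[i, "ALT"]
    needTrim <- which(nchar(ref0) > 1 & nchar(alt0) > 1)
    for (k in needTrim) {
      tr <- trimAlleles(pos0[k], ref0[k], alt0[k])
      pos0[k] <- tr$pos; ref0[k] <- tr$ref; alt0[k] <- tr$alt
    }
    blocks[[length(blocks) + 1L]] <- list(
      sites = data.frame(chrom = fix[i, "CHROM"], pos = pos0, ref = ref0,
                         alt = alt0, id = fix[i, "ID"],
                         stringsAsFactors = FALSE),
      ord = i,
      gt = gtm[i, , drop = FALSE], adRef = adRef, adAlt = adAlt,
      dp = dpm[i, , drop = FALSE], gq = gqm[i, , drop = FALSE])
  }
  if (any(multi)) {
    for (i in which(multi)) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      ad <- lapply(adm[i, ], function(a) {
        if (is.na(a)) return(NA_integer_)
        suppressWarnings(as.integer(strsplit(a, ",", fixed = TRUE)[[1]]))
      })
      sp <- splitMultiallelic(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                              fix[i, "REF"], alts, gtm[i, ], ad)
      for (s in sp) {
        blocks[[length(blocks) + 1L]] <- list(
          sites = data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref,
                             alt = s$alt, id = fix[i, "ID"],
                             stringsAsFactors = FALSE),
          ord = i,
          gt = matrix(s$gt, 1, dimnames = list(NULL, samples)),
          adRef = matrix(s$adRef, 1), adAlt = matrix(s$adAlt, 1),
          dp = dpm[i, , drop = FALSE], gq = gqm[i, , drop = FALSE])
      }
    }
  }
  sites <- do.call(rbind, lapply(blocks, `[[`, "sites"))
  # preserve original record order (fast-path block first, then multiallelics)
  recOrd <- unlist(lapply(blocks, function(b)
    if (length(b$ord) == nrow(b$sites)) b$ord else rep(b$ord, nrow(b$sites))))
  o <- order(recOrd)
  bindM <- function(field) {
    m <- do.call(rbind, lapply(blocks, `[[`, field))
    dimnames(m) <- list(NULL, samples)
    m[o, , drop = FALSE]
  }
  sites <- sites[o, , drop = FALSE]
  toI <- function(m) { storage.mode(m) <- "integer"; m }
  TrioCalls(sites,
            gt    = bindM("gt"),
            adRef = toI(bindM("adRef")),
            adAlt = toI(bindM("adAlt")),
            dp    = toI(bindM("dp")),
            gq    = toI(bindM("gq")))
}

#' Write a TrioCalls object as a VCF
#'
#' Emits a VCF v4.2 with `GT:AD:DP:GQ` FORMAT. Output is gzip compressed
#' when `path` ends in `.gz`, plain text otherwise. Round-tripping through
#' [readTrioVcf()] reproduces all genotype fields.
#'
#' @param calls a [TrioCalls-class].
#' @param path output path.
#' @param source value for the `##source=` header line.
#' @return `path`, invisibly.
#' @export
writeTrioVcf <- function(calls, path, source = "TrioExome") {
  s <- calls@sites
  samples <- sampleNames(calls)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=", source),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  n <- nrow(s)
  body <- character(0)
  if (n > 0) {
    cols <- lapply(seq_along(samples), function(j) {
      gt <- ifelse(is.na(calls@gt[, j]), "./.", calls@gt[, j])
      ad <- ifelse(is.na(calls@adRef[, j]) & is.na(calls@adAlt[, j]), ".",
                   paste(ifelse(is.na(calls@adRef[, j]), ".", calls@adRef[, j]),
                         ifelse(is.na(calls@adAlt[, j]), ".", calls@adAlt[, j]),
                         sep = ","))
      paste(gt, ad,
            ifelse(is.na(calls@dp[, j]), ".", calls@dp[, j]),
            ifelse(is.na(calls@gq[, j]), ".", calls@gq[, j]), sep = ":")
    })
    body <- do.call(paste, c(list(
      s$chrom, s$pos, ifelse(is.na(s$id) | s$id == "", ".", s$id),
      s$ref, s$alt, ".", "PASS", ".", "GT:AD:DP:GQ"), cols, list(sep = "\t")))
  }
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", samples), collapse = "\t")
  lines <- c(meta, header, body)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  invisible(path)
}
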