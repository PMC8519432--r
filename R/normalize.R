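# Variant representation normalization: parsimony trimming and left
# alignment. Exact allele representation matters because population allele
# frequencies are looked up by (chrom, pos, ref, alt); two spellings of the
# same indel would otherwise miss the table.

#' Per-sample alternate allele fraction
#'
#' `altDepth / (refDepth + altDepth)`. Returns `NA` (undefined) when either
#' depth is missing or both are zero; undefined is a value, not an error,
#' and any filter requiring an allele fraction fails on it.
#'
#' @param adRef,adAlt numeric vectors of reference/alternate read counts.
#' @return numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' alleleFraction(18, 2)   # 0.10
#' alleleFraction(0, 0)    # NA
#' @export
alleleFraction <- function(adRef, adAlt) {
  tot <- adRef + adAlt
  out <- ifelse(is.na(tot) | tot == 0, NA_real_, adAlt / tot)
  out
}

#' Trim shared allele bases (parsimony trimming)
#'
#' Removes shared trailing then leading bases from a (pos, ref, alt)
#' representation, keeping at least one base in each allele (the VCF
#' anchor-base convention for indels). Does not left-shift; see
#' [normalizeVariant()] for full normalization against local sequence
#' context.
#'
#' @param pos 1-based position of the first ref base.
#' @param ref,alt allele strings.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
trimAlleles <- function(pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  # shared trailing bases first
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # then shared leading bases
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize a biallelic variant against local sequence context
#'
#' Parsimony-trims and left-aligns a single (pos, ref, alt) representation:
#' shared trailing then leading bases are removed and indels are shifted to
#' the smallest position that preserves the edited sequence, following the
#' standard left-alignment algorithm. The operation is idempotent.
#'
#' @param pos 1-based position of the first `ref` base, in the coordinate
#'   system of `context`.
#' @param ref,alt allele strings (`ref` must match `context` at `pos`).
#' @param context local reference sequence around the variant.
#' @param contextStart 1-based coordinate of the first `context` base
#'   (default 1), so genomic coordinates can be used directly.
#' @return list with elements `pos`, `ref`, `alt`.
#' @examples
#' # deletion of one A in the AAA run, right-most spelling: shifted to the
#' # first repeat copy (pos 3, TA>T)
#' normalizeVariant(5, "AA", "A", context = "GGTAAAC")
#' @export
normalizeVariant <- function(pos, ref, alt, context, contextStart = 1L) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  off <- pos - contextStart + 1L               # 1-based index into context
  if (off < 1L || off + nchar(ref) - 1L > nchar(context))
    stop("variant does not lie within the supplied reference context")
  if (nzchar(ref) && substr(context, off, off + nchar(ref) - 1L) != ref)
    stop(sprintf("reference context inconsistent with ref allele at pos %d ('%s' vs '%s')",
                 pos, substr(context, off, off + nchar(ref) - 1L), ref))
  repeat {
    changed <- FALSE
    # drop a shared last base; if an allele empties, extend left from context
    if (nchar(ref) > 0 && nchar(alt) > 0 &&
        substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
      changed <- TRUE
      if (!nzchar(ref) || !nzchar(alt)) {
        if (off <= 1L)
          stop("left alignment ran off the supplied context; provide more 5' sequence")
        off <- off - 1L
        base <- substr(context, off, off)
        ref <- paste0(base, ref)
        alt <- paste0(base, alt)
      }
    }
    # drop shared leading bases while both alleles keep >= 2 bases
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      off <- off + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = as.integer(off + contextStart - 1L), ref = ref, alt = alt)
}

#' Split a multiallelic record into biallelic representations
#'
#' One output representation per alternate allele. Per-alt allele depths
#' are projected as (ref count, that alt's count); genotype allele indices
#' equal to the current alt become 1 and any other alternate allele is
#' recoded to 0 for that split record (the sample still shows as a carrier
#' of its own alt in that alt's record). Alleles are parsimony-trimmed
#' (and left-aligned when `context` is supplied).
#'
#' @param chrom,pos,ref chromosome, position and reference allele.
#' @param alts character vector of alternate alleles.
#' @param gt character vector of genotype strings (one per sample).
#' @param ad list (one element per sample) of integer vectors of per-allele
#'   depths `(ref, alt1, alt2, ...)`, or `NULL`.
#' @param context,contextStart optional local reference sequence for left
#'   alignment (see [normalizeVariant()]).
#' @return list with one element per alt: `list(chrom, pos, ref, alt, gt,
#'   adRef, adAlt)`.
#' @export
splitMultiallelic <- function(chrom, pos, ref, alts, gt, ad = NULL,
                              context = NULL, contextStart = 1L) {
  out <- vector("list", length(alts))
  for (k in seq_along(alts)) {
    altK <- alts[k]
    gtK <- vapply(gt, function(g) {
      if (is.na(g)) return(NA_character_)
      sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
      al <- strsplit(g, "[/|]")[[1]]
      al <- vapply(al, function(a) {
        if (a == "." || a == "") "."
        else if (a == as.character(k)) "1"
        else "0"
      }, character(1))
      # canonical unphased order (1/2 -> 0/1 at the alt-1 split record)
      if (sep == "/" && !any(al == ".")) al <- sort(al)
      paste(al, collapse = sep)
    }, character(1), USE.NAMES = FALSE)
    adRefK <- adAltK <- rep(NA_integer_, length(gt))
    if (!is.null(ad)) {
      adRefK <- vapply(ad, function(a) if (length(a) >= 1) a[1] else NA_integer_, integer(1))
      adAltK <- vapply(ad, function(a) if (length(a) >= k + 1) a[k + 1] else NA_integer_, integer(1))
    }
    norm <- if (is.null(context)) trimAlleles(pos, ref, altK)
            else normalizeVariant(pos, ref, altK, context, contextStart)
    out[[k]] <- list(chrom = chrom, pos = norm$pos, ref = norm$ref,
                     alt = norm$alt, gt = gtK, adRef = adRefK, adAlt = adAltK)
  }
  out
}
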