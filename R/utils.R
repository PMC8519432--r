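# Small shared helpers: chromosome name canonicalization, genotype-string
# parsing, sequence utilities. Genotype strings follow VCF conventions
# ("0/0", "0|1", haploid "1", missing "./." or ".").

#' Canonicalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chrX"` and `"X"` compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector of canonical names.
#' @export
canonChrom <- function(x) sub("^chr", "", as.character(x))

#' Is a chromosome the X chromosome?
#'
#' @param x character vector of chromosome names (any `"chr"` dialect).
#' @return logical vector.
#' @export
isChrX <- function(x) toupper(canonChrom(x)) == "X"

## --- genotype string helpers (vectorized over VCF GT strings) ---

.gtSplit <- function(gt) strsplit(as.character(gt), "[/|]")

#' Genotype-string predicates
#'
#' Vectorized helpers over VCF genotype strings (`"0/0"`, `"0|1"`, haploid
#' `"1"`, missing `NA`). `gtAltCount()` returns the number of alternate
#' alleles carried (`NA` for missing calls); `gtPloidy()` the number of
#' alleles; `gtIsValid()` whether the call is non-missing; `gtIsHet()`
#' diploid heterozygous; `gtIsHomRef()` all-reference; `gtIsAltOnly()`
#' hemizygous or homozygous alternate (`"1"` or `"1/1"` dialects).
#'
#' @param gt character vector of genotype strings.
#' @return integer or logical vector, one element per genotype.
#' @export
gtAltCount <- function(gt) {
  al <- .gtSplit(gt)
  vapply(al, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".") || any(a == ""))
      return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

#' @rdname gtAltCount
#' @export
gtPloidy <- function(gt) {
  al <- .gtSplit(gt)
  vapply(al, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == ".") || any(a == ""))
      return(NA_integer_)
    length(a)
  }, integer(1))
}

#' @rdname gtAltCount
#' @export
gtIsValid <- function(gt) !is.na(gtAltCount(gt))

#' @rdname gtAltCount
#' @export
gtIsHet <- function(gt) { p <- gtPloidy(gt); n <- gtAltCount(gt); !is.na(n) & p == 2L & n == 1L }

#' @rdname gtAltCount
#' @export
gtIsHomRef <- function(gt) { n <- gtAltCount(gt); !is.na(n) & n == 0L }

#' @rdname gtAltCount
#' @export
gtIsAltOnly <- function(gt) { p <- gtPloidy(gt); n <- gtAltCount(gt); !is.na(n) & n == p }

## --- sequence helpers ---

# Reverse complement of plain character DNA (vectorized).
revcompChar <- function(x) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  out
}

# Run code with a private RNG stream, restoring the caller's stream after.
withPrivateSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Variant key used across frequency/predictor tables and truth records.
siteKey <- function(chrom, pos, ref, alt) {
  paste(canonChrom(chrom), pos, ref, alt, sep = ":")
}
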