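# Minimal parser for the c. notation subset used by the candidate tables:
# coding SNVs, deletions, duplications, insertions, and intron-offset SNVs
# (c.N+M / c.N-M). Full HGVS grammar (UTR coordinates, complex alleles) is
# out of scope.

#' Parse an HGVS-lite c. description
#'
#' Supported forms: `c.1861C>T`, `c.1826delA`, `c.128_130delTGG`,
#' `c.6592_6597dupCTGCAG`, `c.100_101insTT`, and intron-offset
#' substitutions such as `c.237+1G>T`.
#'
#' @param x a single c. string.
#' @return list with elements `kind` (`"snv"`, `"del"`, `"dup"`, `"ins"`,
#'   `"intronic"`), `cdsPos` (first affected CDS position; for `dup`/`ins`
#'   the insertion point, i.e. the position the new sequence precedes),
#'   `ref`, `alt` (event alleles, `""` where empty), and for intronic
#'   variants `exonEdge` (the CDS position of the exon boundary) and
#'   `offset` (signed intron offset).
#' @examples
#' parseCdna("c.1861C>T")
#' parseCdna("c.128_130delTGG")
#' @export
parseCdna <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", x))[[1]]
  if (length(m))
    return(list(kind = "snv", cdsPos = as.integer(m[2]), ref = m[3], alt = m[4]))
  m <- regmatches(x, regexec("^c\\.(\\d+)([+-])(\\d+)([ACGT])>([ACGT])$", x))[[1]]
  if (length(m))
    return(list(kind = "intronic", exonEdge = as.integer(m[2]),
                offset = as.integer(m[4]) * if (m[3] == "+") 1L else -1L,
                ref = m[5], alt = m[6]))
  m <- regmatches(x, regexec("^c\\.(\\d+)(?:_(\\d+))?del([ACGT]*)$", x))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- if (nzchar(m[3])) as.integer(m[3]) else s
    return(list(kind = "del", cdsPos = s, ref = m[4], alt = "", end = e))
  }
  m <- regmatches(x, regexec("^c\\.(\\d+)(?:_(\\d+))?dup([ACGT]+)$", x))[[1]]
  if (length(m)) {
    s <- as.integer(m[2])
    e <- if (nzchar(m[3])) as.integer(m[3]) else s
    return(list(kind = "dup", cdsPos = e + 1L, ref = "", alt = m[4],
                dupStart = s, dupEnd = e))
  }
  m <- regmatches(x, regexec("^c\\.(\\d+)_(\\d+)ins([ACGT]+)$", x))[[1]]
  if (length(m))
    return(list(kind = "ins", cdsPos = as.integer(m[3]), ref = "", alt = m[4]))
  stop(sprintf("unsupported c. notation: '%s'", x))
}

#' Apply a parsed c. event to a transcript model
#'
#' Convenience wrapper: parses `cdna` and runs [classifyCodingChange()]
#' (for coding events) or reports the splice/intronic region (for
#' intron-offset events, via the exon structure).
#'
#' @param tx a [TranscriptModel-class].
#' @param cdna a c. string accepted by [parseCdna()].
#' @return one-row data.frame as from [classifyCodingChange()], with an
#'   extra column `region`; intron-offset events within 2 nt of the exon
#'   boundary yield `region = "splice_site"` and consequence
#'   `"splice_site"`.
#' @export
classifyCdna <- function(tx, cdna) {
  ev <- parseCdna(cdna)
  if (ev$kind == "intronic") {
    reg <- if (abs(ev$offset) <= 2) "splice_site" else "intronic"
    return(data.frame(consequence = if (reg == "splice_site") "splice_site" else "unknown",
                      proteinChange = NA_character_, cdnaChange = cdna,
                      codon = cdsCodonIndex(ev$exonEdge)$codon, region = reg,
                      stringsAsFactors = FALSE))
  }
  ref <- ev$ref
  if (ev$kind == "del" && !nzchar(ref))   # deleted bases not spelled out
    ref <- substr(tx@cds, ev$cdsPos, ev$end)
  out <- classifyCodingChange(tx, ev$cdsPos, ref, ev$alt)
  out$region <- "coding"
  out
}
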