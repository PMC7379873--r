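#' Reduce a polyploid allele call to a two-symbol diploid consensus
#'
#' Collapses the called alleles at one site to a presence-based diploid
#' genotype so polyploids and diploids can enter the same structure-type
#' analysis: `"AATT"` becomes `"AT"`.  Dosage is discarded; one distinct
#' allele is doubled (`"AAAA"` -> `"AA"`); with more than two distinct
#' alleles the two most frequent are kept, ties broken alphabetically.
#'
#' @param call allele call: character vector of alleles or a string such
#'   as `"AATT"` / `"A/A/T/T"`; sizes 1-8 cover ploidies 2x-8x.
#' @return two-character genotype string with alleles in alphabetical
#'   order, or `NA` for a fully missing call.
#' @examples
#' reduce_to_diploid("AATT")   # "AT"
#' reduce_to_diploid("AAGT")   # "AG": A most frequent, then G before T
#' @export
reduce_to_diploid <- function(call) {
  al <- if (is.character(call) && length(call) > 1) toupper(call) else parse_genotype(call)
  al <- al[al %in% DNA_BASES]
  if (length(al) == 0) return(NA_character_)
  if (length(al) > 8) stop("allele call exceeds ploidy 8")
  tab <- sort(table(al), decreasing = TRUE)
  distinct <- names(tab)
  if (length(distinct) == 1) return(paste0(distinct, distinct))
  if (length(distinct) > 2) {
    # keep the two most frequent; resolve frequency ties alphabetically
    counts <- as.integer(tab)
    ord <- order(-counts, distinct)
    distinct <- distinct[ord][1:2]
  }
  paste(sort(distinct), collapse = "")
}

#' IUPAC ambiguity consensus of an allele call
#'
#' Encodes the distinct alleles of one call as the single standard IUPAC
#' symbol (`{A,G}` -> `R`, `{A,C,G,T}` -> `N`); a homozygous call returns
#' its allele.
#'
#' @param call as in [reduce_to_diploid()].
#' @return single-character IUPAC symbol, or `NA` for a missing call.
#' @export
iupac_consensus <- function(call) {
  al <- if (is.character(call) && length(call) > 1) toupper(call) else parse_genotype(call)
  al <- al[al %in% DNA_BASES]
  if (length(al) == 0) return(NA_character_)
  key <- allele_key(al)
  if (nchar(key) == 1) key else unname(.iupac_rev[key])
}

#' Diploidize a mixed-ploidy genotype matrix
#'
#' Applies [reduce_to_diploid()] to every cell of a samples-by-sites
#' genotype matrix whose rows may have different ploidies; diploid calls
#' pass through (re-ordered alphabetically).  Optionally thins to
#' unlinked SNPs (uSNPs): one site per locus, the first polymorphic site
#' in coordinate order.  Polymorphism for uSNP selection can be judged
#' before or after reduction.
#'
#' @param geno samples-by-sites character matrix of allele-call strings
#'   (e.g. `"AG"` for a diploid, `"AATT"` for a tetraploid; `NA` missing).
#' @param ploidy named integer vector, sample -> ploidy; samples absent
#'   from it raise an error.
#' @param locus optional character vector, one locus id per column,
#'   required for `usnp = TRUE`.
#' @param usnp keep only the first polymorphic site of each locus.
#' @param usnp_before_reduction judge polymorphism on the original calls
#'   (`TRUE`, default) or on the reduced matrix (`FALSE`).
#' @return character matrix of two-symbol diploid genotypes (columns
#'   subset when `usnp = TRUE`).
#' @export
reduce_matrix <- function(geno, ploidy, locus = NULL, usnp = FALSE,
                          usnp_before_reduction = TRUE) {
  if (is.null(rownames(geno))) stop("genotype matrix must have sample rownames")
  missing_pl <- setdiff(rownames(geno), names(ploidy))
  if (length(missing_pl))
    stop("unknown ploidy for samples: ", paste(missing_pl, collapse = ", "))
  if (usnp && is.null(locus))
    stop("uSNP selection requires per-column locus ids")
  if (!is.null(locus) && length(locus) != ncol(geno))
    stop("locus vector must have one id per matrix column")

  reduced <- geno
  for (i in seq_len(nrow(geno))) {
    reduced[i, ] <- vapply(geno[i, ], function(g) {
      if (is.na(g)) NA_character_ else reduce_to_diploid(g)
    }, "", USE.NAMES = FALSE)
  }

  if (!usnp) return(reduced)
  judge <- if (usnp_before_reduction) geno else reduced
  polymorphic <- vapply(seq_len(ncol(judge)), function(j) {
    keys <- vapply(judge[, j], function(g) {
      if (is.na(g)) NA_character_ else allele_key(parse_genotype(g))
    }, "", USE.NAMES = FALSE)
    keys <- keys[!is.na(keys)]
    length(unique(unlist(strsplit(keys, "")))) > 1
  }, TRUE)
  keep <- !duplicated(locus) & polymorphic
  # first *polymorphic* site per locus, not merely the first site
  keep <- vapply(seq_len(ncol(judge)), function(j) {
    polymorphic[j] && !any(polymorphic[seq_len(j - 1L)][locus[seq_len(j - 1L)] == locus[j]])
  }, TRUE)
  reduced[, keep, drop = FALSE]
}
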