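DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> sorted base string, and its inverse, derived once from
# Biostrings so the two directions cannot drift apart.
.iupac_map <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  vapply(m, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""), "")
})
.iupac_rev <- local({
  stats::setNames(names(.iupac_map), .iupac_map)
})

#' Expand an IUPAC symbol to its base set
#'
#' @param x single-character IUPAC nucleotide symbol.
#' @return character vector of the bases the symbol denotes (empty for
#'   unrecognised symbols such as `-` or `.`).
#' @examples
#' iupac_bases("R")
#' @export
iupac_bases <- function(x) {
  stopifnot(length(x) == 1L)
  s <- .iupac_map[toupper(x)]
  if (is.na(s)) character(0) else strsplit(s, "")[[1]]
}

# Canonical sorted-distinct-allele string for a vector of alleles ("GA" -> "AG")
allele_key <- function(alleles) {
  paste(sort(unique(alleles)), collapse = "")
}

# Parse a genotype string like "A/A/G/G" (or "AAGG") into an allele vector;
# returns NULL for missing (NA, ".", "./.", "").
parse_genotype <- function(gt) {
  if (length(gt) == 0 || is.na(gt)) return(NULL)
  al <- strsplit(gsub("[/|]", "", toupper(gt)), "")[[1]]
  al <- al[al != "."]
  if (length(al) == 0) return(NULL)
  al
}

# Draw a base different from `base`, uniformly among the other three.
mutate_base <- function(base, n = length(base)) {
  other <- vapply(base, function(b) {
    sample(DNA_BASES[DNA_BASES != b], 1L)
  }, "")
  unname(other)
}

# Derive a per-stage sub-seed from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
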