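# Independent brute-force evaluator of the SNP category rules, written as a
# literal transcription of the category definitions.  Used to check
# classify_site() over the complete finite genotype space.
oracle_classify <- function(ref, p2_alleles, tet_alleles) {
  P1 <- ref
  P2 <- unique(p2_alleles)
  TT <- unique(tet_alleles)
  # parents heterozygous, or more than two alleles in the polyploid -> other
  if (length(P2) != 1L) return("OTHER")
  if (length(TT) > 2L) return("OTHER")
  # variation in the tetraploid not identified between the parental genomes
  if (any(!(TT %in% c(P1, P2)))) return("CAT34")
  # heterozygous for the homeologous alleles of both parental genomes
  if (P1 != P2 && setequal(TT, c(P1, P2))) return("CAT5")
  # allele identical with only one of the parental species
  if (P1 != P2 && setequal(TT, P1)) return("CAT1")
  if (P1 != P2 && setequal(TT, P2)) return("CAT2")
  "invariant"
}

BASES <- c("A", "C", "G", "T")

# Every (ref, ordered parent-2 pair, ordered tetraploid 4-tuple) combination.
enumerate_genotype_space <- function() {
  p2 <- expand.grid(a = BASES, b = BASES, stringsAsFactors = FALSE)
  tet <- expand.grid(a = BASES, b = BASES, c = BASES, d = BASES,
                     stringsAsFactors = FALSE)
  list(ref = BASES, p2 = p2, tet = tet)
}
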