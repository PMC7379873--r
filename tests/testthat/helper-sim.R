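# Build an in-memory site-call table straight from simulated objects
# (ample depth, no missingness), bypassing file emission, for fast
# parameter-recovery runs.
make_calls_from_sim <- function(parents, tet, depth = 100) {
  f1 <- radploid:::flatten_loci(parents$parent1)
  f2 <- radploid:::flatten_loci(parents$parent2)
  p2h <- radploid:::consensus_haplotypes(f2$flat)
  p2key <- radploid:::column_allele_key(p2h)
  tkey <- radploid:::column_allele_key(tet$alleles)
  # restrict to sites where anything varies relative to the reference
  poly <- !(f1$flat == p2key & f1$flat == tkey)
  p2gt <- apply(p2h[, poly, drop = FALSE], 2, paste, collapse = "/")
  tetgt <- apply(tet$alleles[, poly, drop = FALSE], 2, paste, collapse = "/")
  data.frame(locus_id = f1$locus_id[poly],
             pos = which(poly),
             ref_base = f1$flat[poly],
             parent2 = p2gt,
             tetraploid = tetgt,
             depth_parent2 = depth,
             depth_tetraploid = depth,
             stringsAsFactors = FALSE)
}

# Truth joined with assigned categories, by (locus, offset) key.
# Global positions are translated back to within-locus offsets first.
join_truth <- function(table, parents, truth) {
  ref <- build_pseudoreference(parents$parent1)
  loc <- map_coordinate(ref, table$sites$pos)
  assigned <- data.frame(locus_id = loc$locus_id, offset = loc$offset,
                         category = table$sites$category,
                         stringsAsFactors = FALSE)
  merge(assigned, truth, by = c("locus_id", "offset"), all = TRUE)
}
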