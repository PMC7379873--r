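#' Configuration for the synthetic allopolyploid RAD-data generator
#'
#' Bundles and validates every tunable of the simulator.  Defaults emulate
#' the RAD-locus characteristics of a shrub-willow style reduced
#' representation dataset: 86 bp consensus loci, read depths around 52
#' (negative-binomially overdispersed), at most 20 SNPs per locus and at
#' most 4 alleles per site.
#'
#' @param n_loci number of RAD loci to simulate (>= 1).
#' @param locus_length locus length in bp (default 86).
#' @param parent_divergence per-site probability that the two diploid parent
#'   lineages carry different alleles.
#' @param post_origin_rate per-site probability of a mutation in the
#'   tetraploid after the polyploidization event (hits one of its four
#'   allele copies).
#' @param backcross_fraction fraction of tetraploid loci whose alleles from
#'   one parental subgenome are replaced by haplotypes of the other parent,
#'   modelling post-origin backcrossing/introgression.
#' @param backcross_direction which subgenome is overwritten in a
#'   backcrossed locus: `"parent1"` replaces the parent-2 subgenome by
#'   parent-1 haplotypes (sites become CAT1), `"parent2"` the converse
#'   (CAT2), `"both"` picks a direction per locus at random.
#' @param parental_het per-site probability that a diploid parent is
#'   heterozygous (IUPAC-coded in its consensus); populates the OTHER
#'   category.
#' @param missing_rate per-sample, per-locus dropout probability.
#' @param depth_mean mean simulated read depth per position (default 52).
#' @param depth_dispersion negative-binomial size parameter for depth
#'   overdispersion.
#' @param max_snps_per_locus locus cap on segregating sites; violating loci
#'   are redrawn.
#' @param max_alleles_per_site site cap on distinct alleles (<= 4).
#' @param seed integer RNG seed; identical config and seed give
#'   byte-identical outputs.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 1000L,
                              locus_length = 86L,
                              parent_divergence = 0.01,
                              post_origin_rate = 0.002,
                              backcross_fraction = 0,
                              backcross_direction = c("parent1", "parent2", "both"),
                              parental_het = 0,
                              missing_rate = 0,
                              depth_mean = 52,
                              depth_dispersion = 10,
                              max_snps_per_locus = 20L,
                              max_alleles_per_site = 4L,
                              seed = 1L) {
  backcross_direction <- match.arg(backcross_direction)
  probs <- c(parent_divergence = parent_divergence,
             post_origin_rate = post_origin_rate,
             backcross_fraction = backcross_fraction,
             parental_het = parental_het,
             missing_rate = missing_rate)
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad))
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  if (n_loci < 1 || locus_length < 1)
    stop("n_loci and locus_length must be >= 1")
  if (depth_mean <= 0 || depth_dispersion <= 0)
    stop("depth parameters must be positive")
  structure(list(n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 parent_divergence = parent_divergence,
                 post_origin_rate = post_origin_rate,
                 backcross_fraction = backcross_fraction,
                 backcross_direction = backcross_direction,
                 parental_het = parental_het,
                 missing_rate = missing_rate,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 max_snps_per_locus = as.integer(max_snps_per_locus),
                 max_alleles_per_site = as.integer(max_alleles_per_site),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Split a consensus sequence vector into two haplotype site vectors.
# Unambiguous symbols are copied to both haplotypes; two-base IUPAC codes
# are split into their bases (phase is arbitrary and irrelevant downstream:
# only allele sets are consumed).
consensus_haplotypes <- function(flat) {
  h1 <- flat
  h2 <- flat
  amb <- !(flat %in% DNA_BASES)
  if (any(amb)) {
    pieces <- lapply(flat[amb], iupac_bases)
    h1[amb] <- vapply(pieces, function(b) b[1], "")
    h2[amb] <- vapply(pieces, function(b) b[min(2L, length(b))], "")
  }
  rbind(h1, h2)
}

# Flatten a rad_locus_set into one site-per-element character vector plus a
# locus index; loci are taken in stored order.
flatten_loci <- function(x) {
  lens <- nchar(x$sequences)
  list(flat = strsplit(paste(x$sequences, collapse = ""), "")[[1]],
       locus_id = rep(names(x$sequences), lens),
       offset = unlist(lapply(lens, seq_len), use.names = FALSE),
       lens = lens)
}

# Rebuild per-locus sequences from a flat site vector.
unflatten_loci <- function(flat, lens, ids) {
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  stats::setNames(vapply(seq_along(lens), function(i) {
    paste(flat[starts[i]:ends[i]], collapse = "")
  }, ""), ids)
}

# Distinct sorted-allele key per column of an allele matrix, vectorized.
column_allele_key <- function(mat) {
  key <- character(ncol(mat))
  for (b in DNA_BASES) {
    key <- paste0(key, ifelse(colSums(mat == b) > 0, b, ""))
  }
  key
}

iupac_from_key <- function(key) {
  out <- .iupac_rev[key]
  out[key %in% DNA_BASES] <- key[key %in% DNA_BASES]
  unname(out)
}

#' Simulate two diverged diploid parent lineages
#'
#' Draws an ancestral sequence per locus and derives parent 2 by per-site
#' substitution with probability `parent_divergence` (uniform among the
#' three alternative bases, Jukes-Cantor style; no indels).  Optional
#' parental heterozygosity introduces IUPAC ambiguity codes into the
#' consensus sequences.  Loci exceeding `max_snps_per_locus` segregating
#' sites are redrawn so emitted loci respect the assembly-style caps.
#'
#' @param config a [simulation_config()].
#' @return list with elements `ancestral`, `parent1`, `parent2`, each a
#'   [rad_locus_set()] over identical locus ids and lengths.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_loci
  len <- config$locus_length
  ids <- sprintf("locus_%06d", seq_len(n))

  draw_block <- function(n_sites) {
    anc <- sample(DNA_BASES, n_sites, replace = TRUE)
    p2 <- anc
    div <- runif(n_sites) < config$parent_divergence
    if (any(div)) p2[div] <- mutate_base(anc[div])
    p1h2 <- anc
    het1 <- runif(n_sites) < config$parental_het
    if (any(het1)) p1h2[het1] <- mutate_base(anc[het1])
    p2h2 <- p2
    het2 <- runif(n_sites) < config$parental_het
    if (any(het2)) p2h2[het2] <- mutate_base(p2[het2])
    list(anc = anc, p1 = rbind(anc, p1h2), p2 = rbind(p2, p2h2))
  }

  blk <- draw_block(n * len)
  locus_of <- rep(seq_len(n), each = len)
  # enforce the per-locus segregating-site cap by redrawing violating loci
  for (iter in seq_len(100L)) {
    seg <- column_allele_key(rbind(blk$p1, blk$p2))
    n_seg <- tapply(nchar(seg) > 1L, locus_of, sum)
    bad <- which(n_seg > config$max_snps_per_locus)
    if (length(bad) == 0) break
    sites <- which(locus_of %in% bad)
    redo <- draw_block(length(sites))
    blk$anc[sites] <- redo$anc
    blk$p1[, sites] <- redo$p1
    blk$p2[, sites] <- redo$p2
  }

  lens <- rep(len, n)
  to_set <- function(hap) {
    rad_locus_set(unflatten_loci(iupac_from_key(column_allele_key(hap)),
                                 lens, ids))
  }
  list(ancestral = rad_locus_set(unflatten_loci(blk$anc, lens, ids)),
       parent1 = to_set(blk$p1),
       parent2 = to_set(blk$p2))
}

#' Simulate an allotetraploid from two diploid parents
#'
#' Constructs an F1 allotetraploid carrying two allele copies from each
#' parent at every locus, then (i) replaces one parental subgenome by the
#' other parent's haplotypes in a `backcross_fraction` of loci and (ii)
#' applies post-origin mutations at `post_origin_rate` per site (one of the
#' four copies mutates to a different base).  A ground-truth table records,
#' for every polymorphic site, the category a classifier comparing the
#' tetraploid against parent 1 (reference) and parent 2 should assign, and
#' the generating event.
#'
#' @param parent1,parent2 [rad_locus_set()]s over identical locus ids and
#'   lengths (parent 1 is the pseudo-reference parent).
#' @param config a [simulation_config()].
#' @return an object of class `tetraploid_sim`: list with `alleles`
#'   (4 x n_sites character matrix of the tetraploid's allele copies),
#'   `locus_id`/`offset` site index, `truth` (data.frame `locus_id`,
#'   `offset`, `true_category`, `event`), and `backcross` (per-locus
#'   direction, `NA` if not backcrossed).
#' @export
simulate_allotetraploid <- function(parent1, parent2, config) {
  stopifnot(inherits(parent1, "rad_locus_set"),
            inherits(parent2, "rad_locus_set"),
            inherits(config, "simulation_config"))
  if (!identical(names(parent1$sequences), names(parent2$sequences)))
    stop("parents must share identical locus ids")
  if (!identical(nchar(parent1$sequences), nchar(parent2$sequences)))
    stop("parents must share identical locus lengths")
  set.seed(derive_seed(config$seed, 2L))

  f1 <- flatten_loci(parent1)
  f2 <- flatten_loci(parent2)
  n_sites <- length(f1$flat)
  n_loci <- length(f1$lens)
  ids <- names(parent1$sequences)
  locus_of <- rep(seq_len(n_loci), f1$lens)

  p1h <- consensus_haplotypes(f1$flat)
  p2h <- consensus_haplotypes(f2$flat)
  tet <- rbind(p1h, p2h)

  # backcrossing: overwrite one subgenome per selected locus
  bc <- rep(NA_character_, n_loci)
  sel <- runif(n_loci) < config$backcross_fraction
  if (any(sel)) {
    dirs <- switch(config$backcross_direction,
                   parent1 = rep("parent1", sum(sel)),
                   parent2 = rep("parent2", sum(sel)),
                   both = sample(c("parent1", "parent2"), sum(sel), replace = TRUE))
    bc[sel] <- dirs
    to_p1 <- locus_of %in% which(bc == "parent1")
    to_p2 <- locus_of %in% which(bc == "parent2")
    tet[3:4, to_p1] <- p1h[, to_p1]
    tet[1:2, to_p2] <- p2h[, to_p2]
  }

  # post-origin mutations, redrawn per locus if they break the SNP cap
  pre_mut <- tet
  apply_mutations <- function(tet, sites) {
    hit <- sites[runif(length(sites)) < config$post_origin_rate]
    if (length(hit)) {
      copy <- sample(4L, length(hit), replace = TRUE)
      idx <- cbind(copy, hit)
      tet[idx] <- mutate_base(tet[idx])
    }
    tet
  }
  tet <- apply_mutations(tet, seq_len(n_sites))
  for (iter in seq_len(100L)) {
    seg <- column_allele_key(rbind(p1h, p2h, tet))
    n_seg <- tapply(nchar(seg) > 1L, locus_of, sum)
    bad <- which(n_seg > config$max_snps_per_locus)
    if (length(bad) == 0) break
    sites <- which(locus_of %in% bad)
    tet[, sites] <- pre_mut[, sites]
    if (iter == 99L) break  # give up mutating these loci; caps win
    tet <- apply_mutations(tet, sites)
  }

  truth <- derive_truth(p1h, p2h, tet, f1$locus_id, f1$offset, bc[locus_of])
  structure(list(alleles = tet,
                 locus_id = f1$locus_id,
                 offset = f1$offset,
                 lens = f1$lens,
                 locus_ids = ids,
                 truth = truth,
                 backcross = stats::setNames(bc, ids)),
            class = "tetraploid_sim")
}

# Ground-truth category per site from the true allele configurations.
# p1h/p2h: 2 x n parental haplotype matrices; tet: 4 x n tetraploid copies.
derive_truth <- function(p1h, p2h, tet, locus_id, offset, bc_site) {
  p1k <- column_allele_key(p1h)
  p2k <- column_allele_key(p2h)
  tk <- column_allele_key(tet)
  n <- length(p1k)

  het_parent <- nchar(p1k) > 1L | nchar(p2k) > 1L
  nt <- nchar(tk)
  # does the tetraploid carry an allele absent from both parents?
  novel <- rep(FALSE, n)
  for (b in DNA_BASES) {
    in_tet <- colSums(tet == b) > 0
    novel <- novel | (in_tet & p1k != b & p2k != b & !het_parent &
                        !grepl(b, p1k, fixed = TRUE) & !grepl(b, p2k, fixed = TRUE))
  }
  pairk <- ifelse(p1k < p2k, paste0(p1k, p2k), paste0(p2k, p1k))

  cat <- rep(NA_character_, n)
  ev <- rep(NA_character_, n)
  hom <- !het_parent
  cat[het_parent] <- "OTHER"; ev[het_parent] <- "divergence"
  i <- hom & novel & nt <= 2L
  cat[i] <- "CAT34"; ev[i] <- "post_origin"
  i <- hom & novel & nt > 2L
  cat[i] <- "OTHER"; ev[i] <- "post_origin"
  disc <- hom & !novel & p1k != p2k
  i <- disc & tk == pairk
  cat[i] <- "CAT5"; ev[i] <- "divergence"
  i <- disc & tk == p1k
  cat[i] <- "CAT1"
  ev[i] <- ifelse(bc_site[i] %in% "parent1", "backcross", "post_origin")
  i <- disc & tk == p2k
  cat[i] <- "CAT2"
  ev[i] <- ifelse(bc_site[i] %in% "parent2", "backcross", "post_origin")
  # anything still uncategorised at a polymorphic site (e.g. 3 parental +
  # tetraploid alleles combinations) falls through to OTHER
  poly <- nchar(column_allele_key(rbind(p1h, p2h, tet))) > 1L
  i <- poly & is.na(cat)
  cat[i] <- "OTHER"; ev[i] <- "divergence"

  keep <- poly
  data.frame(locus_id = locus_id[keep],
             offset = offset[keep],
             true_category = cat[keep],
             event = ev[keep],
             stringsAsFactors = FALSE)
}

#' Simulate polarized quartet sites for a hybrid with known admixture
#'
#' Generates `n_sites` informative sites for the ordered quartet
#' (outgroup, P1, hybrid, P2): at every site the two parents carry
#' different alleles and the outgroup carries the P1-ancestral state; the
#' hybrid's allele derives from P2 with probability `gamma`, else from P1.
#'
#' @param gamma true admixture proportion in `[0,1]` (0 = identical to P1,
#'   1 = identical to P2).
#' @param n_sites number of informative sites.
#' @param seed integer RNG seed.
#' @return a `quartet_sim`: 4 x n_sites character matrix with rows
#'   `outgroup`, `P1`, `H`, `P2`; the true gamma is stored in
#'   `attr(, "true_gamma")`.
#' @export
simulate_quartet_sites <- function(gamma, n_sites, seed = 1L) {
  if (is.na(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0,1]")
  set.seed(derive_seed(seed, 4L))
  a <- sample(DNA_BASES, n_sites, replace = TRUE)
  b <- mutate_base(a)
  h <- ifelse(runif(n_sites) < gamma, b, a)
  m <- rbind(outgroup = a, P1 = a, H = h, P2 = b)
  attr(m, "true_gamma") <- gamma
  class(m) <- c("quartet_sim", class(m))
  m
}
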