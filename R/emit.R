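#' Write simulated data as the standard pipeline inputs
#'
#' Emits the files a mapping/variant-calling stage would produce from the
#' simulated samples: the parent-1 pseudo-reference (FASTA + offset TSV),
#' one VCF v4.2 per non-reference sample (genotypes with four allele calls
#' for the tetraploid, two for the diploid parent 2), one per-position
#' read-depth TSV per sample (`contig`, 1-based `pos`, `depth`), and the
#' ground-truth category TSV.  Depth is drawn negative-binomially around
#' `depth_mean`; whole-locus dropout is applied per sample at
#' `missing_rate` (dropped loci appear in neither the VCF nor the depth
#' table of that sample).
#'
#' @param parents result of [simulate_parents()].
#' @param tetraploid result of [simulate_allotetraploid()].
#' @param config the [simulation_config()] used to simulate.
#' @param dir output directory (created if needed).
#' @return named list of paths (`reference`, `offsets`, `parent2_vcf`,
#'   `tetraploid_vcf`, `parent2_depth`, `tetraploid_depth`, `truth`) plus
#'   the in-memory `pseudo_reference`.
#' @export
emit_files <- function(parents, tetraploid, config, dir = tempfile("radsim")) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(tetraploid, "tetraploid_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(derive_seed(config$seed, 3L))

  ref <- build_pseudoreference(parents$parent1)
  paths <- write_pseudoreference(ref, file.path(dir, "reference.fasta"))

  f2 <- flatten_loci(parents$parent2)
  p2_alleles <- consensus_haplotypes(f2$flat)
  tet_alleles <- tetraploid$alleles
  n_sites <- length(f2$flat)
  gpos <- global_position(ref, f2$locus_id, f2$offset)
  ref_flat <- strsplit(ref$sequence, "")[[1]][gpos]
  n_loci <- length(f2$lens)
  locus_of <- rep(seq_len(n_loci), f2$lens)

  emit_sample <- function(alleles, name) {
    drop_locus <- runif(n_loci) < config$missing_rate
    present <- !drop_locus[locus_of]
    depth <- rnbinom(sum(present), mu = config$depth_mean,
                     size = config$depth_dispersion)
    depth_path <- file.path(dir, paste0(name, "_depth.tsv"))
    utils::write.table(
      data.frame(contig = ref$contig, pos = gpos[present], depth = depth),
      depth_path, sep = "\t", quote = FALSE, row.names = FALSE)

    is_var <- present & column_allele_key(alleles) != ref_flat
    vcf_path <- file.path(dir, paste0(name, ".vcf"))
    write_sample_vcf(vcf_path, ref, name,
                     pos = gpos[is_var],
                     ref_base = ref_flat[is_var],
                     alleles = alleles[, is_var, drop = FALSE])
    c(vcf = vcf_path, depth = depth_path)
  }

  p2_paths <- emit_sample(p2_alleles, "parent2")
  tet_paths <- emit_sample(tet_alleles, "tetraploid")

  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(tetraploid$truth, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(reference = unname(paths["fasta"]),
       offsets = unname(paths["offsets"]),
       parent2_vcf = unname(p2_paths["vcf"]),
       parent2_depth = unname(p2_paths["depth"]),
       tetraploid_vcf = unname(tet_paths["vcf"]),
       tetraploid_depth = unname(tet_paths["depth"]),
       truth = truth_path,
       pseudo_reference = ref)
}

# Minimal single-sample VCF v4.2 writer: substitution records with GT only.
# alleles: ploidy x n_records character matrix of called allele copies.
write_sample_vcf <- function(path, ref, sample_name, pos, ref_base, alleles) {
  header <- c("##fileformat=VCFv4.2",
              "##source=radploid-simulator",
              sprintf("##contig=<ID=%s,length=%d>", ref$contig, nchar(ref$sequence)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_name), collapse = "\t"))
  lines <- header
  if (length(pos)) {
    alt <- character(length(pos))
    gt <- character(length(pos))
    for (i in seq_along(pos)) {
      al <- alleles[, i]
      alts <- sort(setdiff(unique(al), ref_base[i]))
      codes <- match(al, c(ref_base[i], alts)) - 1L
      alt[i] <- if (length(alts)) paste(alts, collapse = ",") else "."
      gt[i] <- paste(sort(codes), collapse = "/")
    }
    lines <- c(lines,
               paste(ref$contig, pos, ".", ref_base, alt, ".", "PASS", ".",
                     "GT", gt, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-position depth table
#'
#' @param path TSV with columns `contig`, `pos` (1-based), `depth`.
#' @return data.frame with those columns.
#' @export
read_depth_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "integer", "numeric"))
  if (!all(c("contig", "pos", "depth") %in% names(d)))
    stop("depth table must have columns contig, pos, depth: ", path)
  d
}

# Extract (pos, genotype string) per record from a single-sample VCF,
# skipping indel records.  Genotype strings are allele letters joined by
# "/" (e.g. "A/A/G/G"), or NA for missing calls.
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  is_snp <- nchar(ref) == 1L &
    vapply(strsplit(ifelse(is.na(alt), "", alt), ","),
           function(a) all(nchar(a) <= 1L), TRUE)
  geno <- character(length(pos))
  for (i in seq_along(pos)) {
    if (!is_snp[i]) { geno[i] <- NA_character_; next }
    g <- gt_raw[i, 1]
    if (is.na(g) || g %in% c(".", "./.")) { geno[i] <- NA_character_; next }
    codes <- suppressWarnings(as.integer(strsplit(g, "[/|]")[[1]]))
    allele_set <- c(ref[i], strsplit(ifelse(is.na(alt[i]), "", alt[i]), ",")[[1]])
    if (anyNA(codes) || any(codes + 1L > length(allele_set))) {
      geno[i] <- NA_character_
    } else {
      geno[i] <- paste(allele_set[codes + 1L], collapse = "/")
    }
  }
  data.frame(pos = pos, ref = ref, genotype = geno, indel = !is_snp,
             stringsAsFactors = FALSE)
}
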