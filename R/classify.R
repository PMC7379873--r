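CATEGORY_LEVELS <- c("CAT1", "CAT2", "CAT34", "CAT5", "OTHER")

#' Classify one SNP site of a tetraploid against its two putative parents
#'
#' Implements the five-way categorization of allotetraploid SNPs relative
#' to a pseudo-reference built from parent 1 and the genotype of parent 2:
#'
#' * `CAT1` / `CAT2` — interspecific SNPs: the tetraploid carries only the
#'   allele of one parent (`CAT1` = reference parent 1, `CAT2` = parent 2).
#' * `CAT34` — derived SNPs: the tetraploid shows variation not present
#'   between the parental genomes (post-origin mutation).
#' * `CAT5` — homeo-SNPs: the tetraploid is heterozygous for the
#'   homeologous alleles of both parents.
#' * `OTHER` — everything else: heterozygous parents, ambiguous reference
#'   base, or more than two distinct tetraploid alleles.
#'
#' Sites where parent 1, parent 2 and the tetraploid all share one allele
#' are invariant and excluded from category denominators.  Allelic dosage
#' is ignored: only the distinct-allele sets enter the rules.
#'
#' @param ref_base parent-1 (reference) base at the site; a single symbol.
#' @param parent2 parent-2 genotype: character vector of allele calls or a
#'   string like `"G/G"`; `NA` for missing.
#' @param tetraploid tetraploid genotype: up to four allele calls or a
#'   string like `"A/A/G/G"`; `NA` for missing.
#' @param depth_parent2,depth_tetraploid read depths at the site.
#' @param min_depth minimum depth both samples must reach (default 8, the
#'   base-calling threshold of the upstream assembly).
#' @return list with `category` (one of CAT1, CAT2, CAT34, CAT5, OTHER,
#'   `"invariant"`, or `NA` for skipped sites) and `reason` (a short code;
#'   `"ok"` for classified sites).
#' @examples
#' classify_site("A", "G/G", "A/A/G/G")$category  # homeo-SNP -> CAT5
#' classify_site("A", "A/A", "A/A/T/T")$category  # derived   -> CAT34
#' @export
classify_site <- function(ref_base, parent2, tetraploid,
                          depth_parent2 = Inf, depth_tetraploid = Inf,
                          min_depth = 8) {
  if (is.na(depth_parent2) || is.na(depth_tetraploid) ||
      depth_parent2 < min_depth || depth_tetraploid < min_depth)
    return(list(category = NA_character_, reason = "low_depth"))
  p2 <- if (is.character(parent2) && length(parent2) > 1) parent2 else parse_genotype(parent2)
  tet <- if (is.character(tetraploid) && length(tetraploid) > 1) tetraploid else parse_genotype(tetraploid)
  if (is.null(p2) || is.null(tet))
    return(list(category = NA_character_, reason = "missing_genotype"))
  if (is.na(ref_base) || !(toupper(ref_base) %in% DNA_BASES))
    return(list(category = "OTHER", reason = "ambiguous_reference"))
  if (!all(toupper(p2) %in% DNA_BASES) || !all(toupper(tet) %in% DNA_BASES))
    return(list(category = "OTHER", reason = "non_acgt_allele"))

  p1set <- toupper(ref_base)
  p2set <- sort(unique(toupper(p2)))
  tset <- sort(unique(toupper(tet)))

  if (length(p2set) != 1L)
    return(list(category = "OTHER", reason = "heterozygous_parent"))
  if (length(tset) > 2L)
    return(list(category = "OTHER", reason = "gt2_alleles"))
  if (length(setdiff(tset, c(p1set, p2set))) > 0L)
    return(list(category = "CAT34", reason = "ok"))
  if (p1set == p2set)  # no novel allele, parents identical -> tset == p1set
    return(list(category = "invariant", reason = "invariant"))
  if (setequal(tset, c(p1set, p2set)))
    return(list(category = "CAT5", reason = "ok"))
  if (identical(tset, p1set))
    return(list(category = "CAT1", reason = "ok"))
  list(category = "CAT2", reason = "ok")
}

#' Assemble per-site calls from pseudo-reference, VCFs and depth tables
#'
#' Builds the site-call table the classifier consumes: the union of SNP
#' positions recorded in either sample's VCF, with per-sample genotypes
#' (homozygous-reference where a covered position is absent from a
#' sample's VCF) and per-sample depths looked up from the depth tables.
#' Indel records are carried through flagged so they can be skipped with a
#' reason code.
#'
#' @param ref a `pseudo_reference` (or path handled by
#'   [read_pseudoreference()] callers).
#' @param parent2_vcf,tetraploid_vcf single-sample VCF paths.
#' @param parent2_depth,tetraploid_depth depth TSV paths
#'   (`contig`, `pos`, `depth`).
#' @return data.frame of site calls: `locus_id`, `pos`, `ref_base`,
#'   `parent2`, `tetraploid`, `depth_parent2`, `depth_tetraploid`, `indel`.
#' @export
read_site_calls <- function(ref, parent2_vcf, tetraploid_vcf,
                            parent2_depth, tetraploid_depth) {
  stopifnot(inherits(ref, "pseudo_reference"))
  g2 <- read_vcf_genotypes(parent2_vcf)
  gt <- read_vcf_genotypes(tetraploid_vcf)
  d2 <- read_depth_tsv(parent2_depth)
  dt <- read_depth_tsv(tetraploid_depth)

  pos <- sort(union(g2$pos, gt$pos))
  i2 <- match(pos, g2$pos)
  it <- match(pos, gt$pos)
  dep2 <- d2$depth[match(pos, d2$pos)]
  dept <- dt$depth[match(pos, dt$pos)]
  ref_base <- ref_base_at(ref, pos)

  # a position absent from one sample's VCF but covered in its depth table
  # is an implied homozygous-reference call for that sample (a record that
  # is present but has a missing GT stays missing)
  gt2 <- g2$genotype[i2]
  gtt <- gt$genotype[it]
  fill2 <- is.na(i2) & !is.na(dep2) & ref_base %in% DNA_BASES
  fillt <- is.na(it) & !is.na(dept) & ref_base %in% DNA_BASES
  gt2[fill2] <- ref_base[fill2]
  gtt[fillt] <- ref_base[fillt]

  loc <- map_coordinate(ref, pos)
  data.frame(locus_id = loc$locus_id,
             pos = pos,
             ref_base = ref_base,
             parent2 = gt2,
             tetraploid = gtt,
             depth_parent2 = ifelse(is.na(dep2), 0, dep2),
             depth_tetraploid = ifelse(is.na(dept), 0, dept),
             indel = (!is.na(i2) & g2$indel[i2]) | (!is.na(it) & gt$indel[it]),
             stringsAsFactors = FALSE)
}

#' Classify all site calls and tabulate category proportions
#'
#' Applies [classify_site()] to every row of a site-call table, keeping
#' per-site assignments, per-reason skip tallies, and category counts over
#' classified polymorphic sites (invariant sites are excluded from the
#' denominator).
#'
#' @param calls data.frame as returned by [read_site_calls()] (columns
#'   `locus_id`, `pos`, `ref_base`, `parent2`, `tetraploid`,
#'   `depth_parent2`, `depth_tetraploid`, optional `indel`).
#' @param min_depth minimum depth for both samples (default 8).
#' @return a `category_table`: list with `sites` (per-site data.frame with
#'   `category` and `reason`), `counts` (named category counts),
#'   `skipped` (named skip-reason counts), `n_invariant`, and the
#'   orientation note that CAT1 refers to the pseudo-reference parent.
#' @export
classify_all <- function(calls, min_depth = 8) {
  needed <- c("locus_id", "pos", "ref_base", "parent2", "tetraploid",
              "depth_parent2", "depth_tetraploid")
  if (!all(needed %in% names(calls)))
    stop("site-call table lacks columns: ",
         paste(setdiff(needed, names(calls)), collapse = ", "))
  n <- nrow(calls)
  category <- character(n)
  reason <- character(n)
  indel <- if ("indel" %in% names(calls)) calls$indel else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(indel[i])) {
      category[i] <- NA_character_; reason[i] <- "indel"; next
    }
    r <- classify_site(calls$ref_base[i], calls$parent2[i], calls$tetraploid[i],
                       calls$depth_parent2[i], calls$depth_tetraploid[i],
                       min_depth = min_depth)
    category[i] <- r$category
    reason[i] <- r$reason
  }
  sites <- cbind(calls, category = category, reason = reason,
                 stringsAsFactors = FALSE)
  classified <- !is.na(category) & category %in% CATEGORY_LEVELS
  counts <- vapply(CATEGORY_LEVELS,
                   function(k) sum(category == k, na.rm = TRUE), 0L)
  skipped <- table(reason[is.na(category)])
  structure(list(sites = sites,
                 counts = counts,
                 skipped = stats::setNames(as.integer(skipped), names(skipped)),
                 n_classified = sum(classified),
                 n_invariant = sum(category == "invariant", na.rm = TRUE),
                 orientation = "CAT1 = tetraploid matches pseudo-reference parent (parent 1) only; CAT2 = matches parent 2 only"),
            class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  cat("category_table:", x$n_classified, "classified sites,",
      x$n_invariant, "invariant,", sum(x$skipped), "skipped\n")
  if (x$n_classified > 0) {
    p <- summarize_proportions(x)
    for (k in names(p$percent))
      cat(sprintf("  %-6s %6d  %6.2f%%\n", k, x$counts[[k]], p$percent[[k]]))
  }
  cat(" ", x$orientation, "\n")
  invisible(x)
}

#' Summarize category proportions
#'
#' Converts classified-site counts into the percentage summary typically
#' shown as a pie chart of SNP categories.
#'
#' @param table a `category_table` from [classify_all()].
#' @return list with `counts`, `percent` (sums to 100), and `n`.
#' @export
summarize_proportions <- function(table) {
  stopifnot(inherits(table, "category_table"))
  n <- sum(table$counts)
  if (n == 0) stop("no classified sites to summarize")
  list(counts = table$counts,
       percent = 100 * table$counts / n,
       n = n,
       orientation = table$orientation)
}
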