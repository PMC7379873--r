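#' Build a concatenated pseudo-reference from one parent's RAD loci
#'
#' Concatenates the consensus RAD loci of one putative diploid parent, in
#' sorted locus-id order, into a single contig used as a mapping reference
#' in lieu of a genome assembly.  An offset table records, for every locus,
#' its half-open 0-based `[start, end)` interval on the contig, so that
#' global VCF coordinates can be translated back to (locus, offset) pairs.
#'
#' @param loci a [rad_locus_set()] of the reference parent.
#' @param contig name of the single concatenated contig.
#' @return a `pseudo_reference`: list with `sequence` (character scalar),
#'   `offsets` (data.frame `locus_id`, `start0`, `end0`) and `contig`.
#' @export
build_pseudoreference <- function(loci, contig = "pseudoref") {
  stopifnot(inherits(loci, "rad_locus_set"))
  if (length(loci) == 0) stop("cannot build a pseudo-reference from an empty locus set")
  ids <- sort(names(loci$sequences))
  seqs <- loci$sequences[ids]
  len <- nchar(seqs)
  end0 <- cumsum(len)
  offsets <- data.frame(locus_id = ids,
                        start0 = c(0L, end0[-length(end0)]),
                        end0 = end0,
                        stringsAsFactors = FALSE)
  rownames(offsets) <- NULL
  structure(list(sequence = paste(seqs, collapse = ""),
                 offsets = offsets,
                 contig = contig),
            class = "pseudo_reference")
}

#' @export
print.pseudo_reference <- function(x, ...) {
  cat("pseudo_reference '", x$contig, "': ", nrow(x$offsets), " loci, ",
      nchar(x$sequence), " bp\n", sep = "")
  invisible(x)
}

#' Map a global reference position to its locus
#'
#' Inverse of the offset table: translates a 1-based position on the
#' concatenated pseudo-reference into the locus it falls in and the
#' 1-based offset within that locus.
#'
#' @param ref a `pseudo_reference` from [build_pseudoreference()].
#' @param global_pos 1-based position(s) on the concatenated contig.
#' @return data.frame with columns `locus_id` and `offset` (1-based).
#' @export
map_coordinate <- function(ref, global_pos) {
  stopifnot(inherits(ref, "pseudo_reference"))
  n <- nchar(ref$sequence)
  if (any(global_pos < 1 | global_pos > n))
    stop("position out of range 1..", n)
  idx <- findInterval(global_pos - 1L, ref$offsets$start0)
  data.frame(locus_id = ref$offsets$locus_id[idx],
             offset = as.integer(global_pos - ref$offsets$start0[idx]),
             stringsAsFactors = FALSE)
}

#' Map a (locus, offset) pair to the global reference position
#'
#' @param ref a `pseudo_reference`.
#' @param locus_id locus identifier(s) present in the offset table.
#' @param offset 1-based offset(s) within the locus.
#' @return integer vector of 1-based global positions.
#' @export
global_position <- function(ref, locus_id, offset) {
  stopifnot(inherits(ref, "pseudo_reference"))
  i <- match(locus_id, ref$offsets$locus_id)
  if (anyNA(i)) stop("unknown locus id: ",
                     paste(unique(locus_id[is.na(i)]), collapse = ", "))
  len <- ref$offsets$end0[i] - ref$offsets$start0[i]
  if (any(offset < 1 | offset > len)) stop("offset outside locus")
  as.integer(ref$offsets$start0[i] + offset)
}

#' Extract the reference base at global positions
#' @param ref a `pseudo_reference`.
#' @param global_pos 1-based position(s).
#' @return character vector of single symbols (may be IUPAC codes).
#' @export
ref_base_at <- function(ref, global_pos) {
  substring(ref$sequence, global_pos, global_pos)
}

#' Write a pseudo-reference as FASTA plus offset table
#'
#' @param ref a `pseudo_reference`.
#' @param fasta_path output FASTA path (single record named by contig).
#' @param offsets_path output TSV path (`locus_id`, `start0`, `end0`);
#'   default replaces the FASTA extension with `_offsets.tsv`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_pseudoreference <- function(ref, fasta_path,
                                  offsets_path = sub("\\.fa(sta)?$", "", fasta_path)) {
  stopifnot(inherits(ref, "pseudo_reference"))
  if (identical(offsets_path, fasta_path) || !grepl("_offsets\\.tsv$", offsets_path))
    offsets_path <- paste0(sub("\\.fa(sta)?$", "", fasta_path), "_offsets.tsv")
  dna <- Biostrings::BStringSet(stats::setNames(ref$sequence, ref$contig))
  Biostrings::writeXStringSet(dna, fasta_path)
  utils::write.table(ref$offsets, offsets_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, offsets = offsets_path))
}

#' Read a pseudo-reference from FASTA plus offset table
#'
#' @param fasta_path single-contig FASTA written by [write_pseudoreference()].
#' @param offsets_path the sidecar offset TSV.
#' @return a `pseudo_reference`.
#' @export
read_pseudoreference <- function(fasta_path, offsets_path) {
  dna <- Biostrings::readBStringSet(fasta_path)
  if (length(dna) != 1) stop("pseudo-reference FASTA must contain exactly one contig")
  offsets <- utils::read.table(offsets_path, sep = "\t", header = TRUE,
                               colClasses = c("character", "integer", "integer"))
  seqlen <- nchar(as.character(dna[[1]]))
  if (offsets$end0[nrow(offsets)] != seqlen)
    stop("offset table does not cover the reference (", seqlen, " bp)")
  structure(list(sequence = as.character(dna[[1]]),
                 offsets = offsets,
                 contig = sub("\\s.*$", "", names(dna)[1])),
            class = "pseudo_reference")
}
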