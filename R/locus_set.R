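#' Construct a RAD locus set
#'
#' A `rad_locus_set` holds consensus RAD loci (one sequence per locus,
#' IUPAC ambiguity codes at heterozygous positions) together with
#' per-sample presence flags used by the locus-coverage filter.
#'
#' @param sequences named character vector, locus id -> consensus sequence
#'   over `A,C,G,T,N` and IUPAC ambiguity codes.
#' @param presence logical matrix (loci x samples) marking which samples
#'   recovered each locus, or `NULL` for a single-sample set where every
#'   locus is present.
#' @return an object of class `rad_locus_set`.
#' @export
rad_locus_set <- function(sequences, presence = NULL) {
  if (length(sequences) == 0) stop("locus set must contain at least one locus")
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all loci must be named")
  if (anyDuplicated(ids)) stop("duplicate locus ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(sequences) == 0)) stop("sequences must be non-empty")
  if (is.null(presence)) {
    presence <- matrix(TRUE, nrow = length(ids), ncol = 1,
                       dimnames = list(ids, "sample1"))
  }
  if (!is.matrix(presence) || !identical(rownames(presence), ids))
    stop("presence must be a logical matrix with one row per locus, in locus order")
  structure(list(sequences = sequences, presence = presence),
            class = "rad_locus_set")
}

#' @export
print.rad_locus_set <- function(x, ...) {
  cat("rad_locus_set:", length(x$sequences), "loci,",
      ncol(x$presence), "sample(s), total",
      sum(nchar(x$sequences)), "bp\n")
  invisible(x)
}

#' @export
length.rad_locus_set <- function(x) length(x$sequences)

#' Read consensus RAD loci from FASTA
#'
#' @param path FASTA file, one record per locus; record ids become locus ids.
#' @return a [rad_locus_set()].
#' @export
read_locus_fasta <- function(path) {
  dna <- Biostrings::readBStringSet(path)
  rad_locus_set(stats::setNames(as.character(dna),
                                sub("\\s.*$", "", names(dna))))
}

#' Write a locus set to FASTA
#'
#' @param x a [rad_locus_set()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(x, path) {
  stopifnot(inherits(x, "rad_locus_set"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x$sequences), path)
  invisible(path)
}

#' Filter loci by the number of samples sharing them
#'
#' Retains the loci present in at least `m` samples — the locus-coverage
#' threshold (`m`) applied when assembling a shared RAD-locus matrix.
#'
#' @param loci a [rad_locus_set()].
#' @param m minimum number of samples that must share a locus (>= 1).
#' @return a filtered [rad_locus_set()]; with a warning and an empty set if
#'   `m` exceeds the sample count.
#' @export
filter_loci_by_coverage <- function(loci, m) {
  stopifnot(inherits(loci, "rad_locus_set"), m >= 1)
  n_samples <- ncol(loci$presence)
  if (m > n_samples)
    warning("m = ", m, " exceeds the number of samples (", n_samples,
            "); no locus can satisfy the threshold")
  keep <- rowSums(loci$presence) >= m
  out <- list(sequences = loci$sequences[keep],
              presence = loci$presence[keep, , drop = FALSE])
  structure(out, class = "rad_locus_set")
}
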