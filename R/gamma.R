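#' Count polarized site patterns for a quartet
#'
#' For the ordered quartet (outgroup, P1, hybrid, P2) a site is
#' *informative* when the two parents carry different (unambiguous)
#' alleles, the outgroup matches exactly one of them (polarization), and
#' the hybrid matches one of the two parents.  Informative sites are split
#' into those where the hybrid shares P1's allele and those where it
#' shares P2's; everything else is uninformative.  IUPAC-ambiguous symbols
#' are resolved by sampling one allele uniformly per site per row (seeded),
#' which preserves expected pattern frequencies for consensus input.
#'
#' @param out_seq,p1_seq,h_seq,p2_seq equal-length character vectors of
#'   per-site symbols (or single sequence strings, which are split).
#' @param seed seed for ambiguity resolution.
#' @return a `quartet_pattern_counts` list: `n_concordant_P1`,
#'   `n_concordant_P2`, `n_uninformative`, `total_sites`.
#' @export
count_site_patterns <- function(out_seq, p1_seq, h_seq, p2_seq, seed = 1L) {
  as_sites <- function(x) if (length(x) == 1L && nchar(x) > 1L)
    strsplit(toupper(x), "")[[1]] else toupper(x)
  rows <- lapply(list(out_seq, p1_seq, h_seq, p2_seq), as_sites)
  n <- unique(lengths(rows))
  if (length(n) != 1L) stop("sequence rows differ in length")
  set.seed(derive_seed(seed, 5L))
  rows <- lapply(rows, resolve_ambiguities)
  o <- rows[[1]]; p1 <- rows[[2]]; h <- rows[[3]]; p2 <- rows[[4]]

  ok <- o %in% DNA_BASES & p1 %in% DNA_BASES & h %in% DNA_BASES & p2 %in% DNA_BASES
  informative <- ok & p1 != p2 & xor(o == p1, o == p2) & (h == p1 | h == p2)
  n1 <- sum(informative & h == p1)
  n2 <- sum(informative & h == p2)
  structure(list(n_concordant_P1 = n1,
                 n_concordant_P2 = n2,
                 n_uninformative = n - n1 - n2,
                 total_sites = n),
            class = "quartet_pattern_counts")
}

# Sample one base uniformly from each symbol's IUPAC set; symbols outside
# the IUPAC alphabet (gaps, N with 4 bases is kept as a draw among 4) pass
# through and are later treated as uninformative.
resolve_ambiguities <- function(x) {
  amb <- !(x %in% DNA_BASES) & x %in% names(.iupac_map)
  if (any(amb)) {
    x[amb] <- vapply(x[amb], function(s) {
      b <- iupac_bases(s)
      b[sample.int(length(b), 1L)]
    }, "")
  }
  x
}

#' Estimate the admixture proportion gamma for one quartet
#'
#' The estimator is the concordant-site ratio
#' `gamma_hat = n_P2 / (n_P1 + n_P2)`: 0 when the hybrid always sides with
#' parent P1, 1 when it always sides with P2, about 0.5 for a 50:50
#' hybrid.  Significance of an admixture signal is assessed with an exact
#' binomial test of the minority count `min(n_P1, n_P2)` against a small
#' boundary null proportion `p0` (one-sided, greater), i.e. the null that
#' the hybrid is effectively one of the parents (gamma at 0 or 1) up to a
#' trickle of discordance from noise and lineage sorting.
#'
#' @param counts a `quartet_pattern_counts` from [count_site_patterns()].
#' @param p0 boundary null proportion for the significance test
#'   (default 0.02).
#' @param alpha significance level applied after any multiple-testing
#'   correction (default 0.05).
#' @param p_adjust_n number of tests to Bonferroni-correct across
#'   (default 1 = no correction; [run_combinations()] sets it).
#' @return a `quartet_gamma_result`: list with `gamma`, `n_informative`,
#'   `statistic` (minority count), `p_value`, `significant`, `event_class`
#'   and `reason` (`"ok"` or `"no_informative_sites"`).
#' @export
estimate_gamma <- function(counts, p0 = 0.02, alpha = 0.05, p_adjust_n = 1L) {
  stopifnot(inherits(counts, "quartet_pattern_counts"))
  n1 <- counts$n_concordant_P1
  n2 <- counts$n_concordant_P2
  n <- n1 + n2
  if (n == 0)
    return(structure(list(gamma = NA_real_, n_informative = 0L,
                          statistic = NA_real_, p_value = NA_real_,
                          significant = FALSE, event_class = "undefined",
                          reason = "no_informative_sites"),
                     class = "quartet_gamma_result"))
  gamma <- n2 / n
  k <- min(n1, n2)
  p <- stats::binom.test(k, n, p = p0, alternative = "greater")$p.value
  p_adj <- min(1, p * p_adjust_n)
  significant <- p_adj <= alpha
  structure(list(gamma = gamma, n_informative = n, statistic = k,
                 p_value = p, p_adjusted = p_adj, significant = significant,
                 event_class = classify_event(gamma, significant),
                 reason = "ok"),
            class = "quartet_gamma_result")
}

#' Classify a gamma estimate into a hybridization event class
#'
#' Applies the gamma-range convention for interpreting significant
#' admixture signals: `0.4 <= gamma <= 0.6` indicates a recent
#' hybridization event, `0.1 <= gamma < 0.4` and `0.6 < gamma <= 0.9`
#' older (intermediate) events, and significant values below 0.1 or above
#' 0.9 are excluded as likely incomplete lineage sorting or ancient
#' signal.  Non-significant results are reported as such regardless of
#' gamma.
#'
#' @param gamma estimated admixture proportion in `[0,1]` (or a
#'   `quartet_gamma_result`).
#' @param significant logical significance flag (ignored when a result
#'   object is supplied).
#' @return one of `"recent"`, `"intermediate_low"`, `"intermediate_high"`,
#'   `"excluded"`, `"nonsignificant"`.
#' @export
classify_event <- function(gamma, significant = TRUE) {
  if (inherits(gamma, "quartet_gamma_result")) {
    significant <- gamma$significant
    gamma <- gamma$gamma
  }
  if (is.na(gamma)) return("undefined")
  if (!significant) return("nonsignificant")
  if (gamma >= 0.4 && gamma <= 0.6) return("recent")
  if (gamma >= 0.1 && gamma < 0.4) return("intermediate_low")
  if (gamma > 0.6 && gamma <= 0.9) return("intermediate_high")
  "excluded"
}

#' Test all parent-hybrid-parent combinations of a sample alignment
#'
#' Enumerates every unordered parental pair with every remaining entity as
#' the putative hybrid — in `"taxon"` mode the entities are taxa and the
#' site-pattern counts of all their individuals (crossed with all outgroup
#' individuals) are pooled before estimation; in `"individual"` mode every
#' non-outgroup individual is its own entity.  P1/P2 orientation follows
#' lexicographic entity order; swapping them maps gamma to 1 - gamma.
#' P-values are Bonferroni-corrected across all tested triples.
#'
#' @param aln samples-by-sites character matrix (rownames = individual
#'   ids); cells may be IUPAC-coded.
#' @param assignment named character vector individual -> taxon (or
#'   data.frame with columns `individual`, `taxon`).
#' @param outgroup taxon used to polarize sites.
#' @param mode `"taxon"` or `"individual"`.
#' @param p0,alpha see [estimate_gamma()].
#' @param seed seed for ambiguity resolution.
#' @return data.frame with one row per tested triple (`p1`, `hybrid`,
#'   `p2`, `n_informative`, `gamma`, `p_value`, `p_adjusted`,
#'   `significant`, `event_class`) with a `summary` attribute (counts per
#'   class and mean gamma over significant events).
#' @export
run_combinations <- function(aln, assignment, outgroup,
                             mode = c("taxon", "individual"),
                             p0 = 0.02, alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (is.data.frame(assignment))
    assignment <- stats::setNames(as.character(assignment$taxon),
                                  as.character(assignment$individual))
  if (is.null(rownames(aln))) stop("alignment must have individual rownames")
  unknown <- setdiff(rownames(aln), names(assignment))
  if (length(unknown))
    stop("individuals missing from assignment map: ",
         paste(unknown, collapse = ", "))
  if (!(outgroup %in% assignment))
    stop("outgroup taxon '", outgroup, "' not present in assignment map")

  out_ind <- names(assignment)[assignment == outgroup]
  out_ind <- intersect(out_ind, rownames(aln))
  if (mode == "taxon") {
    members <- split(names(assignment)[assignment != outgroup],
                     assignment[assignment != outgroup])
    members <- lapply(members, intersect, rownames(aln))
    members <- members[lengths(members) > 0]
  } else {
    ind <- setdiff(rownames(aln), out_ind)
    members <- stats::setNames(as.list(ind), ind)
  }
  entities <- sort(names(members))
  if (length(entities) < 3)
    stop("need at least 3 non-outgroup entities, got ", length(entities))

  pooled_counts <- function(p1_members, h_members, p2_members) {
    n1 <- 0L; n2 <- 0L; nu <- 0L; tot <- 0L
    for (io in out_ind) for (i1 in p1_members)
      for (ih in h_members) for (i2 in p2_members) {
        cs <- count_site_patterns(aln[io, ], aln[i1, ], aln[ih, ], aln[i2, ],
                                  seed = seed)
        n1 <- n1 + cs$n_concordant_P1
        n2 <- n2 + cs$n_concordant_P2
        nu <- nu + cs$n_uninformative
        tot <- tot + cs$total_sites
      }
    structure(list(n_concordant_P1 = n1, n_concordant_P2 = n2,
                   n_uninformative = nu, total_sites = tot),
              class = "quartet_pattern_counts")
  }

  triples <- list()
  for (i in seq_along(entities)) for (j in seq_along(entities)) {
    if (i >= j) next
    for (h in setdiff(entities, entities[c(i, j)]))
      triples[[length(triples) + 1L]] <- c(entities[i], h, entities[j])
  }
  n_tests <- length(triples)

  rows <- lapply(triples, function(tr) {
    cs <- pooled_counts(members[[tr[1]]], members[[tr[2]]], members[[tr[3]]])
    r <- estimate_gamma(cs, p0 = p0, alpha = alpha, p_adjust_n = n_tests)
    data.frame(p1 = tr[1], hybrid = tr[2], p2 = tr[3],
               n_informative = r$n_informative, gamma = r$gamma,
               p_value = r$p_value, p_adjusted = r$p_adjusted %||% NA_real_,
               significant = r$significant, event_class = r$event_class,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  sig <- res$significant & res$event_class %in%
    c("recent", "intermediate_low", "intermediate_high")
  attr(res, "summary") <- list(
    n_tested = nrow(res),
    n_significant = sum(res$significant, na.rm = TRUE),
    class_counts = table(res$event_class),
    mean_gamma_significant = if (any(sig)) mean(res$gamma[sig]) else NA_real_,
    mode = mode)
  res
}
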