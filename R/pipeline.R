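#' Run the full synthetic-to-summary pipeline
#'
#' Orchestrates an end-to-end run: simulate two diploid parents and an
#' allotetraploid, emit the standard input files (pseudo-reference FASTA,
#' per-sample VCF and depth TSV), rebuild the reference from disk,
#' classify every SNP against the two parents, summarize category
#' proportions, diploidize the tetraploid genotype matrix, and estimate
#' gamma for a simulated quartet.  All randomness derives from the single
#' configured seed, so identical configurations reproduce identical
#' reports.
#'
#' @param config a list (or YAML path read with [read_run_config()]) with
#'   any of: the [simulation_config()] fields, `min_depth` (default 8),
#'   `gamma` (true quartet admixture, default 0.5), `n_quartet_sites`
#'   (default 10000), `p0`, `alpha`, `out_dir` (default a tempdir),
#'   `report_path` (optional JSON output path).
#' @return a `run_report` list: per-stage record counts, skip tallies by
#'   reason, category counts and percentages, gamma estimate with event
#'   class, and the provenance block (config and seed).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  sim_fields <- names(formals(simulation_config))
  sc <- do.call(simulation_config, config[intersect(names(config), sim_fields)])
  min_depth <- config$min_depth %||% 8
  out_dir <- config$out_dir %||% tempfile("radploid_run")

  parents <- simulate_parents(sc)
  tet <- simulate_allotetraploid(parents$parent1, parents$parent2, sc)
  files <- emit_files(parents, tet, sc, dir = out_dir)

  ref <- read_pseudoreference(files$reference, files$offsets)
  calls <- read_site_calls(ref, files$parent2_vcf, files$tetraploid_vcf,
                           files$parent2_depth, files$tetraploid_depth)
  tab <- classify_all(calls, min_depth = min_depth)
  props <- if (tab$n_classified > 0) summarize_proportions(tab) else NULL

  qs <- simulate_quartet_sites(config$gamma %||% 0.5,
                               config$n_quartet_sites %||% 10000L,
                               seed = sc$seed)
  cs <- count_site_patterns(qs["outgroup", ], qs["P1", ], qs["H", ], qs["P2", ],
                            seed = sc$seed)
  gr <- estimate_gamma(cs, p0 = config$p0 %||% 0.02,
                       alpha = config$alpha %||% 0.05)

  report <- list(
    provenance = list(package = "radploid",
                      version = as.character(utils::packageVersion("radploid")),
                      seed = sc$seed,
                      config = unclass(sc),
                      min_depth = min_depth,
                      out_dir = out_dir),
    simulate = list(n_loci = sc$n_loci,
                    n_sites = sc$n_loci * sc$locus_length,
                    n_truth_records = nrow(tet$truth)),
    classify = list(n_input_sites = nrow(calls),
                    n_classified = tab$n_classified,
                    n_invariant = tab$n_invariant,
                    n_skipped = sum(tab$skipped),
                    skipped_by_reason = as.list(tab$skipped),
                    counts = as.list(tab$counts),
                    percent = if (is.null(props)) NULL else as.list(props$percent),
                    orientation = tab$orientation),
    gamma = list(true_gamma = attr(qs, "true_gamma"),
                 gamma_hat = gr$gamma,
                 n_informative = gr$n_informative,
                 p_value = gr$p_value,
                 event_class = gr$event_class),
    files = files[names(files) != "pseudo_reference"])
  class(report) <- "run_report"
  if (!is.null(config$report_path))
    jsonlite::write_json(unclass(report), config$report_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("radploid run (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  loci:", x$simulate$n_loci, " sites:", x$simulate$n_sites, "\n")
  cat("  classified:", x$classify$n_classified,
      " invariant:", x$classify$n_invariant,
      " skipped:", x$classify$n_skipped, "\n")
  if (!is.null(x$classify$percent)) {
    pc <- unlist(x$classify$percent)
    cat("  ", paste(sprintf("%s %.1f%%", names(pc), pc), collapse = "  "), "\n")
  }
  cat(sprintf("  quartet gamma: true %.2f, estimate %.4f (%s)\n",
              x$gamma$true_gamma, x$gamma$gamma_hat, x$gamma$event_class))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the `config` argument of
#'   [run_pipeline()].
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Validate standard pipeline input files
#'
#' Checks well-formedness of a pseudo-reference FASTA with its offset
#' table, per-sample VCFs and depth TSVs: the offset table must partition
#' the reference; VCF positions must fall inside the reference and GT
#' ploidy should be consistent within a sample; depth positions must be in
#' range.  Violations are collected, not thrown.
#'
#' @param reference,offsets pseudo-reference FASTA and offset-TSV paths.
#' @param vcfs named character vector of VCF paths (names = sample ids).
#' @param depths named character vector of depth-TSV paths.
#' @return data.frame with columns `file`, `record`, `rule`, `severity`
#'   (`"error"`/`"warning"`); zero rows for clean inputs.
#' @export
validate_inputs <- function(reference, offsets, vcfs = character(),
                            depths = character()) {
  issues <- list()
  note <- function(file, record, rule, severity) {
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, record = as.character(record), rule = rule,
      severity = severity, stringsAsFactors = FALSE)
  }

  ref <- tryCatch(read_pseudoreference(reference, offsets), error = function(e) {
    note(reference, NA, conditionMessage(e), "error")
    NULL
  })
  if (!is.null(ref)) {
    off <- ref$offsets
    gaps <- which(off$start0 != c(0L, off$end0[-nrow(off)]))
    for (g in gaps) note(offsets, off$locus_id[g],
                         "offset table has a gap or overlap", "error")
    if (any(off$end0 <= off$start0))
      note(offsets, NA, "empty locus interval", "error")
    reflen <- nchar(ref$sequence)

    for (s in names(vcfs)) {
      gts <- tryCatch(read_vcf_genotypes(vcfs[[s]]), error = function(e) {
        note(vcfs[[s]], NA, conditionMessage(e), "error")
        NULL
      })
      if (is.null(gts)) next
      out_of_range <- which(gts$pos < 1 | gts$pos > reflen)
      for (i in out_of_range)
        note(vcfs[[s]], gts$pos[i], "VCF position beyond reference length", "error")
      ploidies <- unique(lengths(lapply(gts$genotype[!is.na(gts$genotype)],
                                        parse_genotype)))
      if (length(ploidies) > 1)
        note(vcfs[[s]], NA,
             paste0("ploidy mismatch: GT fields with ",
                    paste(sort(ploidies), collapse = "/"), " allele calls"),
             "warning")
    }
    for (s in names(depths)) {
      d <- tryCatch(read_depth_tsv(depths[[s]]), error = function(e) {
        note(depths[[s]], NA, conditionMessage(e), "error")
        NULL
      })
      if (is.null(d)) next
      bad <- which(d$pos < 1 | d$pos > reflen)
      for (i in bad) note(depths[[s]], d$pos[i],
                          "depth position beyond reference length", "error")
      if (any(d$depth < 0, na.rm = TRUE))
        note(depths[[s]], NA, "negative depth", "error")
    }
  }
  if (length(issues) == 0)
    return(data.frame(file = character(), record = character(),
                      rule = character(), severity = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
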