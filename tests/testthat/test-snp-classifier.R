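test_that("category rules match their definitions on the canonical cases", {
  expect_equal(classify_site("A", "G/G", "A/A/G/G")$category, "CAT5")
  expect_equal(classify_site("A", "G/G", "A/A/A/A")$category, "CAT1")
  expect_equal(classify_site("A", "G/G", "G/G/G/G")$category, "CAT2")
  expect_equal(classify_site("A", "A/A", "A/A/T/T")$category, "CAT34")
  expect_equal(classify_site("A", "A/G", "A/A/G/G")$category, "OTHER")
  expect_equal(classify_site("A", "A/G", "A/A/A/A")$category, "OTHER")
  expect_equal(classify_site("A", "G/G", "A/C/G/T")$category, "OTHER")
  expect_equal(classify_site("A", "A/A", "A/A/A/A")$category, "invariant")
  # dosage never subdivides categories
  expect_equal(classify_site("A", "G/G", "A/G/G/G")$category, "CAT5")
  expect_equal(classify_site("A", "G/G", "A/A/A/G")$category, "CAT5")
})

test_that("depth gating and missing data skip sites with a reason code", {
  low <- classify_site("A", "G/G", "A/A/G/G", depth_parent2 = 5,
                       depth_tetraploid = 50, min_depth = 8)
  expect_true(is.na(low$category))
  expect_equal(low$reason, "low_depth")
  miss <- classify_site("A", NA, "A/A/G/G")
  expect_equal(miss$reason, "missing_genotype")
  amb <- classify_site("R", "G/G", "A/A/G/G")
  expect_equal(amb$category, "OTHER")
  expect_equal(amb$reason, "ambiguous_reference")
})

test_that("classify_site agrees with the brute-force oracle on the full genotype space", {
  space <- enumerate_genotype_space()
  for (r in space$ref) {
    for (i in seq_len(nrow(space$p2))) {
      p2 <- unlist(space$p2[i, ], use.names = FALSE)
      for (j in seq_len(nrow(space$tet))) {
        tet <- unlist(space$tet[j, ], use.names = FALSE)
        got <- classify_site(r, p2, tet)$category
        want <- oracle_classify(r, p2, tet)
        if (!identical(got, want)) {
          fail(sprintf("mismatch at ref=%s p2=%s tet=%s: got %s, oracle %s",
                       r, paste(p2, collapse = "/"),
                       paste(tet, collapse = "/"), got, want))
        }
      }
    }
  }
  succeed()
})

test_that("assigned categories recover simulator truth site by site", {
  cfg <- simulation_config(n_loci = 400, backcross_fraction = 0.2,
                           backcross_direction = "both",
                           post_origin_rate = 0.002, seed = 21)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  tab <- classify_all(make_calls_from_sim(p, tet))
  j <- join_truth(tab, p, tet$truth)
  j <- j[!is.na(j$true_category) & !is.na(j$category), ]
  expect_gt(nrow(j), 300)
  agreement <- mean(j$category == j$true_category)
  expect_gte(agreement, 0.99)
})

test_that("empty and malformed inputs are handled", {
  empty <- classify_all(data.frame(locus_id = character(), pos = integer(),
                                   ref_base = character(), parent2 = character(),
                                   tetraploid = character(),
                                   depth_parent2 = numeric(),
                                   depth_tetraploid = numeric()))
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$n_classified, 0)
  expect_error(classify_all(data.frame(x = 1)), "lacks columns")
  expect_error(summarize_proportions(empty), "no classified sites")
})

test_that("proportions sum to 100 and match the counts", {
  cfg <- simulation_config(n_loci = 100, backcross_fraction = 0.3,
                           backcross_direction = "both",
                           post_origin_rate = 0.005, seed = 2)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  tab <- classify_all(make_calls_from_sim(p, tet))
  s <- summarize_proportions(tab)
  expect_equal(sum(s$percent), 100, tolerance = 1e-4)
  expect_equal(unname(s$counts["CAT5"] / s$n * 100), unname(s$percent["CAT5"]))

  for (seed in 1:5) {
    cfg <- simulation_config(n_loci = 50, backcross_fraction = runif(1),
                             backcross_direction = "both",
                             post_origin_rate = runif(1, 0, 0.01), seed = seed)
    p <- simulate_parents(cfg)
    tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
    tab <- classify_all(make_calls_from_sim(p, tet))
    if (tab$n_classified > 0)
      expect_equal(sum(summarize_proportions(tab)$percent), 100, tolerance = 1e-4)
  }
})

test_that("swapping the parents swaps CAT1 and CAT2 and fixes CAT5/CAT34", {
  cfg <- simulation_config(n_loci = 300, backcross_fraction = 0.3,
                           backcross_direction = "both",
                           post_origin_rate = 0.002, seed = 31)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  fwd <- classify_all(make_calls_from_sim(p, tet))
  swapped <- list(parent1 = p$parent2, parent2 = p$parent1)
  rev <- classify_all(make_calls_from_sim(swapped, tet))
  expect_equal(unname(fwd$counts["CAT1"]), unname(rev$counts["CAT2"]))
  expect_equal(unname(fwd$counts["CAT2"]), unname(rev$counts["CAT1"]))
  expect_equal(unname(fwd$counts["CAT5"]), unname(rev$counts["CAT5"]))
  expect_equal(unname(fwd$counts["CAT34"]), unname(rev$counts["CAT34"]))
})

test_that("file-based classification matches in-memory classification", {
  cfg <- simulation_config(n_loci = 120, backcross_fraction = 0.2,
                           post_origin_rate = 0.002, seed = 13)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  f <- emit_files(p, tet, cfg)
  ref <- read_pseudoreference(f$reference, f$offsets)
  calls <- read_site_calls(ref, f$parent2_vcf, f$tetraploid_vcf,
                           f$parent2_depth, f$tetraploid_depth)
  from_files <- classify_all(calls, min_depth = 8)
  in_memory <- classify_all(make_calls_from_sim(p, tet))
  expect_equal(from_files$counts, in_memory$counts)
})
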