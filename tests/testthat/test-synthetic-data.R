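test_that("configuration validation rejects invalid probabilities", {
  expect_error(simulation_config(parent_divergence = 1.5), "\\[0,1\\]")
  expect_error(simulation_config(missing_rate = -0.1), "\\[0,1\\]")
  expect_error(simulation_config(n_loci = 0), ">= 1")
  expect_s3_class(simulation_config(), "simulation_config")
})

test_that("parent divergence yields the closed-form expected SNP count", {
  cfg <- simulation_config(n_loci = 1000, locus_length = 86,
                           parent_divergence = 0.01, seed = 1)
  p <- simulate_parents(cfg)
  s1 <- strsplit(paste(p$parent1$sequences, collapse = ""), "")[[1]]
  s2 <- strsplit(paste(p$parent2$sequences, collapse = ""), "")[[1]]
  n_disc <- sum(s1 != s2)
  expected <- 1000 * 86 * 0.01
  sigma <- sqrt(1000 * 86 * 0.01 * 0.99)
  expect_gt(n_disc, expected - 3 * sigma)
  expect_lt(n_disc, expected + 3 * sigma)
})

test_that("zero divergence gives identical parents; same seed gives identical bytes", {
  cfg <- simulation_config(n_loci = 30, parent_divergence = 0, seed = 5)
  p <- simulate_parents(cfg)
  expect_identical(p$parent1$sequences, p$parent2$sequences)

  cfg2 <- simulation_config(n_loci = 40, parent_divergence = 0.02, seed = 9)
  fa <- replicate(2, {
    path <- tempfile(fileext = ".fasta")
    write_locus_fasta(simulate_parents(cfg2)$parent2, path)
    path
  })
  expect_identical(readBin(fa[1], "raw", file.size(fa[1])),
                   readBin(fa[2], "raw", file.size(fa[2])))
})

test_that("F1 construction forces homeo-SNP truth; full backcrossing removes it", {
  cfg <- simulation_config(n_loci = 200, backcross_fraction = 0,
                           post_origin_rate = 0, seed = 3)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  expect_gt(nrow(tet$truth), 0)
  expect_true(all(tet$truth$true_category == "CAT5"))

  cfg_bc <- simulation_config(n_loci = 200, backcross_fraction = 1,
                              post_origin_rate = 0, seed = 3)
  tet_bc <- simulate_allotetraploid(p$parent1, p$parent2, cfg_bc)
  expect_equal(sum(tet_bc$truth$true_category == "CAT5"), 0)
  expect_true(all(tet_bc$truth$true_category == "CAT1"))

  cfg_bc2 <- simulation_config(n_loci = 200, backcross_fraction = 1,
                               backcross_direction = "parent2",
                               post_origin_rate = 0, seed = 3)
  tet_bc2 <- simulate_allotetraploid(p$parent1, p$parent2, cfg_bc2)
  expect_true(all(tet_bc2$truth$true_category == "CAT2"))

  expect_error(simulate_allotetraploid(
    p$parent1, rad_locus_set(c(odd = "ACGT")), cfg), "locus ids")
})

test_that("post-origin mutations match the closed-form expected count", {
  cfg <- simulation_config(n_loci = 1000, locus_length = 86,
                           parent_divergence = 0.01,
                           post_origin_rate = 0.002, seed = 2)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  n_cat34 <- sum(tet$truth$true_category == "CAT34")
  expected <- 1000 * 86 * 0.002
  sigma <- sqrt(expected)
  expect_gt(n_cat34, expected - 3 * sigma)
  expect_lt(n_cat34, expected + 3 * sigma)
})

test_that("truth is conserved and emitted loci respect the assembly caps", {
  cfg <- simulation_config(n_loci = 300, backcross_fraction = 0.3,
                           backcross_direction = "both",
                           post_origin_rate = 0.003, parental_het = 0.002,
                           seed = 8)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  # every polymorphic site has exactly one record in a known category
  expect_true(all(tet$truth$true_category %in%
                    c("CAT1", "CAT2", "CAT34", "CAT5", "OTHER")))
  expect_equal(anyDuplicated(tet$truth[c("locus_id", "offset")]), 0L)
  counts <- table(factor(tet$truth$true_category,
                         c("CAT1", "CAT2", "CAT34", "CAT5", "OTHER")))
  expect_equal(sum(counts), nrow(tet$truth))

  # <= 20 segregating sites per locus and <= 4 alleles per site
  snps_per_locus <- tapply(rep(1, nrow(tet$truth)), tet$truth$locus_id, sum)
  expect_true(all(snps_per_locus <= 20))
  expect_true(all(nchar(radploid:::column_allele_key(tet$alleles)) <= 4))
})

test_that("emitted files honor depth, dropout and tetraploid-genotype contracts", {
  cfg <- simulation_config(n_loci = 100, depth_mean = 50, missing_rate = 0,
                           backcross_fraction = 0, post_origin_rate = 0,
                           seed = 4)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  f <- emit_files(p, tet, cfg)

  d <- read_depth_tsv(f$tetraploid_depth)
  expect_equal(nrow(d), 100 * 86)  # missing_rate 0: every position covered
  sigma_mean <- sqrt(50 + 50^2 / cfg$depth_dispersion) / sqrt(nrow(d))
  expect_lt(abs(mean(d$depth) - 50), 3 * sigma_mean)

  # at a CAT5 truth site the tetraploid VCF lists 2 distinct alleles, 2+2
  ref <- read_pseudoreference(f$reference, f$offsets)
  gt <- radploid:::read_vcf_genotypes(f$tetraploid_vcf)
  cat5 <- tet$truth[tet$truth$true_category == "CAT5", ][1, ]
  pos5 <- global_position(ref, cat5$locus_id, cat5$offset)
  g <- gt$genotype[gt$pos == pos5]
  al <- strsplit(g, "/")[[1]]
  expect_length(al, 4)
  expect_equal(sort(as.integer(table(al))), c(2L, 2L))
})

test_that("dropout removes whole loci from a sample's files", {
  cfg <- simulation_config(n_loci = 200, missing_rate = 0.3, seed = 12)
  p <- simulate_parents(cfg)
  tet <- simulate_allotetraploid(p$parent1, p$parent2, cfg)
  f <- emit_files(p, tet, cfg)
  d <- read_depth_tsv(f$parent2_depth)
  expect_lt(nrow(d), 200 * 86)
  expect_equal(nrow(d) %% 86, 0)  # dropout acts on whole loci
  frac <- 1 - nrow(d) / (200 * 86)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 200))
})

test_that("backcross and mutation rates shift truth categories monotonically", {
  mean_counts <- function(backcross, po) {
    res <- vapply(1:20, function(s) {
      cfg <- simulation_config(n_loci = 150, backcross_fraction = backcross,
                               post_origin_rate = po, seed = s)
      p <- simulate_parents(cfg)
      tr <- simulate_allotetraploid(p$parent1, p$parent2, cfg)$truth
      c(cat5 = sum(tr$true_category == "CAT5"),
        cat12 = sum(tr$true_category %in% c("CAT1", "CAT2")),
        cat34 = sum(tr$true_category == "CAT34"))
    }, c(cat5 = 0, cat12 = 0, cat34 = 0))
    rowMeans(res)
  }
  lo <- mean_counts(0, 0.001)
  hi <- mean_counts(0.5, 0.001)
  expect_lt(hi[["cat5"]], lo[["cat5"]])
  expect_gt(hi[["cat12"]], lo[["cat12"]])
  po_hi <- mean_counts(0, 0.005)
  expect_gt(po_hi[["cat34"]], lo[["cat34"]])
})

test_that("quartet simulation matches its admixture proportion", {
  q0 <- simulate_quartet_sites(0, 500, seed = 1)
  expect_identical(q0["H", ], q0["P1", ])
  q1 <- simulate_quartet_sites(1, 500, seed = 1)
  expect_identical(q1["H", ], q1["P2", ])

  q <- simulate_quartet_sites(0.5, 10000, seed = 7)
  frac_p2 <- mean(q["H", ] == q["P2", ])
  expect_lt(abs(frac_p2 - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(simulate_quartet_sites(1.2, 10), "\\[0,1\\]")
})
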