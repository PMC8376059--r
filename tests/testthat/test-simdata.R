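# Synthetic-data generator: coverage structure, brood transmission,
# diverged coding-sequence pairs.

test_that("noise-free coverage equals per-copy depth times copy number", {
  g <- default_genome_spec(n_hemizygous = 5, n_par = 3, n_autosomal = 4,
                           n_duplicated = 1)
  co <- cohort_spec(data.frame(name = "p", n_males = 2, n_females = 2,
                               depth_multiplier = 1),
                    per_copy_depth = 20, noise = "none")
  ds <- simulate_coverage_dataset(g, co, seed = 1)
  males <- ds$samples$individual_id[ds$samples$sex == "M"]
  females <- ds$samples$individual_id[ds$samples$sex == "F"]
  hemi <- ds$genes$gene_id[ds$genes$true_class == "hemizygous"]
  dup <- ds$genes$gene_id[ds$genes$true_class == "duplicated"]
  dip <- ds$genes$gene_id[ds$genes$true_class == "diploid"]
  expect_true(all(ds$values[hemi, males] == 20))
  expect_true(all(ds$values[hemi, females] == 40))
  expect_true(all(ds$values[dip, ] == 40))
  expect_true(all(ds$values[dup, males] == 60))
  expect_true(all(ds$values[dup, females] == 40))
})

test_that("depth multipliers scale expectations and misassembly ignores sex", {
  g <- default_genome_spec(n_hemizygous = 2, n_par = 2, n_autosomal = 50,
                           n_misassembled = 30)
  co <- cohort_spec(data.frame(name = c("a", "b"), n_males = 1, n_females = 1,
                               depth_multiplier = c(1, 3)),
                    per_copy_depth = 10, noise = "none")
  ds <- simulate_coverage_dataset(g, co, seed = 9)
  auto <- ds$genes$gene_id[ds$genes$chrom == "chrAuto"]
  expect_true(all(ds$values[auto, ds$samples$population == "a"] == 20))
  expect_true(all(ds$values[auto, ds$samples$population == "b"] == 60))
  mis <- ds$genes$gene_id[ds$genes$true_class == "misassembled"]
  # misassembled copy numbers vary per individual and are drawn from {1,2,3}
  expect_true(all(ds$values[mis, ds$samples$population == "a"] %in%
                    c(10, 20, 30)))
  expect_gt(length(unique(as.vector(ds$values[mis, ]))), 2)
})

test_that("identical seeds reproduce identical datasets; seeds differ", {
  co <- cohort_spec(data.frame(name = "p", n_males = 3, n_females = 3,
                               depth_multiplier = 1))
  g <- default_genome_spec(n_hemizygous = 20, n_par = 5, n_autosomal = 20)
  d1 <- simulate_coverage_dataset(g, co, seed = 11)
  d2 <- simulate_coverage_dataset(g, co, seed = 11)
  d3 <- simulate_coverage_dataset(g, co, seed = 12)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, d3$values))
})

test_that("simulated mean coverage converges to its expectation", {
  n <- 400
  g <- default_genome_spec(n_hemizygous = n, n_par = 10, n_autosomal = 10)
  co <- cohort_spec(data.frame(name = "p", n_males = 1, n_females = 1,
                               depth_multiplier = 1),
                    per_copy_depth = 20, noise = "poisson")
  ds <- simulate_coverage_dataset(g, co, seed = 4)
  hemi <- ds$genes$gene_id[ds$genes$true_class == "hemizygous"]
  m <- ds$samples$individual_id[ds$samples$sex == "M"]
  # Poisson(20): SE of the mean over n genes is sqrt(20/n)
  expect_lt(abs(mean(ds$values[hemi, m]) - 20), 3 * sqrt(20 / n))
  f <- ds$samples$individual_id[ds$samples$sex == "F"]
  expect_lt(abs(mean(ds$values[hemi, f]) - 40), 3 * sqrt(40 / n))
})

test_that("negative-binomial noise is overdispersed relative to Poisson", {
  g <- default_genome_spec(n_hemizygous = 2, n_par = 2, n_autosomal = 500)
  pops <- data.frame(name = "p", n_males = 1, n_females = 1,
                     depth_multiplier = 1)
  nb <- simulate_coverage_dataset(
    g, cohort_spec(pops, per_copy_depth = 20, noise = "negative_binomial",
                   dispersion = 2), seed = 5)
  po <- simulate_coverage_dataset(
    g, cohort_spec(pops, per_copy_depth = 20, noise = "poisson"), seed = 5)
  auto <- nb$genes$gene_id[nb$genes$chrom == "chrAuto"]
  expect_gt(stats::var(nb$values[auto, 1]), 2 * stats::var(po$values[auto, 1]))
})

test_that("degenerate cohort and spec inputs error", {
  g <- default_genome_spec(n_hemizygous = 2, n_par = 2, n_autosomal = 2)
  empty <- cohort_spec(data.frame(name = "p", n_males = 0, n_females = 0,
                                  depth_multiplier = 1))
  expect_error(simulate_coverage_dataset(g, empty, seed = 1),
               "zero individuals")
  expect_error(cohort_spec(data.frame(name = "p", n_males = 1, n_females = 1,
                                      depth_multiplier = 1),
                           noise = "lognormal"))
  expect_error(cohort_spec(data.frame(name = "p", n_males = 1, n_females = 1,
                                      depth_multiplier = 0)),
               "depth_multiplier")
  expect_error(cohort_spec(data.frame(name = "p", n_males = 1, n_females = 1,
                                      depth_multiplier = 1),
                           noise = "negative_binomial"),
               "dispersion")
  expect_error(
    genome_spec(data.frame(name = "c", length = 100),
                data.frame(gene_id = "g", chrom = "c", start = 50, end = 200,
                           true_class = "diploid"),
                "c", c(1, 40), c(60, 100)),
    "outside")
  expect_error(
    genome_spec(data.frame(name = "c", length = 1000),
                data.frame(gene_id = "g", chrom = "c", start = 1, end = 10,
                           true_class = "diploid"),
                "c", c(1, 500), c(400, 1000)),
    "disjoint")
})

test_that("brood simulation respects X/Y transmission rules", {
  # x_hemizygous, no recombination: every son shows a single dam allele
  fam <- simulate_family(clean_family_spec(n_sons = 8, n_daughters = 8),
                         seed = 2)
  sons <- fam$truth$individual_id[fam$truth$sex == "M"]
  gs <- fam$genotypes[fam$genotypes$individual_id %in% sons, ]
  expect_true(all(is.na(gs$allele2)))
  expect_true(all(gs$allele1 %in% c("a", "b", "c", "d")))
  # xy_both, sire X = 957, Y = 930: all daughters carry 957, all sons 930
  spec <- family_spec(
    dam = list(zer1 = c("941", "951")),
    sires = list(list(x = c(zer1 = "957"), y = c(zer1 = "930"))),
    progeny = data.frame(sire = 1, n_sons = 5, n_daughters = 5),
    recombination = 0, mode = "xy_both")
  fam2 <- simulate_family(spec, seed = 3)
  for (i in seq_len(nrow(fam2$truth))) {
    al <- c(fam2$genotypes$allele1[i], fam2$genotypes$allele2[i])
    expected <- if (fam2$truth$sex[i] == "F") "957" else "930"
    expect_true(expected %in% al)
    expect_false(setdiff(c("957", "930"), expected) %in% al)
  }
})

test_that("progeny sex counts are specified exactly and recombination rate is honoured", {
  spec <- clean_family_spec(n_sons = 7, n_daughters = 4)
  fam <- simulate_family(spec, seed = 6)
  expect_identical(as.vector(table(fam$truth$sex)[c("F", "M")]), c(4L, 7L))
  # recombination 0.5: recombinant fraction among sons' markers ~ Binomial(0.5)
  spec5 <- clean_family_spec(n_sons = 50, n_daughters = 0,
                             recombination = 0.5, mode = "xy_both")
  n_rec <- 0
  n_tot <- 0
  for (s in 1:10) {
    fam5 <- simulate_family(spec5, seed = s)
    n_rec <- n_rec + sum(fam5$truth$n_recombinant_markers)
    n_tot <- n_tot + 2 * nrow(fam5$truth)
  }
  expect_lt(abs(n_rec / n_tot - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("diverged CDS pairs hit targets, stay stop-free, and are reproducible", {
  same <- simulate_diverged_cds(50, 0, 0, seed = 1)
  expect_identical(same[["seq_a"]], same[["seq_b"]])
  p1 <- simulate_diverged_cds(200, 0.05, 0.01, seed = 9)
  p2 <- simulate_diverged_cds(200, 0.05, 0.01, seed = 9)
  expect_identical(p1, p2)
  expect_false(identical(p1, simulate_diverged_cds(200, 0.05, 0.01, seed = 10)))
  for (s in 1:5) {
    p <- simulate_diverged_cds(120, 0.1, 0.05, seed = s)
    for (seqc in p) {
      expect_identical(nchar(seqc), 360L)
      expect_false(grepl("-", seqc))
      codons <- substring(seqc, 3 * (1:120) - 2, 3 * (1:120))
      expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
    }
  }
  expect_error(simulate_diverged_cds(10, 0.8, 0, seed = 1), "0.7")
  expect_error(simulate_diverged_cds(0, 0.1, 0, seed = 1), "n_codons")
})
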