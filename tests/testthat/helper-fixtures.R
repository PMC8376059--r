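# In-code fixtures shared across test files.

# A tiny hand-built coverage dataset: 2 sex-linked + 3 autosomal genes,
# 3 males + 3 females in one population. Values are exact expected depths
# (per-copy depth `d`): hemizygous gene sexg1 has 1 male copy, PAR gene
# sexg2 and the autosomal genes 2 copies in both sexes.
tiny_dataset <- function(d = 10) {
  genes <- data.frame(
    gene_id = c("sexg1", "sexg2", "auto1", "auto2", "auto3"),
    chrom = c("chrSex", "chrSex", "chrA", "chrA", "chrA"),
    start = c(1e6, 25e6, 1e6, 2e6, 3e6),
    end = c(1e6, 25e6, 1e6, 2e6, 3e6) + 999
  )
  samples <- data.frame(
    individual_id = c("m1", "m2", "m3", "f1", "f2", "f3"),
    population = "pop1",
    sex = rep(c("M", "F"), each = 3)
  )
  v <- matrix(2 * d, 5, 6, dimnames = list(genes$gene_id,
                                           samples$individual_id))
  v["sexg1", c("m1", "m2", "m3")] <- d
  coverage_dataset(genes, samples, v)
}

# Simulated dataset covering the standard study conditions: hemizygous +
# PAR genes on the sex chromosome plus autosomal genes, Poisson depth.
sim_dataset <- function(seed, n_hemizygous = 100, n_par = 20,
                        n_autosomal = 100, n_males = 10, n_females = 10,
                        depth = 20, populations = 1, noise = "poisson",
                        n_duplicated = 0) {
  g <- default_genome_spec(n_hemizygous = n_hemizygous, n_par = n_par,
                           n_autosomal = n_autosomal,
                           n_duplicated = n_duplicated)
  pops <- data.frame(name = sprintf("pop%d", seq_len(populations)),
                     n_males = n_males, n_females = n_females,
                     depth_multiplier = 1)
  co <- cohort_spec(pops, per_copy_depth = depth, noise = noise)
  list(genome = g, dataset = simulate_coverage_dataset(g, co, seed = seed))
}

# A brood spec with a heterozygous dam and sire alleles distinct from the
# dam's at every marker (a "conflict-free" configuration for sex inference).
clean_family_spec <- function(n_sons = 6, n_daughters = 6, recombination = 0,
                              mode = "x_hemizygous", n_sires = 1) {
  sires <- lapply(seq_len(n_sires), function(i) {
    list(x = c(m1 = sprintf("x1_%d", i), m2 = sprintf("x2_%d", i)),
         y = c(m1 = sprintf("y1_%d", i), m2 = sprintf("y2_%d", i)))
  })
  family_spec(
    dam = list(m1 = c("a", "b"), m2 = c("c", "d")),
    sires = sires,
    progeny = data.frame(sire = seq_len(n_sires), n_sons = n_sons,
                         n_daughters = n_daughters),
    recombination = recombination, mode = mode
  )
}

truth_sexes <- function(fam) {
  sx <- fam$truth$sex
  names(sx) <- fam$truth$individual_id
  sx
}
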