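# Pedigree and population sex-linkage inference.

# One hand-built brood: dam A/B at m1, C/D at m2 (both hemizygous-mode).
hand_family <- function(genotypes, dam = list(m1 = c("A", "B"),
                                              m2 = c("C", "D")),
                        mode = "x_hemizygous") {
  family_genotypes(
    family_id = "fam1", dam = dam, genotypes = genotypes,
    markers = data.frame(marker_id = names(dam), position = NA_real_,
                         mode = mode))
}

test_that("progeny sexing follows the dam-allele hemizygosity rules", {
  g <- rbind(
    data.frame(individual_id = "p1", marker_id = c("m1", "m2"),
               allele1 = c("A", "C"), allele2 = c(NA, NA)),      # all single dam
    data.frame(individual_id = "p2", marker_id = c("m1", "m2"),
               allele1 = c("A", "C"), allele2 = c("E", "F")),    # two alleles
    data.frame(individual_id = "p3", marker_id = c("m1", "m2"),
               allele1 = c("A", "B"), allele2 = c(NA, "E")),     # conflict
    data.frame(individual_id = "p4", marker_id = c("m1", "m2"),
               allele1 = c("Z", "C"), allele2 = c(NA, NA)))      # non-Mendelian
  calls <- infer_progeny_sex(hand_family(g))
  expect_equal(calls$call[match(c("p1", "p2", "p3", "p4"),
                                calls$individual_id)],
               c("M", "F", "unassigned", "non_mendelian"))
  expect_match(calls$note[calls$individual_id == "p3"], "conflict")
})

test_that("sexing requires informative hemizygous-mode markers", {
  g <- data.frame(individual_id = "p1", marker_id = "m1",
                  allele1 = "A", allele2 = NA)
  fam <- family_genotypes("f", dam = list(m1 = "A"), genotypes = g,
                          markers = data.frame(marker_id = "m1",
                                               position = NA,
                                               mode = "x_hemizygous"))
  expect_error(infer_progeny_sex(fam), "informative")
  fam2 <- hand_family(g)
  fam2$markers$mode <- NA_character_
  expect_error(infer_progeny_sex(fam2), "hemizygous-mode")
})

test_that("sex calls are invariant to marker and progeny row order", {
  fam <- simulate_family(clean_family_spec(n_sons = 5, n_daughters = 5),
                         seed = 17)
  calls <- infer_progeny_sex(fam)
  shuffled <- fam
  withr::with_seed(1, {
    shuffled$genotypes <- shuffled$genotypes[sample(nrow(shuffled$genotypes)), ]
  })
  calls2 <- infer_progeny_sex(shuffled)
  m <- match(calls$individual_id, calls2$individual_id)
  expect_identical(calls$call, calls2$call[m])
})

test_that("sexing recovers 100% of true sexes on conflict-free broods", {
  for (s in 1:5) {
    fam <- simulate_family(clean_family_spec(n_sons = 6, n_daughters = 6),
                           seed = s)
    calls <- infer_progeny_sex(fam)
    truth <- truth_sexes(fam)
    expect_identical(calls$call, unname(truth[calls$individual_id]))
  }
})

test_that("paternal X deduction groups daughters into paternity clusters", {
  # daughters' non-dam haplotypes: C-E, C-E, D-F -> two sires
  g <- rbind(
    data.frame(individual_id = "d1", marker_id = c("m1", "m2"),
               allele1 = c("A", "C2"), allele2 = c("C", "E")),
    data.frame(individual_id = "d2", marker_id = c("m1", "m2"),
               allele1 = c("B", "D2"), allele2 = c("C", "E")),
    data.frame(individual_id = "d3", marker_id = c("m1", "m2"),
               allele1 = c("A", "C2"), allele2 = c("D", "F")))
  fam <- hand_family(g, dam = list(m1 = c("A", "B"), m2 = c("C2", "D2")))
  sexes <- c(d1 = "F", d2 = "F", d3 = "F")
  pa <- infer_paternal_alleles(fam, sexes)
  expect_equal(pa$n_sires, 2L)
  expect_equal(sort(unique(pa$clusters$cluster)), 1:2)
  expect_setequal(
    pa$paternal$allele[pa$paternal$individual_id == "d1"], c("C", "E"))
  # a daughter sharing both alleles with the dam is ambiguous at that marker
  g2 <- data.frame(individual_id = "d9", marker_id = "m1",
                   allele1 = "A", allele2 = "B")
  fam2 <- hand_family(g2, dam = list(m1 = c("A", "B")))
  pa2 <- infer_paternal_alleles(fam2, c(d9 = "F"))
  expect_true(pa2$paternal$ambiguous[1])
  expect_error(infer_paternal_alleles(fam2, c(d9 = "M")), "no daughters")
})

test_that("complete sex linkage: sons inherit only the sire's other allele", {
  # sire 957/x; 6 sons carry x, 5 daughters carry 957
  g <- rbind(
    data.frame(individual_id = paste0("s", 1:6), marker_id = "zer1",
               allele1 = "941", allele2 = "x"),
    data.frame(individual_id = paste0("d", 1:5), marker_id = "zer1",
               allele1 = "941", allele2 = "957"))
  fam <- hand_family(g, dam = list(zer1 = c("941", "951")), mode = "xy_both")
  sexes <- c(stats::setNames(rep("M", 6), paste0("s", 1:6)),
             stats::setNames(rep("F", 5), paste0("d", 1:5)))
  call <- classify_marker_family(fam, "zer1", sexes)
  expect_equal(call$class, "complete_sex_linked")
  expect_equal(call$recombinant_count, 0L)
  expect_equal(call$n_informative_progeny, 11L)
})

test_that("partial linkage and autosomal segregation are separated", {
  mk_fam <- function(n_x_sons, n_y_daughters = 0, n_sons = 10,
                     n_daughters = 10) {
    g <- rbind(
      data.frame(individual_id = paste0("s", seq_len(n_sons)),
                 marker_id = "m1", allele1 = "A",
                 allele2 = c(rep("X", n_x_sons),
                             rep("Y", n_sons - n_x_sons))),
      data.frame(individual_id = paste0("d", seq_len(n_daughters)),
                 marker_id = "m1", allele1 = "A",
                 allele2 = c(rep("Y", n_y_daughters),
                             rep("X", n_daughters - n_y_daughters))))
    hand_family(g, dam = list(m1 = c("A", "B")), mode = "xy_both")
  }
  sexes <- c(stats::setNames(rep("M", 10), paste0("s", 1:10)),
             stats::setNames(rep("F", 10), paste0("d", 1:10)))
  partial <- classify_marker_family(mk_fam(2), "m1", sexes)
  expect_equal(partial$class, "partial_sex_linked")
  expect_equal(partial$recombinant_count, 2L)
  # paternal alleles split 5:5 across the sexes -> independent of sex
  auto <- classify_marker_family(mk_fam(5, 5), "m1", sexes)
  expect_equal(auto$class, "autosomal_like")
  # no segregating variation -> uninformative
  mono <- hand_family(
    data.frame(individual_id = "s1", marker_id = "m1",
               allele1 = "A", allele2 = NA),
    dam = list(m1 = "A"), mode = "xy_both")
  expect_equal(classify_marker_family(mono, "m1", c(s1 = "M"))$class,
               "uninformative")
})

test_that("hemizygous-pattern markers are recognized and annotated", {
  g <- rbind(
    data.frame(individual_id = paste0("s", 1:5), marker_id = "m1",
               allele1 = c("A", "B", "A", "B", "A"), allele2 = NA),
    data.frame(individual_id = paste0("d", 1:4), marker_id = "m1",
               allele1 = "A", allele2 = "E"))
  fam <- hand_family(g, dam = list(m1 = c("A", "B")))
  sexes <- c(stats::setNames(rep("M", 5), paste0("s", 1:5)),
             stats::setNames(rep("F", 4), paste0("d", 1:4)))
  call <- classify_marker_family(fam, "m1", sexes)
  expect_equal(call$class, "hemizygous")
  expect_match(call$note, "null alleles")
})

test_that("near-size microsatellite alleles trigger a warning note", {
  g <- data.frame(individual_id = paste0("d", 1:6), marker_id = "m1",
                  allele1 = "100", allele2 = "102")
  fam <- hand_family(g, dam = list(m1 = c("100", "104")))
  sexes <- stats::setNames(rep("F", 6), paste0("d", 1:6))
  call <- classify_marker_family(fam, "m1", sexes)
  expect_match(call$note, "near-size")
})

test_that("simulated recombination-free families classify as complete", {
  for (s in 1:10) {
    fam <- simulate_family(clean_family_spec(n_sons = 5, n_daughters = 5,
                                             mode = "xy_both"),
                           seed = s)
    call <- classify_marker_family(fam, "m1", truth_sexes(fam))
    expect_equal(call$class, "complete_sex_linked")
    expect_equal(call$recombinant_count, 0L)
  }
})

test_that("population summaries reproduce the three archetypal patterns", {
  # females fixed for one allele, males heterozygous for male-specific alleles
  zer1 <- rbind(
    data.frame(individual_id = paste0("f", 1:31), sex = "F",
               marker_id = "zer1", allele1 = "957", allele2 = "957"),
    data.frame(individual_id = paste0("m", 1:18), sex = "M",
               marker_id = "zer1", allele1 = "957", allele2 = "957"),
    data.frame(individual_id = paste0("m", 19:31), sex = "M",
               marker_id = "zer1", allele1 = "957",
               allele2 = paste0("y", rep(1:8, length.out = 13))))
  s1 <- population_linkage_summary(zer1)
  expect_equal(s1$class, "complete_sex_linked_Y_polymorphic")
  expect_equal(s1$n_heterozygous_males, 13L)
  expect_equal(length(s1$male_specific_alleles), 8L)
  expect_equal(s1$fixed_female_allele, "957")
  expect_false(s1$male_specific_low_confidence)

  # polymorphic marker but no male ever heterozygous
  bifurca <- rbind(
    data.frame(individual_id = paste0("f", 1:8), sex = "F", marker_id = "ms1",
               allele1 = c("150", "150", "154", "154", "150", "154", "150",
                           "154"),
               allele2 = c("154", "150", "154", "150", "150", "154", "154",
                           "154")),
    data.frame(individual_id = paste0("m", 1:13), sex = "M",
               marker_id = "ms1",
               allele1 = rep(c("150", "154", "158"), length.out = 13),
               allele2 = NA))
  s2 <- population_linkage_summary(bifurca)
  expect_equal(s2$class, "hemizygous_consistent")
  expect_equal(s2$n_heterozygous_males, 0L)
  expect_true(s2$male_specific_low_confidence)  # only 8 females sampled

  # males heterozygous for alleles shared with females
  fpgs <- rbind(
    data.frame(individual_id = paste0("f", 1:5), sex = "F", marker_id = "fp",
               allele1 = "200", allele2 = c("204", "204", "200", "200",
                                            "204")),
    data.frame(individual_id = paste0("m", 1:13), sex = "M", marker_id = "fp",
               allele1 = "200",
               allele2 = c(rep("204", 7), rep(NA, 6))))
  s3 <- population_linkage_summary(fpgs)
  expect_equal(s3$class, "partial_sex_linked_like")
  expect_equal(s3$n_heterozygous_males, 7L)
  expect_error(population_linkage_summary(fpgs[1:7, ]), "per sex")
})

test_that("genotype TSV reader reconstructs families with dam rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- rbind(
    data.frame(individual_id = "dam", family_id = "T1", sex = "F",
               marker_id = c("m1", "m2"), allele1 = c("A", "C"),
               allele2 = c("B", "D"), mode = "x_hemizygous"),
    data.frame(individual_id = c("p1", "p1"), family_id = "T1", sex = "U",
               marker_id = c("m1", "m2"), allele1 = c("A", "C"),
               allele2 = NA, mode = "x_hemizygous"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fams <- read_genotypes(path)
  expect_equal(length(fams), 1L)
  expect_s3_class(fams$T1, "family_genotypes")
  expect_equal(sort(fams$T1$dam$m1), c("A", "B"))
  expect_equal(infer_progeny_sex(fams$T1)$call, "M")
})
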