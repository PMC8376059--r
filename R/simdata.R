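# Synthetic-data generators: coverage datasets with sex-linked copy-number
# structure, X/Y broods with multiple paternity, and diverged coding-sequence
# pairs. These emulate the statistical structure the analysis modules assume,
# so the whole pipeline can be exercised without sequencing data.

#' Specify a genome for coverage simulation
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive) and `true_class`, one of `"hemizygous"`, `"diploid"`,
#'   `"duplicated"`, `"misassembled"`.
#' @param sex_chromosome name of the sex chromosome (XY system: males are the
#'   heterogametic sex).
#' @param hemizygous_interval,par_interval numeric length-2 bp ranges on the
#'   sex chromosome: the fully sex-linked (degenerated) region and the
#'   pseudoautosomal region. Must be disjoint.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes, genes, sex_chromosome,
                        hemizygous_interval, par_interval) {
  chromosomes <- as.data.frame(chromosomes)
  genes <- as.data.frame(genes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("gene_id", "chrom", "start", "end", "true_class") %in%
                  names(genes)))
  ok_class <- c("hemizygous", "diploid", "duplicated", "misassembled")
  bad <- setdiff(unique(genes$true_class), ok_class)
  if (length(bad)) stop_data("unknown true_class: ", paste(bad, collapse = ", "))
  if (!sex_chromosome %in% chromosomes$name) {
    stop_data("sex_chromosome not among chromosomes")
  }
  len <- chromosomes$length[match(genes$chrom, chromosomes$name)]
  if (any(is.na(len))) stop_data("gene on unknown chromosome")
  if (any(genes$start < 1 | genes$end > len | genes$start > genes$end)) {
    stop_data("gene interval outside its chromosome")
  }
  if (max(hemizygous_interval[1], par_interval[1]) <=
      min(hemizygous_interval[2], par_interval[2])) {
    stop_data("hemizygous and PAR intervals must be disjoint")
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 sex_system = "XY", sex_chromosome = sex_chromosome,
                 hemizygous_interval = as.numeric(hemizygous_interval),
                 par_interval = as.numeric(par_interval)),
            class = "genome_spec")
}

#' A compact sex-chromosome-plus-autosome genome layout
#'
#' Builds a `genome_spec` shaped like a fish sex chromosome whose distal tip
#' is pseudoautosomal: `n_hemizygous` single-copy (in males) genes spread over
#' the proximal region, then `n_par` diploid genes in the distal PAR, plus
#' `n_autosomal` genes on a separate autosome, with optional duplicated and
#' misassembled genes interleaved in the hemizygous region.
#'
#' @param n_hemizygous,n_par,n_autosomal,n_duplicated,n_misassembled gene
#'   counts per class.
#' @param sex_chrom_length,autosome_length chromosome sizes in bp; the PAR is
#'   the distal ~5% of the sex chromosome.
#' @return a `genome_spec`.
#' @export
default_genome_spec <- function(n_hemizygous = 200, n_par = 40,
                                n_autosomal = 200, n_duplicated = 0,
                                n_misassembled = 0,
                                sex_chrom_length = 26.5e6,
                                autosome_length = 24e6) {
  par_start <- round(sex_chrom_length * 0.95)
  hem_end <- par_start - 1
  n_hem_all <- n_hemizygous + n_duplicated + n_misassembled
  place <- function(n, lo, hi) {
    if (n == 0L) return(numeric(0))
    round(seq(lo, hi - 1000, length.out = n))
  }
  hem_pos <- place(n_hem_all, 1e5, hem_end - 1e4)
  hem_class <- rep("hemizygous", n_hem_all)
  if (n_duplicated > 0 || n_misassembled > 0) {
    # interleave the oddballs deterministically among the hemizygous genes
    odd <- c(rep("duplicated", n_duplicated), rep("misassembled", n_misassembled))
    idx <- round(seq(1, n_hem_all, length.out = length(odd) + 2))[-c(1, length(odd) + 2)]
    hem_class[idx] <- odd
  }
  par_pos <- place(n_par, par_start, sex_chrom_length - 1e4)
  auto_pos <- place(n_autosomal, 1e5, autosome_length - 1e4)
  genes <- data.frame(
    gene_id = c(sprintf("sexg%04d", seq_len(n_hem_all + n_par)),
                sprintf("auto%04d", seq_len(n_autosomal))),
    chrom = c(rep("chrSex", n_hem_all + n_par), rep("chrAuto", n_autosomal)),
    start = c(hem_pos, par_pos, auto_pos),
    end = c(hem_pos, par_pos, auto_pos) + 999,
    true_class = c(hem_class, rep("diploid", n_par),
                   rep("diploid", n_autosomal))
  )
  genome_spec(
    chromosomes = data.frame(name = c("chrSex", "chrAuto"),
                             length = c(sex_chrom_length, autosome_length)),
    genes = genes, sex_chromosome = "chrSex",
    hemizygous_interval = c(1, hem_end),
    par_interval = c(par_start, sex_chrom_length)
  )
}

#' Specify a sequencing cohort for coverage simulation
#'
#' @param populations data.frame with columns `name`, `n_males`, `n_females`
#'   and `depth_multiplier` (> 0; library-depth differences between
#'   populations).
#' @param per_copy_depth expected reads-per-base for a single gene copy.
#' @param noise `"poisson"`, `"negative_binomial"` or `"none"` (deterministic
#'   expected values, used for exactness tests).
#' @param dispersion negative-binomial size parameter; the Poisson model is
#'   the `dispersion -> Inf` limit.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(populations, per_copy_depth = 20,
                        noise = c("poisson", "negative_binomial", "none"),
                        dispersion = NULL) {
  noise <- match.arg(noise)
  populations <- as.data.frame(populations)
  stopifnot(all(c("name", "n_males", "n_females") %in% names(populations)))
  if (is.null(populations$depth_multiplier)) populations$depth_multiplier <- 1
  if (any(populations$depth_multiplier <= 0)) {
    stop_data("depth_multiplier must be > 0")
  }
  if (any(populations$n_males < 0 | populations$n_females < 0)) {
    stop_data("negative sample size")
  }
  if (noise == "negative_binomial" &&
      (is.null(dispersion) || dispersion <= 0)) {
    stop_data("negative_binomial noise needs dispersion > 0")
  }
  structure(list(populations = populations, per_copy_depth = per_copy_depth,
                 noise = noise, dispersion = dispersion),
            class = "cohort_spec")
}

# Gene copy number carried by each individual, by sex and true class.
copies_for <- function(true_class, sex) {
  switch(true_class,
         hemizygous = if (sex == "M") 1 else 2,
         diploid = 2,
         duplicated = if (sex == "M") 3 else 2,
         stop_data("copies_for: unknown class ", true_class))
}

#' Simulate a coverage dataset
#'
#' Draws one mean-depth value per (gene, individual). The expectation is
#' `per_copy_depth * copies * depth_multiplier`, with copies = 1 for
#' hemizygous genes in males and 2 otherwise, 3 in males for genes carrying a
#' Y-linked duplication, and, for misassembled genes, a copy number drawn per
#' individual independently of sex (mimicking sequence placed on the wrong
#' chromosome). Identical seeds yield identical datasets.
#'
#' @param genome a `genome_spec`.
#' @param cohort a `cohort_spec`.
#' @param seed integer seed; all draws flow from it.
#' @return a `coverage_dataset` whose `genes` table retains `true_class`.
#' @export
simulate_coverage_dataset <- function(genome, cohort, seed) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cohort, "cohort_spec"))
  pops <- cohort$populations
  n_ind <- sum(pops$n_males) + sum(pops$n_females)
  if (n_ind == 0L) stop_data("cohort has zero individuals")
  samples <- do.call(rbind, lapply(seq_len(nrow(pops)), function(i) {
    p <- pops[i, ]
    data.frame(
      individual_id = c(if (p$n_males > 0)
                          sprintf("%s_M%02d", p$name, seq_len(p$n_males)),
                        if (p$n_females > 0)
                          sprintf("%s_F%02d", p$name, seq_len(p$n_females))),
      population = p$name,
      sex = c(rep("M", p$n_males), rep("F", p$n_females)),
      depth_multiplier = p$depth_multiplier
    )
  }))
  genes <- genome$genes
  copies <- matrix(0, nrow(genes), nrow(samples),
                   dimnames = list(genes$gene_id, samples$individual_id))
  for (j in seq_len(nrow(samples))) {
    sex <- samples$sex[j]
    copies[, j] <- vapply(genes$true_class, function(cl) {
      if (cl == "misassembled") 0 else copies_for(cl, sex)
    }, 0)
  }
  mis <- which(genes$true_class == "misassembled")
  if (length(mis) > 0L) {
    copies[mis, ] <- with_stream(seed, "simdata/misassembled", {
      matrix(sample(c(1, 2, 3), length(mis) * nrow(samples), replace = TRUE,
                    prob = c(0.25, 0.5, 0.25)),
             length(mis), nrow(samples))
    })
  }
  mu <- sweep(copies * cohort$per_copy_depth, 2L, samples$depth_multiplier, `*`)
  values <- with_stream(seed, "simdata/coverage", {
    switch(cohort$noise,
           none = mu,
           poisson = matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu)),
           negative_binomial = matrix(
             stats::rnbinom(length(mu), mu = mu, size = cohort$dispersion),
             nrow(mu), ncol(mu)))
  })
  dimnames(values) <- dimnames(mu)
  samples$depth_multiplier <- NULL
  coverage_dataset(genes, samples, values)
}

#' Specify a brood for X/Y transmission simulation
#'
#' @param dam list (or matrix-like) of dam genotypes, one character vector of
#'   1-2 allele labels per marker; names are marker ids.
#' @param sires list of sires; each sire is a list with elements `x` and `y`,
#'   named character vectors of per-marker X- and Y-linked allele labels. In
#'   `x_hemizygous` mode the `y` element is ignored (males carry no second
#'   allele).
#' @param progeny data.frame with one row per sire: `sire` (index into
#'   `sires`), `n_sons`, `n_daughters`. Counts are specified, not sampled.
#' @param recombination per-marker probability that a gamete swaps the
#'   paternal X and Y alleles (0 for complete sex linkage). Recycled.
#' @param mode `"x_hemizygous"` (microsatellite on a degenerated Y: males show
#'   a single allele) or `"xy_both"` (males carry X and Y alleles).
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(dam, sires, progeny, recombination = 0,
                        mode = c("x_hemizygous", "xy_both")) {
  mode <- match.arg(mode)
  markers <- names(dam)
  if (is.null(markers)) stop_data("dam genotypes must be named by marker")
  if (any(!vapply(dam, function(a) length(a) %in% 1:2 && all(nzchar(a)), TRUE))) {
    stop_data("each dam genotype needs 1 or 2 nonempty allele labels")
  }
  recombination <- rep_len(recombination, length(markers))
  if (any(recombination < 0 | recombination > 1)) {
    stop_data("recombination probabilities must lie in [0, 1]")
  }
  for (s in sires) {
    if (!all(markers %in% names(s$x))) stop_data("sire lacks X allele for a marker")
    if (mode == "xy_both" && !all(markers %in% names(s$y))) {
      stop_data("sire lacks Y allele for a marker in xy_both mode")
    }
  }
  progeny <- as.data.frame(progeny)
  stopifnot(all(c("sire", "n_sons", "n_daughters") %in% names(progeny)),
            all(progeny$sire %in% seq_along(sires)))
  structure(list(markers = markers, dam = dam, sires = sires,
                 progeny = progeny, recombination = recombination,
                 mode = mode),
            class = "family_spec")
}

#' Simulate one brood under X/Y Mendelian transmission
#'
#' Each offspring receives one random dam allele per marker. Daughters also
#' receive the sire's X allele (or, with the per-marker recombination
#' probability, his Y allele); sons receive the sire's Y allele in `xy_both`
#' mode, or nothing paternal in `x_hemizygous` mode, with recombinants
#' receiving the sire's X allele instead. True sexes, sires and recombinant
#' status are recorded for scoring.
#'
#' @param spec a `family_spec`.
#' @param seed integer seed.
#' @param family_id label for the brood.
#' @return a `family_genotypes` object (see [family_genotypes()]); its
#'   `truth` element records sex, sire and per-marker recombinant status.
#' @export
simulate_family <- function(spec, seed, family_id = "sim_family") {
  stopifnot(inherits(spec, "family_spec"))
  with_stream(seed, "simdata/family", {
    rows <- list()
    truth <- list()
    k <- 0L
    for (i in seq_len(nrow(spec$progeny))) {
      sire <- spec$sires[[spec$progeny$sire[i]]]
      n_s <- spec$progeny$n_sons[i]
      n_d <- spec$progeny$n_daughters[i]
      for (sex in c(rep("M", n_s), rep("F", n_d))) {
        k <- k + 1L
        id <- sprintf("prog%03d", k)
        rec_flags <- stats::runif(length(spec$markers)) < spec$recombination
        for (m in seq_along(spec$markers)) {
          mk <- spec$markers[m]
          dam_allele <- sample(spec$dam[[mk]], 1L)
          pat <- if (sex == "F") {
            if (rec_flags[m]) {
              if (spec$mode == "xy_both") sire$y[[mk]] else NA_character_
            } else sire$x[[mk]]
          } else {
            if (rec_flags[m]) sire$x[[mk]]
            else if (spec$mode == "xy_both") sire$y[[mk]] else NA_character_
          }
          al <- sort(unique(c(dam_allele, if (!is.na(pat)) pat)))
          rows[[length(rows) + 1L]] <- data.frame(
            individual_id = id, marker_id = mk,
            allele1 = al[1],
            allele2 = if (length(al) > 1L) al[2] else NA_character_)
        }
        truth[[k]] <- data.frame(
          individual_id = id, sex = sex, sire = spec$progeny$sire[i],
          n_recombinant_markers = sum(rec_flags))
      }
    }
    fam <- family_genotypes(
      family_id = family_id,
      dam = spec$dam,
      genotypes = do.call(rbind, rows),
      markers = data.frame(marker_id = spec$markers, position = NA_real_,
                           mode = spec$mode)
    )
    fam$truth <- do.call(rbind, truth)
    fam
  })
}

# --- coding-sequence pair simulation ------------------------------------

#' Simulate a pair of diverged coding sequences
#'
#' Draws a random stop-free ancestral sequence and evolves it along two
#' branches by placing synonymous and nonsynonymous substitutions at random
#' eligible positions, alternating between branches, until the expected
#' Jukes-Cantor-corrected synonymous and nonsynonymous divergences reach the
#' targets. Substitutions creating stop codons are rejected, so both
#' sequences stay translatable; repeated hits at one site are allowed (the
#' JC correction accounts for them in expectation). The pair is returned
#' aligned and gap-free.
#'
#' @param n_codons number of codons (>= 1).
#' @param target_ks,target_ka target JC-corrected synonymous and
#'   nonsynonymous divergence, each in `[0, 0.7)`.
#' @param seed integer seed.
#' @return named character vector of two in-frame DNA sequences
#'   (`seq_a`, `seq_b`), with attributes `n_syn_events` and `n_nonsyn_events`.
#' @export
simulate_diverged_cds <- function(n_codons, target_ks, target_ka, seed) {
  if (n_codons < 1) stop_data("n_codons must be >= 1")
  if (target_ks < 0 || target_ks >= 0.7 || target_ka < 0 || target_ka >= 0.7) {
    stop_data("divergence targets must lie in [0, 0.7)")
  }
  code <- genetic_code_tables()
  with_stream(seed, "simdata/cds", {
    anc <- sample(code$sense, n_codons, replace = TRUE)
    sc <- site_counts_matrix()[anc, , drop = FALSE]
    S <- sum(sc[, "s"])
    N <- sum(sc[, "n"])
    n_syn <- round(jc_inverse(target_ks) * S)
    n_non <- round(jc_inverse(target_ka) * N)
    if (n_syn > 0 && S < 1) {
      stop_data("unreachable target_ks: no synonymous sites in ancestor")
    }
    seqs <- list(anc, anc)
    # one substitution per nucleotide site: the realized difference
    # proportion then equals the JC-inverted target in expectation, so the
    # downstream JC correction recovers the target divergence
    used <- matrix(FALSE, n_codons, 3L)
    place <- function(branch, synonymous) {
      cods <- seqs[[branch]]
      for (try in seq_len(5000L)) {
        i <- sample.int(length(cods), 1L)
        pos <- sample.int(3L, 1L)
        if (used[i, pos]) next
        # prefer untouched codons: substitutions sharing a codon entangle
        # the synonymous/nonsynonymous pathway decomposition
        if (any(used[i, ]) && try < 2500L) next
        from <- substr(cods[i], pos, pos)
        to <- sample(setdiff(c("A", "C", "G", "T"), from), 1L)
        cand <- cods[i]
        substr(cand, pos, pos) <- to
        if (code$is_stop[[cand]]) next
        if ((code$aa[[cand]] == code$aa[[cods[i]]]) == synonymous) {
          cods[i] <- cand
          seqs[[branch]] <<- cods
          used[i, pos] <<- TRUE
          return(invisible(TRUE))
        }
      }
      stop_data("unreachable divergence target: no eligible ",
                if (synonymous) "synonymous" else "nonsynonymous",
                " change found")
    }
    for (e in seq_len(n_syn)) place(1L + e %% 2L, TRUE)
    for (e in seq_len(n_non)) place(1L + e %% 2L, FALSE)
    out <- c(seq_a = paste(seqs[[1]], collapse = ""),
             seq_b = paste(seqs[[2]], collapse = ""))
    attr(out, "n_syn_events") <- n_syn
    attr(out, "n_nonsyn_events") <- n_non
    out
  })
}

#' Write a simulated coding-sequence pair as FASTA
#'
#' @param pair result of [simulate_diverged_cds()].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
write_cds_pair <- function(pair, path) {
  x <- Biostrings::DNAStringSet(as.character(pair))
  names(x) <- names(pair)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
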