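# Marker sex-linkage classification from brood genotypes (progeny sexing via
# dam-allele hemizygosity, paternal-X deduction, paternity clustering,
# recombinant scoring) and from population samples (male-specific alleles,
# male homozygosity).

#' Construct a brood genotype set
#'
#' @param family_id brood label.
#' @param dam named list: per marker, a character vector of 1-2 dam allele
#'   labels (microsatellite sizes in bp, or SNP alleles).
#' @param genotypes long data.frame: `individual_id`, `marker_id`, `allele1`,
#'   `allele2` (`NA` when a single allele was observed).
#' @param markers data.frame `marker_id`, `position` (bp, may be `NA`),
#'   `mode` (`"x_hemizygous"`, `"xy_both"` or `NA`).
#' @param known_sexes optional named character vector of progeny sexes.
#' @return an object of class `family_genotypes`.
#' @export
family_genotypes <- function(family_id, dam, genotypes,
                             markers = NULL, known_sexes = NULL) {
  genotypes <- as.data.frame(genotypes)
  stopifnot(all(c("individual_id", "marker_id", "allele1", "allele2") %in%
                  names(genotypes)))
  if (is.null(markers)) {
    markers <- data.frame(marker_id = names(dam), position = NA_real_,
                          mode = NA_character_)
  }
  markers <- as.data.frame(markers)
  if (anyDuplicated(markers$marker_id)) stop_data("duplicated marker_id")
  bad <- setdiff(unique(genotypes$marker_id), names(dam))
  if (length(bad)) stop_data("genotyped marker lacking a dam genotype: ", bad[1])
  if (any(!vapply(dam, function(a) length(a) %in% 1:2, TRUE))) {
    stop_data("each dam genotype needs 1 or 2 alleles")
  }
  structure(list(family_id = family_id, dam = dam, genotypes = genotypes,
                 markers = markers, known_sexes = known_sexes),
            class = "family_genotypes")
}

#' @export
print.family_genotypes <- function(x, ...) {
  cat(sprintf("<family_genotypes> %s: %d markers, %d progeny\n",
              x$family_id, nrow(x$markers),
              length(unique(x$genotypes$individual_id))))
  invisible(x)
}

# Distinct observed alleles of one progeny at one marker (character(0) when
# not genotyped).
progeny_alleles <- function(fam, individual, marker) {
  g <- fam$genotypes[fam$genotypes$individual_id == individual &
                       fam$genotypes$marker_id == marker, , drop = FALSE]
  if (nrow(g) == 0L) return(character(0))
  unique(stats::na.omit(c(g$allele1[1], g$allele2[1])))
}

# Markers usable for hemizygosity-based sexing: hemizygous-mode (or unknown
# mode) markers segregating in the family (>= 2 distinct alleles observed).
informative_sexing_markers <- function(fam, x_hemizygous_marker_ids) {
  vapply(x_hemizygous_marker_ids, function(mk) {
    seen <- unique(stats::na.omit(c(
      fam$dam[[mk]],
      fam$genotypes$allele1[fam$genotypes$marker_id == mk],
      fam$genotypes$allele2[fam$genotypes$marker_id == mk])))
    length(seen) >= 2L
  }, TRUE)
}

#' Infer progeny sexes from dam-allele hemizygosity
#'
#' At markers whose Y copy is lost, sons are hemizygous and show exactly one
#' allele, inherited from the dam; daughters also carry a paternal X allele.
#' A progeny is called male when every informative hemizygous-mode marker
#' shows a single dam allele, female when at least one such marker shows two
#' alleles, and left unassigned with a conflict note when both kinds of
#' evidence occur (a pattern that can also arise when a daughter's paternal X
#' carries a dam allele - conflicts are reported, not resolved). A single
#' observed allele absent from the dam is flagged non-Mendelian and that
#' progeny is excluded from calling.
#'
#' @param fam a `family_genotypes`.
#' @param x_hemizygous_marker_ids markers assumed hemizygous in males;
#'   defaults to the markers whose `mode` is `"x_hemizygous"`.
#' @return data.frame `individual_id`, `call` (`"M"`, `"F"`,
#'   `"unassigned"`, `"non_mendelian"`), `n_markers_used`, `note`.
#' @export
infer_progeny_sex <- function(fam, x_hemizygous_marker_ids = NULL) {
  stopifnot(inherits(fam, "family_genotypes"))
  if (is.null(x_hemizygous_marker_ids)) {
    x_hemizygous_marker_ids <-
      fam$markers$marker_id[!is.na(fam$markers$mode) &
                              fam$markers$mode == "x_hemizygous"]
  }
  if (length(x_hemizygous_marker_ids) == 0L) {
    stop_data("no hemizygous-mode markers available for sexing")
  }
  inf <- informative_sexing_markers(fam, x_hemizygous_marker_ids)
  use <- x_hemizygous_marker_ids[inf]
  if (length(use) == 0L) {
    stop_data("no informative (segregating) hemizygous-mode marker")
  }
  prog <- unique(fam$genotypes$individual_id)
  out <- lapply(prog, function(id) {
    ev <- character(0)
    for (mk in use) {
      al <- progeny_alleles(fam, id, mk)
      if (length(al) == 0L) next
      dam <- fam$dam[[mk]]
      if (length(al) == 1L) {
        ev <- c(ev, if (al %in% dam) "M" else "X")   # X = non-Mendelian
      } else {
        ev <- c(ev, "F")
      }
    }
    if (any(ev == "X")) {
      return(data.frame(individual_id = id, call = "non_mendelian",
                        n_markers_used = length(ev),
                        note = "allele absent from dam"))
    }
    call <- if (length(ev) == 0L) "unassigned"
    else if (all(ev == "M")) "M"
    else if (all(ev == "F")) "F"
    else "unassigned"
    note <- if (length(ev) > 0L && any(ev == "M") && any(ev == "F")) {
      "conflict: single-allele and two-allele markers disagree"
    } else ""
    data.frame(individual_id = id, call = call,
               n_markers_used = length(ev), note = note)
  })
  do.call(rbind, out)
}

#' Deduce paternal X alleles and paternity clusters from daughters
#'
#' For each daughter, the allele not carried by the dam at each marker is her
#' paternal X allele (ambiguous when both her alleles are dam alleles).
#' Daughters are grouped into paternity clusters by compatibility of their
#' multi-marker paternal haplotypes (two daughters share a cluster when no
#' marker gives them conflicting unambiguous paternal alleles; the grouping
#' is the transitive closure). The number of clusters is the inferred minimum
#' sire count.
#'
#' @param fam a `family_genotypes`.
#' @param sexes progeny sex calls: a named character vector or the data.frame
#'   from [infer_progeny_sex()].
#' @return list with `paternal` (data.frame `individual_id`, `marker_id`,
#'   `allele`, `ambiguous`), `clusters` (data.frame `individual_id`,
#'   `cluster`), `haplotypes` (data.frame `cluster`, `marker_id`, `allele`),
#'   and `n_sires`.
#' @export
infer_paternal_alleles <- function(fam, sexes) {
  stopifnot(inherits(fam, "family_genotypes"))
  if (is.data.frame(sexes)) {
    v <- sexes$call
    names(v) <- sexes$individual_id
    sexes <- v
  }
  daughters <- names(sexes)[sexes == "F"]
  daughters <- intersect(daughters, unique(fam$genotypes$individual_id))
  if (length(daughters) == 0L) stop_data("no daughters to deduce sires from")
  mks <- fam$markers$marker_id
  pat <- matrix(NA_character_, length(daughters), length(mks),
                dimnames = list(daughters, mks))
  rows <- list()
  for (id in daughters) {
    for (mk in mks) {
      al <- progeny_alleles(fam, id, mk)
      if (length(al) == 0L) next
      nondam <- setdiff(al, fam$dam[[mk]])
      amb <- length(nondam) != 1L
      if (!amb) pat[id, mk] <- nondam
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = id, marker_id = mk,
        allele = if (amb) NA_character_ else nondam, ambiguous = amb)
    }
  }
  # compatibility clustering (union-find): no conflicting unambiguous allele
  cl <- seq_along(daughters)
  find <- function(i) {
    while (cl[i] != i) i <- cl[i]
    i
  }
  for (i in seq_along(daughters)) {
    for (j in seq_len(i - 1L)) {
      both <- !is.na(pat[i, ]) & !is.na(pat[j, ])
      if (any(both) && all(pat[i, both] == pat[j, both])) {
        cl[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_along(daughters), find, 0L)
  cluster_id <- match(roots, unique(roots))
  hap <- do.call(rbind, lapply(unique(cluster_id), function(cid) {
    members <- which(cluster_id == cid)
    do.call(rbind, lapply(mks, function(mk) {
      als <- unique(stats::na.omit(pat[members, mk]))
      data.frame(cluster = cid, marker_id = mk,
                 allele = if (length(als) == 1L) als else NA_character_)
    }))
  }))
  list(paternal = if (length(rows)) do.call(rbind, rows) else
         data.frame(individual_id = character(), marker_id = character(),
                    allele = character(), ambiguous = logical()),
       clusters = data.frame(individual_id = daughters, cluster = cluster_id),
       haplotypes = hap,
       n_sires = length(unique(cluster_id)))
}

# Modal value of a character vector (NA when empty).
modal <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  names(sort(table(x), decreasing = TRUE))[1]
}

# Warn when two numeric (microsatellite-size) alleles differ by <= 2 bp:
# such pairs are easy to mis-score.
near_size_note <- function(alleles) {
  sizes <- suppressWarnings(as.numeric(alleles))
  sizes <- sort(sizes[!is.na(sizes)])
  if (length(sizes) < 2L) return("")
  d <- diff(sizes)
  if (any(d > 0 & d <= 2)) {
    i <- which(d > 0 & d <= 2)[1]
    sprintf("near-size alleles %g and %g differ by <= 2 bp", sizes[i],
            sizes[i + 1])
  } else ""
}

#' Classify one marker's sex linkage within a brood
#'
#' Scores recombinants against the sire's X allele (deduced from daughters)
#' and Y allele (the allele sires transmit to sons, when males carry two
#' alleles): a recombinant is a son carrying the sire-X allele or a daughter
#' carrying the sire-Y allele. Classes: `complete_sex_linked` when no
#' recombinant is seen among at least `min_informative` informative progeny;
#' `partial_sex_linked` when the recombinant fraction is positive but below
#' `partial_max`; `autosomal_like` when paternal alleles travel independently
#' of sex (exact binomial test against 0.5 not rejected); `hemizygous` when
#' all sons show a single allele at a marker where daughters show two;
#' `uninformative` otherwise.
#'
#' @param fam a `family_genotypes`.
#' @param marker_id marker to classify.
#' @param sexes progeny sex calls (named vector or [infer_progeny_sex()]
#'   output).
#' @param min_informative minimum informative progeny for a
#'   `complete_sex_linked` call (default 5).
#' @param partial_max recombinant-fraction cut between partial linkage and
#'   the binomial test (default 0.3).
#' @param alpha significance level for the binomial test (default 0.05).
#' @return one-row data.frame: `marker_id`, `class`, `recombinant_count`,
#'   `n_informative_progeny`, `note`.
#' @export
classify_marker_family <- function(fam, marker_id, sexes,
                                   min_informative = 5L, partial_max = 0.3,
                                   alpha = 0.05) {
  stopifnot(inherits(fam, "family_genotypes"))
  if (is.data.frame(sexes)) {
    v <- sexes$call
    names(v) <- sexes$individual_id
    sexes <- v
  }
  prog <- intersect(unique(fam$genotypes$individual_id), names(sexes))
  sons <- prog[sexes[prog] == "M"]
  daughters <- prog[sexes[prog] == "F"]
  dam <- fam$dam[[marker_id]]
  if (is.null(dam)) stop_data("unknown marker: ", marker_id)

  all_seen <- character(0)
  geno <- list()
  for (id in prog) {
    geno[[id]] <- progeny_alleles(fam, id, marker_id)
    all_seen <- c(all_seen, geno[[id]])
  }
  note <- near_size_note(unique(c(dam, all_seen)))
  res <- function(class, rec = 0L, n_inf = 0L, extra = "") {
    data.frame(marker_id = marker_id, class = class,
               recombinant_count = as.integer(rec),
               n_informative_progeny = as.integer(n_inf),
               note = trimws(paste(note, extra)))
  }
  if (length(unique(c(dam, all_seen))) < 2L) {
    return(res("uninformative", extra = "no segregating variation"))
  }

  paternal <- lapply(geno, function(al) setdiff(al, dam))
  son_pat <- unlist(lapply(sons, function(id) paternal[[id]]))
  dau_pat <- unlist(lapply(daughters, function(id) paternal[[id]]))
  son_two <- vapply(sons, function(id) length(geno[[id]]) >= 2L, TRUE)
  dau_two <- vapply(daughters, function(id) length(geno[[id]]) >= 2L, TRUE)

  # hemizygous pattern: sons never show a second/paternal allele while
  # daughters do
  if (length(sons) > 0L && !any(son_two) && any(dau_two)) {
    n_inf <- length(sons) + sum(dau_two)
    if (length(sons) >= 1L && n_inf >= min_informative) {
      return(res("hemizygous", 0L, n_inf,
                 paste("all", length(sons), "sons single-allele;",
                       "single-allele sons could also be heterozygotes for",
                       "common null alleles")))
    }
    return(res("uninformative", 0L, n_inf, "too few informative progeny"))
  }

  sire_x <- modal(dau_pat)
  sire_y <- modal(son_pat)
  sire_alleles <- unique(c(dau_pat, son_pat))
  # single sire heterozygous for two alleles: the allele that is not the
  # daughters' (X) allele must be the Y allele, and vice versa
  if (length(sire_alleles) == 2L) {
    if (!is.na(sire_x)) sire_y <- setdiff(sire_alleles, sire_x)
    else if (!is.na(sire_y)) sire_x <- setdiff(sire_alleles, sire_y)
  }
  if (is.na(sire_x) || is.na(sire_y) || sire_x == sire_y) {
    return(res("uninformative",
               extra = "paternal X and Y alleles not distinguishable"))
  }
  rec_sons <- sum(vapply(sons, function(id) sire_x %in% paternal[[id]], TRUE))
  rec_daus <- sum(vapply(daughters, function(id) sire_y %in% paternal[[id]],
                         TRUE))
  inf_sons <- sum(vapply(sons, function(id) length(paternal[[id]]) > 0L, TRUE))
  inf_daus <- sum(vapply(daughters, function(id) length(paternal[[id]]) > 0L,
                         TRUE))
  rec <- rec_sons + rec_daus
  n_inf <- inf_sons + inf_daus
  if (n_inf == 0L) return(res("uninformative"))
  frac <- rec / n_inf
  if (rec == 0L) {
    if (n_inf >= min_informative) return(res("complete_sex_linked", 0L, n_inf))
    return(res("uninformative", 0L, n_inf, "too few informative progeny"))
  }
  if (frac < partial_max) return(res("partial_sex_linked", rec, n_inf))
  p <- stats::binom.test(rec, n_inf, 0.5)$p.value
  if (p > alpha) {
    return(res("autosomal_like", rec, n_inf,
               sprintf("binomial p = %.3f vs 0.5", p)))
  }
  res("partial_sex_linked", rec, n_inf,
      sprintf("recombinant fraction %.2f, binomial p = %.3f", frac, p))
}

#' Population-sample sex-linkage summary for a marker
#'
#' From genotypes of males and females sampled in a population: computes the
#' female and male allele sets, the count of heterozygous males, the
#' male-specific alleles (observed only in males; flagged low-confidence when
#' fewer than 10 females were sampled) and the fixed female allele, if any.
#' Inferred classes: `complete_sex_linked_Y_polymorphic` when females are
#' fixed for one allele and heterozygous males carry male-specific alleles
#' (an X-fixed allele with a polymorphic Y); `hemizygous_consistent` when the
#' marker is polymorphic but no male is ever heterozygous;
#' `partial_sex_linked_like` when males are heterozygous for alleles shared
#' with females; `uninformative` otherwise.
#'
#' @param genotypes data.frame: `individual_id`, `sex` (`"M"`/`"F"`),
#'   `marker_id`, `allele1`, `allele2` (`NA` = single observed allele, scored
#'   as homozygous/hemizygous).
#' @param marker_id marker to summarize (default: the only one present).
#' @param min_per_sex minimum individuals per sex (default 5).
#' @return an object of class `population_marker_summary`.
#' @export
population_linkage_summary <- function(genotypes, marker_id = NULL,
                                       min_per_sex = 5L) {
  genotypes <- as.data.frame(genotypes)
  stopifnot(all(c("individual_id", "sex", "marker_id", "allele1", "allele2")
                %in% names(genotypes)))
  if (is.null(marker_id)) {
    marker_id <- unique(genotypes$marker_id)
    if (length(marker_id) != 1L) stop_data("specify marker_id")
  }
  g <- genotypes[genotypes$marker_id == marker_id &
                   genotypes$sex %in% c("M", "F"), , drop = FALSE]
  n_m <- sum(g$sex == "M")
  n_f <- sum(g$sex == "F")
  if (n_m < min_per_sex || n_f < min_per_sex) {
    stop_data("need >= ", min_per_sex, " genotyped individuals per sex, have ",
              n_m, " males / ", n_f, " females")
  }
  alleles_of <- function(rows) unique(stats::na.omit(c(rows$allele1,
                                                       rows$allele2)))
  gm <- g[g$sex == "M", , drop = FALSE]
  gf <- g[g$sex == "F", , drop = FALSE]
  m_alleles <- alleles_of(gm)
  f_alleles <- alleles_of(gf)
  het <- function(rows) !is.na(rows$allele2) & rows$allele2 != rows$allele1
  m_het <- het(gm)
  male_specific <- setdiff(m_alleles, f_alleles)
  f_fixed <- if (length(f_alleles) == 1L && !any(het(gf))) f_alleles else
    NA_character_
  het_specific <- any(vapply(which(m_het), function(i) {
    any(c(gm$allele1[i], gm$allele2[i]) %in% male_specific)
  }, TRUE))
  class <- if (length(unique(c(m_alleles, f_alleles))) < 2L) {
    "uninformative"
  } else if (!is.na(f_fixed) && length(male_specific) >= 1L &&
             any(m_het) && het_specific) {
    "complete_sex_linked_Y_polymorphic"
  } else if (!any(m_het)) {
    "hemizygous_consistent"
  } else if (any(vapply(which(m_het), function(i) {
    all(c(gm$allele1[i], gm$allele2[i]) %in% f_alleles)
  }, TRUE))) {
    "partial_sex_linked_like"
  } else {
    "uninformative"
  }
  structure(list(
    marker_id = marker_id,
    n_males = n_m, n_females = n_f,
    male_alleles = m_alleles, female_alleles = f_alleles,
    male_specific_alleles = male_specific,
    male_specific_low_confidence = n_f < 10L && length(male_specific) > 0L,
    n_heterozygous_males = sum(m_het),
    fixed_female_allele = f_fixed,
    class = class,
    note = near_size_note(unique(c(m_alleles, f_alleles)))
  ), class = "population_marker_summary")
}

#' @export
print.population_marker_summary <- function(x, ...) {
  cat(sprintf(
    "<population_marker_summary> %s: %s (%d M / %d F; %d het males; male-specific: %s)\n",
    x$marker_id, x$class, x$n_males, x$n_females, x$n_heterozygous_males,
    if (length(x$male_specific_alleles)) {
      paste(x$male_specific_alleles, collapse = ",")
    } else "none"))
  invisible(x)
}

#' Read brood or population genotypes from TSV
#'
#' Long-format genotype table with columns `individual_id`, `family_id` (or
#' `population`), `sex`, `marker_id`, `allele1`, `allele2`. Rows whose
#' `individual_id` is `"dam"` define the dam genotype of that family.
#'
#' @param path TSV file path.
#' @return list of `family_genotypes` (one per `family_id`) when a
#'   `family_id` column is present, otherwise the data.frame itself for
#'   [population_linkage_summary()].
#' @export
read_genotypes <- function(path) {
  df <- read_tsv_cols(path, c("individual_id", "marker_id", "allele1"))
  if (is.null(df$allele2)) df$allele2 <- NA_character_
  df$allele1 <- as.character(df$allele1)
  df$allele2 <- as.character(df$allele2)
  if (!"family_id" %in% names(df)) return(df)
  lapply(split(df, df$family_id), function(d) {
    dam_rows <- d[d$individual_id == "dam", , drop = FALSE]
    if (nrow(dam_rows) == 0L) stop_data("family ", d$family_id[1],
                                        " lacks dam rows")
    dam <- lapply(split(dam_rows, dam_rows$marker_id), function(r) {
      unique(stats::na.omit(c(r$allele1, r$allele2)))
    })
    prog <- d[d$individual_id != "dam", , drop = FALSE]
    known <- NULL
    if ("sex" %in% names(prog) && any(prog$sex %in% c("M", "F"))) {
      known <- prog$sex[!duplicated(prog$individual_id)]
      names(known) <- prog$individual_id[!duplicated(prog$individual_id)]
    }
    mode <- if ("mode" %in% names(d)) {
      md <- d$mode[!duplicated(d$marker_id)]
      names(md) <- d$marker_id[!duplicated(d$marker_id)]
      md[names(dam)]
    } else NA_character_
    family_genotypes(
      family_id = d$family_id[1], dam = dam,
      genotypes = prog[c("individual_id", "marker_id", "allele1", "allele2")],
      markers = data.frame(marker_id = names(dam), position = NA_real_,
                           mode = unname(mode)),
      known_sexes = known)
  })
}
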