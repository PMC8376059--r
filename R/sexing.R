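# Genetic sexing from X/autosome coverage ratios. In an XY system with a
# degenerated Y, males carry one copy of most X-linked genes and females two,
# so after autosomal normalization an individual's median coverage over
# X-linked genes (the X/A ratio) is about 0.5 in males and 1 in females.

#' X/autosome coverage ratio per individual
#'
#' Median normalized coverage over a set of putative X-linked genes; because
#' the autosomal median is 1 after normalization, this equals the X/A ratio.
#'
#' @param x a normalized `coverage_dataset`.
#' @param x_gene_ids candidate X-linked gene ids (flagged genes are skipped).
#' @param min_genes minimum number of usable X genes (default 10).
#' @return named numeric vector of X/A ratios, one per individual, with
#'   attribute `n_genes_used`.
#' @export
xa_ratios <- function(x, x_gene_ids, min_genes = 10L) {
  if (!is_normalized(x)) stop_data("xa_ratios needs a normalized dataset")
  use <- setdiff(intersect(x_gene_ids, rownames(x$values)), flagged_genes(x))
  if (length(use) < min_genes) {
    stop_data("too few usable X-linked genes: ", length(use), " < ", min_genes)
  }
  r <- apply(x$values[use, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  attr(r, "n_genes_used") <- length(use)
  r
}

#' Assign sexes from X/A ratios
#'
#' Fixed-threshold classifier: an individual is called male when its X/A
#' ratio is at most `male_max`, female when at least `female_min`, otherwise
#' left unassigned (and excluded from downstream sexed scopes). For cohorts
#' where the two clusters sit elsewhere, `method = "kmeans"` splits the
#' ratios by 1-D two-means and labels the lower-centre cluster male.
#'
#' @param ratios named numeric vector from [xa_ratios()].
#' @param male_max call M when ratio <= this (default 0.70).
#' @param female_min call F when ratio >= this (default 0.85).
#' @param method `"threshold"` (default) or `"kmeans"`.
#' @return data.frame with columns `individual_id`, `xa_ratio`, `call`
#'   (`"M"`, `"F"` or `"unassigned"`) and `n_genes_used`.
#' @export
assign_sexes <- function(ratios, male_max = 0.70, female_min = 0.85,
                         method = c("threshold", "kmeans")) {
  method <- match.arg(method)
  if (method == "threshold" && male_max >= female_min) {
    stop_config("male_max must be < female_min")
  }
  call <- if (method == "threshold") {
    ifelse(ratios <= male_max, "M",
           ifelse(ratios >= female_min, "F", "unassigned"))
  } else {
    if (length(unique(ratios)) < 2L) {
      rep("unassigned", length(ratios))
    } else {
      km <- stats::kmeans(ratios, centers = 2L, nstart = 5L)
      male_cluster <- which.min(km$centers)
      ifelse(km$cluster == male_cluster, "M", "F")
    }
  }
  data.frame(individual_id = names(ratios),
             xa_ratio = unname(ratios),
             call = unname(call),
             n_genes_used = attr(ratios, "n_genes_used") %||% NA_integer_,
             row.names = NULL)
}

#' Sex every individual in a dataset
#'
#' Convenience wrapper: [xa_ratios()] then [assign_sexes()]. Known sexes from
#' the sample sheet override the coverage-based calls; disagreements are
#' reported in a `conflict` column.
#'
#' @param x a normalized `coverage_dataset`.
#' @param x_gene_ids candidate X-linked gene ids.
#' @param override_known keep sample-sheet sexes where recorded (default
#'   TRUE).
#' @inheritParams assign_sexes
#' @inheritParams xa_ratios
#' @return the [assign_sexes()] data.frame plus `known_sex` and `conflict`
#'   columns.
#' @export
sex_individuals <- function(x, x_gene_ids, male_max = 0.70, female_min = 0.85,
                            method = c("threshold", "kmeans"),
                            min_genes = 10L, override_known = TRUE) {
  r <- xa_ratios(x, x_gene_ids, min_genes = min_genes)
  calls <- assign_sexes(r, male_max = male_max, female_min = female_min,
                        method = method)
  known <- x$samples$sex[match(calls$individual_id, x$samples$individual_id)]
  calls$known_sex <- known
  has_known <- known %in% c("M", "F")
  calls$conflict <- has_known & calls$call %in% c("M", "F") &
    calls$call != known
  if (override_known) calls$call[has_known] <- known[has_known]
  calls
}
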