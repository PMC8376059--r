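# Gene-level degeneration calls from M/F coverage ratios, region contrasts,
# cross-population consistency, and pseudoautosomal-boundary detection.

#' Classification windows for M/F coverage ratios
#'
#' The biological anchors are 0.5 (one male copy, two female copies), 1
#' (diploid in both sexes) and the > 1.4 cut for Y-linked duplications; the
#' window widths around 0.5 and 1 are tunable.
#'
#' @param hemizygous closed interval for hemizygous calls (default
#'   `c(0.3, 0.7)`).
#' @param diploid closed interval for diploid calls (default `c(0.8, 1.2)`).
#' @param duplicated_min ratios strictly above this are duplicated (default
#'   1.4).
#' @return named list of windows.
#' @export
class_windows <- function(hemizygous = c(0.3, 0.7), diploid = c(0.8, 1.2),
                          duplicated_min = 1.4) {
  if (hemizygous[2] >= diploid[1] || diploid[2] > duplicated_min) {
    stop_config("class windows must be ordered and non-overlapping")
  }
  list(hemizygous = hemizygous, diploid = diploid,
       duplicated_min = duplicated_min)
}

#' Classify genes by M/F coverage ratio
#'
#' `hemizygous` within the hemizygous window (closed), `diploid` within the
#' diploid window (closed), `duplicated` strictly above the duplication cut,
#' `ambiguous` elsewhere, `no-call` for undefined (`NA`) ratios. The windows
#' partition `[0, Inf)` without overlap.
#'
#' @param mf_ratio numeric vector of M/F ratios (may contain `NA`).
#' @param windows list from [class_windows()].
#' @return character vector of classes.
#' @export
#' @examples
#' classify_gene(c(0.53, 1.01, 1.5, 0.75, NA))
classify_gene <- function(mf_ratio, windows = class_windows()) {
  out <- rep("ambiguous", length(mf_ratio))
  out[which(mf_ratio >= windows$hemizygous[1] &
              mf_ratio <= windows$hemizygous[2])] <- "hemizygous"
  out[which(mf_ratio >= windows$diploid[1] &
              mf_ratio <= windows$diploid[2])] <- "diploid"
  out[which(mf_ratio > windows$duplicated_min)] <- "duplicated"
  out[is.na(mf_ratio)] <- "no-call"
  out
}

#' Per-gene degeneration calls with region labels
#'
#' Joins a ratio table with the gene annotation, classifies each gene, and
#' labels its region (`hemizygous_region`, `PAR`, `autosome` or `other`) from
#' the genome intervals when a `genome_spec` is supplied.
#'
#' @param ratios data.frame from [ratio_table()].
#' @param genes gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param windows list from [class_windows()].
#' @param genome optional `genome_spec` supplying region intervals.
#' @return data.frame `gene_id, scope, chrom, start, mf_ratio, class, region`.
#' @export
gene_calls <- function(ratios, genes, windows = class_windows(),
                       genome = NULL) {
  m <- match(ratios$gene_id, genes$gene_id)
  if (anyNA(m)) stop_data("ratio table contains genes absent from annotation")
  out <- data.frame(gene_id = ratios$gene_id, scope = ratios$scope,
                    chrom = genes$chrom[m], start = genes$start[m],
                    mf_ratio = ratios$mf_ratio,
                    class = classify_gene(ratios$mf_ratio, windows),
                    region = "other", row.names = NULL)
  if (!is.null(genome)) {
    on_sex <- out$chrom == genome$sex_chromosome
    out$region[!on_sex] <- "autosome"
    hz <- genome$hemizygous_interval
    pr <- genome$par_interval
    out$region[on_sex & out$start >= hz[1] & out$start <= hz[2]] <-
      "hemizygous_region"
    out$region[on_sex & out$start >= pr[1] & out$start <= pr[2]] <- "PAR"
  }
  out
}

#' Summarize calls in a genomic region
#'
#' Counts and median M/F ratio over genes whose start coordinate lies in the
#' region, skipping no-calls for the median.
#'
#' @param calls data.frame from [gene_calls()] (one scope).
#' @param region numeric length-2 bp interval `c(start, end)`.
#' @param chromosome chromosome name; defaults to all chromosomes in `calls`.
#' @return list `n_genes`, `n_per_class` (named integer vector),
#'   `median_mf_ratio`.
#' @export
region_summary <- function(calls, region, chromosome = NULL) {
  sel <- calls$start >= region[1] & calls$start <= region[2]
  if (!is.null(chromosome)) sel <- sel & calls$chrom == chromosome
  sub <- calls[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    warning("region contains no genes")
    return(list(n_genes = 0L, n_per_class = integer(0),
                median_mf_ratio = NA_real_))
  }
  list(n_genes = nrow(sub),
       n_per_class = table(sub$class),
       median_mf_ratio = stats::median(sub$mf_ratio, na.rm = TRUE))
}

#' Compare M/F ratios between two gene sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For small samples
#' (`min(n) <= 8`, and a feasible number of rank assignments) the p-value is
#' computed by exact enumeration of all assignments of the pooled midranks,
#' which remains exact in the presence of ties; otherwise the normal
#' approximation with continuity correction is used.
#'
#' @param ratios_a,ratios_b numeric vectors (each nonempty; `NA` dropped).
#' @param exact_max_n largest `min(n)` for which enumeration is attempted
#'   (default 8).
#' @return list `statistic` (rank-sum W of the first set), `p_value`,
#'   `method`.
#' @export
compare_regions <- function(ratios_a, ratios_b, exact_max_n = 8L) {
  a <- ratios_a[!is.na(ratios_a)]
  b <- ratios_b[!is.na(ratios_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop_data("compare_regions: both sets must be nonempty")
  }
  n1 <- length(a)
  n <- n1 + length(b)
  rk <- rank(c(a, b))
  w_obs <- sum(rk[seq_len(n1)])
  n_assign <- choose(n, n1)
  if (min(n1, n - n1) <= exact_max_n && n_assign <= 5e5) {
    mu <- n1 * (n + 1) / 2
    sums <- utils::combn(rk, n1, sum)
    p <- mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = w_obs, p_value = p, method = "exact_enumeration"))
  }
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(statistic = w_obs, p_value = wt$p.value,
       method = "normal_approximation")
}

#' Cross-population consistency of a call class
#'
#' For a given class (e.g. `"duplicated"`), records, for every gene called
#' that class in at least one population, the pattern of populations making
#' the call, and counts genes per pattern - the tabulation behind an upset
#' plot. Degeneration is expected to give consistent hemizygosity across
#' populations, whereas artefactual duplication signals tend to be
#' population-specific.
#'
#' @param calls data.frame from [gene_calls()] with per-population scopes
#'   (the `"pooled"` scope is ignored).
#' @param class class label to trace across populations.
#' @return list with `patterns` (data.frame `pattern`, `n_genes`),
#'   `gene_patterns` (data.frame `gene_id`, `pattern`, `n_populations`),
#'   `n_populations`, and `n_consistent` (genes called in every population).
#' @export
consistency_table <- function(calls, class) {
  calls <- calls[calls$scope != "pooled", , drop = FALSE]
  pops <- sort(unique(calls$scope))
  if (length(pops) < 2L) stop_data("consistency needs >= 2 populations")
  hit <- calls[calls$class == class, c("gene_id", "scope")]
  if (nrow(hit) == 0L) {
    return(list(patterns = data.frame(pattern = character(),
                                      n_genes = integer()),
                gene_patterns = data.frame(gene_id = character(),
                                           pattern = character(),
                                           n_populations = integer()),
                n_populations = length(pops), n_consistent = 0L))
  }
  by_gene <- split(hit$scope, hit$gene_id)
  gp <- data.frame(
    gene_id = names(by_gene),
    pattern = vapply(by_gene, function(p) paste(sort(unique(p)),
                                                collapse = "+"), ""),
    n_populations = vapply(by_gene, function(p) length(unique(p)), 0L),
    row.names = NULL)
  tab <- table(gp$pattern)
  list(patterns = data.frame(pattern = names(tab),
                             n_genes = as.integer(tab), row.names = NULL),
       gene_patterns = gp,
       n_populations = length(pops),
       n_consistent = sum(gp$n_populations == length(pops)))
}

#' Detect the pseudoautosomal boundary along a chromosome
#'
#' Models the ordered M/F ratios as a step function: hemizygous level
#' (default 0.5) proximal to the boundary, diploid level (default 1) distal
#' to it, and picks the change-point `k` minimizing the residual sum of
#' squares `sum_(i<=k) (r_i - 0.5)^2 + sum_(i>k) (r_i - 1)^2` over
#' `k = 0..n`. `k = 0` means the whole chromosome looks pseudoautosomal;
#' `k = n` means no PAR. Ties are broken toward the most distal `k`. With
#' `free_levels = TRUE` the two segment levels are fitted as segment means
#' instead (a QC variant not tied to the 0.5/1 hypothesis).
#'
#' @param calls data.frame with columns `gene_id`, `start`, `mf_ratio`
#'   (one scope, one chromosome); rows with `NA` ratios are dropped.
#' @param levels fixed `c(proximal, distal)` levels (default `c(0.5, 1)`).
#' @param free_levels fit segment means instead of fixed levels.
#' @param chromosome label carried into the result.
#' @return an object of class `boundary_estimate`: list with `chromosome`,
#'   `k` (number of genes proximal to the boundary), `boundary_bp` (midpoint
#'   between the flanking gene starts, or the chromosome end gene start at
#'   the extremes), `flanking_genes`, `proximal_level`, `distal_level`,
#'   `residual`, `n_genes`.
#' @export
detect_boundary <- function(calls, levels = c(0.5, 1), free_levels = FALSE,
                            chromosome = NA_character_) {
  d <- calls[!is.na(calls$mf_ratio), , drop = FALSE]
  d <- d[order(d$start, d$gene_id), , drop = FALSE]
  n <- nrow(d)
  if (n < 4L) stop_data("detect_boundary needs >= 4 genes with defined ratios")
  r <- d$mf_ratio
  if (free_levels) {
    rss <- vapply(0:n, function(k) {
      lo <- if (k > 0) sum((r[seq_len(k)] - mean(r[seq_len(k)]))^2) else 0
      hi <- if (k < n) sum((r[(k + 1):n] - mean(r[(k + 1):n]))^2) else 0
      lo + hi
    }, 0)
  } else {
    cs1 <- cumsum((r - levels[1])^2)
    cs2 <- cumsum((r - levels[2])^2)
    # rss(k) = cs1[k] + (cs2[n] - cs2[k]); k = 0..n
    rss <- c(0, cs1) + (cs2[n] - c(0, cs2))
  }
  k <- max(which(rss <= min(rss) + 1e-12)) - 1L # ties -> most distal k
  prox_level <- if (free_levels && k > 0) mean(r[seq_len(k)]) else levels[1]
  dist_level <- if (free_levels && k < n) mean(r[(k + 1):n]) else levels[2]
  boundary_bp <- if (k == 0L) d$start[1] else if (k == n) d$start[n] else
    (d$start[k] + d$start[k + 1L]) / 2
  flank <- c(if (k > 0L) d$gene_id[k] else NA_character_,
             if (k < n) d$gene_id[k + 1L] else NA_character_)
  structure(list(chromosome = chromosome, k = k, boundary_bp = boundary_bp,
                 flanking_genes = flank,
                 proximal_level = prox_level, distal_level = dist_level,
                 residual = rss[k + 1L], n_genes = n),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf(
    "<boundary_estimate> %s: boundary after %d of %d genes (bp %.0f), levels %.3g -> %.3g, residual %.4g\n",
    x$chromosome, x$k, x$n_genes, x$boundary_bp,
    x$proximal_level, x$distal_level, x$residual))
  invisible(x)
}
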