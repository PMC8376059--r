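# Coverage datasets: container, I/O, per-individual normalization,
# gene-level quality filters and M/F, M/A, F/A ratio tables.

#' Construct a coverage dataset
#'
#' Bundles a per-gene annotation table, a sample sheet and a genes-by-
#' individuals matrix of mean read depths into one object. Depth values are
#' reads-per-base averages over each gene, one value per (gene, individual).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive base-pair coordinates) and optionally `true_class`
#'   (carried along by the simulator for scoring).
#' @param samples data.frame with columns `individual_id`, `population`, `sex`
#'   (`"M"`, `"F"` or `"U"` for unknown).
#' @param values numeric matrix of coverage, rows = genes (rownames =
#'   `gene_id`), columns = individuals (colnames = `individual_id`). `NA`
#'   encodes a gene with no genotype/coverage call in that individual.
#' @param flags data.frame of per-gene exclusion flags with columns `gene_id`
#'   and `reason`; empty by default.
#' @return an object of class `coverage_dataset`.
#' @export
coverage_dataset <- function(genes, samples, values,
                             flags = data.frame(gene_id = character(),
                                                reason = character())) {
  genes <- as.data.frame(genes)
  samples <- as.data.frame(samples)
  need_g <- c("gene_id", "chrom", "start", "end")
  if (!all(need_g %in% names(genes))) {
    stop_data("gene annotation needs columns: ", paste(need_g, collapse = ", "))
  }
  need_s <- c("individual_id", "population", "sex")
  if (!all(need_s %in% names(samples))) {
    stop_data("sample sheet needs columns: ", paste(need_s, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) stop_data("duplicated gene_id in annotation")
  if (anyDuplicated(samples$individual_id)) {
    stop_data("duplicated individual_id in sample sheet")
  }
  if (any(genes$start > genes$end)) stop_data("gene with start > end")
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_data("coverage matrix must carry gene and individual dimnames")
  }
  if (!setequal(rownames(values), genes$gene_id) ||
      !setequal(colnames(values), samples$individual_id)) {
    stop_data("coverage matrix dimnames must match annotation and sample sheet")
  }
  values <- values[genes$gene_id, samples$individual_id, drop = FALSE]
  if (any(values < 0, na.rm = TRUE)) stop_data("negative coverage value")
  structure(
    list(genes = genes, samples = samples, values = values,
         flags = as.data.frame(flags)),
    class = "coverage_dataset",
    normalized = FALSE
  )
}

#' @export
print.coverage_dataset <- function(x, ...) {
  cat(sprintf(
    "<coverage_dataset> %d genes x %d individuals (%d populations)%s\n",
    nrow(x$values), ncol(x$values), length(unique(x$samples$population)),
    if (isTRUE(attr(x, "normalized"))) ", normalized" else ""
  ))
  if (nrow(x$flags) > 0L) {
    cat(sprintf("  %d flagged gene(s): %s\n",
                length(unique(x$flags$gene_id)),
                paste(names(sort(table(x$flags$reason), decreasing = TRUE)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Is a dataset normalized?
#' @param x a `coverage_dataset`.
#' @return logical scalar.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# Gene ids currently carrying at least one exclusion flag.
flagged_genes <- function(x) unique(x$flags$gene_id)

#' Autosomal gene ids of a dataset
#'
#' Convenience accessor: every gene on a chromosome other than
#' `sex_chromosome`.
#'
#' @param x a `coverage_dataset`.
#' @param sex_chromosome chromosome name carrying the sex-determining region.
#' @return character vector of gene ids.
#' @export
autosomal_genes <- function(x, sex_chromosome) {
  x$genes$gene_id[x$genes$chrom != sex_chromosome]
}

#' Normalize one individual's coverage by its autosomal baseline
#'
#' Divides each gene's depth by the individual's median (or mean) depth over
#' autosomal genes, so the autosomal baseline becomes exactly 1 and
#' individuals sequenced to different depths become comparable.
#'
#' @param values named numeric vector of coverage for one individual.
#' @param autosomal_gene_ids character vector of gene ids forming the
#'   baseline.
#' @param stat `"median"` (default, robust to sex-linked copy-number) or
#'   `"mean"`.
#' @return numeric vector of normalized coverage, same names as `values`.
#' @export
#' @examples
#' normalize_individual(c(a = 10, b = 20, c = 30, x = 10), c("a", "b", "c"))
normalize_individual <- function(values, autosomal_gene_ids,
                                 stat = c("median", "mean")) {
  stat <- match.arg(stat)
  auto <- values[intersect(names(values), autosomal_gene_ids)]
  auto <- auto[!is.na(auto)]
  if (length(auto) == 0L || !any(auto > 0)) {
    stop_data("cannot normalize: no positive autosomal coverage")
  }
  base <- if (stat == "median") stats::median(auto) else mean(auto)
  values / base
}

#' Normalize every individual in a dataset
#'
#' Applies [normalize_individual()] column-wise. Flagged genes are excluded
#' from the autosomal baseline but are still themselves rescaled.
#' Normalization is idempotent: the baseline of an already-normalized
#' individual is 1.
#'
#' @param x a `coverage_dataset`.
#' @param sex_chromosome name of the sex chromosome; every gene elsewhere is
#'   autosomal. Ignored when `autosomal_gene_ids` is given.
#' @param autosomal_gene_ids explicit baseline gene set (optional).
#' @param stat passed to [normalize_individual()].
#' @return the dataset with normalized values and `normalized` attribute set.
#' @export
normalize_dataset <- function(x, sex_chromosome = NULL,
                              autosomal_gene_ids = NULL,
                              stat = c("median", "mean")) {
  stat <- match.arg(stat)
  if (is.null(autosomal_gene_ids)) {
    if (is.null(sex_chromosome)) {
      stop_data("give sex_chromosome or autosomal_gene_ids")
    }
    autosomal_gene_ids <- autosomal_genes(x, sex_chromosome)
  }
  autosomal_gene_ids <- setdiff(autosomal_gene_ids, flagged_genes(x))
  if (length(autosomal_gene_ids) == 0L) {
    stop_data("no unflagged autosomal genes to normalize against")
  }
  x$values <- apply(x$values, 2L, normalize_individual,
                    autosomal_gene_ids = autosomal_gene_ids, stat = stat)
  attr(x, "normalized") <- TRUE
  x
}

#' Default gene-filter policy
#'
#' Thresholds for [filter_genes()]. A gene is flagged (never deleted) when it
#' is missing a value in any individual, when its mean per-individual depth
#' does not exceed `min_mean_count`, when its mean depth exceeds
#' `high_count_multiplier` times the dataset-wide median of gene means
#' (repetitive/collapsed sequence), or (normalized data with sexed samples
#' only) when the pooled female normalized coverage falls below
#' `min_female_norm`.
#'
#' @param min_mean_count minimum mean raw depth per individual; default 10.
#' @param high_count_multiplier multiple of the median gene mean above which
#'   a gene is considered repetitive; default 20.
#' @param min_female_norm minimum pooled female normalized coverage; default
#'   0.1.
#' @param require_complete flag genes missing in some individuals; default
#'   TRUE.
#' @return a named list of thresholds.
#' @export
filter_policy <- function(min_mean_count = 10, high_count_multiplier = 20,
                          min_female_norm = 0.1, require_complete = TRUE) {
  stopifnot(min_mean_count >= 0, high_count_multiplier > 1,
            min_female_norm >= 0)
  list(min_mean_count = min_mean_count,
       high_count_multiplier = high_count_multiplier,
       min_female_norm = min_female_norm,
       require_complete = require_complete)
}

#' Flag low-quality genes
#'
#' Applies the inclusion rules of the filter policy and records
#' machine-readable reasons: `missing_in_some_individuals`, `low_mean_count`,
#' `extreme_high_count`, and `low_female_coverage` (the last only when the
#' dataset is normalized and contains individuals of known female sex).
#' Downstream operations skip flagged genes.
#'
#' @param x a `coverage_dataset` (raw or normalized).
#' @param policy a list from [filter_policy()].
#' @param sexes optional named character vector of sex calls
#'   (`individual_id` -> `"M"`/`"F"`/`"U"`) overriding the sample sheet.
#' @return the dataset with its `flags` table extended.
#' @export
filter_genes <- function(x, policy = filter_policy(), sexes = NULL) {
  v <- x$values
  flags <- list(x$flags)
  if (isTRUE(policy$require_complete)) {
    miss <- rownames(v)[rowSums(is.na(v)) > 0L]
    if (length(miss)) {
      flags <- c(flags, list(data.frame(gene_id = miss,
                                        reason = "missing_in_some_individuals")))
    }
  }
  gene_means <- rowMeans(v, na.rm = TRUE)
  if (!is_normalized(x)) {
    low <- names(gene_means)[is.finite(gene_means) &
                               gene_means <= policy$min_mean_count]
    if (length(low)) {
      flags <- c(flags, list(data.frame(gene_id = low,
                                        reason = "low_mean_count")))
    }
    med <- stats::median(gene_means, na.rm = TRUE)
    hi <- names(gene_means)[is.finite(gene_means) &
                              gene_means > policy$high_count_multiplier * med]
    if (length(hi)) {
      flags <- c(flags, list(data.frame(gene_id = hi,
                                        reason = "extreme_high_count")))
    }
  }
  if (is_normalized(x)) {
    sx <- resolve_sexes(x, sexes)
    f_ids <- names(sx)[sx == "F"]
    if (length(f_ids) > 0L) {
      fmean <- rowMeans(v[, f_ids, drop = FALSE], na.rm = TRUE)
      lowf <- names(fmean)[is.finite(fmean) & fmean < policy$min_female_norm]
      if (length(lowf)) {
        flags <- c(flags, list(data.frame(gene_id = lowf,
                                          reason = "low_female_coverage")))
      }
    }
  }
  fl <- do.call(rbind, flags)
  fl <- fl[!duplicated(fl[c("gene_id", "reason")]), , drop = FALSE]
  rownames(fl) <- NULL
  x$flags <- fl
  if (length(setdiff(x$genes$gene_id, fl$gene_id)) == 0L) {
    warning("all genes flagged; nothing survives the filter")
  }
  x
}

# Sample sexes, optionally overridden by a named vector of calls.
resolve_sexes <- function(x, sexes = NULL) {
  sx <- x$samples$sex
  names(sx) <- x$samples$individual_id
  if (!is.null(sexes)) {
    if (is.data.frame(sexes)) {
      v <- sexes$call
      names(v) <- sexes$individual_id
      sexes <- v
    }
    known <- intersect(names(sexes), names(sx))
    sx[known] <- sexes[known]
  }
  sx
}

#' Per-gene M/F, M/A and F/A coverage ratios
#'
#' For each scope (each population, then a pooled scope) computes, per gene,
#' the ratio of mean normalized male coverage to mean normalized female
#' coverage (M/F), and the sex-specific means themselves, which after
#' autosomal-median normalization are male/autosome (M/A) and female/autosome
#' (F/A) ratios. The pooled scope averages per-population ratios with equal
#' weight over the populations where the ratio is defined, so unevenly sized
#' populations do not dominate. Genes whose female mean is 0 are returned as
#' `NA` (no-call) rather than infinity; flagged genes and unsexed individuals
#' are skipped.
#'
#' @param x a normalized `coverage_dataset`.
#' @param sexes optional sex calls overriding the sample sheet (a named
#'   vector or the data.frame from [assign_sexes()]).
#' @param pooling `"per_population_mean"` (default) or `"all_individuals"`,
#'   which pools every sexed individual into one scope directly.
#' @return data.frame with columns `gene_id`, `scope`, `mf_ratio`,
#'   `ma_ratio`, `fa_ratio`, `n_males`, `n_females`.
#' @export
ratio_table <- function(x, sexes = NULL,
                        pooling = c("per_population_mean", "all_individuals")) {
  pooling <- match.arg(pooling)
  if (!is_normalized(x)) stop_data("ratio_table needs a normalized dataset")
  sx <- resolve_sexes(x, sexes)
  keep_genes <- setdiff(x$genes$gene_id, flagged_genes(x))
  if (length(keep_genes) == 0L) stop_data("no unflagged genes")
  v <- x$values[keep_genes, , drop = FALSE]

  scope_ratio <- function(ids, scope) {
    m_ids <- ids[sx[ids] == "M"]
    f_ids <- ids[sx[ids] == "F"]
    if (length(m_ids) == 0L || length(f_ids) == 0L) return(NULL)
    m <- rowMeans(v[, m_ids, drop = FALSE], na.rm = TRUE)
    f <- rowMeans(v[, f_ids, drop = FALSE], na.rm = TRUE)
    mf <- ifelse(is.finite(f) & f > 0, m / f, NA_real_)
    data.frame(gene_id = keep_genes, scope = scope, mf_ratio = mf,
               ma_ratio = m, fa_ratio = f,
               n_males = length(m_ids), n_females = length(f_ids),
               row.names = NULL)
  }

  ids_all <- x$samples$individual_id
  if (pooling == "all_individuals") {
    out <- scope_ratio(ids_all, "pooled")
    if (is.null(out)) stop_data("need at least one individual of each sex")
    return(out)
  }

  pops <- split(ids_all, x$samples$population)
  per_pop <- Filter(Negate(is.null),
                    mapply(scope_ratio, pops, names(pops), SIMPLIFY = FALSE))
  if (length(per_pop) == 0L) {
    stop_data("no population has individuals of both sexes")
  }
  pop_df <- do.call(rbind, per_pop)
  # pooled scope: equal-weight mean of per-population ratios where defined
  pool_one <- function(col) {
    m <- matrix(unlist(lapply(per_pop, `[[`, col)), nrow = length(keep_genes))
    rowMeans(m, na.rm = TRUE)
  }
  pooled <- data.frame(
    gene_id = keep_genes, scope = "pooled",
    mf_ratio = pool_one("mf_ratio"),
    ma_ratio = pool_one("ma_ratio"),
    fa_ratio = pool_one("fa_ratio"),
    n_males = sum(vapply(per_pop, function(d) d$n_males[1], 0L)),
    n_females = sum(vapply(per_pop, function(d) d$n_females[1], 0L)),
    row.names = NULL
  )
  pooled$mf_ratio[is.nan(pooled$mf_ratio)] <- NA_real_
  out <- rbind(pop_df, pooled)
  rownames(out) <- NULL
  out
}

#' Read a coverage dataset from TSV files
#'
#' Expects a long-format coverage table (`gene_id`, `individual_id`,
#' `coverage`), a gene annotation table (`gene_id`, `chrom`, `start`, `end`;
#' 1-based inclusive coordinates) and a sample sheet (`individual_id`,
#' `population`, `sex`). Pairs absent from the coverage table become `NA`.
#'
#' @param coverage_path,annotation_path,samples_path file paths.
#' @return a `coverage_dataset`.
#' @export
read_coverage_dataset <- function(coverage_path, annotation_path,
                                  samples_path) {
  cov <- read_tsv_cols(coverage_path,
                       c("gene_id", "individual_id", "coverage"))
  genes <- read_tsv_cols(annotation_path,
                         c("gene_id", "chrom", "start", "end"))
  samples <- read_tsv_cols(samples_path,
                           c("individual_id", "population", "sex"))
  if (anyDuplicated(cov[c("gene_id", "individual_id")])) {
    stop_data("duplicate (gene, individual) pair in coverage table")
  }
  bad_g <- setdiff(cov$gene_id, genes$gene_id)
  if (length(bad_g)) stop_data("coverage gene absent from annotation: ", bad_g[1])
  bad_i <- setdiff(cov$individual_id, samples$individual_id)
  if (length(bad_i)) stop_data("coverage individual absent from samples: ", bad_i[1])
  v <- matrix(NA_real_, nrow(genes), nrow(samples),
              dimnames = list(genes$gene_id, samples$individual_id))
  v[cbind(cov$gene_id, cov$individual_id)] <- cov$coverage
  coverage_dataset(genes, samples, v)
}

#' Write a coverage dataset to TSV files
#'
#' Inverse of [read_coverage_dataset()]; writes `coverage.tsv`,
#' `annotation.tsv`, `samples.tsv` (and `flags.tsv` when any gene is flagged)
#' under `dir`.
#'
#' @param x a `coverage_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_coverage_dataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- data.frame(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    individual_id = rep(colnames(x$values), each = nrow(x$values)),
    coverage = as.vector(x$values)
  )
  long <- long[!is.na(long$coverage), , drop = FALSE]
  write_tsv(long, file.path(dir, "coverage.tsv"))
  write_tsv(x$genes, file.path(dir, "annotation.tsv"))
  write_tsv(x$samples, file.path(dir, "samples.tsv"))
  if (nrow(x$flags) > 0L) write_tsv(x$flags, file.path(dir, "flags.tsv"))
  invisible(dir)
}
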