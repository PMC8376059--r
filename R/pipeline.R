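# End-to-end orchestration: flat key=value config, staged execution with
# logging, stage TSV outputs and a JSON summary. Reruns with the same config
# produce byte-identical numeric outputs.

#' Read a flat key=value pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment; blank lines are
#' ignored. Values are coerced to numeric where possible. See
#' [pipeline_defaults()] for the recognized keys and their defaults.
#'
#' @param path config file path.
#' @return a validated named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad)) stop_config("unparseable config line: ", bad[1])
  cfg <- stats::setNames(
    lapply(kv, function(m) {
      v <- trimws(m[3])
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }),
    vapply(kv, `[[`, "", 2)
  )
  validate_pipeline_config(cfg)
}

#' Default pipeline configuration values
#'
#' Every tunable threshold of the pipeline with its default: normalization
#' statistic (`median`), sexing thresholds (0.70 / 0.85), classification
#' windows (0.3-0.7, 0.8-1.2) and duplication cut (1.4), filter limits
#' (mean count > 10, 20x high-count multiplier, female normalized
#' coverage >= 0.1), bootstrap replicates (1000), neutral mutation rate
#' (1e-9 per site per generation) and master seed.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    sex_chromosome = "chrSex",
    norm_stat = "median",
    male_max = 0.70,
    female_min = 0.85,
    min_x_genes = 10,
    hemizygous_lo = 0.3, hemizygous_hi = 0.7,
    diploid_lo = 0.8, diploid_hi = 1.2,
    duplicated_min = 1.4,
    min_mean_count = 10,
    high_count_multiplier = 20,
    min_female_norm = 0.1,
    boundary_min_genes = 4,
    bootstrap_reps = 1000,
    mu = 1e-9,
    seed = 1
  )
}

validate_pipeline_config <- function(cfg) {
  cfg <- utils::modifyList(pipeline_defaults(), cfg)
  if (is.null(cfg$output_dir)) stop_config("config needs output_dir")
  if (is.null(cfg$coverage_tsv) || is.null(cfg$annotation_tsv) ||
      is.null(cfg$samples_tsv)) {
    stop_config("config needs coverage_tsv, annotation_tsv and samples_tsv")
  }
  if (cfg$male_max >= cfg$female_min) {
    stop_config("male_max (", cfg$male_max, ") must be < female_min (",
                cfg$female_min, ")")
  }
  if (!cfg$norm_stat %in% c("median", "mean")) {
    stop_config("norm_stat must be median or mean")
  }
  if (cfg$mu <= 0) stop_config("mu must be > 0")
  if (cfg$duplicated_min <= cfg$diploid_hi) {
    stop_config("duplicated_min must exceed diploid_hi")
  }
  if (cfg$seed != round(cfg$seed)) stop_config("seed must be an integer")
  structure(cfg, class = "pipeline_config")
}

#' Run the full degeneration-diagnosis pipeline
#'
#' Executes filter, normalize, sex, ratios, classify, consistency and
#' boundary stages on the configured coverage inputs, then (when inputs are
#' configured) the divergence and linkage stages. Each stage writes a TSV
#' under `output_dir`; a `summary.json` collects counts per class, region
#' medians, the boundary estimate, sexing tallies, divergence medians and
#' the generation estimate, and `log.txt` records the full configuration
#' and per-stage record counts. No stage mutates another stage's outputs.
#'
#' @param config a `pipeline_config`, a config file path, or a named list
#'   (validated against the defaults).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- validate_pipeline_config(as.list(config))
  }
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "log.txt")
  log_lines <- c(sprintf("ydegen %s | R %s",
                         as.character(utils::packageVersion("ydegen")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 "config:",
                 sprintf("  %s = %s", names(cfg),
                         vapply(cfg, function(v) paste(format(v),
                                                       collapse = ","), "")))
  stage <- function(name, n_in, n_out, extra = "") {
    log_lines <<- c(log_lines,
                    sprintf("stage %-12s in=%d out=%d %s", name, n_in, n_out,
                            extra))
  }
  fail <- function(name, e) {
    stop_data("stage ", name, " failed: ", conditionMessage(e))
  }

  ds <- tryCatch(read_coverage_dataset(cfg$coverage_tsv, cfg$annotation_tsv,
                                       cfg$samples_tsv),
                 error = function(e) fail("read", e))
  stage("read", nrow(ds$genes), nrow(ds$genes),
        sprintf("individuals=%d", nrow(ds$samples)))

  policy <- filter_policy(min_mean_count = cfg$min_mean_count,
                          high_count_multiplier = cfg$high_count_multiplier,
                          min_female_norm = cfg$min_female_norm)
  ds <- tryCatch(filter_genes(ds, policy), error = function(e) fail("filter", e))
  stage("filter", nrow(ds$genes),
        length(setdiff(ds$genes$gene_id, flagged_genes(ds))),
        sprintf("flags=%d", nrow(ds$flags)))

  ds <- tryCatch(normalize_dataset(ds, sex_chromosome = cfg$sex_chromosome,
                                   stat = cfg$norm_stat),
                 error = function(e) fail("normalize", e))
  stage("normalize", ncol(ds$values), ncol(ds$values))

  x_genes <- ds$genes$gene_id[ds$genes$chrom == cfg$sex_chromosome]
  sex_calls <- tryCatch(
    sex_individuals(ds, x_genes, male_max = cfg$male_max,
                    female_min = cfg$female_min,
                    min_genes = cfg$min_x_genes),
    error = function(e) fail("sex", e))
  write_tsv(sex_calls, file.path(cfg$output_dir, "sex_calls.tsv"))
  stage("sex", nrow(sex_calls), sum(sex_calls$call %in% c("M", "F")),
        sprintf("unassigned=%d conflicts=%d",
                sum(sex_calls$call == "unassigned"), sum(sex_calls$conflict)))

  # female-coverage filter needs normalized values and sex calls
  ds <- filter_genes(ds, policy, sexes = sex_calls)
  write_tsv(ds$flags, file.path(cfg$output_dir, "flags.tsv"))

  ratios <- tryCatch(ratio_table(ds, sexes = sex_calls),
                     error = function(e) fail("ratios", e))
  write_tsv(ratios, file.path(cfg$output_dir, "ratios.tsv"))
  stage("ratios", nrow(ratios), nrow(ratios),
        sprintf("scopes=%d", length(unique(ratios$scope))))

  windows <- class_windows(c(cfg$hemizygous_lo, cfg$hemizygous_hi),
                           c(cfg$diploid_lo, cfg$diploid_hi),
                           cfg$duplicated_min)
  calls <- gene_calls(ratios, ds$genes, windows)
  write_tsv(calls, file.path(cfg$output_dir, "gene_calls.tsv"))
  pooled <- calls[calls$scope == "pooled", , drop = FALSE]
  stage("classify", nrow(calls), nrow(pooled))

  n_pops <- length(setdiff(unique(calls$scope), "pooled"))
  consist <- NULL
  if (n_pops >= 2L) {
    consist <- consistency_table(calls, "hemizygous")
    write_tsv(consist$gene_patterns,
              file.path(cfg$output_dir, "consistency.tsv"))
    stage("consistency", nrow(consist$gene_patterns), consist$n_consistent)
  }

  sex_pooled <- pooled[pooled$chrom == cfg$sex_chromosome, , drop = FALSE]
  boundary <- NULL
  if (sum(!is.na(sex_pooled$mf_ratio)) >= cfg$boundary_min_genes) {
    boundary <- detect_boundary(sex_pooled, chromosome = cfg$sex_chromosome)
    jsonlite::write_json(boundary[c("chromosome", "k", "boundary_bp",
                                    "flanking_genes", "residual", "n_genes")],
                         file.path(cfg$output_dir, "boundary.json"),
                         auto_unbox = TRUE, digits = NA)
    stage("boundary", boundary$n_genes, boundary$k)
  }

  div_summary <- NULL
  if (!is.null(cfg$cds_dir)) {
    fastas <- sort(list.files(cfg$cds_dir, pattern = "\\.(fa|fasta)$",
                              full.names = TRUE))
    if (length(fastas) == 0L) stop_data("stage divergence failed: no FASTA in ",
                                        cfg$cds_dir)
    est <- do.call(rbind, lapply(fastas, function(f) {
      estimate_divergence(read_codon_alignment(f),
                          gene = sub("\\.(fa|fasta)$", "", basename(f)),
                          n_reps = cfg$bootstrap_reps, seed = cfg$seed)
    }))
    div_summary <- summarize_divergence(est)
    write_tsv(div_summary$per_gene, file.path(cfg$output_dir, "divergence.tsv"))
    stage("divergence", length(fastas), nrow(est),
          sprintf("median_ks=%.4f", div_summary$median_ks))
  }

  linkage_calls <- NULL
  if (!is.null(cfg$genotypes_tsv)) {
    fams <- read_genotypes(cfg$genotypes_tsv)
    if (is.data.frame(fams)) fams <- list()
    linkage_calls <- do.call(rbind, lapply(fams, function(fam) {
      sx <- fam$known_sexes
      if (is.null(sx)) sx <- infer_progeny_sex(fam)
      out <- do.call(rbind, lapply(fam$markers$marker_id, function(mk) {
        classify_marker_family(fam, mk, sx)
      }))
      out$family_id <- fam$family_id
      out
    }))
    if (!is.null(linkage_calls)) {
      write_tsv(linkage_calls, file.path(cfg$output_dir, "linkage.tsv"))
      stage("linkage", nrow(linkage_calls), nrow(linkage_calls))
    }
  }

  hz_sum <- region_summary(
    sex_pooled,
    c(0, if (!is.null(boundary)) boundary$boundary_bp else Inf))
  summary <- list(
    n_genes = nrow(ds$genes),
    n_flagged = length(flagged_genes(ds)),
    sexing = as.list(table(sex_calls$call)),
    class_counts_pooled = as.list(table(pooled$class)),
    hemizygous_region_median_mf =
      stats::median(pooled$mf_ratio[pooled$class == "hemizygous"],
                    na.rm = TRUE),
    proximal_region = hz_sum[c("n_genes", "median_mf_ratio")],
    boundary = if (!is.null(boundary)) {
      boundary[c("chromosome", "k", "boundary_bp")]
    },
    consistency = if (!is.null(consist)) {
      list(n_populations = consist$n_populations,
           n_consistent_hemizygous = consist$n_consistent)
    },
    divergence = if (!is.null(div_summary)) {
      list(median_ks = div_summary$median_ks,
           median_ka = div_summary$median_ka,
           median_k_all = div_summary$median_k_all,
           generations = ks_to_generations(div_summary$median_ks, cfg$mu))
    },
    linkage = if (!is.null(linkage_calls)) {
      as.list(table(linkage_calls$class))
    },
    seed = cfg$seed
  )
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, log_path)
  invisible(summary)
}
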