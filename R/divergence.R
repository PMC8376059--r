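# Pairwise coding-sequence divergence: Nei-Gojobori (1986) site and
# difference counting with stop-codon-aware pathway averaging, Jukes-Cantor
# correction, complete-deletion gap handling, codon-bootstrap confidence
# intervals, and conversion of synonymous divergence to generations.

.ydegen_cache <- new.env(parent = emptyenv())

# Standard nuclear genetic code, split into the lookups the counters need.
genetic_code_tables <- function() {
  if (is.null(.ydegen_cache$code)) {
    gc <- Biostrings::GENETIC_CODE
    .ydegen_cache$code <- list(
      aa = gc,
      is_stop = gc == "*",
      sense = names(gc)[gc != "*"]
    )
  }
  .ydegen_cache$code
}

# s/n site counts for every sense codon, cached as a 61 x 2 matrix.
site_counts_matrix <- function() {
  if (is.null(.ydegen_cache$sites)) {
    code <- genetic_code_tables()
    m <- t(vapply(code$sense, ng86_site_counts, c(s = 0, n = 0)))
    .ydegen_cache$sites <- m
  }
  .ydegen_cache$sites
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' For each of the three codon positions, considers the three possible
#' single-nucleotide changes; changes that create a stop codon are excluded
#' from the denominator at that position. The synonymous site count `s` is
#' the sum over positions of the fraction of counted changes that leave the
#' amino acid unchanged, and `n = 3 - s`.
#'
#' @param codon a 3-letter DNA string encoding a sense codon.
#' @return named numeric vector `c(s = , n = )`.
#' @export
#' @examples
#' ng86_site_counts("TTT")  # s = 1/3
#' ng86_site_counts("ATG")  # s = 0
ng86_site_counts <- function(codon) {
  code <- genetic_code_tables()
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop_data("ng86_site_counts: ambiguous or malformed codon: ", codon)
  }
  if (code$is_stop[[codon]]) {
    stop_data("ng86_site_counts: stop codon: ", codon)
  }
  aa0 <- code$aa[[codon]]
  s <- 0
  for (pos in 1:3) {
    from <- substr(codon, pos, pos)
    syn <- 0L
    counted <- 0L
    for (to in setdiff(c("A", "C", "G", "T"), from)) {
      cand <- codon
      substr(cand, pos, pos) <- to
      if (code$is_stop[[cand]]) next
      counted <- counted + 1L
      if (code$aa[[cand]] == aa0) syn <- syn + 1L
    }
    if (counted > 0L) s <- s + syn / counted
  }
  c(s = s, n = 3 - s)
}

# Orderings in which d differing positions can be substituted.
path_orders <- function(idx) {
  d <- length(idx)
  if (d == 1L) return(list(idx))
  if (d == 2L) return(list(idx, idx[c(2, 1)]))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) idx[p])
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons. Pathways crossing a stop codon are dropped and the weights
# renormalized; if every pathway crosses a stop, each differing position
# contributes by majority vote of its per-position synonymy in the two codon
# contexts (ties split 0.5/0.5).
codon_pair_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  code <- genetic_code_tables()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- path_orders(diff_pos)
  tallies <- list()
  for (ord in paths) {
    cur <- c1
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code$is_stop[[nxt]]) {
        ok <- FALSE
        break
      }
      if (code$aa[[nxt]] == code$aa[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) tallies[[length(tallies) + 1L]] <- c(sd, nd)
  }
  if (length(tallies) > 0L) {
    avg <- Reduce(`+`, tallies) / length(tallies)
    return(c(sd = avg[1], nd = avg[2]))
  }
  # all pathways blocked by stops: split each position by majority vote
  sd <- 0
  nd <- 0
  for (pos in diff_pos) {
    votes <- logical(0)
    a <- c1
    substr(a, pos, pos) <- substr(c2, pos, pos)
    if (!code$is_stop[[a]]) votes <- c(votes, code$aa[[a]] == code$aa[[c1]])
    b <- c2
    substr(b, pos, pos) <- substr(c1, pos, pos)
    if (!code$is_stop[[b]]) votes <- c(votes, code$aa[[b]] == code$aa[[c2]])
    frac_syn <- if (length(votes) == 0L) 0.5 else mean(votes)
    if (frac_syn > 0.5) sd <- sd + 1
    else if (frac_syn < 0.5) nd <- nd + 1
    else {
      sd <- sd + 0.5
      nd <- nd + 0.5
    }
  }
  c(sd = sd, nd = nd)
}

#' Build a codon alignment pair with complete deletion
#'
#' Splits two aligned, equal-length, in-frame sequences into codon columns
#' and drops (complete deletion) every column containing a gap or ambiguous
#' base in either sequence, or a stop codon in either sequence. All
#' divergence statistics are computed over the retained columns.
#'
#' @param seq_a,seq_b aligned DNA sequences (character scalars), equal
#'   lengths divisible by 3.
#' @return an object of class `codon_alignment` with elements `codons_a`,
#'   `codons_b` (retained columns), `n_codons` (input length) and `dropped`
#'   (reason per dropped column).
#' @export
codon_alignment <- function(seq_a, seq_b) {
  seq_a <- toupper(as.character(seq_a))
  seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) != nchar(seq_b)) {
    stop_data("aligned sequences must have equal length")
  }
  if (nchar(seq_a) %% 3L != 0L) {
    stop_data("aligned length must be divisible by 3")
  }
  n <- nchar(seq_a) %/% 3L
  split3 <- function(s) substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  ca <- split3(seq_a)
  cb <- split3(seq_b)
  code <- genetic_code_tables()
  clean <- function(x) !grepl("[^ACGT]", x)
  ok <- clean(ca) & clean(cb)
  reason <- rep(NA_character_, n)
  reason[!ok] <- "gap_or_ambiguity"
  is_stop <- unname(ok & (code$is_stop[ca] %in% TRUE |
                            code$is_stop[cb] %in% TRUE))
  reason[is_stop] <- "stop_codon"
  keep <- ok & !is_stop
  structure(list(codons_a = ca[keep], codons_b = cb[keep],
                 n_codons = n,
                 dropped = data.frame(column = which(!keep),
                                      reason = reason[!keep])),
            class = "codon_alignment")
}

#' Read an aligned coding-sequence pair from FASTA
#'
#' @param path FASTA file containing exactly two aligned, in-frame records.
#' @return a `codon_alignment`.
#' @export
read_codon_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 2L) {
    stop_data("expected exactly 2 FASTA records, found ", length(x),
              " in ", path)
  }
  codon_alignment(as.character(x[[1]]), as.character(x[[2]]))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` for an observed difference proportion `p`.
#'
#' @param p observed proportion(s) of differing sites, each in `[0, 0.75)`.
#' @return corrected divergence, same length as `p`.
#' @export
#' @examples
#' jukes_cantor(0.05)
jukes_cantor <- function(p) {
  if (any(p < 0)) stop_data("jukes_cantor: negative proportion")
  if (any(p >= 0.75)) {
    stop_data("jukes_cantor: saturation (p >= 0.75), divergence not estimable")
  }
  -0.75 * log(1 - 4 * p / 3)
}

# Inverse of the JC correction: expected observed proportion at divergence d.
jc_inverse <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Per-retained-codon statistics backing both the point estimate and the
# bootstrap: columns s, n, sd, nd (pathway-averaged) and ndiff (nucleotide
# differences).
codon_stats <- function(pair) {
  sm <- site_counts_matrix()
  sa <- sm[pair$codons_a, , drop = FALSE]
  sb <- sm[pair$codons_b, , drop = FALSE]
  L <- length(pair$codons_a)
  dif <- t(mapply(codon_pair_diff, pair$codons_a, pair$codons_b))
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, pair$codons_a, pair$codons_b)
  cbind(s = (sa[, "s"] + sb[, "s"]) / 2,
        n = (sa[, "n"] + sb[, "n"]) / 2,
        sd = dif[, "sd"], nd = dif[, "nd"], ndiff = ndiff)
}

# Turn summed per-codon statistics into the divergence measures; any p >= 0.75
# is a saturation failure.
divergence_from_sums <- function(S, N, Sd, Nd, ndiff, L, gene = NULL) {
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  p_all <- ndiff / (3 * L)
  if (ps >= 0.75 || pn >= 0.75 || p_all >= 0.75) {
    stop_data("saturation (p >= 0.75)",
              if (!is.null(gene)) paste0(" for gene ", gene), ": ",
              sprintf("ps = %.3f, pn = %.3f, p_all = %.3f", ps, pn, p_all))
  }
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  list(L = L, S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
       ks = ks, ka = ka, k_all = jukes_cantor(p_all),
       ka_ks = if (ks > 0) ka / ks else NA_real_)
}

#' Nei-Gojobori pairwise divergence estimate
#'
#' Computes synonymous (`S`) and nonsynonymous (`N`) site counts averaged
#' over the two sequences, pathway-averaged synonymous (`Sd`) and
#' nonsynonymous (`Nd`) difference counts (orderings that cross stop codons
#' are dropped and the weights renormalized), the proportions `ps = Sd/S` and
#' `pn = Nd/N`, their Jukes-Cantor corrections `Ks` and `Ka`, and the
#' all-sites divergence `K_all` from the per-nucleotide difference proportion
#' over retained columns.
#'
#' @param pair a `codon_alignment` (or a 2-element character vector of
#'   aligned sequences, converted via [codon_alignment()]).
#' @param gene optional gene label used in error messages.
#' @return an object of class `divergence_estimate`: a list with elements
#'   `L`, `S`, `N`, `Sd`, `Nd`, `ps`, `pn`, `ks`, `ka`, `k_all`, `ka_ks`.
#' @export
ng86_pairwise <- function(pair, gene = NULL) {
  if (is.character(pair) && length(pair) == 2L) {
    pair <- codon_alignment(pair[[1]], pair[[2]])
  }
  stopifnot(inherits(pair, "codon_alignment"))
  L <- length(pair$codons_a)
  if (L == 0L) stop_data("no retained codons after complete deletion")
  st <- codon_stats(pair)
  est <- divergence_from_sums(sum(st[, "s"]), sum(st[, "n"]),
                              sum(st[, "sd"]), sum(st[, "nd"]),
                              sum(st[, "ndiff"]), L, gene)
  structure(est, class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf(
    "<divergence_estimate> L = %d codons; Ks = %.4f, Ka = %.4f, K_all = %.4f (Ka/Ks = %s)\n",
    x$L, x$ks, x$ka, x$k_all,
    if (is.na(x$ka_ks)) "NA" else sprintf("%.3f", x$ka_ks)))
  invisible(x)
}

#' Codon-bootstrap confidence intervals for divergence measures
#'
#' Resamples retained codon columns with replacement (implemented as
#' multinomial column weights, which is the same resampling distribution)
#' and reports percentile 2.5%/97.5% bounds for `Ks`, `Ka`, `K_all` and
#' `Ka/Ks`. Replicates that hit saturation (p >= 0.75) or have no synonymous
#' divergence (for `Ka/Ks`) are excluded and counted.
#'
#' @param pair a `codon_alignment`.
#' @param n_reps number of bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed (required: the resampling is stochastic).
#' @return list with elements `ks`, `ka`, `k_all`, `ka_ks` (each
#'   `c(lower, upper)`), `n_reps`, and `n_saturated`.
#' @export
bootstrap_ci <- function(pair, n_reps = 1000L, seed) {
  stopifnot(inherits(pair, "codon_alignment"))
  if (n_reps < 100L) stop_data("bootstrap needs n_reps >= 100")
  L <- length(pair$codons_a)
  if (L < 10L) stop_data("bootstrap needs >= 10 retained codons, have ", L)
  st <- codon_stats(pair)
  with_stream(seed, "divergence/bootstrap", {
    w <- stats::rmultinom(n_reps, L, rep(1 / L, L)) # L x n_reps
    sums <- t(st) %*% w                             # 5 x n_reps
    ps <- sums["sd", ] / sums["s", ]
    pn <- sums["nd", ] / sums["n", ]
    pall <- sums["ndiff", ] / (3 * L)
    ps[sums["s", ] == 0] <- 0
    pn[sums["n", ] == 0] <- 0
    sat <- ps >= 0.75 | pn >= 0.75 | pall >= 0.75
    if (any(sat)) {
      warning(sum(sat), " bootstrap replicate(s) hit saturation and were excluded")
    }
    ks <- jukes_cantor(ps[!sat])
    ka <- jukes_cantor(pn[!sat])
    kall <- jukes_cantor(pall[!sat])
    kaks <- (ka / ks)[ks > 0]
    ci <- function(x) {
      if (length(x) == 0L) return(c(NA_real_, NA_real_))
      unname(stats::quantile(x, c(0.025, 0.975)))
    }
    list(ks = ci(ks), ka = ci(ka), k_all = ci(kall), ka_ks = ci(kaks),
         n_reps = n_reps, n_saturated = sum(sat))
  })
}

#' Point estimate plus bootstrap CI for one aligned gene pair
#'
#' @param pair a `codon_alignment` or 2-element character vector.
#' @param gene gene label.
#' @param n_reps bootstrap replicates; `0` skips the bootstrap.
#' @param seed integer seed for the bootstrap.
#' @return one-row data.frame with the `divergence_estimate` fields plus
#'   `*_lo`/`*_hi` CI bounds.
#' @export
estimate_divergence <- function(pair, gene = "gene", n_reps = 1000L,
                                seed = 1L) {
  if (is.character(pair) && length(pair) == 2L) {
    pair <- codon_alignment(pair[[1]], pair[[2]])
  }
  est <- ng86_pairwise(pair, gene = gene)
  row <- data.frame(gene = gene, L = est$L, S = est$S, N = est$N,
                    Sd = est$Sd, Nd = est$Nd, ps = est$ps, pn = est$pn,
                    ks = est$ks, ka = est$ka, k_all = est$k_all,
                    ka_ks = est$ka_ks)
  if (n_reps > 0L) {
    ci <- bootstrap_ci(pair, n_reps = n_reps, seed = seed)
    row$ks_lo <- ci$ks[1]; row$ks_hi <- ci$ks[2]
    row$ka_lo <- ci$ka[1]; row$ka_hi <- ci$ka[2]
    row$k_all_lo <- ci$k_all[1]; row$k_all_hi <- ci$k_all[2]
    row$ka_ks_lo <- ci$ka_ks[1]; row$ka_ks_hi <- ci$ka_ks[2]
  }
  row
}

#' Cross-gene divergence summary
#'
#' Medians of `Ks`, `Ka` and `K_all` over genes with defined estimates, and a
#' per-gene neutrality flag set when the bootstrap CI of `Ka/Ks` contains 1
#' (no evidence of selective constraint).
#'
#' @param estimates data.frame of per-gene rows from [estimate_divergence()].
#' @return list with `median_ks`, `median_ka`, `median_k_all`, `n_genes`, and
#'   the per-gene table with a `neutral` column added.
#' @export
summarize_divergence <- function(estimates) {
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0L) stop_data("no divergence estimates to summarize")
  neutral <- if (all(c("ka_ks_lo", "ka_ks_hi") %in% names(estimates))) {
    !is.na(estimates$ka_ks_lo) & !is.na(estimates$ka_ks_hi) &
      estimates$ka_ks_lo <= 1 & estimates$ka_ks_hi >= 1
  } else rep(NA, nrow(estimates))
  estimates$neutral <- neutral
  list(median_ks = stats::median(estimates$ks, na.rm = TRUE),
       median_ka = stats::median(estimates$ka, na.rm = TRUE),
       median_k_all = stats::median(estimates$k_all, na.rm = TRUE),
       n_genes = nrow(estimates),
       per_gene = estimates)
}

#' Convert synonymous divergence to generations
#'
#' Treats `ks` as the total (two-branch) divergence between a pair of
#' lineages, so the time back to their common ancestor is
#' `t = ks / (2 * mu)` generations at a neutral mutation rate `mu` per site
#' per generation.
#'
#' @param ks synonymous site divergence (proportion, >= 0).
#' @param mu neutral mutation rate per site per generation (> 0).
#' @return number of generations since the common ancestor.
#' @export
#' @examples
#' ks_to_generations(0.054, 1e-9)  # 2.7e7 generations
ks_to_generations <- function(ks, mu) {
  if (any(ks < 0)) stop_data("ks must be >= 0")
  if (any(mu <= 0)) stop_data("mu must be > 0")
  ks / (2 * mu)
}
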