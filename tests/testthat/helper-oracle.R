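# Independent brute-force oracles, written as plain enumerations so they
# share no code path with the package implementation.

ORACLE_CODE <- Biostrings::GENETIC_CODE
ORACLE_NTS <- c("A", "C", "G", "T")

oracle_translate <- function(codon) ORACLE_CODE[[codon]]

# Site counts by direct enumeration of the nine single-nucleotide changes.
oracle_site_counts <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    counted <- 0
    for (nt in ORACLE_NTS) {
      if (nt == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), nt, substr(codon, pos + 1, 3))
      if (oracle_translate(mut) == "*") next
      counted <- counted + 1
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
    if (counted > 0) s <- s + syn / counted
  }
  c(s = s, n = 3 - s)
}

# All permutations of a vector (recursive; at most 3! = 6 here).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged difference counts by explicit pathway walking.
oracle_pair_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  valid <- list()
  for (ord in oracle_perms(pos)) {
    cur <- c1
    steps <- c(0, 0)
    blocked <- FALSE
    for (p in ord) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(c2, p, p),
                    substr(cur, p + 1, 3))
      if (oracle_translate(nxt) == "*") {
        blocked <- TRUE
        break
      }
      if (oracle_translate(nxt) == oracle_translate(cur)) {
        steps[1] <- steps[1] + 1
      } else {
        steps[2] <- steps[2] + 1
      }
      cur <- nxt
    }
    if (!blocked) valid[[length(valid) + 1L]] <- steps
  }
  if (length(valid) > 0L) {
    avg <- Reduce(`+`, valid) / length(valid)
    return(c(sd = avg[1], nd = avg[2]))
  }
  # all pathways stop-blocked: majority vote per differing position
  sd <- 0
  nd <- 0
  for (p in pos) {
    votes <- c()
    m1 <- paste0(substr(c1, 1, p - 1), substr(c2, p, p), substr(c1, p + 1, 3))
    if (oracle_translate(m1) != "*") {
      votes <- c(votes, oracle_translate(m1) == oracle_translate(c1))
    }
    m2 <- paste0(substr(c2, 1, p - 1), substr(c1, p, p), substr(c2, p + 1, 3))
    if (oracle_translate(m2) != "*") {
      votes <- c(votes, oracle_translate(m2) == oracle_translate(c2))
    }
    f <- if (length(votes) == 0) 0.5 else mean(votes)
    if (f > 0.5) sd <- sd + 1 else if (f < 0.5) nd <- nd + 1 else {
      sd <- sd + 0.5
      nd <- nd + 0.5
    }
  }
  c(sd = sd, nd = nd)
}

# Full pairwise estimate by enumeration, for oracle-equivalence checks.
oracle_pairwise <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  ca <- substring(seq_a, 3 * (1:n) - 2, 3 * (1:n))
  cb <- substring(seq_b, 3 * (1:n) - 2, 3 * (1:n))
  S <- 0
  Sd <- 0
  Nd <- 0
  for (i in seq_len(n)) {
    S <- S + (oracle_site_counts(ca[i])[["s"]] +
                oracle_site_counts(cb[i])[["s"]]) / 2
    d <- oracle_pair_diff(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  N <- 3 * n - S
  list(S = S, N = N, Sd = Sd, Nd = Nd, ps = Sd / S, pn = Nd / N)
}

ORACLE_SENSE_CODONS <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
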