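# Shared fixtures and independent oracles for the test suite.
# Oracles are literal transcriptions of the textbook definitions, coded
# independently of the package's vectorized implementations.

# small planted cohort used by several files
small_cohort <- function(seed = 11, n_genes = 300, n_samples = 120,
                         module_sizes = c(60, 40), relapse_effect = 1.5,
                         noise_sd = 0.5) {
  generate_cohort(cohort_config(
    n_genes = n_genes, n_samples = n_samples, module_sizes = module_sizes,
    noise_sd = noise_sd, relapse_effect = relapse_effect, seed = seed))
}

# brute-force biweight midcorrelation, literal transcription of the formula
oracle_bicor <- function(x, y) {
  wdev <- function(v) {
    med <- median(v)
    mad0 <- median(abs(v - med))
    if (mad0 == 0) return(v - mean(v))
    u <- (v - med) / (9 * mad0)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    w * (v - med)
  }
  a <- wdev(x); b <- wdev(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# triple-loop topological overlap
oracle_tom <- function(A) {
  n <- nrow(A)
  TOM <- diag(n)
  k <- sapply(seq_len(n), function(i) sum(A[i, -i]))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    TOM[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  TOM
}

# brute-force hypergeometric upper tail P[X >= ov]
oracle_hyper_tail <- function(ov, set_size, bg_size, query_size) {
  ks <- ov:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(bg_size - set_size, query_size - ks)) /
    choose(bg_size, query_size)
}

# pair-counting AUC (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# textbook BH step-up
oracle_bh <- function(p) stats::p.adjust(p, method = "BH")
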