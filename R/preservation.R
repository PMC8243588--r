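# Cross-cohort module preservation: do reference-cohort modules keep their
# density and connectivity structure in an independent test cohort?
# Observed statistics per module are compared with a permutation null built
# from random same-size gene sets in the test data; Z = (obs - mean) / sd.
#
# Implemented statistic battery (a declared subset of the full reference
# convention): mean within-module correlation (density), correlation of
# intramodular connectivity between cohorts and correlation of kME vectors
# between cohorts (connectivity).

# per-gene-set statistics: density and connectivity summaries in the test
# cohort paired with reference-module quantities
.preservation_one <- function(ref_kIM, ref_kME, test_X, genes, beta, cor_method) {
  Ct <- .cor_xy(t(test_X[genes, , drop = FALSE]),
                t(test_X[genes, , drop = FALSE]), cor_method)
  Ct[is.na(Ct)] <- 0
  mean_cor <- mean(Ct[upper.tri(Ct)])
  At <- ((1 + .clamp(Ct)) / 2)^beta
  diag(At) <- 1
  kIM_t <- rowSums(At) - 1
  cor_kIM <- suppressWarnings(stats::cor(ref_kIM, kIM_t))
  me_t <- module_eigengene(test_X, genes)$me
  kME_t <- as.numeric(suppressWarnings(
    stats::cor(t(test_X[genes, , drop = FALSE]), me_t)))
  cor_kME <- suppressWarnings(stats::cor(ref_kME, kME_t))
  c(mean_cor = mean_cor, cor_kIM = cor_kIM, cor_kME = cor_kME)
}

#' Module preservation statistics between two cohorts
#'
#' For each reference module (label 0 excluded), computes on the shared gene
#' universe: the mean within-module correlation in the test cohort
#' (density), and the correlations of intramodular connectivity and of kME
#' vectors between reference and test (connectivity). A permutation null is
#' built from \code{n_perm} random same-size gene sets drawn without
#' replacement from the shared universe excluding the module's genes;
#' \code{Z = (obs - mean_null) / sd_null}. \code{Z_density} comes from the
#' mean correlation, \code{Z_connectivity} is the mean of the kIM and kME
#' z-scores, and \code{Z_summary = (Z_density + Z_connectivity) / 2}.
#' \code{median_rank} is the median of the per-statistic ranks across modules
#' (rank 1 = most preserved). Conventional reporting labels: Z < 2 none,
#' 2-10 weak-to-moderate, > 10 strong.
#'
#' @param ref,test gene x sample log2 expression matrices sharing gene ids.
#' @param assignment named module labels on the reference genes.
#' @param n_perm permutation count (default 100).
#' @param seed integer seed making the permutation draw deterministic.
#' @param beta soft power for the intramodular adjacency.
#' @param cor_method correlation flavour.
#' @param min_shared modules with fewer shared genes are skipped with a
#'   warning.
#' @return data frame of class \code{preservation_report}: module, size,
#'   mean_cor, cor_kIM, cor_kME, Z_density, Z_connectivity, Z_summary,
#'   median_rank, n_perm, label.
#' @export
preservation_stats <- function(ref, test, assignment, n_perm = 100,
                               seed = NULL, beta = 5.5,
                               cor_method = c("bicor", "pearson"),
                               min_shared = 3) {
  cor_method <- match.arg(cor_method)
  ref <- as.matrix(ref); test <- as.matrix(test)
  shared <- intersect(rownames(ref), rownames(test))
  if (length(shared) < 10) .stopf("preservation_stats: < 10 shared genes")
  assignment <- assignment[intersect(names(assignment), shared)]
  labels <- sort(unique(assignment[assignment > 0]))
  if (length(labels) == 0) .stopf("preservation_stats: no modules to test")
  if (!is.null(seed)) set.seed(as.integer(seed))

  rows <- list()
  for (m in labels) {
    genes <- names(assignment)[assignment == m]
    if (length(genes) < min_shared) {
      .warnf("module %d has < %d shared genes; skipped", m, min_shared)
      next
    }
    # reference-side quantities, computed once
    Cr <- .cor_xy(t(ref[genes, , drop = FALSE]),
                  t(ref[genes, , drop = FALSE]), cor_method)
    Cr[is.na(Cr)] <- 0
    Ar <- ((1 + .clamp(Cr)) / 2)^beta
    diag(Ar) <- 1
    ref_kIM <- rowSums(Ar) - 1
    me_r <- module_eigengene(ref, genes)$me
    ref_kME <- as.numeric(suppressWarnings(
      stats::cor(t(ref[genes, , drop = FALSE]), me_r)))

    obs <- .preservation_one(ref_kIM, ref_kME, test, genes, beta, cor_method)
    pool <- setdiff(shared, genes)
    if (length(pool) < length(genes)) {
      .warnf("module %d larger than the non-module universe; null draws use the full shared universe", m)
      pool <- shared
    }
    null_mat <- vapply(seq_len(n_perm), function(b) {
      rand <- sample(pool, length(genes))
      .preservation_one(ref_kIM, ref_kME, test, rand, beta, cor_method)
    }, numeric(3))
    mu <- rowMeans(null_mat)
    sdev <- apply(null_mat, 1, stats::sd)
    z <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
    z_density <- z["mean_cor"]
    z_connect <- mean(z[c("cor_kIM", "cor_kME")], na.rm = TRUE)
    rows[[as.character(m)]] <- data.frame(
      module = m, size = length(genes),
      mean_cor = obs["mean_cor"], cor_kIM = obs["cor_kIM"],
      cor_kME = obs["cor_kME"],
      Z_density = unname(z_density), Z_connectivity = z_connect,
      Z_summary = (unname(z_density) + z_connect) / 2,
      n_perm = n_perm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # median of per-statistic preservation ranks (rank 1 = most preserved)
  rk <- cbind(rank(-out$mean_cor), rank(-out$cor_kIM), rank(-out$cor_kME))
  out$median_rank <- apply(rk, 1, stats::median)
  out$label <- cut(out$Z_summary, c(-Inf, 2, 10, Inf),
                   labels = c("none", "weak-to-moderate", "strong"))
  class(out) <- c("preservation_report", class(out))
  out
}
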