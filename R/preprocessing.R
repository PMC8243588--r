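# RPKM cleaning: low-expression filter, log2 transform, iterative
# connectivity-based outlier-sample removal, PCA quality check.

#' Remove genes with too many zero RPKM values
#'
#' A gene is retained iff its fraction of exact-zero entries is strictly
#' below \code{max_zero_fraction}; the default removes genes with zeros in
#' 50\% or more of the samples (inclusive boundary).
#'
#' @param X non-negative gene x sample RPKM matrix.
#' @param max_zero_fraction removal boundary (default 0.5).
#' @return list with \code{expr} (filtered matrix) and \code{report}
#'   (genes_in, genes_kept, max_zero_fraction).
#' @export
filter_low_expression <- function(X, max_zero_fraction = 0.5) {
  X <- as.matrix(X)
  if (length(X) == 0) .stopf("filter_low_expression: empty matrix")
  if (any(X < 0)) .stopf("filter_low_expression: negative entries; expected RPKM")
  zf <- rowMeans(X == 0)
  keep <- zf < max_zero_fraction
  out <- X[keep, , drop = FALSE]
  attr(out, "scale") <- attr(X, "scale")
  list(expr = out,
       report = list(genes_in = nrow(X), genes_kept = sum(keep),
                     max_zero_fraction = max_zero_fraction))
}

#' Log2-transform an RPKM matrix after adding a small offset
#'
#' @param X non-negative RPKM matrix.
#' @param offset RPKM units added before taking log2 (default 0.05).
#' @return matrix of \code{log2(x + offset)} with attribute
#'   \code{scale = "log2"}.
#' @export
log_transform <- function(X, offset = 0.05) {
  X <- as.matrix(X)
  if (any(X < 0)) .stopf("log_transform: negative entries; expected RPKM")
  Y <- log2(X + offset)
  attr(Y, "scale") <- "log2"
  attr(Y, "offset") <- offset
  Y
}

#' Iteratively remove outlier samples by standardized connectivity
#'
#' Per iteration the connectivity of each sample is
#' \code{k_i = sum_{j != i} corr(sample_i, sample_j)} over genes; k is
#' z-transformed across samples and every sample with \code{|z.k| >=
#' z_threshold} is removed (all offenders together, so the result does not
#' depend on sample order). Iterates until no outliers remain.
#'
#' @param X log2 gene x sample matrix with >= 4 samples.
#' @param z_threshold removal boundary in SDs (default 3).
#' @param cor_method correlation flavour for connectivity; biweight
#'   midcorrelation by default for consistency with the network stage.
#' @return list with \code{expr} and \code{report} (data frame
#'   \code{samples_removed} with sample_id, z_k, iteration; \code{iterations}).
#' @export
remove_outlier_samples <- function(X, z_threshold = 3,
                                   cor_method = c("bicor", "pearson")) {
  cor_method <- match.arg(cor_method)
  X <- as.matrix(X)
  if (ncol(X) < 4) .stopf("remove_outlier_samples: need >= 4 samples")
  removed <- data.frame(sample_id = character(0), z_k = numeric(0),
                        iteration = integer(0), stringsAsFactors = FALSE)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    C <- if (cor_method == "bicor") bicor_matrix(X) else
      suppressWarnings(stats::cor(X))
    k <- colSums(C, na.rm = TRUE) - diag(C)
    if (stats::sd(k) == 0) break
    zk <- (k - mean(k)) / stats::sd(k)
    out <- which(abs(zk) >= z_threshold)
    if (length(out) == 0) break
    removed <- rbind(removed, data.frame(
      sample_id = colnames(X)[out], z_k = unname(zk[out]), iteration = iter,
      stringsAsFactors = FALSE))
    X <- X[, -out, drop = FALSE]
    if (ncol(X) == 0) {
      cond <- structure(class = c("coexpnet_all_samples_removed", "error",
                                  "condition"),
                        list(message = "all samples removed as outliers",
                             call = NULL, report = removed))
      stop(cond)
    }
    if (ncol(X) < 4) break
  }
  list(expr = X, report = list(samples_removed = removed, iterations = iter,
                               z_threshold = z_threshold))
}

#' Principal component QC of a cohort
#'
#' Scores samples on the first two principal components of the sample x gene
#' matrix (genes centered) and reports the variance fractions, for a quick
#' before/after-cleaning quality check.
#'
#' @param X gene x sample matrix with >= 3 samples.
#' @return list with \code{scores} (sample x 2 matrix) and \code{var_frac}
#'   (length-2 vector of variance fractions).
#' @export
pca_qc <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 3) .stopf("pca_qc: need >= 3 samples")
  S <- t(X)
  tot <- sum(apply(S, 2, stats::var))
  if (tot == 0) .stopf("pca_qc: constant matrix, PCA degenerate")
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  var_frac <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  list(scores = scores, var_frac = var_frac)
}

#' Full preprocessing stage
#'
#' Low-expression filter, log2 transform, iterative outlier-sample removal,
#' and a PCA quality check, with a combined cleaning report.
#'
#' @param X non-negative gene x sample RPKM matrix.
#' @inheritParams filter_low_expression
#' @inheritParams log_transform
#' @inheritParams remove_outlier_samples
#' @return list with \code{expr} (cleaned log2 matrix) and \code{report}.
#' @export
preprocess <- function(X, max_zero_fraction = 0.5, offset = 0.05,
                       z_threshold = 3, cor_method = c("bicor", "pearson")) {
  cor_method <- match.arg(cor_method)
  f <- filter_low_expression(X, max_zero_fraction)
  Y <- log_transform(f$expr, offset)
  o <- remove_outlier_samples(Y, z_threshold, cor_method)
  pca <- pca_qc(o$expr)
  report <- list(genes_in = f$report$genes_in,
                 genes_kept = f$report$genes_kept,
                 offset = offset,
                 samples_removed = o$report$samples_removed,
                 iterations = o$report$iterations,
                 pca = pca)
  list(expr = o$expr, report = report)
}
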