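# Module-trait inference: robust correlation of module eigengenes with
# clinical traits (Student t p-values), ME relatedness dendrogram, sample
# clustering on ME profiles, and per-unit variance partitioning across
# covariates.

# coerce a traits data frame to a numeric matrix: numerics pass through,
# two-level factors/characters/logicals are coded 0/1, everything else is
# dropped with a warning
.traits_numeric <- function(traits) {
  traits <- as.data.frame(traits)
  keep <- list()
  for (nm in setdiff(colnames(traits), "sample_id")) {
    v <- traits[[nm]]
    if (is.numeric(v)) { keep[[nm]] <- as.numeric(v); next }
    if (is.logical(v)) { keep[[nm]] <- as.numeric(v); next }
    u <- sort(unique(stats::na.omit(as.character(v))))
    if (length(u) == 2) {
      keep[[nm]] <- as.numeric(as.character(v) == u[2])
    } else {
      .warnf("trait '%s' is non-numeric with %d levels; dropped", nm, length(u))
    }
  }
  if (length(keep) == 0) .stopf("no usable traits")
  M <- do.call(cbind, keep)
  rownames(M) <- rownames(traits)
  M
}

#' Correlate module eigengenes with clinical traits
#'
#' Per (module, trait) pair, computes the correlation over pairwise-complete
#' samples and a two-sided Student p-value from
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} with \code{n - 2} df. Binary
#' traits are coded 0/1; with biweight midcorrelation they fall back to
#' mean-centering via the MAD-zero rule (point-biserial behaviour).
#'
#' @param ME module x sample eigengene matrix.
#' @param traits per-sample data frame (rownames = sample ids).
#' @param method correlation flavour.
#' @param min_n traits with fewer non-missing values are reported missing.
#' @return list of class \code{module_trait_result} with \code{rho}, \code{p},
#'   \code{n_used} (module x trait matrices).
#' @export
module_trait_correlation <- function(ME, traits, method = c("bicor", "pearson"),
                                     min_n = 4) {
  method <- match.arg(method)
  ME <- as.matrix(ME)
  TM <- .traits_numeric(traits)
  shared <- intersect(colnames(ME), rownames(TM))
  if (length(shared) < min_n) .stopf("module_trait_correlation: too few shared samples")
  ME <- ME[, shared, drop = FALSE]
  TM <- TM[shared, , drop = FALSE]
  nm <- nrow(ME); nt <- ncol(TM)
  rho <- p <- matrix(NA_real_, nm, nt, dimnames = list(rownames(ME), colnames(TM)))
  n_used <- matrix(NA_integer_, nm, nt, dimnames = dimnames(rho))
  for (j in seq_len(nt)) {
    ok <- !is.na(TM[, j])
    n <- sum(ok)
    if (n < min_n) {
      .warnf("trait '%s' has < %d non-missing values; reported missing",
             colnames(TM)[j], min_n)
      next
    }
    y <- TM[ok, j]
    for (i in seq_len(nm)) {
      x <- ME[i, ok]
      r <- tryCatch(
        if (method == "bicor") bicor(x, y) else stats::cor(x, y),
        error = function(e) NA_real_)
      rho[i, j] <- r
      n_used[i, j] <- n
      if (!is.na(r)) {
        if (abs(r) >= 1) {
          p[i, j] <- 0
        } else {
          tval <- r * sqrt((n - 2) / (1 - r^2))
          p[i, j] <- 2 * stats::pt(-abs(tval), df = n - 2)
        }
      }
    }
  }
  structure(list(rho = rho, p = p, n_used = n_used),
            class = "module_trait_result")
}

#' Module eigengene relatedness dendrogram
#'
#' Average-linkage tree on \code{1 - cor(ME_i, ME_j)}. Leaf order is the
#' deterministic hclust order (ties resolved by module label order).
#'
#' @param ME module x sample eigengene matrix (>= 2 modules).
#' @return an \code{hclust} object.
#' @export
me_dendrogram <- function(ME) {
  ME <- as.matrix(ME)
  if (nrow(ME) < 2) .stopf("me_dendrogram: need >= 2 modules")
  D <- 1 - suppressWarnings(stats::cor(t(ME)))
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Newick serialization of a dendrogram
#'
#' @param hc an \code{hclust} object.
#' @return single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

# mean silhouette width of a labeling given a dist object
.mean_silhouette <- function(d, labels) {
  D <- as.matrix(d)
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster samples by their module-eigengene profiles
#'
#' Hierarchical clustering (average linkage) of samples on Euclidean distance
#' over z-scored ME profiles, cut to \code{k} clusters; when \code{k} is NULL
#' it is chosen by maximum mean silhouette over 2..10. If a relapse flag is
#' supplied, per-cluster relapse fractions are reported and clusters with a
#' fraction above \code{enrich_threshold} are flagged relapse-enriched.
#'
#' @param ME module x sample eigengene matrix.
#' @param k cluster count, or NULL for automatic selection.
#' @param relapse optional named (by sample) 0/1 relapse flags.
#' @param enrich_threshold relapse-enrichment boundary (default 0.8,
#'   exclusive).
#' @return list with \code{labels}, \code{k}, \code{hclust},
#'   \code{relapse_fraction}, \code{relapse_enriched}, \code{silhouette}.
#' @export
cluster_samples_by_me <- function(ME, k = NULL, relapse = NULL,
                                  enrich_threshold = 0.8) {
  ME <- as.matrix(ME)
  n <- ncol(ME)
  if (!is.null(k) && k > n) .stopf("cluster_samples_by_me: k > n_samples")
  Z <- t(scale(t(ME)))
  d <- stats::dist(t(Z))
  hc <- stats::hclust(d, method = "average")
  sil <- NA_real_
  if (is.null(k)) {
    ks <- 2:min(10, n - 1)
    sils <- vapply(ks, function(kk) .mean_silhouette(d, stats::cutree(hc, k = kk)),
                   numeric(1))
    k <- ks[which.max(sils)]
    sil <- max(sils)
  }
  labels <- if (k == 1) stats::setNames(rep(1L, n), colnames(ME)) else
    stats::cutree(hc, k = k)
  rf <- NULL; enriched <- NULL
  if (!is.null(relapse)) {
    relapse <- relapse[names(labels)]
    rf <- tapply(as.numeric(relapse), labels, mean, na.rm = TRUE)
    enriched <- rf > enrich_threshold
  }
  list(labels = labels, k = k, hclust = hc, relapse_fraction = rf,
       relapse_enriched = enriched, silhouette = sil)
}

#' Partition per-unit variance across covariates
#'
#' For each unit (gene or module eigengene row), fits a fixed-effect linear
#' model on all covariates and decomposes the explained sum of squares
#' sequentially; fractions are averaged over all covariate orderings when
#' there are at most \code{max_exhaustive} covariates (otherwise the declared
#' input order is used). Fractions are invariant to covariate scaling and sum
#' with the residual to 1.
#'
#' @param X unit x sample matrix (genes or MEs in rows).
#' @param covariates per-sample data frame of covariates (rownames = sample
#'   ids); binary factors are coded 0/1.
#' @param max_exhaustive largest covariate count for exhaustive ordering
#'   averaging.
#' @return data frame with one row per unit: covariate fractions and
#'   \code{residual}.
#' @export
variance_partition <- function(X, covariates, max_exhaustive = 5) {
  X <- as.matrix(X)
  CM <- .traits_numeric(covariates)
  shared <- intersect(colnames(X), rownames(CM))
  if (length(shared) < ncol(CM) + 2)
    .stopf("variance_partition: too few shared samples")
  X <- X[, shared, drop = FALSE]
  CM <- CM[shared, , drop = FALSE]
  p <- ncol(CM)
  # collinearity check
  if (p > 1) {
    cc <- suppressWarnings(stats::cor(CM))
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      if (!is.na(cc[i, j]) && abs(cc[i, j]) > 0.9999)
        .stopf("variance_partition: covariates '%s' and '%s' are collinear",
               colnames(CM)[i], colnames(CM)[j])
    }
  }
  if (qr(cbind(1, scale(CM)))$rank < p + 1)
    .stopf("variance_partition: covariate matrix is rank deficient")
  orderings <- if (p <= max_exhaustive) {
    perms <- function(v) if (length(v) == 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(rest) c(v[i], rest))))
    perms(seq_len(p))
  } else list(seq_len(p))

  decomp_one <- function(y) {
    tot <- sum((y - mean(y))^2)
    if (tot == 0) return(c(rep(0, p), 1))
    acc <- numeric(p)
    for (ord in orderings) {
      rss_prev <- tot
      Xd <- matrix(1, length(y), 1)
      for (pos in seq_along(ord)) {
        Xd <- cbind(Xd, CM[, ord[pos]])
        fit <- stats::lm.fit(Xd, y)
        rss <- sum(fit$residuals^2)
        acc[ord[pos]] <- acc[ord[pos]] + (rss_prev - rss)
        rss_prev <- rss
      }
    }
    fr <- acc / length(orderings) / tot
    c(fr, 1 - sum(fr))
  }
  res <- t(apply(X, 1, decomp_one))
  colnames(res) <- c(colnames(CM), "residual")
  out <- as.data.frame(res)
  out$unit_id <- rownames(X)
  out[, c("unit_id", colnames(CM), "residual")]
}
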