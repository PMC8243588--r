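# Signed weighted co-expression network construction and module detection:
# soft-threshold selection by scale-free fit, signed adjacency, topological
# overlap, average-linkage clustering with a static height cut and minimum
# module size, module eigengenes, kME, and eigengene-based module merging.

#' Network construction parameters
#'
#' @param beta soft-thresholding power (> 0). The pipeline treats
#'   \code{\link{pick_soft_threshold}} as advisory; the configured beta is
#'   authoritative.
#' @param min_module_size smallest cluster kept as a module (>= 3).
#' @param merge_height module-eigengene dissimilarity below which modules are
#'   merged.
#' @param max_block_size genes per block for blockwise decomposition.
#' @param cut_fraction static tree-cut height as a fraction of the maximum
#'   merge height of the dendrogram.
#' @param kme_reassign_threshold unassigned genes with kME at or above this to
#'   a unique best module are adopted by it (set to \code{NA} to disable).
#' @param kme_prune_threshold module members whose kME to their own module
#'   falls below this are returned to label 0 after merging (the reference
#'   convention for cleaning genes swept into a cluster by the tree cut; set
#'   to \code{NA} to disable).
#' @param min_variance_explained coherence floor: detected clusters whose
#'   eigengene explains less than this fraction of member variance are
#'   dissolved to label 0. A static height cut can leave residual background
#'   genes as a large but incoherent cluster; a genuine co-expression module
#'   has a dominant first principal component while background clusters sit
#'   near the Marchenko-Pastur noise level.
#' @param cor_method gene-gene correlation flavour.
#' @return list of class \code{network_config}.
#' @export
network_config <- function(beta = 5.5, min_module_size = 30,
                           merge_height = 0.25, max_block_size = 25000,
                           cut_fraction = 0.95, kme_reassign_threshold = 0.7,
                           kme_prune_threshold = 0.3,
                           min_variance_explained = 0.1,
                           cor_method = c("bicor", "pearson")) {
  if (beta <= 0) .stopf("network_config: beta must be > 0")
  if (min_module_size < 3) .stopf("network_config: min_module_size >= 3")
  cfg <- list(beta = beta, network_type = "signed",
              min_module_size = as.integer(min_module_size),
              merge_height = merge_height,
              max_block_size = as.integer(max_block_size),
              cut_fraction = cut_fraction,
              kme_reassign_threshold = kme_reassign_threshold,
              kme_prune_threshold = kme_prune_threshold,
              min_variance_explained = min_variance_explained,
              cor_method = match.arg(cor_method))
  class(cfg) <- "network_config"
  cfg
}

#' Signed adjacency from a correlation matrix
#'
#' \code{a_ij = ((1 + c_ij) / 2)^beta}, mapping correlation -1 to 0 and +1 to
#' 1 before powering so anti-correlated genes are not connected. Diagonal is
#' set to 1.
#'
#' @param C symmetric correlation matrix with entries in [-1, 1].
#' @param beta soft-thresholding power.
#' @return adjacency matrix in [0, 1].
#' @export
signed_adjacency <- function(C, beta) {
  C <- as.matrix(C)
  if (!isSymmetric(unname(C), tol = 1e-8))
    .stopf("signed_adjacency: correlation matrix must be symmetric")
  if (any(C < -1 - 1e-12 | C > 1 + 1e-12, na.rm = TRUE))
    .stopf("signed_adjacency: entries outside [-1, 1]")
  A <- ((1 + .clamp(C)) / 2)^beta
  diag(A) <- 1
  A
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins \code{log10(k)} (default 10 equal-width bins over k), regresses
#' \code{log10(frequency)} on \code{log10(mean k per bin)} and returns the
#' squared Pearson correlation of that regression, signed negative when the
#' slope is positive (a scale-free degree distribution has a negative slope).
#'
#' @param k connectivity vector.
#' @param n_bins number of bins.
#' @return list with \code{r2} (signed), \code{slope}, \code{n_bins_used}.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins || length(unique(k)) < 2)
    return(list(r2 = NA_real_, slope = NA_real_, n_bins_used = 0L))
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_,
                               n_bins_used = sum(ok)))
  x <- log10(mean_k[ok]); y <- log10(freq[ok] / length(k))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(stats::cor(x, y))^2
  if (!is.finite(slope)) return(list(r2 = NA_real_, slope = NA_real_,
                                     n_bins_used = sum(ok)))
  list(r2 = if (slope > 0) -r2 else r2, slope = slope,
       n_bins_used = as.integer(sum(ok)))
}

#' Soft-threshold candidate table
#'
#' For each candidate power, computes the signed adjacency, the connectivity
#' \code{k_i = sum_{j != i} a_ij}, its scale-free regression fit, and the mean
#' connectivity. The recommended power is the smallest candidate whose signed
#' R-squared reaches \code{r2_target}; the configured beta remains
#' authoritative.
#'
#' @param C gene-gene correlation matrix (>= 50 genes for a meaningful fit).
#' @param candidate_betas powers to scan.
#' @param n_bins histogram bins for the fit.
#' @param r2_target fit threshold for the recommendation.
#' @return data frame (beta, scale_free_r2, slope, mean_connectivity) with
#'   attribute \code{recommended_beta} (NA when no candidate reaches target).
#' @export
pick_soft_threshold <- function(C, candidate_betas = c(1:10, 12, 14, 16, 18, 20),
                                n_bins = 10, r2_target = 0.8) {
  C <- as.matrix(C)
  if (nrow(C) < 50)
    .warnf("pick_soft_threshold: < 50 genes, scale-free fit unreliable")
  rows <- lapply(candidate_betas, function(b) {
    A <- signed_adjacency(C, b)
    k <- colSums(A) - 1
    fit <- scale_free_fit(k, n_bins)
    data.frame(beta = b, scale_free_r2 = fit$r2, slope = fit$slope,
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$scale_free_r2) & tab$scale_free_r2 >= r2_target
  attr(tab, "recommended_beta") <- if (any(ok)) min(tab$beta[ok]) else NA_real_
  tab
}

#' Topological overlap similarity
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} for i != j,
#' where \code{l_ij = sum_{u != i,j} a_iu a_uj} and
#' \code{k_i = sum_{u != i} a_iu}; diagonal is 1. Genes sharing many strong
#' neighbours score high even when their direct adjacency is moderate.
#'
#' @param A symmetric adjacency with entries in [0, 1] and unit diagonal.
#' @return TOM matrix in [0, 1].
#' @export
tom_similarity <- function(A) {
  A <- as.matrix(A)
  if (any(A < 0 | A > 1)) .stopf("tom_similarity: entries outside [0, 1]")
  if (any(abs(diag(A) - 1) > 1e-10))
    .stopf("tom_similarity: adjacency must have unit diagonal")
  k <- colSums(A) - 1
  L <- A %*% A - 2 * A        # l_ij for i != j given unit diagonal
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  .clamp(TOM, 0, 1)
}

#' Detect modules by static cut of a TOM dendrogram
#'
#' Average-linkage hierarchical clustering on \code{1 - TOM}, cut at
#' \code{cut_fraction} of the maximum merge height; clusters smaller than
#' \code{min_module_size} become label 0 (unassigned), and surviving modules
#' are labeled 1..M by decreasing size.
#'
#' @param tom TOM similarity matrix.
#' @param config a \code{\link{network_config}}.
#' @return named integer assignment vector (0 = unassigned).
#' @export
detect_modules <- function(tom, config = network_config()) {
  tom <- as.matrix(tom)
  n <- nrow(tom)
  if (is.null(rownames(tom))) rownames(tom) <- colnames(tom) <-
      sprintf("g%d", seq_len(n))
  if (n < config$min_module_size) {
    .warnf("detect_modules: fewer genes (%d) than min_module_size", n)
    return(stats::setNames(integer(n), rownames(tom)))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut_h <- config$cut_fraction * max(hc$height)
  cl <- stats::cutree(hc, h = cut_h)
  relabel_by_size(cl, config$min_module_size)
}

# drop clusters below min size to 0 and relabel survivors 1..M by
# decreasing size (ties broken by the original cluster label); an incoming
# label 0 always stays unassigned
relabel_by_size <- function(cl, min_module_size) {
  sizes <- table(cl[cl != 0])
  keep <- names(sizes)[sizes >= min_module_size]
  out <- stats::setNames(integer(length(cl)), names(cl))
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[keep], as.numeric(keep))]
    for (i in seq_along(ord)) out[cl == as.numeric(ord[i])] <- i
  }
  out
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression: each
#' gene is z-scored across samples, the first right singular vector gives the
#' per-sample scores, scaled to unit variance and sign-aligned so the ME
#' correlates non-negatively with the module's average standardized
#' expression.
#'
#' @param X log2 gene x sample matrix.
#' @param genes gene identifiers (>= 2, present in X).
#' @return list with \code{me} (named sample vector, unit variance) and
#'   \code{variance_explained} (first eigenvalue fraction).
#' @export
module_eigengene <- function(X, genes) {
  X <- as.matrix(X)
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0)
    .stopf("module_eigengene: genes absent from matrix: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  if (length(genes) < 2) .stopf("module_eigengene: need >= 2 genes")
  M <- X[genes, , drop = FALSE]
  sds <- apply(M, 1, stats::sd)
  if (any(sds == 0)) {
    .warnf("module_eigengene: dropping %d constant gene rows", sum(sds == 0))
    M <- M[sds > 0, , drop = FALSE]
    if (nrow(M) < 2) .stopf("module_eigengene: < 2 non-constant genes")
  }
  Z <- t(scale(t(M)))
  sv <- svd(Z, nu = 0, nv = 1)
  me <- sv$v[, 1]
  avg <- colMeans(Z)
  if (sum(me * avg) < 0) me <- -me
  me <- me / stats::sd(me)
  list(me = stats::setNames(me, colnames(X)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes of all modules
#'
#' @param X log2 gene x sample matrix.
#' @param assignment named module labels (0 skipped).
#' @return list with \code{eigengenes} (module x sample matrix, rows
#'   \code{M1..}) and \code{variance_explained}.
#' @export
module_eigengenes <- function(X, assignment) {
  labels <- sort(unique(assignment[assignment > 0]))
  if (length(labels) == 0) .stopf("module_eigengenes: no modules")
  mes <- lapply(labels, function(m)
    module_eigengene(X, names(assignment)[assignment == m]))
  E <- do.call(rbind, lapply(mes, `[[`, "me"))
  rownames(E) <- paste0("M", labels)
  colnames(E) <- colnames(X)
  list(eigengenes = E,
       variance_explained = stats::setNames(
         vapply(mes, `[[`, numeric(1), "variance_explained"),
         paste0("M", labels)))
}

#' kME table: gene-to-eigengene Pearson correlations
#'
#' @param X gene x sample matrix.
#' @param eigengenes module x sample ME matrix.
#' @return gene x module matrix of Pearson correlations (NA for constant
#'   genes).
#' @export
kme_table <- function(X, eigengenes) {
  X <- as.matrix(X); E <- as.matrix(eigengenes)
  shared <- intersect(colnames(X), colnames(E))
  if (length(shared) < 3) .stopf("kme_table: < 3 shared samples")
  K <- suppressWarnings(stats::cor(t(X[, shared, drop = FALSE]),
                                   t(E[, shared, drop = FALSE])))
  dimnames(K) <- list(rownames(X), rownames(E))
  K
}

#' Hub-gene predicate on a kME table
#'
#' A gene is a hub of its assigned module when its kME there is positive, at
#' or above \code{threshold}, and strictly higher than its kME to any other
#' module.
#'
#' @param kme gene x module kME matrix.
#' @param assignment named module labels.
#' @param threshold kME boundary (default 0.7, inclusive).
#' @return named logical vector.
#' @export
is_hub_gene <- function(kme, assignment, threshold = 0.7) {
  out <- stats::setNames(rep(FALSE, nrow(kme)), rownames(kme))
  for (g in rownames(kme)) {
    m <- assignment[g]
    if (is.na(m) || m == 0) next
    v <- kme[g, ]
    own <- v[paste0("M", m)]
    if (is.na(own) || own < threshold) next
    out[g] <- all(own > v[setdiff(names(v), paste0("M", m))], na.rm = TRUE)
  }
  out
}

#' Merge modules whose eigengenes are highly correlated
#'
#' Clusters MEs by \code{1 - cor} with average linkage, merges clusters below
#' \code{merge_height}, recomputes MEs and iterates to a fixpoint. Labels are
#' re-ranked by size after merging.
#'
#' @param X log2 gene x sample matrix.
#' @param assignment named module labels.
#' @param merge_height ME dissimilarity cut (default 0.25).
#' @param min_module_size passed to the relabeling step.
#' @return merged assignment vector.
#' @export
merge_modules <- function(X, assignment, merge_height = 0.25,
                          min_module_size = 3) {
  repeat {
    labels <- sort(unique(assignment[assignment > 0]))
    if (length(labels) < 2) break
    E <- module_eigengenes(X, assignment)$eigengenes
    D <- 1 - suppressWarnings(stats::cor(t(E)))
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    grp <- stats::cutree(hc, h = merge_height)
    if (max(grp) == length(labels)) break
    map <- stats::setNames(grp[paste0("M", labels)], labels)
    new_assign <- assignment
    for (m in labels) new_assign[assignment == m] <- map[as.character(m)]
    assignment <- relabel_by_size(new_assign, min_module_size)
  }
  assignment
}

# split genes into blocks of at most max_block_size by k-means on the top
# principal components of the standardized gene profiles (projective
# pre-clustering), so correlated genes tend to share a block
.assign_blocks <- function(X, max_block_size) {
  n <- nrow(X)
  n_blocks <- ceiling(n / max_block_size)
  if (n_blocks == 1) return(rep(1L, n))
  Z <- t(scale(t(X)))
  Z[is.na(Z)] <- 0
  npc <- min(10, ncol(Z) - 1, n - 1)
  pcs <- svd(Z, nu = npc, nv = 0)$u
  km <- stats::kmeans(pcs, centers = n_blocks, nstart = 10, iter.max = 50)
  blk <- km$cluster
  # enforce the size cap by spilling overflow into the smallest blocks
  repeat {
    sizes <- tabulate(blk, n_blocks)
    over <- which(sizes > max_block_size)
    if (length(over) == 0) break
    for (b in over) {
      excess <- which(blk == b)
      spill <- excess[seq_len(sizes[b] - max_block_size)]
      target <- which.min(tabulate(blk, n_blocks) + (seq_len(n_blocks) == b) * n)
      blk[spill] <- target
    }
  }
  blk
}

#' Build a signed co-expression network end to end
#'
#' Gene-gene correlation (bicor by default), signed adjacency at the
#' configured power, topological overlap, average-linkage clustering with a
#' static height cut and minimum module size, eigengene-based module merging,
#' kME computation and optional kME-based adoption of unassigned genes.
#' Matrices larger than \code{max_block_size} genes are decomposed into
#' blocks by projective pre-clustering; block-wise modules are then merged by
#' eigengene correlation.
#'
#' @param X cleaned log2 gene x sample matrix.
#' @param config a \code{\link{network_config}}.
#' @return object of class \code{network_model}: config, assignment,
#'   eigengenes, kme, variance_explained.
#' @export
build_network <- function(X, config = network_config()) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("g%d", seq_len(nrow(X)))
  blocks <- .assign_blocks(X, config$max_block_size)
  n_blocks <- length(unique(blocks))
  # with several blocks a module can be split across them; per-block
  # detection keeps fragments at half the size floor so the eigengene merge
  # can reunite them, and the full floor is enforced afterwards
  block_cfg <- config
  if (n_blocks > 1)
    block_cfg$min_module_size <- max(3L, ceiling(config$min_module_size / 2))
  assignment <- stats::setNames(integer(nrow(X)), rownames(X))
  offset <- 0L
  for (b in sort(unique(blocks))) {
    idx <- which(blocks == b)
    Xb <- X[idx, , drop = FALSE]
    C <- if (config$cor_method == "bicor") bicor_matrix(t(Xb)) else
      suppressWarnings(stats::cor(t(Xb)))
    C[is.na(C)] <- 0
    A <- signed_adjacency(C, config$beta)
    TOM <- tom_similarity(A)
    a_b <- detect_modules(TOM, block_cfg)
    a_b[a_b > 0] <- a_b[a_b > 0] + offset
    offset <- max(c(offset, a_b))
    assignment[idx] <- a_b
  }
  assignment <- relabel_by_size(assignment, block_cfg$min_module_size)
  # dissolve incoherent clusters (residual background swept up by the
  # static cut) before merging
  if (config$min_variance_explained > 0) {
    for (m in unique(assignment[assignment > 0])) {
      ve <- module_eigengene(X, names(assignment)[assignment == m])$variance_explained
      if (ve < config$min_variance_explained) assignment[assignment == m] <- 0L
    }
    assignment <- relabel_by_size(assignment, block_cfg$min_module_size)
  }
  if (any(assignment > 0))
    assignment <- merge_modules(X, assignment, config$merge_height,
                                block_cfg$min_module_size)
  assignment <- relabel_by_size(assignment, config$min_module_size)
  mes <- if (any(assignment > 0)) module_eigengenes(X, assignment) else
    list(eigengenes = NULL, variance_explained = numeric(0))
  kme <- if (!is.null(mes$eigengenes)) kme_table(X, mes$eigengenes) else NULL
  # prune members whose own-module kME is weak (genes swept into a cluster
  # by the tree cut rather than genuinely co-expressed)
  prune <- config$kme_prune_threshold
  if (!is.null(kme) && !is.na(prune)) {
    own <- kme[cbind(names(assignment), paste0("M", pmax(assignment, 1)))]
    drop <- assignment > 0 & (is.na(own) | own < prune)
    if (any(drop)) {
      assignment[drop] <- 0L
      assignment <- relabel_by_size(assignment, config$min_module_size)
      if (any(assignment > 0)) {
        mes <- module_eigengenes(X, assignment)
        kme <- kme_table(X, mes$eigengenes)
      } else {
        mes <- list(eigengenes = NULL, variance_explained = numeric(0))
        kme <- NULL
      }
    }
  }
  thr <- config$kme_reassign_threshold
  if (!is.null(kme) && !is.na(thr)) {
    grey <- names(assignment)[assignment == 0]
    cols <- colnames(kme)
    for (g in grey) {
      v <- kme[g, ]
      if (all(is.na(v))) next
      best <- which.max(v)
      if (v[best] >= thr && sum(v >= thr, na.rm = TRUE) == 1)
        assignment[g] <- as.integer(sub("^M", "", cols[best]))
    }
    if (length(grey) > 0 && any(assignment[grey] > 0)) {
      assignment <- relabel_by_size(assignment, config$min_module_size)
      mes <- module_eigengenes(X, assignment)
      kme <- kme_table(X, mes$eigengenes)
    }
  }
  structure(list(config = config, assignment = assignment,
                 eigengenes = mes$eigengenes, kme = kme,
                 variance_explained = mes$variance_explained),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  n_mod <- length(unique(x$assignment[x$assignment > 0]))
  cat(sprintf("network_model: %d genes, %d modules (beta = %g, signed)\n",
              length(x$assignment), n_mod, x$config$beta))
  if (n_mod > 0) {
    sizes <- table(x$assignment[x$assignment > 0])
    cat("module sizes:", paste(sprintf("M%s=%d", names(sizes), sizes),
                               collapse = " "), "\n")
  }
  cat(sprintf("unassigned: %d\n", sum(x$assignment == 0)))
  invisible(x)
}

#' Conventional module color aliases
#'
#' Color names conventionally paired with module ranks M1, M2, ... in
#' co-expression analyses (M1 = turquoise, M2 = blue, ...), for
#' interoperability of output tables.
#'
#' @param n number of aliases.
#' @return character vector of length \code{n}.
#' @export
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("module%d", seq_len(n - length(base))))
}
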