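# Differential expression: one-way ANOVA with Tukey HSD post-hoc on genes
# and module eigengenes across the four Binet-stage x relapse groups, a
# two-group Wilcoxon rank-sum test, fold changes, and the hub-biomarker gate.

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Classic equal-variance one-way ANOVA plus Tukey-Kramer adjusted pairwise
#' p-values from the studentized range distribution with (k, N - k)
#' parameters. Groups with fewer than 2 observations are excluded from the
#' Tukey family with a warning. The log2 fold change is the focal-group mean
#' minus the reference-group mean.
#'
#' @param y numeric response (log2 expression of one gene or one ME).
#' @param groups group labels.
#' @param focal_pair optional character vector \code{c(focal, reference)} for
#'   the reported lfc and focal p-value.
#' @return list: \code{F}, \code{p} (ANOVA), \code{tukey_p} (named per pair
#'   \code{"a.vs.b"}), \code{lfc}, \code{focal_p}.
#' @export
anova_tukey <- function(y, groups, focal_pair = NULL) {
  groups <- factor(groups)
  ok <- !is.na(y) & !is.na(groups)
  y <- y[ok]; groups <- droplevels(groups[ok])
  counts <- table(groups)
  k <- nlevels(groups)
  if (k < 2 || sum(counts >= 2) < 2)
    .stopf("anova_tukey: need >= 2 groups with >= 2 samples each")
  N <- length(y)
  means <- tapply(y, groups, mean)
  grand <- mean(y)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((y - means[groups])^2)
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  Fstat <- if (ssb == 0) 0 else if (msw == 0) Inf else (ssb / df1) / msw
  p_anova <- if (is.infinite(Fstat)) 0 else
    stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  tukey_levels <- names(counts)[counts >= 2]
  if (length(tukey_levels) < k)
    .warnf("anova_tukey: groups with < 2 samples excluded from Tukey: %s",
           paste(setdiff(names(counts), tukey_levels), collapse = ", "))
  pairs <- utils::combn(tukey_levels, 2)
  tukey_p <- apply(pairs, 2, function(pr) {
    ni <- counts[pr[1]]; nj <- counts[pr[2]]
    se <- sqrt(msw / 2 * (1 / ni + 1 / nj))
    if (se == 0) return(if (means[pr[1]] == means[pr[2]]) 1 else 0)
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    stats::ptukey(q, nmeans = length(tukey_levels), df = df2,
                  lower.tail = FALSE)
  })
  names(tukey_p) <- apply(pairs, 2, paste, collapse = ".vs.")

  lfc <- NA_real_; focal_p <- NA_real_
  if (!is.null(focal_pair)) {
    if (!all(focal_pair %in% levels(groups)))
      .warnf("anova_tukey: focal pair levels absent")
    else {
      lfc <- unname(means[focal_pair[1]] - means[focal_pair[2]])
      key <- paste(focal_pair, collapse = ".vs.")
      key_rev <- paste(rev(focal_pair), collapse = ".vs.")
      focal_p <- if (key %in% names(tukey_p)) unname(tukey_p[key]) else
        if (key_rev %in% names(tukey_p)) unname(tukey_p[key_rev]) else NA_real_
    }
  }
  list(F = unname(Fstat), p = unname(p_anova), tukey_p = tukey_p,
       lfc = lfc, focal_p = focal_p)
}

#' Two-group Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Exact permutation p-value by enumeration when both groups have at most
#' \code{exact_max} observations, otherwise the tie-corrected normal
#' approximation with continuity correction. Two-sided.
#'
#' @param x numeric values.
#' @param labels binary group indicator (logical or 0/1).
#' @param exact_max enumeration bound per group (default 10).
#' @return list with \code{statistic} (Mann-Whitney U of group 1) and \code{p}.
#' @export
wilcoxon_two_group <- function(x, labels, exact_max = 10) {
  g <- as.logical(labels)
  if (sum(g) == 0 || sum(!g) == 0)
    .stopf("wilcoxon_two_group: both groups must be non-empty")
  n1 <- sum(g); n2 <- sum(!g); N <- n1 + n2
  r <- rank(x)
  U <- sum(r[g]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    # exact permutation distribution of the rank sum (ties handled by
    # permuting the observed ranks)
    combs <- utils::combn(N, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    u_all <- sums - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= U), mean(u_all >= U))
    return(list(statistic = U, p = min(1, p)))
  }
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(list(statistic = U, p = 1))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(statistic = U, p = min(1, 2 * stats::pnorm(-z)))
}

#' Gene-wise differential expression across Binet-stage x relapse groups
#'
#' Runs \code{\link{anova_tukey}} on every gene with the four-group design
#' (stage A/B crossed with relapse yes/no) and the focal pair
#' stage-A-relapse vs stage-A-no-relapse.
#'
#' @param X log2 gene x sample matrix.
#' @param traits per-sample data frame with \code{binet_stage} and
#'   \code{relapse} columns.
#' @param assignment optional named module labels added to the table.
#' @param stage_col,relapse_col trait column names.
#' @param focal_pair group labels \code{c(focal, reference)}.
#' @return data frame: gene, F, p_anova, focal tukey p, lfc, module.
#' @export
diffexp_table <- function(X, traits, assignment = NULL,
                          stage_col = "binet_stage", relapse_col = "relapse",
                          focal_pair = c("A_relapse", "A_norelapse")) {
  X <- as.matrix(X)
  shared <- intersect(colnames(X), rownames(traits))
  if (length(shared) < 8) .stopf("diffexp_table: too few shared samples")
  X <- X[, shared, drop = FALSE]
  tr <- traits[shared, ]
  groups <- paste0(tr[[stage_col]], ifelse(as.numeric(tr[[relapse_col]]) == 1,
                                           "_relapse", "_norelapse"))
  res <- lapply(rownames(X), function(g) {
    a <- suppressWarnings(anova_tukey(X[g, ], groups, focal_pair))
    data.frame(gene = g, F = a$F, p_anova = a$p, tukey_p = a$focal_p,
               lfc = a$lfc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$module <- if (is.null(assignment)) NA_integer_ else
    unname(assignment[out$gene])
  out
}

#' Select differentially expressed hub biomarkers
#'
#' The gate is \code{p < p_max} (strict), \code{kME >= kme_min} in the gene's
#' assigned module (inclusive) and \code{|lfc| >= lfc_min} (inclusive);
#' unassigned genes never pass.
#'
#' @param records data frame from \code{\link{diffexp_table}} (columns gene,
#'   tukey_p, lfc, module).
#' @param kme gene x module kME matrix.
#' @param p_max,kme_min,lfc_min thresholds.
#' @return data frame of qualifying genes (gene, module, tukey_p, kme, lfc),
#'   ordered by module then p.
#' @export
select_biomarkers <- function(records, kme, p_max = 0.05, kme_min = 0.7,
                              lfc_min = 0.5) {
  recs <- records[!is.na(records$module) & records$module > 0, , drop = FALSE]
  if (nrow(recs) == 0)
    return(data.frame(gene = character(0), module = integer(0),
                      tukey_p = numeric(0), kme = numeric(0),
                      lfc = numeric(0)))
  own_kme <- vapply(seq_len(nrow(recs)), function(i) {
    col <- paste0("M", recs$module[i])
    if (recs$gene[i] %in% rownames(kme) && col %in% colnames(kme))
      kme[recs$gene[i], col] else NA_real_
  }, numeric(1))
  pass <- !is.na(recs$tukey_p) & recs$tukey_p < p_max &
    !is.na(own_kme) & own_kme >= kme_min &
    !is.na(recs$lfc) & abs(recs$lfc) >= lfc_min
  out <- data.frame(gene = recs$gene[pass], module = recs$module[pass],
                    tukey_p = recs$tukey_p[pass], kme = own_kme[pass],
                    lfc = recs$lfc[pass], stringsAsFactors = FALSE)
  out[order(out$module, out$tukey_p), , drop = FALSE]
}

#' Volcano table of differential expression records
#'
#' @param records data frame from \code{\link{diffexp_table}}.
#' @return data frame (gene, lfc, neg_log10_p, direction) sorted by p
#'   ascending then |lfc| descending; direction is "up"/"down" by lfc sign.
#' @export
volcano_table <- function(records) {
  out <- data.frame(gene = records$gene, lfc = records$lfc,
                    neg_log10_p = -log10(records$tukey_p),
                    direction = ifelse(records$lfc >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out[order(records$tukey_p, -abs(records$lfc)), , drop = FALSE]
}
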