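# Over-representation analysis of gene lists against GMT gene-set
# collections: one-sided Fisher (hypergeometric tail) tests, analytic
# enrichment z-scores, and Benjamini-Hochberg adjustment.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated
#' \code{name, description, gene1, gene2, ...}; single-gene sets are valid.
#'
#' @param path file path.
#' @return named list of character gene vectors with attribute
#'   \code{descriptions}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) .stopf("read_gmt: empty file '%s'", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0)
    .stopf("read_gmt: line %d has fewer than 3 fields", bad[1])
  sets <- lapply(fields, function(f) unique(f[-c(1, 2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), names(sets))
  sets
}

#' Fisher exact over-representation of a query gene list
#'
#' One-sided hypergeometric tail per set: \code{P[X >= overlap]} with
#' \code{X ~ Hypergeom(background_size, set_size, query_size)}, sets being
#' intersected with the background before testing. Also reports the
#' normal-approximation enrichment z-score \code{(overlap - E[X]) / SD[X]}
#' and BH-adjusted p-values.
#'
#' @param query character gene list (must be a subset of the background).
#' @param sets named list of gene sets (e.g. from \code{\link{read_gmt}}).
#' @param background gene universe, by default all genes surviving
#'   preprocessing.
#' @return data frame (set_name, overlap, set_size, query_size,
#'   background_size, p, p_adj, z) sorted by p then set name.
#' @export
fisher_enrichment <- function(query, sets, background) {
  background <- unique(background)
  if (length(background) == 0) .stopf("fisher_enrichment: empty background")
  query <- unique(query)
  extra <- setdiff(query, background)
  if (length(extra) > 0)
    .stopf("fisher_enrichment: query genes not in background: %s",
           paste(utils::head(extra, 5), collapse = ", "))
  B <- length(background); Q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], background)
    K <- length(s)
    ov <- length(intersect(query, s))
    p <- if (K == 0 || Q == 0) 1 else
      stats::phyper(ov - 1, K, B - K, Q, lower.tail = FALSE)
    E <- Q * K / B
    V <- Q * (K / B) * (1 - K / B) * (B - Q) / (B - 1)
    z <- if (V > 0) (ov - E) / sqrt(V) else NA_real_
    data.frame(set_name = nm, overlap = ov, set_size = K, query_size = Q,
               background_size = B, p = p, z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p, out$set_name), c("set_name", "overlap", "set_size",
                                    "query_size", "background_size",
                                    "p", "p_adj", "z")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up adjustment, capped at 1, returned in the input order.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- cummin(n / (n:1) * p[o])
  pmin(1, adj)[ro]
}
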