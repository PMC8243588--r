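# Biweight midcorrelation.
#
# Robust correlation built from Tukey biweights around the median:
#   u_i = (x_i - med(x)) / (9 * mad(x)),   mad = median absolute deviation
#   w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]
# and the correlation of the weighted deviations w_i * (x_i - med(x)).
# The mad here is the raw median absolute deviation (no consistency constant);
# the 9 * mad scaling makes the weights vanish beyond nine mads.

# weighted, centered, unit-norm deviations for one vector; falls back to
# plain mean-centering (i.e. the Pearson contribution) when mad(x) == 0
.bicor_prep <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0) {
    d <- x - mean(x)
  } else {
    u <- (x - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    d <- w * (x - med)
  }
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) return(rep(NA_real_, length(x)))
  d / nrm
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation that down-weights outliers using Tukey biweights around
#' the median. A vector whose median absolute deviation is zero falls back to
#' plain mean-centering (Pearson behaviour) for that vector only, which also
#' covers 0/1-coded binary traits.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in [-1, 1].
#' @examples
#' x <- rnorm(20)
#' bicor(x, 2 * x + 1) # 1
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) .stopf("bicor: vectors differ in length")
  if (length(x) < 3) .stopf("bicor: need at least 3 observations")
  a <- .bicor_prep(x)
  b <- .bicor_prep(y)
  if (anyNA(a) || anyNA(b))
    .stopf("bicor: correlation undefined for a constant vector")
  .clamp(sum(a * b))
}

#' Biweight midcorrelation matrix
#'
#' Pairwise biweight midcorrelation between the columns of a matrix
#' (observations in rows, variables in columns), the robust analogue of
#' \code{cor(M)}. Constant columns yield \code{NA} rows/columns.
#'
#' @param M numeric matrix, observations x variables.
#' @return variables x variables correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 3) .stopf("bicor_matrix: need at least 3 observations")
  P <- apply(M, 2, .bicor_prep)
  C <- crossprod(P)
  C <- .clamp(C)
  diag(C) <- ifelse(is.na(diag(C)), NA_real_, 1)
  dimnames(C) <- list(colnames(M), colnames(M))
  C
}

# correlation matrix between columns of M and columns of N (shared rows)
.cor_xy <- function(M, N, method = c("pearson", "bicor")) {
  method <- match.arg(method)
  if (method == "pearson") {
    suppressWarnings(stats::cor(M, N))
  } else {
    A <- apply(as.matrix(M), 2, .bicor_prep)
    B <- apply(as.matrix(N), 2, .bicor_prep)
    .clamp(crossprod(A, B))
  }
}
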