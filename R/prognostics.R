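# Relapse-risk and survival evaluation: nonparametric ROC/AUC with a z-test
# against 0.5, prognostic-ratio combination screening at fixed relapse
# horizons, Kaplan-Meier product-limit curves, log-rank tests with Pike
# hazard ratios, and optimal expression cutpoints.

#' Nonparametric ROC AUC with a z-test against 0.5
#'
#' AUC is the Mann-Whitney U statistic divided by \code{n_pos * n_neg} (ties
#' count one half); the standard error follows Hanley & McNeil, and
#' \code{z = (AUC - 0.5) / SE} with a two-sided normal p-value.
#'
#' @param scores numeric marker values (higher = more positive).
#' @param labels binary outcome (logical or 0/1); both classes required.
#' @param marker_name optional label carried into the result.
#' @return list of class \code{roc_result}: marker_name, auc, se, z, p,
#'   n_pos, n_neg.
#' @export
roc_auc <- function(scores, labels, marker_name = NA_character_) {
  g <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(g)
  scores <- scores[ok]; g <- g[ok]
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0) .stopf("roc_auc: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else sign(auc - 0.5) * Inf
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else
    if (auc == 0.5) 1 else 0
  structure(list(marker_name = marker_name, auc = auc, se = se, z = z, p = p,
                 n_pos = n1, n_neg = n0), class = "roc_result")
}

#' Z-score a log2 expression matrix gene-wise
#'
#' @param X gene x sample matrix.
#' @return matrix with each gene row standardized to mean 0, SD 1.
#' @export
zscore_expression <- function(X) {
  Z <- t(scale(t(as.matrix(X))))
  attr(Z, "scale") <- "zscore"
  Z
}

#' Prognostic-ratio score contrasting two gene sets
#'
#' Per sample, contrasts the mean z-scored expression of relapse-up
#' (numerator) genes against relapse-down (denominator) genes. The default
#' \code{difference} mode scores \code{mean(Z[num]) - mean(Z[den])}, which is
#' robust for z-scores that cross zero; \code{literal_ratio} divides the set
#' means (with a 1e-6 guard and a stability warning when any denominator mean
#' is within (-0.1, 0.1)).
#'
#' @param Z z-scored gene x sample matrix (see \code{\link{zscore_expression}}).
#' @param numerator,denominator disjoint gene sets of size 1-3 each.
#' @param mode scoring mode.
#' @return named per-sample score vector.
#' @export
prognostic_ratio <- function(Z, numerator, denominator,
                             mode = c("difference", "literal_ratio")) {
  mode <- match.arg(mode)
  if (length(intersect(numerator, denominator)) > 0)
    .stopf("prognostic_ratio: numerator and denominator must be disjoint")
  if (length(numerator) < 1 || length(numerator) > 3 ||
      length(denominator) < 1 || length(denominator) > 3)
    .stopf("prognostic_ratio: sets must have 1-3 genes")
  missing <- setdiff(c(numerator, denominator), rownames(Z))
  if (length(missing) > 0)
    .stopf("prognostic_ratio: genes absent: %s", paste(missing, collapse = ", "))
  num <- colMeans(Z[numerator, , drop = FALSE])
  den <- colMeans(Z[denominator, , drop = FALSE])
  if (mode == "difference") return(num - den)
  if (any(abs(den) < 0.1))
    .warnf("prognostic_ratio: denominator means near zero; literal ratio unstable")
  eps <- 1e-6 * ifelse(den >= 0, 1, -1)
  num / (den + eps)
}

#' Enumerate numerator/denominator gene-set combinations
#'
#' Cartesian product of all numerator subsets of size 1..\code{max_size} with
#' all denominator subsets of size 1..\code{max_size}, in deterministic
#' lexicographic order (by size, then pool order).
#'
#' @param numerator_pool,denominator_pool disjoint gene pools.
#' @param max_size largest subset size (default 3).
#' @return list of \code{list(numerator =, denominator =)} pairs, with
#'   attribute \code{n_combinations}.
#' @export
enumerate_combinations <- function(numerator_pool, denominator_pool,
                                   max_size = 3) {
  if (length(intersect(numerator_pool, denominator_pool)) > 0)
    .stopf("enumerate_combinations: pools must be disjoint")
  subsets <- function(pool) {
    out <- list()
    for (s in seq_len(min(max_size, length(pool))))
      out <- c(out, utils::combn(pool, s, simplify = FALSE))
    out
  }
  nums <- subsets(numerator_pool)
  dens <- subsets(denominator_pool)
  combos <- vector("list", length(nums) * length(dens))
  k <- 0L
  for (nu in nums) for (de in dens) {
    k <- k + 1L
    combos[[k]] <- list(numerator = nu, denominator = de)
  }
  attr(combos, "n_combinations") <- k
  combos
}

#' Dichotomize relapse-free survival at a horizon
#'
#' Positive = relapse event within the horizon; negative = followed
#' event-free to at least the horizon; samples censored before the horizon
#' are excluded and listed.
#'
#' @param records data frame with \code{time} (days) and \code{event}
#'   (1 = relapse observed, 0 = censored); rownames or a \code{sample_id}
#'   column identify samples.
#' @param horizon days (> 0).
#' @return list with \code{labels} (named 0/1 vector over usable samples) and
#'   \code{excluded} (sample ids censored before the horizon).
#' @export
dichotomize_rfs <- function(records, horizon) {
  if (horizon <= 0) .stopf("dichotomize_rfs: horizon must be positive")
  ids <- if ("sample_id" %in% names(records)) records$sample_id else
    rownames(records)
  pos <- records$event == 1 & records$time <= horizon
  neg <- !pos & records$time >= horizon
  excl <- !(pos | neg)
  list(labels = stats::setNames(as.numeric(pos[!excl]), ids[!excl]),
       excluded = ids[excl])
}

#' Relapse-interval horizons in days
#'
#' 15 and 18 months (30.44-day months) and 3 and 5 years (365.25-day years).
#'
#' @return named numeric vector of declared horizon constants.
#' @export
rfs_horizons <- function() {
  c("15mo" = 456, "18mo" = 548, "3y" = 1095, "5y" = 1826)
}

#' Screen gene-set combinations for horizon-specific relapse prediction
#'
#' Enumerates numerator/denominator combinations, scores every sample with
#' \code{\link{prognostic_ratio}}, dichotomizes relapse-free survival at each
#' horizon and records the AUC.
#'
#' @param Z z-scored gene x sample matrix.
#' @param numerator_pool,denominator_pool disjoint candidate pools.
#' @param records relapse-free-survival records (see
#'   \code{\link{dichotomize_rfs}}); sample ids must match columns of
#'   \code{Z}.
#' @param horizons named vector of horizons in days.
#' @param max_size largest subset size.
#' @param mode scoring mode for \code{\link{prognostic_ratio}}.
#' @return data frame with one row per combination: numerator, denominator
#'   (slash-joined), and one AUC column per horizon; attribute
#'   \code{n_combinations}.
#' @export
screen_combinations <- function(Z, numerator_pool, denominator_pool, records,
                                horizons = rfs_horizons(), max_size = 3,
                                mode = "difference") {
  combos <- enumerate_combinations(numerator_pool, denominator_pool, max_size)
  labs <- lapply(horizons, function(h) dichotomize_rfs(records, h)$labels)
  rows <- lapply(combos, function(cb) {
    sc <- prognostic_ratio(Z, cb$numerator, cb$denominator, mode = mode)
    aucs <- vapply(labs, function(l) {
      use <- intersect(names(l), names(sc))
      if (length(unique(l[use])) < 2) return(NA_real_)
      roc_auc(sc[use], l[use])$auc
    }, numeric(1))
    c(aucs)
  })
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- paste0("auc_", names(horizons))
  out <- cbind(
    data.frame(
      numerator = vapply(combos, function(cb) paste(cb$numerator, collapse = "+"),
                         character(1)),
      denominator = vapply(combos, function(cb) paste(cb$denominator, collapse = "+"),
                           character(1)),
      stringsAsFactors = FALSE),
    out)
  attr(out, "n_combinations") <- attr(combos, "n_combinations")
  out
}

#' Kaplan-Meier product-limit curve
#'
#' @param time non-negative follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @return data frame with one row per distinct observed time: time, n_risk,
#'   n_event, n_censor, surv (survival just after that time). S(0) = 1 and
#'   the curve drops only at event times.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1) .stopf("km_curve: need >= 1 record")
  if (any(time < 0)) .stopf("km_curve: negative times")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

# pooled log-rank O/E machinery shared by the test and the cutpoint scan
.logrank_core <- function(time, event, group) {
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  O2 <- E2 <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group)
    n2 <- n - n1
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    E1 <- E1 + d * n1 / n
    E2 <- E2 + d * n2 / n
    O1 <- O1 + d1
    O2 <- O2 + (d - d1)
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, O2 = O2, E2 = E2, V = V)
}

#' Log-rank test and Pike hazard ratio between two groups
#'
#' Standard log-rank: at each distinct event time the risk sets are pooled,
#' observed and expected events accumulated per group;
#' \code{chi2 = (O_a - E_a)^2 / Var} with a chi-square df-1 p-value. The
#' hazard ratio is the Pike estimator \code{(O_a / E_a) / (O_b / E_b)},
#' reported for group A relative to group B.
#'
#' @param group_a,group_b data frames with \code{time} and \code{event}
#'   columns.
#' @return list: chi2, p, hr, obs (length-2), exp (length-2), status
#'   ("ok" or "no_events").
#' @export
logrank_and_hr <- function(group_a, group_b) {
  if (nrow(group_a) < 1 || nrow(group_b) < 1)
    .stopf("logrank_and_hr: both groups need >= 1 subject")
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  group <- c(rep(TRUE, nrow(group_a)), rep(FALSE, nrow(group_b)))
  if (sum(event) == 0)
    return(list(chi2 = NA_real_, p = NA_real_, hr = NA_real_,
                obs = c(0, 0), exp = c(0, 0), status = "no_events"))
  oe <- .logrank_core(time, event, group)
  chi2 <- if (oe$V > 0) (oe$O1 - oe$E1)^2 / oe$V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  hr <- if (oe$E1 > 0 && oe$E2 > 0 && oe$O2 > 0)
    (oe$O1 / oe$E1) / (oe$O2 / oe$E2) else NA_real_
  list(chi2 = chi2, p = p, hr = hr, obs = c(oe$O1, oe$O2),
       exp = c(oe$E1, oe$E2), status = "ok")
}

#' Optimal survival cutpoint on an expression vector
#'
#' Scans the midpoints between consecutive sorted unique expression values
#' whose induced low/high split leaves each group at least
#' \code{min_group_frac} of the samples, and selects the cutpoint maximizing
#' the log-rank chi-square (ties resolved to the lower cutpoint). The
#' reported test is selection-biased by construction: the p-value is not
#' corrected for scanning.
#'
#' @param expression named per-sample values.
#' @param records data frame with \code{time} and \code{event}, rows aligned
#'   with \code{expression}.
#' @param min_group_frac smallest admissible group fraction (default 0.1).
#' @return list: cutpoint, labels ("low"/"high" per sample), logrank (for low
#'   vs high), n_low, n_high, status ("ok" or "no_admissible_split").
#' @export
optimal_cutpoint <- function(expression, records, min_group_frac = 0.1) {
  n <- length(expression)
  if (n < 10) .stopf("optimal_cutpoint: need >= 10 subjects")
  if (nrow(records) != n) .stopf("optimal_cutpoint: records misaligned")
  ux <- sort(unique(expression))
  if (length(ux) < 2)
    return(list(cutpoint = NA_real_, labels = NULL, logrank = NULL,
                n_low = NA, n_high = NA, status = "no_admissible_split"))
  mids <- (ux[-1] + ux[-length(ux)]) / 2
  min_n <- ceiling(min_group_frac * n)
  best <- NULL
  for (ct in mids) {
    low <- expression <= ct
    if (sum(low) < min_n || sum(!low) < min_n) next
    oe <- .logrank_core(records$time, records$event, low)
    chi2 <- if (oe$V > 0) (oe$O1 - oe$E1)^2 / oe$V else 0
    if (is.null(best) || chi2 > best$chi2 + 1e-12)
      best <- list(cut = ct, chi2 = chi2)
  }
  if (is.null(best))
    return(list(cutpoint = NA_real_, labels = NULL, logrank = NULL,
                n_low = NA, n_high = NA, status = "no_admissible_split"))
  low <- expression <= best$cut
  lr <- logrank_and_hr(records[low, , drop = FALSE],
                       records[!low, , drop = FALSE])
  list(cutpoint = best$cut,
       labels = stats::setNames(ifelse(low, "low", "high"), names(expression)),
       logrank = lr, n_low = sum(low), n_high = sum(!low), status = "ok")
}
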