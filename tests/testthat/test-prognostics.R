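test_that("AUC equals the pair-counting oracle, including ties", {
  set.seed(111)
  for (i in 1:15) {
    n <- sample(8:50, 1)
    scores <- sample(1:10, n, replace = TRUE) # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
  # perfect separation and all-ties closed forms
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  # label flip symmetry
  set.seed(112)
  s <- rnorm(30); l <- rbinom(30, 1, 0.5)
  expect_equal(roc_auc(s, l)$auc, 1 - roc_auc(s, 1 - l)$auc,
               tolerance = 1e-12)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("Hanley-McNeil z-test behaves at the null and the extreme", {
  set.seed(113)
  r <- roc_auc(rnorm(200), rbinom(200, 1, 0.5))
  expect_gt(r$p, 1e-4) # a null marker is rarely wildly significant
  sep <- roc_auc(c(rnorm(50), rnorm(50) + 10), rep(c(0, 1), each = 50))
  expect_equal(sep$auc, 1)
  expect_equal(sep$p, 0)
})

test_that("prognostic ratio: difference mode identities", {
  Z <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  Z[2, ] <- Z[1, ]  # identical z rows
  sc <- prognostic_ratio(Z, "g1", "g2")
  expect_equal(unname(sc), rep(0, 10), tolerance = 1e-12)
  a <- prognostic_ratio(Z, c("g1", "g3"), c("g4", "g5"))
  b <- prognostic_ratio(Z, c("g4", "g5"), c("g1", "g3"))
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(prognostic_ratio(Z, c("g1"), c("g1", "g2")), "disjoint")
  expect_error(prognostic_ratio(Z, character(0), "g2"), "1-3 genes")
  # literal ratio warns near zero denominators
  Z["g3", 1] <- 0.01
  expect_warning(prognostic_ratio(Z, "g1", "g3", mode = "literal_ratio"),
                 "unstable")
})

test_that("combination enumeration counts and uniqueness", {
  c1 <- enumerate_combinations(c("a", "b"), "x", max_size = 2)
  expect_equal(attr(c1, "n_combinations"), 3)
  c2 <- enumerate_combinations(letters[1:4], c("x", "y", "z"), max_size = 3)
  expect_equal(attr(c2, "n_combinations"), (4 + 6 + 4) * (3 + 3 + 1))
  keys <- vapply(c2, function(cb)
    paste(paste(sort(cb$numerator), collapse = "+"),
          paste(sort(cb$denominator), collapse = "+"), sep = "/"),
    character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(enumerate_combinations(c("a", "b"), c("b")), "disjoint")
})

test_that("RFS dichotomization applies the horizon rules", {
  rec <- data.frame(time = c(100, 200, 2000, 450, 500),
                    event = c(1, 0, 0, 1, 0),
                    row.names = sprintf("s%d", 1:5))
  d <- dichotomize_rfs(rec, 450)
  expect_equal(d$labels[["s1"]], 1)      # event before horizon
  expect_false("s2" %in% names(d$labels)) # censored before horizon
  expect_equal(d$excluded, "s2")
  expect_equal(d$labels[["s3"]], 0)      # event-free past horizon
  expect_equal(d$labels[["s4"]], 1)      # event at horizon counts
  expect_equal(d$labels[["s5"]], 0)
  expect_error(dichotomize_rfs(rec, 0), "positive")
  expect_equal(unname(rfs_horizons()), c(456, 548, 1095, 1826))
})

test_that("Kaplan-Meier matches closed forms and the survival package", {
  # 4 subjects, events at 1..4
  km <- km_curve(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  km2 <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # mixed 8-subject fixture against survival::survfit
  tm <- c(2, 3, 3, 5, 7, 8, 11, 12)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0)
  km3 <- km_curve(tm, ev)
  sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  expect_equal(km3$surv, summary(sf, times = km3$time)$surv,
               tolerance = 1e-12)
  expect_error(km_curve(-1, 1), "negative")
})

test_that("log-rank chi2/HR match survdiff and obey symmetry", {
  ga <- data.frame(time = c(6, 13, 21, 30, 31, 37), event = c(1, 1, 1, 1, 0, 1))
  gb <- data.frame(time = c(10, 15, 24, 33, 40, 45), event = c(1, 1, 0, 1, 1, 0))
  lr <- logrank_and_hr(ga, gb)
  sd <- survival::survdiff(
    survival::Surv(c(ga$time, gb$time), c(ga$event, gb$event)) ~
      rep(c("a", "b"), each = 6))
  expect_equal(lr$chi2, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$obs, unname(sd$obs), tolerance = 1e-12)
  expect_equal(lr$exp, unname(sd$exp), tolerance = 1e-12)
  # Pike estimator from the O/E table
  expect_equal(lr$hr, (lr$obs[1] / lr$exp[1]) / (lr$obs[2] / lr$exp[2]),
               tolerance = 1e-12)
  # swap symmetry
  lr2 <- logrank_and_hr(gb, ga)
  expect_equal(lr2$chi2, lr$chi2, tolerance = 1e-12)
  expect_equal(lr2$hr, 1 / lr$hr, tolerance = 1e-12)
  # identical groups: chi2 = 0, HR = 1
  lr3 <- logrank_and_hr(ga, ga)
  expect_equal(lr3$chi2, 0, tolerance = 1e-12)
  expect_equal(lr3$hr, 1, tolerance = 1e-12)
  # no events anywhere -> explicit status
  none <- data.frame(time = c(1, 2), event = c(0, 0))
  expect_identical(logrank_and_hr(none, none)$status, "no_events")
})

test_that("optimal cutpoint recovers a planted split and is rank-invariant", {
  set.seed(114)
  n <- 60
  expr <- c(rnorm(n / 2, 0), rnorm(n / 2, 5))
  names(expr) <- sprintf("s%02d", 1:n)
  # events concentrated in the high-expression half
  rec <- data.frame(
    time = c(rexp(n / 2, 1 / 2000), rexp(n / 2, 1 / 300)),
    event = 1, row.names = names(expr))
  cp <- optimal_cutpoint(expr, rec)
  expect_identical(cp$status, "ok")
  expect_gt(cp$cutpoint, max(sort(expr)[1:(n / 2 - 3)]))
  expect_lt(cp$cutpoint, min(sort(expr)[(n / 2 + 4):n]))
  # affine transformation leaves the split unchanged
  cp2 <- optimal_cutpoint(expr * 7 - 3, rec)
  expect_identical(cp$labels, cp2$labels)
  expect_equal(cp$logrank$chi2, cp2$logrank$chi2, tolerance = 1e-10)
  # constant expression: no admissible split
  cp3 <- optimal_cutpoint(setNames(rep(1, n), names(expr)), rec)
  expect_identical(cp3$status, "no_admissible_split")
})

test_that("relapse-linked prognostic ratios separate at RFS horizons", {
  # [DERIVED: simulation] AUC > 0.7 in >= 80% of seeds at effect 1.5
  hits <- 0
  for (s in 1:10) {
    coh <- small_cohort(seed = 400 + s, n_genes = 120, n_samples = 200,
                        module_sizes = c(40, 30), relapse_effect = 1.5)
    X <- log_transform(coh$expression)
    Z <- zscore_expression(X)
    num <- coh$truth[[1]]$gene_ids[1:3]          # load on relapse module
    den <- setdiff(rownames(X), unlist(lapply(coh$truth, `[[`, "gene_ids")))[1:3]
    sc <- prognostic_ratio(Z, num, den)
    rec <- data.frame(time = coh$traits$rfs_days, event = coh$traits$rfs_event,
                      row.names = rownames(coh$traits))
    d <- dichotomize_rfs(rec, 1095)
    if (length(unique(d$labels)) == 2) {
      auc <- roc_auc(sc[names(d$labels)], d$labels)$auc
      if (auc > 0.7) hits <- hits + 1
    }
  }
  expect_gte(hits, 8)
})

test_that("combination screening ranks the truly linked pair highly", {
  # spec invariant (scaled down): linked pair in the top 5% of combinations
  coh <- small_cohort(seed = 115, n_genes = 150, n_samples = 200,
                      module_sizes = c(40, 30), relapse_effect = 1.5)
  X <- log_transform(coh$expression)
  Z <- zscore_expression(X)
  rec <- data.frame(time = coh$traits$rfs_days, event = coh$traits$rfs_event,
                    row.names = rownames(coh$traits))
  bg <- setdiff(rownames(X), unlist(lapply(coh$truth, `[[`, "gene_ids")))
  num_pool <- c(coh$truth[[1]]$gene_ids[1:2], bg[1:2])
  den_pool <- bg[3:6]
  comb <- screen_combinations(Z, num_pool, den_pool, rec,
                              horizons = c("3y" = 1095), max_size = 2)
  expect_equal(attr(comb, "n_combinations"),
               (4 + 6) * (4 + 6))
  linked <- grepl(coh$truth[[1]]$gene_ids[1], comb$numerator, fixed = TRUE) &
    grepl(coh$truth[[1]]$gene_ids[2], comb$numerator, fixed = TRUE)
  best_linked <- max(comb$auc_3y[linked], na.rm = TRUE)
  q95 <- quantile(comb$auc_3y, 0.95, na.rm = TRUE)
  expect_gte(best_linked, q95)
})
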