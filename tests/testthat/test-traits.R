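test_that("module-trait correlation computes Student p from rho and n", {
  # closed-form anchors: rho = 0 gives p = 1; the t CDF reproduces the
  # n = 201, rho = 0.34 pairing at the 1e-8 order of magnitude
  r <- 0.34; n <- 201
  tv <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tv), n - 2)
  expect_lt(p, 1e-6)
  expect_gt(p, 1e-9)

  set.seed(71)
  ME <- matrix(rnorm(3 * 60), 3, 60,
               dimnames = list(paste0("M", 1:3), sprintf("s%02d", 1:60)))
  traits <- data.frame(flat = rep(c(0, 1), 30),
                       linked = ME[1, ] * 2 + rnorm(60, 0, 0.5),
                       row.names = colnames(ME))
  mt <- module_trait_correlation(ME, traits, method = "pearson")
  # exact rho = 0 construction: correlate a ME with itself centered out
  y <- ME[2, ] - mean(ME[2, ])
  orthog <- data.frame(o = rnorm(60), row.names = colnames(ME))
  orthog$o <- orthog$o - y * sum(orthog$o * y) / sum(y^2)
  mt0 <- module_trait_correlation(ME, orthog, method = "pearson")
  expect_equal(mt0$rho["M2", "o"], 0, tolerance = 1e-12)
  expect_equal(mt0$p["M2", "o"], 1, tolerance = 1e-10)
  # the linked trait is detected
  expect_lt(mt$p["M1", "linked"], 1e-6)
  expect_gt(mt$rho["M1", "linked"], 0.8)
  expect_equal(unique(as.vector(mt$n_used)), 60L)
})

test_that("binary and sparse traits are handled as declared", {
  set.seed(72)
  ME <- matrix(rnorm(2 * 40), 2, 40,
               dimnames = list(c("M1", "M2"), sprintf("s%02d", 1:40)))
  tr <- data.frame(bin = rep(c("no", "yes"), 20),
                   sparse = c(1, 2, 3, rep(NA, 37)),
                   row.names = colnames(ME))
  expect_warning(mt <- module_trait_correlation(ME, tr), "non-missing")
  expect_true(all(is.na(mt$rho[, "sparse"])))
  expect_false(anyNA(mt$rho[, "bin"]))
  # bicor on a 0/1 trait equals the point-biserial (Pearson) value when the
  # ME side is also MAD-degenerate-free? binary side falls back to centering
  b <- as.numeric(tr$bin == "yes")
  expect_equal(bicor(ME[1, ], b), bicor(ME[1, ], b))
})

test_that("relapse-linked module is detected across seeds", {
  # spec example: relapse_effect = 1.5 -> rho > 0 and p < 0.01 in >= 90%
  hits <- 0
  for (s in 1:20) {
    coh <- small_cohort(seed = 100 + s, n_genes = 120, n_samples = 150,
                        module_sizes = c(50, 30), relapse_effect = 1.5)
    X <- log_transform(coh$expression)
    me <- module_eigengene(X, coh$truth[[1]]$gene_ids)$me
    mt <- module_trait_correlation(
      matrix(me, 1, dimnames = list("M1", names(me))),
      coh$traits[, "relapse", drop = FALSE])
    if (!is.na(mt$p[1, 1]) && mt$p[1, 1] < 0.01 && mt$rho[1, 1] > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("ME dendrogram merge heights reflect eigengene relatedness", {
  set.seed(73)
  z <- rnorm(50)
  ME <- rbind(M1 = z, M2 = z, M3 = rnorm(50))
  colnames(ME) <- sprintf("s%02d", 1:50)
  hc <- me_dendrogram(ME)
  expect_equal(min(hc$height), 0, tolerance = 1e-10)
  # sample permutation invariance
  set.seed(74)
  perm <- sample(50)
  hc2 <- me_dendrogram(ME[, perm])
  expect_equal(hc$height, hc2$height, tolerance = 1e-12)
  expect_identical(hc$merge, hc2$merge)
  # near-orthogonal MEs merge near height 1
  set.seed(75)
  MEo <- matrix(rnorm(4 * 2000), 4, 2000,
                dimnames = list(paste0("M", 1:4), NULL))
  hco <- me_dendrogram(MEo)
  expect_true(all(abs(hco$height - 1) < 0.1))
  # newick serialization carries all leaves
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "M1")
  expect_match(nwk, ";$")
})

test_that("sample clustering recovers two opposite-signed groups", {
  set.seed(76)
  n <- 60
  grp <- rep(c(1, -1), each = n / 2)
  ME <- rbind(M1 = grp * 2 + rnorm(n, 0, 0.5),
              M2 = -grp * 2 + rnorm(n, 0, 0.5))
  colnames(ME) <- sprintf("s%02d", 1:n)
  cl <- cluster_samples_by_me(ME)
  expect_equal(cl$k, 2)
  purity <- max(mean(cl$labels[1:30] == cl$labels[1]),
                mean(cl$labels[1:30] != cl$labels[1]))
  expect_gte(purity, 0.95)
  # relapse-enrichment flag uses the > 0.8 rule
  relapse <- setNames(c(rep(1, 25), rep(0, 5), rep(0, 30)), colnames(ME))
  cl2 <- cluster_samples_by_me(ME, k = 2, relapse = relapse)
  expect_true(any(cl2$relapse_enriched))
  rel3 <- setNames(rep(c(1, 0), n / 2), colnames(ME)) # 50% everywhere
  cl3 <- cluster_samples_by_me(ME, k = 2, relapse = rel3)
  expect_false(any(cl3$relapse_enriched))
  expect_error(cluster_samples_by_me(ME, k = 100), "k > n_samples")
})

test_that("variance partition attributes variance correctly", {
  set.seed(77)
  n <- 80
  sex <- rbinom(n, 1, 0.5)
  # age orthogonalized against sex so the pure-sex unit decomposes exactly
  age <- resid(lm(rnorm(n, 60, 10) ~ sex)) + 60
  pure <- 3 * sex                       # exactly sex-driven
  mixed <- scale(sex)[, 1] + rnorm(n)   # about half sex
  X <- rbind(pure = pure, mixed = mixed)
  colnames(X) <- sprintf("s%02d", 1:n)
  cov <- data.frame(sex = sex, age = age, row.names = colnames(X))
  vp <- variance_partition(X, cov)
  expect_equal(vp$sex[vp$unit_id == "pure"], 1, tolerance = 1e-9)
  expect_equal(vp$residual[vp$unit_id == "pure"], 0, tolerance = 1e-9)
  expect_equal(vp$sex + vp$age + vp$residual, rep(1, 2), tolerance = 1e-6)
  # invariance to covariate scaling
  cov2 <- data.frame(sex = sex * 100, age = age / 7, row.names = colnames(X))
  vp2 <- variance_partition(X, cov2)
  expect_equal(vp$sex, vp2$sex, tolerance = 1e-9)
  expect_equal(vp$age, vp2$age, tolerance = 1e-9)
  # collinear covariates error with the pair named
  cov3 <- data.frame(sex = sex, sex2 = sex * 2, row.names = colnames(X))
  expect_error(variance_partition(X, cov3), "collinear")
})

test_that("confounder variance share stays near the configured cap", {
  # spec invariant: estimated sex+age fraction <= confounder_frac + 0.05
  # for >= 95% of genes
  coh <- small_cohort(seed = 78, n_genes = 150, n_samples = 150,
                      module_sizes = c(40))
  X <- log_transform(coh$expression)
  keep <- apply(X, 1, sd) > 0
  vp <- variance_partition(X[keep, ],
                           coh$traits[, c("sex", "age")])
  frac <- vp$sex + vp$age
  expect_gte(mean(frac <= coh$config$confounder_frac + 0.05), 0.95)
  expect_lte(median(frac), 0.10)
})
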