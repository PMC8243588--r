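test_that("bicor matches its literal-formula oracle and affine equivariance", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(bicor(x, y), oracle_bicor(x, y), tolerance = 1e-12)
  }
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, 3 * x + 2), 1)
  expect_equal(bicor(x, -0.5 * x + 1), -1)
  expect_error(bicor(1:2, 1:2), "3 observations")
  expect_error(bicor(1:5, 1:4), "length")
  expect_error(bicor(rep(1, 5), rep(2, 5)), "constant")
})

test_that("bicor approaches Pearson on outlier-free Gaussian data", {
  # spec invariant: median |bicor - pearson| < 0.05 at n = 100
  set.seed(52)
  diffs <- replicate(200, {
    x <- rnorm(100); y <- rnorm(100)
    abs(bicor(x, y) - cor(x, y))
  })
  expect_lt(median(diffs), 0.05)
})

test_that("bicor_matrix agrees with pairwise bicor", {
  set.seed(53)
  M <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, letters[1:6]))
  C <- bicor_matrix(M)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(C[i, j], bicor(M[, i], M[, j]), tolerance = 1e-12)
  expect_true(isSymmetric(C))
})

test_that("signed adjacency maps correlations as specified", {
  C <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(signed_adjacency(C, 5.5)[1, 2], 1)
  C[1, 2] <- C[2, 1] <- -1
  expect_equal(signed_adjacency(C, 5.5)[1, 2], 0)
  C[1, 2] <- C[2, 1] <- 0
  expect_equal(signed_adjacency(C, 5.5)[1, 2], 0.5^5.5, tolerance = 1e-12)
  # monotone in c over a grid
  cs <- seq(-1, 1, by = 0.05)
  as <- ((1 + cs) / 2)^5.5
  expect_true(all(diff(as) >= 0))
  bad <- matrix(c(1, 0.5, -0.5, 1), 2, 2)
  expect_error(signed_adjacency(bad, 2), "symmetric")
})

test_that("mean connectivity strictly decreases in beta", {
  set.seed(54)
  X <- matrix(rnorm(60 * 80), 80, 60)
  C <- bicor_matrix(X)
  tab <- pick_soft_threshold(C, candidate_betas = c(1, 2, 4, 6, 8))
  expect_true(all(diff(tab$mean_connectivity) < 0))
})

test_that("scale-free fit recognizes a power-law degree sequence", {
  # [DERIVED: simulation] exact power-law connectivities give signed R2 >= 0.9
  set.seed(55)
  k <- sample(1:200, 3000, replace = TRUE, prob = (1:200)^-2)
  fit <- scale_free_fit(k)
  expect_gte(fit$r2, 0.9)
  expect_lt(fit$slope, 0)
  # R2 matches an independent two-pass regression oracle
  kk <- k[k > 0]
  breaks <- seq(min(kk), max(kk), length.out = 11)
  bin <- cut(kk, breaks, include.lowest = TRUE)
  xm <- tapply(kk, bin, mean); fr <- tapply(kk, bin, length) / length(kk)
  ok <- !is.na(xm)
  x <- log10(xm[ok]); y <- log10(fr[ok])
  mx <- mean(x); my <- mean(y)
  slope_o <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  r2_o <- (sum((x - mx) * (y - my)))^2 / (sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(abs(fit$r2), r2_o, tolerance = 1e-10)
  expect_equal(fit$slope, slope_o, tolerance = 1e-10)
})

test_that("TOM matches the triple-loop oracle and closed forms", {
  A3 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(A3)[1, 2], 1)
  expect_equal(tom_similarity(diag(5))[1, 2], 0)
  set.seed(56)
  A <- matrix(runif(25, 0, 0.9), 5, 5)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  expect_equal(tom_similarity(A), oracle_tom(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(tom_similarity(matrix(2, 3, 3)), "outside")
})

test_that("module detection recovers planted blocks and ignores noise", {
  set.seed(57)
  n <- 130
  z1 <- rnorm(100); z2 <- rnorm(100)
  X <- rbind(
    t(sapply(1:50, function(i) sqrt(0.7) * z1 + sqrt(0.3) * rnorm(100))),
    t(sapply(1:50, function(i) sqrt(0.7) * z2 + sqrt(0.3) * rnorm(100))),
    matrix(rnorm(30 * 100), 30, 100))
  rownames(X) <- sprintf("g%03d", 1:n)
  C <- bicor_matrix(t(X)); A <- signed_adjacency(C, 5.5)
  a <- detect_modules(tom_similarity(A), network_config(min_module_size = 20))
  expect_equal(length(unique(a[a > 0])), 2)
  # block purity: each planted block maps to exactly one detected label
  expect_equal(length(unique(a[1:50])), 1)
  expect_equal(length(unique(a[51:100])), 1)
  expect_true(a[1] != a[51])
  # module 1 is the largest by construction of the relabeling
  sizes <- table(a[a > 0])
  expect_equal(names(which.max(sizes)), "1")
  # gene-order permutation invariance
  set.seed(58)
  perm <- sample(n)
  TOMp <- tom_similarity(signed_adjacency(C[perm, perm], 5.5))
  ap <- detect_modules(TOMp, network_config(min_module_size = 20))
  expect_equal(adjusted_rand_index(a[rownames(X)[perm]], ap), 1)
})

test_that("module eigengene follows the declared conventions", {
  set.seed(59)
  g <- rnorm(50)
  X <- rbind(a = g, b = g, c = g)
  colnames(X) <- sprintf("s%02d", 1:50)
  me <- module_eigengene(X, c("a", "b", "c"))
  expect_equal(me$variance_explained, 1, tolerance = 1e-12)
  expect_equal(cor(me$me, as.numeric(scale(g))), 1, tolerance = 1e-10)
  expect_equal(sd(me$me), 1, tolerance = 1e-12)
  # sign convention: mean kME of members is non-negative
  set.seed(60)
  Y <- t(sapply(1:20, function(i) 0.8 * g + rnorm(50, 0, 0.6)))
  rownames(Y) <- sprintf("m%02d", 1:20)
  colnames(Y) <- colnames(X)
  me2 <- module_eigengene(Y, rownames(Y))
  kme <- cor(t(Y), me2$me)
  expect_gte(mean(kme), 0)
})

test_that("kME table matches a brute-force correlation oracle", {
  coh <- small_cohort(seed = 61, n_genes = 120, n_samples = 60,
                      module_sizes = c(40, 30))
  X <- log_transform(coh$expression)
  a <- truth_assignment(coh$truth, rownames(X))
  mes <- module_eigengenes(X, a)
  K <- kme_table(X, mes$eigengenes)
  set.seed(62)
  for (g in sample(rownames(X), 10)) for (m in rownames(mes$eigengenes))
    expect_equal(K[g, m], cor(X[g, ], mes$eigengenes[m, ]), tolerance = 1e-12)
  # a module's own ME injected as pseudo-gene has kME 1 with itself
  Xp <- rbind(X, pseudo = mes$eigengenes["M1", ])
  Kp <- kme_table(Xp, mes$eigengenes)
  expect_equal(Kp["pseudo", "M1"], 1, tolerance = 1e-12)
})

test_that("hub predicate applies the kME >= 0.7 unique-best rule", {
  kme <- rbind(hub = c(M1 = 0.85, M2 = 0.2),
               border = c(M1 = 0.7, M2 = 0.1),
               low = c(M1 = 0.69, M2 = 0.1),
               wrongmax = c(M1 = 0.75, M2 = 0.9))
  a <- c(hub = 1L, border = 1L, low = 1L, wrongmax = 1L)
  h <- is_hub_gene(kme, a)
  expect_true(h[["hub"]])
  expect_true(h[["border"]])   # 0.7 exactly is inclusive
  expect_false(h[["low"]])
  expect_false(h[["wrongmax"]]) # higher kME elsewhere
})

test_that("module merging collapses shared-factor modules and is idempotent", {
  set.seed(63)
  z <- rnorm(80); w <- rnorm(80)
  X <- rbind(
    t(sapply(1:30, function(i) 0.9 * z + rnorm(80, 0, 0.3))),
    t(sapply(1:30, function(i) 0.9 * z + rnorm(80, 0, 0.3))),
    t(sapply(1:30, function(i) 0.9 * w + rnorm(80, 0, 0.3))))
  rownames(X) <- sprintf("g%02d", 1:90)
  colnames(X) <- sprintf("s%02d", 1:80)
  a0 <- setNames(rep(1:3, each = 30), rownames(X))
  m1 <- merge_modules(X, a0, merge_height = 0.25)
  expect_equal(length(unique(m1[m1 > 0])), 2)
  # the two same-factor blocks share a label
  expect_equal(m1[["g01"]], m1[["g31"]])
  expect_true(m1[["g61"]] != m1[["g01"]])
  m2 <- merge_modules(X, m1, merge_height = 0.25)
  expect_identical(m1, m2)
  # orthogonal modules unchanged
  a_orth <- setNames(rep(c(1, 2), each = 30), rownames(X)[c(1:30, 61:90)])
  m3 <- merge_modules(X[c(1:30, 61:90), ], a_orth, merge_height = 0.25)
  expect_equal(length(unique(m3[m3 > 0])), 2)
})

test_that("blockwise decomposition agrees with single-block detection", {
  coh <- small_cohort(seed = 64, n_genes = 260, n_samples = 120,
                      module_sizes = c(60, 50))
  X <- log_transform(coh$expression)
  nm1 <- build_network(X, network_config(beta = 5.5))
  nm2 <- build_network(X, network_config(beta = 5.5, max_block_size = 150))
  tr <- truth_assignment(coh$truth, rownames(X))
  expect_gte(adjusted_rand_index(tr, nm1$assignment), 0.8)
  expect_gte(adjusted_rand_index(tr, nm2$assignment), 0.8)
  expect_gte(adjusted_rand_index(nm1$assignment, nm2$assignment), 0.8)
})

test_that("module color aliases follow the conventional order", {
  expect_identical(module_colors(3), c("turquoise", "blue", "brown"))
  expect_identical(module_colors(13)[13], "salmon")
})
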