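# Synthetic cohort generator with planted co-expression modules, clinical
# traits, relapse and censored survival. Ground truth for every downstream
# stage: module assignments, latent eigengene signals and trait effect sizes
# are returned alongside the data.
#
# Simulation happens on the log2 scale; RPKM values are emitted as
# 2^x - 0.05 floored at 0, so the preprocessing "+0.05 RPKM, log2" transform
# round-trips exactly.

#' Configuration for a synthetic cohort
#'
#' Defaults describe the standard verification cohort: 5,000 genes, 150
#' samples, six planted modules of 50-300 genes on a zero-inflated RPKM
#' scale, a relapse effect of 1.5 log-odds per eigengene SD on the first
#' module and a survival effect on the second, with sex/age confounding
#' capped at 5\% of per-gene variance.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param module_sizes integer vector of planted module sizes; genes not in
#'   any module are independent background noise.
#' @param noise_sd per-gene Gaussian noise SD on the log2 scale.
#' @param zero_inflation probability that a background gene-sample cell is an
#'   exact zero RPKM.
#' @param relapse_effect log-odds of relapse per SD of the first module's
#'   eigengene.
#' @param survival_effect log-hazard per SD of the second module's eigengene
#'   (first module when only one is planted).
#' @param censor_rate probability a sample's survival time is censored.
#' @param confounder_frac fraction (in [0, 0.1]) of per-gene variance
#'   contributed jointly by sex and age.
#' @param loading_range min/max gene loading on the module eigengene signal,
#'   within (0, 1].
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 expression.
#' @param seed integer seed; identical configs and seeds give bitwise
#'   identical cohorts.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_genes = 5000, n_samples = 150,
                          module_sizes = c(300, 250, 150, 100, 75, 50),
                          noise_sd = 0.5, zero_inflation = 0.3,
                          relapse_effect = 1.5, survival_effect = 0.7,
                          censor_rate = 0.25, confounder_frac = 0.05,
                          loading_range = c(0.5, 0.9),
                          baseline_log2_mean = 3, baseline_log2_sd = 1.5,
                          seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_modules = length(module_sizes),
              module_sizes = as.integer(module_sizes),
              noise_sd = noise_sd, zero_inflation = zero_inflation,
              relapse_effect = relapse_effect, survival_effect = survival_effect,
              censor_rate = censor_rate, confounder_frac = confounder_frac,
              loading_range = loading_range,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (sum(cfg$module_sizes) > cfg$n_genes)
    .stopf("cohort_config: module sizes (%d) exceed n_genes (%d)",
           sum(cfg$module_sizes), cfg$n_genes)
  if (cfg$noise_sd <= 0) .stopf("cohort_config: noise_sd must be positive")
  if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1)
    .stopf("cohort_config: zero_inflation must be in [0,1]")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1)
    .stopf("cohort_config: censor_rate must be in [0,1]")
  if (cfg$confounder_frac < 0 || cfg$confounder_frac > 0.1)
    .stopf("cohort_config: confounder_frac must be in [0, 0.1]")
  if (cfg$loading_range[1] <= 0 || cfg$loading_range[2] > 1 ||
      cfg$loading_range[1] > cfg$loading_range[2])
    .stopf("cohort_config: loading_range must be within (0, 1]")
  invisible(cfg)
}

# draw ages: Normal(62, 10) truncated at >= 25
.draw_ages <- function(n) {
  a <- stats::rnorm(n, 62, 10)
  while (any(a < 25)) a[a < 25] <- stats::rnorm(sum(a < 25), 62, 10)
  a
}

#' Generate a synthetic cohort with planted modules and trait effects
#'
#' Module genes are loading * eigen_signal + Gaussian noise on the log2
#' scale, back-transformed to RPKM (2^x - 0.05, floored at 0). Background
#' genes are independent noise with \code{zero_inflation} exact zeros. Relapse
#' is drawn by a logistic link on the first module's eigengene, survival times
#' are exponential with a proportional log-hazard on the second module's
#' eigengene, censored independently at \code{censor_rate}. Sex and age enter
#' every gene with a variance share of \code{confounder_frac}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with elements \code{expression} (gene x sample RPKM matrix,
#'   attribute \code{scale = "rpkm"}), \code{traits} (per-sample data frame:
#'   sex, age, Binet stage, relapse flag and interval, survival days, vital
#'   status), and \code{truth} (list of planted-module descriptions:
#'   module_id, gene_ids, eigen_signal, loadings, loading_range, trait_links).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  set.seed(cfg$seed)
  ng <- cfg$n_genes; ns <- cfg$n_samples
  gene_ids <- sprintf("G%05d", seq_len(ng))
  sample_ids <- sprintf("S%04d", seq_len(ns))

  # confounders drawn first so the latent signals can be decorrelated from
  # them: confounder_frac must CAP the sex/age variance share, so chance
  # in-sample correlation between eigengenes and confounders is removed
  sex <- stats::rbinom(ns, 1, 0.57)
  age <- .draw_ages(ns)
  sex_z <- as.numeric(scale(sex)); age_z <- as.numeric(scale(age))

  # latent module eigengene signals: unit variance, orthogonal to sex/age
  Z <- matrix(stats::rnorm(cfg$n_modules * ns), cfg$n_modules, ns)
  Z <- t(apply(Z, 1, function(z)
    as.numeric(scale(stats::lm.fit(cbind(1, sex_z, age_z), z)$residuals))))

  assignment <- integer(ng)
  idx <- 1L
  for (m in seq_len(cfg$n_modules)) {
    assignment[idx:(idx + cfg$module_sizes[m] - 1L)] <- m
    idx <- idx + cfg$module_sizes[m]
  }

  mu <- stats::rnorm(ng, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  loadings <- stats::runif(ng, cfg$loading_range[1], cfg$loading_range[2])

  X <- matrix(stats::rnorm(ng * ns, 0, cfg$noise_sd), ng, ns)
  for (m in seq_len(cfg$n_modules)) {
    rows <- which(assignment == m)
    X[rows, ] <- X[rows, ] + loadings[rows] %o% Z[m, ]
  }
  X <- X + mu

  # sex and age jointly contribute confounder_frac of per-gene variance
  signal_var <- ifelse(assignment > 0, loadings^2 + cfg$noise_sd^2,
                       cfg$noise_sd^2)
  if (cfg$confounder_frac > 0) {
    c2 <- cfg$confounder_frac * signal_var / (1 - cfg$confounder_frac)
    coef_sex <- sqrt(c2 / 2) * sample(c(-1, 1), ng, replace = TRUE)
    coef_age <- sqrt(c2 / 2) * sample(c(-1, 1), ng, replace = TRUE)
    X <- X + coef_sex %o% sex_z + coef_age %o% age_z
  }

  # RPKM back-transform: round-trips the "+0.05 RPKM, log2" preprocessing
  R <- pmax(2^X - 0.05, 0)
  bg <- which(assignment == 0L)
  if (length(bg) > 0 && cfg$zero_inflation > 0) {
    mask <- matrix(stats::rbinom(length(bg) * ns, 1, cfg$zero_inflation) == 1,
                   length(bg), ns)
    R[bg, ][mask] <- 0
  }
  dimnames(R) <- list(gene_ids, sample_ids)
  attr(R, "scale") <- "rpkm"

  # clinical traits -----------------------------------------------------
  relapse_mod <- 1L
  surv_mod <- if (cfg$n_modules >= 2) 2L else 1L
  z_rel <- Z[relapse_mod, ]
  z_srv <- Z[surv_mod, ]

  binet <- sample(c("A", "B"), ns, replace = TRUE, prob = c(179, 15) / 194)
  p_rel <- stats::plogis(stats::qlogis(0.45) + cfg$relapse_effect * z_rel)
  relapse <- stats::rbinom(ns, 1, p_rel)

  # overall survival: exponential baseline (median ~2000 days), independent
  # censoring at censor_rate (censor time uniform before the event)
  lambda <- log(2) / 2000 * exp(cfg$survival_effect * z_srv)
  t_event <- stats::rexp(ns, rate = lambda)
  censored <- stats::rbinom(ns, 1, cfg$censor_rate) == 1
  surv_days <- ifelse(censored, stats::runif(ns, 0, t_event), t_event)
  vital_status <- as.integer(!censored)

  # relapse interval (days): shorter for samples high on the linked module
  lambda_r <- log(2) / 600 * exp(0.5 * cfg$relapse_effect * z_rel)
  t_rel <- stats::rexp(ns, rate = lambda_r)
  relapse_interval <- ifelse(relapse == 1, round(t_rel), NA_real_)
  # relapse-free-survival encoding: relapsers observe the interval, others
  # are followed event-free to their observed survival time
  rfs_time <- ifelse(relapse == 1, round(t_rel), round(surv_days))
  rfs_event <- relapse

  traits <- data.frame(
    sample_id = sample_ids,
    sex = sex,
    age = round(age, 1),
    binet_stage = binet,
    relapse = relapse,
    relapse_interval_days = relapse_interval,
    rfs_days = rfs_time,
    rfs_event = rfs_event,
    survival_days = round(surv_days),
    vital_status = vital_status,
    stringsAsFactors = FALSE
  )
  rownames(traits) <- sample_ids

  truth <- lapply(seq_len(cfg$n_modules), function(m) {
    links <- list()
    if (m == relapse_mod) links$relapse <- cfg$relapse_effect
    if (m == surv_mod) links$survival <- cfg$survival_effect
    list(module_id = m,
         gene_ids = gene_ids[assignment == m],
         eigen_signal = stats::setNames(Z[m, ], sample_ids),
         loadings = stats::setNames(loadings[assignment == m],
                                    gene_ids[assignment == m]),
         loading_range = cfg$loading_range,
         trait_links = links)
  })

  list(expression = R, traits = traits, truth = truth, config = cfg)
}

#' Truth assignment vector from a planted-module description
#'
#' @param truth the \code{truth} element of \code{\link{generate_cohort}}.
#' @param gene_ids all gene identifiers of the cohort.
#' @return named integer vector; 0 for background genes.
#' @export
truth_assignment <- function(truth, gene_ids) {
  a <- stats::setNames(integer(length(gene_ids)), gene_ids)
  for (m in truth) a[m$gene_ids] <- m$module_id
  a
}

#' Generate a validation cohort that regenerates (or scrambles) planted modules
#'
#' Draws a fresh set of samples in which selected reference modules keep
#' their gene loadings (so density and connectivity structure recur) while
#' modules listed in \code{scramble} are replaced by independent noise,
#' emulating a second cohort in which only part of the network replicates.
#'
#' @param truth planted-module truth from \code{\link{generate_cohort}}.
#' @param gene_ids gene identifiers of the reference cohort (all of them are
#'   re-emitted so the gene universe is shared).
#' @param n_samples validation cohort size.
#' @param scramble integer module ids whose co-expression is destroyed.
#' @param noise_sd,zero_inflation,baseline_log2_mean,baseline_log2_sd as in
#'   \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @return gene x sample RPKM matrix (attribute \code{scale = "rpkm"}).
#' @export
generate_validation_cohort <- function(truth, gene_ids, n_samples = 93,
                                       scramble = integer(0),
                                       noise_sd = 0.5, zero_inflation = 0.3,
                                       baseline_log2_mean = 3,
                                       baseline_log2_sd = 1.5, seed = 1) {
  set.seed(as.integer(seed))
  ng <- length(gene_ids); ns <- as.integer(n_samples)
  sample_ids <- sprintf("V%04d", seq_len(ns))
  mu <- stats::rnorm(ng, baseline_log2_mean, baseline_log2_sd)
  X <- matrix(stats::rnorm(ng * ns, 0, noise_sd), ng, ns,
              dimnames = list(gene_ids, sample_ids))
  module_gene <- character(0)
  for (m in truth) {
    if (m$module_id %in% scramble) next
    z <- as.numeric(scale(stats::rnorm(ns)))
    rows <- match(m$gene_ids, gene_ids)
    X[rows, ] <- X[rows, ] + as.numeric(m$loadings) %o% z
    module_gene <- c(module_gene, m$gene_ids)
  }
  X <- X + mu
  R <- pmax(2^X - 0.05, 0)
  bg <- setdiff(gene_ids, unlist(lapply(truth, `[[`, "gene_ids")))
  if (length(bg) > 0 && zero_inflation > 0) {
    rows <- match(bg, gene_ids)
    mask <- matrix(stats::rbinom(length(rows) * ns, 1, zero_inflation) == 1,
                   length(rows), ns)
    R[rows, ][mask] <- 0
  }
  attr(R, "scale") <- "rpkm"
  R
}

#' Write a synthetic cohort to disk
#'
#' Expression as gene x sample TSV (first column \code{gene_id}), traits as a
#' sample x trait TSV, and the planted truth as JSON.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_expr <- file.path(dir, "expression.tsv")
  p_traits <- file.path(dir, "traits.tsv")
  p_truth <- file.path(dir, "truth.json")
  write_expression(cohort$expression, p_expr)
  utils::write.table(cohort$traits, p_traits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_json <- lapply(cohort$truth, function(m)
    list(module_id = m$module_id, gene_ids = m$gene_ids,
         eigen_signal = unname(m$eigen_signal),
         loadings = unname(m$loadings),
         loading_range = m$loading_range, trait_links = m$trait_links))
  jsonlite::write_json(truth_json, p_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(expression = p_expr, traits = p_traits, truth = p_truth))
}
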