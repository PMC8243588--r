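# End-to-end orchestration: preprocess -> network -> traits -> diffexp ->
# enrichment -> [preservation] -> prognostics, with per-stage derived seeds,
# write-once outputs and a reproducibility manifest.

#' Pipeline configuration
#'
#' Validates paths eagerly; the seed is mandatory and all stage-level
#' randomness is derived from it via stage-name-hashed sub-seeds, so stages
#' are independently reproducible.
#'
#' @param expr path to the gene x sample RPKM TSV.
#' @param traits path to the sample x trait TSV.
#' @param outdir output directory (must not contain a previous manifest).
#' @param gmt optional GMT gene-set collection for enrichment.
#' @param test_expr optional second-cohort expression TSV for preservation.
#' @param seed mandatory integer master seed.
#' @param preprocessing,network,traits_params,diffexp,enrichment,preservation,prognostics
#'   per-stage parameter lists merged over defaults.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(expr, traits, outdir, gmt = NULL, test_expr = NULL,
                            seed, preprocessing = list(), network = list(),
                            traits_params = list(), diffexp = list(),
                            enrichment = list(), preservation = list(),
                            prognostics = list()) {
  if (missing(seed)) .stopf("pipeline_config: seed is mandatory")
  for (p in c(expr, traits, gmt, test_expr))
    if (!is.null(p) && !file.exists(p)) .stopf("pipeline_config: missing file '%s'", p)
  cfg <- list(
    expr = expr, traits = traits, outdir = outdir, gmt = gmt,
    test_expr = test_expr, seed = as.integer(seed),
    preprocessing = utils::modifyList(
      list(max_zero_fraction = 0.5, offset = 0.05, z_threshold = 3), preprocessing),
    network = utils::modifyList(as.list(unclass(network_config())), network),
    traits_params = utils::modifyList(
      list(method = "bicor", trait_cols = NULL, relapse_col = "relapse"),
      traits_params),
    diffexp = utils::modifyList(
      list(stage_col = "binet_stage", relapse_col = "relapse",
           focal_pair = c("A_relapse", "A_norelapse")), diffexp),
    enrichment = utils::modifyList(list(), enrichment),
    preservation = utils::modifyList(list(n_perm = 100), preservation),
    prognostics = utils::modifyList(
      list(horizons = rfs_horizons(), max_pool = 5, max_size = 3,
           time_col = "rfs_days", event_col = "rfs_event",
           surv_time_col = "survival_days", surv_event_col = "vital_status"),
      prognostics))
  class(cfg) <- "pipeline_config"
  cfg
}

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages run in order; each stage's outputs are written before the next
#' starts and a failure aborts with a partial manifest on disk. Deterministic
#' given the config seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the run manifest (also written to \code{manifest.json}):
#'   config hash, per-stage output checksums and wall-clock seconds,
#'   package version, warnings.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("coexpnet")),
    seed = cfg$seed, stages = list(), warnings = character(0))
  warn_log <- character(0)
  outputs <- character(0)
  manifest_path <- file.path(cfg$outdir, "manifest.json")

  cfg_json <- file.path(cfg$outdir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest$config_hash <- unname(tools::md5sum(cfg_json))

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                             digits = NA)
        .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        warn_log <<- c(warn_log, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = as.list(tools::md5sum(res$files)))
    outputs <<- c(outputs, res$files)
    res$value
  }

  X0 <- read_expression(cfg$expr)
  traits <- read_traits(cfg$traits)
  check_sample_alignment(X0, traits)

  # ---- preprocess ------------------------------------------------------
  pre <- run_stage("preprocess", function() {
    pr <- preprocess(X0, cfg$preprocessing$max_zero_fraction,
                     cfg$preprocessing$offset, cfg$preprocessing$z_threshold)
    d <- file.path(cfg$outdir, "01_preprocess"); dir.create(d, showWarnings = FALSE)
    f1 <- write_expression(pr$expr, file.path(d, "cleaned.tsv"))
    rep <- pr$report
    rep$pca$scores <- NULL
    f2 <- file.path(d, "cleaning_report.json")
    jsonlite::write_json(list(
      genes_in = rep$genes_in, genes_kept = rep$genes_kept,
      offset = rep$offset, iterations = rep$iterations,
      samples_removed = rep$samples_removed,
      pca_var_frac = pr$report$pca$var_frac), f2, auto_unbox = TRUE, digits = NA)
    f3 <- .write_tsv(data.frame(sample_id = rownames(pr$report$pca$scores),
                                pr$report$pca$scores),
                     file.path(d, "pca_scores.tsv"))
    list(value = pr, files = c(f1, f2, f3))
  })
  X <- pre$expr
  traits <- traits[colnames(X), , drop = FALSE]

  # ---- network ---------------------------------------------------------
  net <- run_stage("network", function() {
    ncfg <- do.call(network_config,
                    cfg$network[names(cfg$network) != "network_type"])
    nm <- build_network(X, ncfg)
    d <- file.path(cfg$outdir, "02_network"); dir.create(d, showWarnings = FALSE)
    labels <- sort(unique(nm$assignment[nm$assignment > 0]))
    alias <- stats::setNames(module_colors(length(labels)), labels)
    f1 <- .write_tsv(data.frame(
      gene_id = names(nm$assignment), module_label = unname(nm$assignment),
      module_color_alias = ifelse(nm$assignment > 0,
                                  alias[as.character(nm$assignment)], "grey")),
      file.path(d, "assignment.tsv"))
    f2 <- .write_tsv(data.frame(module = rownames(nm$eigengenes),
                                nm$eigengenes, check.names = FALSE),
                     file.path(d, "eigengenes.tsv"))
    f3 <- .write_tsv(data.frame(gene_id = rownames(nm$kme), nm$kme,
                                check.names = FALSE),
                     file.path(d, "kme.tsv"))
    # advisory soft-threshold scan on a seeded gene subsample
    set.seed(.stage_seed(cfg$seed, "network"))
    sub <- sample(nrow(X), min(1500, nrow(X)))
    Csub <- if (ncfg$cor_method == "bicor") bicor_matrix(t(X[sub, ])) else
      suppressWarnings(stats::cor(t(X[sub, ])))
    Csub[is.na(Csub)] <- 0
    sft <- pick_soft_threshold(Csub)
    f4 <- .write_tsv(sft, file.path(d, "soft_threshold.tsv"))
    list(value = nm, files = c(f1, f2, f3, f4))
  })

  # ---- trait statistics ------------------------------------------------
  trt <- run_stage("traits", function() {
    tcols <- cfg$traits_params$trait_cols
    tdf <- if (is.null(tcols)) traits[, setdiff(colnames(traits), "sample_id"),
                                      drop = FALSE]
      else traits[, tcols, drop = FALSE]
    mt <- module_trait_correlation(net$eigengenes, tdf,
                                   method = cfg$traits_params$method)
    d <- file.path(cfg$outdir, "03_traits"); dir.create(d, showWarnings = FALSE)
    f1 <- .write_tsv(data.frame(module = rownames(mt$rho), mt$rho,
                                check.names = FALSE), file.path(d, "rho.tsv"))
    f2 <- .write_tsv(data.frame(module = rownames(mt$p), mt$p,
                                check.names = FALSE), file.path(d, "p.tsv"))
    files <- c(f1, f2)
    if (nrow(net$eigengenes) >= 2) {
      nwk <- dendrogram_newick(me_dendrogram(net$eigengenes))
      f3 <- file.path(d, "me_dendrogram.nwk"); writeLines(nwk, f3)
      files <- c(files, f3)
    }
    rel <- cfg$traits_params$relapse_col
    relv <- if (rel %in% colnames(traits))
      stats::setNames(as.numeric(traits[[rel]]), rownames(traits)) else NULL
    cl <- cluster_samples_by_me(net$eigengenes, relapse = relv)
    f4 <- .write_tsv(data.frame(sample_id = names(cl$labels),
                                cluster = unname(cl$labels)),
                     file.path(d, "sample_clusters.tsv"))
    files <- c(files, f4)
    covs <- intersect(c("sex", "age"), colnames(traits))
    vp <- NULL
    if (length(covs) >= 1) {
      vp <- variance_partition(net$eigengenes, traits[, covs, drop = FALSE])
      f5 <- .write_tsv(vp, file.path(d, "variance_partition.tsv"))
      files <- c(files, f5)
    }
    list(value = list(mt = mt, clusters = cl, vp = vp), files = files)
  })

  # ---- differential expression ----------------------------------------
  de <- run_stage("diffexp", function() {
    tab <- diffexp_table(X, traits, net$assignment,
                         stage_col = cfg$diffexp$stage_col,
                         relapse_col = cfg$diffexp$relapse_col,
                         focal_pair = cfg$diffexp$focal_pair)
    d <- file.path(cfg$outdir, "04_diffexp"); dir.create(d, showWarnings = FALSE)
    f1 <- .write_tsv(tab, file.path(d, "diffexp.tsv"))
    f2 <- .write_tsv(volcano_table(tab), file.path(d, "volcano.tsv"))
    bio <- select_biomarkers(tab, net$kme)
    f3 <- .write_tsv(bio, file.path(d, "biomarkers.tsv"))
    list(value = list(tab = tab, biomarkers = bio), files = c(f1, f2, f3))
  })

  # ---- enrichment (optional) ------------------------------------------
  if (!is.null(cfg$gmt)) {
    run_stage("enrich", function() {
      sets <- read_gmt(cfg$gmt)
      d <- file.path(cfg$outdir, "05_enrich"); dir.create(d, showWarnings = FALSE)
      files <- character(0)
      for (m in sort(unique(net$assignment[net$assignment > 0]))) {
        q <- intersect(names(net$assignment)[net$assignment == m], rownames(X))
        er <- fisher_enrichment(q, sets, rownames(X))
        f <- .write_tsv(er, file.path(d, sprintf("enrichment_M%d.tsv", m)))
        files <- c(files, f)
      }
      list(value = NULL, files = files)
    })
  }

  # ---- preservation (optional second cohort) ---------------------------
  if (!is.null(cfg$test_expr)) {
    run_stage("preserve", function() {
      Xt0 <- read_expression(cfg$test_expr)
      prt <- preprocess(Xt0, cfg$preprocessing$max_zero_fraction,
                        cfg$preprocessing$offset, cfg$preprocessing$z_threshold)
      pres <- preservation_stats(X, prt$expr, net$assignment,
                                 n_perm = cfg$preservation$n_perm,
                                 seed = .stage_seed(cfg$seed, "preserve"),
                                 beta = cfg$network$beta)
      d <- file.path(cfg$outdir, "06_preserve"); dir.create(d, showWarnings = FALSE)
      f1 <- .write_tsv(as.data.frame(pres), file.path(d, "preservation.tsv"))
      f2 <- file.path(d, "preservation.json")
      jsonlite::write_json(as.data.frame(pres), f2, auto_unbox = TRUE, digits = NA)
      list(value = pres, files = c(f1, f2))
    })
  }

  # ---- prognostics -----------------------------------------------------
  run_stage("prognose", function() {
    pg <- cfg$prognostics
    d <- file.path(cfg$outdir, "07_prognostics"); dir.create(d, showWarnings = FALSE)
    files <- character(0)
    rfs <- data.frame(time = traits[[pg$time_col]],
                      event = as.numeric(traits[[pg$event_col]]),
                      row.names = rownames(traits))
    bio <- de$biomarkers
    # fall back to top-|lfc| significant genes when the hub gate is empty
    cand <- if (nrow(bio) > 0) bio else {
      tt <- de$tab[!is.na(de$tab$tukey_p) & de$tab$tukey_p < 0.05, ]
      tt <- tt[order(-abs(tt$lfc)), ]
      utils::head(data.frame(gene = tt$gene, lfc = tt$lfc), 10)
    }
    rel <- stats::setNames(as.numeric(traits[[cfg$diffexp$relapse_col]]),
                           rownames(traits))
    roc_rows <- lapply(cand$gene, function(g) {
      r <- roc_auc(X[g, names(rel)], rel, marker_name = g)
      data.frame(gene = g, auc = r$auc, z = r$z, p = r$p,
                 module = unname(net$assignment[g]))
    })
    if (length(roc_rows) > 0)
      files <- c(files, .write_tsv(do.call(rbind, roc_rows),
                                   file.path(d, "roc.tsv")))
    # combination screening: up- vs down-regulated candidates
    up <- cand$gene[cand$lfc > 0]
    dn <- cand$gene[cand$lfc < 0]
    up <- utils::head(up, pg$max_pool); dn <- utils::head(dn, pg$max_pool)
    if (length(up) >= 1 && length(dn) >= 1) {
      Zm <- zscore_expression(X)
      comb <- screen_combinations(Zm, up, dn, rfs, horizons = pg$horizons,
                                  max_size = pg$max_size)
      files <- c(files, .write_tsv(comb, file.path(d, "combination_auc.tsv")))
    }
    # KM / cutpoints for the candidates on overall survival
    os <- data.frame(time = traits[[pg$surv_time_col]],
                     event = as.numeric(traits[[pg$surv_event_col]]),
                     row.names = rownames(traits))
    cp_rows <- lapply(utils::head(cand$gene, 10), function(g) {
      cp <- optimal_cutpoint(stats::setNames(X[g, rownames(os)], rownames(os)), os)
      if (cp$status != "ok")
        return(data.frame(gene = g, cutpoint = NA, chi2 = NA, p = NA, hr = NA))
      data.frame(gene = g, cutpoint = cp$cutpoint, chi2 = cp$logrank$chi2,
                 p = cp$logrank$p, hr = cp$logrank$hr)
    })
    if (length(cp_rows) > 0)
      files <- c(files, .write_tsv(do.call(rbind, cp_rows),
                                   file.path(d, "cutpoints.tsv")))
    files <- c(files, .write_tsv(km_curve(os$time, os$event),
                                 file.path(d, "km_overall.tsv")))
    list(value = NULL, files = files)
  })

  manifest$warnings <- warn_log
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
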