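#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable threshold at its
#' default: univariate screen at p < 0.05 with a 30-day follow-up
#' exclusion, replication in >= 2 cohorts, consensus clustering with 500
#' resamples of 80% of samples over k = 2..10, k = 3 subtypes, ssGSEA
#' exponent alpha = 0.25, and the co-expression block (beta = 10, minimum
#' module size 60, deep split 4, merge height 0.25, kME > 0.85). A
#' `simulation` block generates three synthetic cohorts (one discovery,
#' two validation) at the generator defaults.
#'
#' @param seed Global seed; expanded into per-stage seeds.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    alpha = 0.25,
    normalize = FALSE,
    p_thresh = 0.05,
    min_days = 30,
    min_cohorts = 2,
    k = 3,
    k_range = c(2, 10),
    n_resamples = 500,
    frac = 0.8,
    igp_metric = "pearson",
    validation_mode = "projection",
    simulation = list(n_cohorts = 3, n_genes = 2000, n_samples = 150, K = 3,
                      n_signatures = 17, genes_per_signature = 20,
                      effect_size = 1.0, noise_sd = 1.0, censor_rate = 0.3),
    coexpression = list(enabled = TRUE, beta = 10, signed = FALSE,
                        mad_top_prop = 0.5, min_size = 60, deep_split = 4,
                        merge_height = 0.25, kme_thresh = 0.85,
                        cox_p_thresh = 0.05)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps its default.
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1)
  modifyList(cfg, user)
}

# deterministic per-stage seed expansion from the global seed; stays below
# 2^31 so it is always a valid R integer seed
stage_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647L)
}

#' Run the full subtype-discovery pipeline
#'
#' Executes: expression filter -> log transform -> ssGSEA scoring ->
#' per-cohort Cox screening -> cross-cohort overlap -> consensus clustering
#' of the discovery cohort -> prognosis-ordered labels -> nearest-centroid
#' projection, IGP, and centroid matching on each validation cohort ->
#' survival/TMB/mutation/score characterization -> co-expression modules.
#' All stage outputs are written as TSV into `out_dir` along with a
#' `manifest.json` recording the configuration, per-stage seeds, and md5
#' hashes of every output; identical configurations reproduce identical
#' files. On a stage failure the error names the stage, partial outputs
#' are kept, and an `INCOMPLETE` marker file is written.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.create(file.path(out_dir, "INCOMPLETE"))
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- load or simulate cohorts ------------------------------------------
  cohorts <- stage("load", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      scfg <- simulation_config(
        n_genes = sim$n_genes %||% 2000, n_samples = sim$n_samples %||% 150,
        K = sim$K %||% 3, n_signatures = sim$n_signatures %||% 17,
        genes_per_signature = sim$genes_per_signature %||% 20,
        effect_size = sim$effect_size %||% 1.0,
        noise_sd = sim$noise_sd %||% 1.0,
        censor_rate = sim$censor_rate %||% 0.3,
        seed = stage_seed(config$seed, 1))
      n_coh <- sim$n_cohorts %||% 3
      out <- lapply(seq_len(n_coh), function(i) {
        co <- simulate_cohort(scfg, sample_seed = stage_seed(config$seed, 1 + i),
                              prefix = paste0("C", LETTERS[i]))
        list(id = paste0("cohort", i), expression = co$expression,
             survival = co$survival, mutations = co$mutations,
             truth = co$truth, sets = co$signature_sets)
      })
      out
    } else {
      if (is.null(config$cohorts) || length(config$cohorts) < 1)
        stop("config needs a 'simulation' or a 'cohorts' block")
      sets <- read_gene_sets(config$gene_sets)
      lapply(config$cohorts, function(cc) {
        if (is.null(cc$survival))
          stop("cohort '", cc$id, "' has no survival table")
        list(id = cc$id,
             expression = read_expression(cc$expression),
             survival = read_survival(cc$survival),
             mutations = if (!is.null(cc$mutations)) read_mutations(cc$mutations),
             truth = NULL, sets = sets)
      })
    }
  })
  names(cohorts) <- vapply(cohorts, `[[`, "", "id")

  ## -- filter, transform, score ------------------------------------------
  scores <- stage("score", lapply(cohorts, function(co) {
    x <- filter_expressed_genes(co$expression, min_prop = 0.5)
    x <- log_transform(x)
    ssgsea_scores(x, co$sets, alpha = config$alpha,
                  normalize = isTRUE(config$normalize))
  }))
  for (id in names(scores)) tsv(
    data.frame(signature = rownames(scores[[id]]), scores[[id]],
               check.names = FALSE), paste0("scores_", id, ".tsv"))

  ## -- per-cohort screen and overlap -------------------------------------
  reports <- stage("screen", lapply(names(cohorts), function(id) {
    r <- screen_cohort(scores[[id]], cohorts[[id]]$survival,
                       p_thresh = config$p_thresh, min_days = config$min_days,
                       cohort_id = id)
    tsv(r$results, paste0("screen_", id, ".tsv"))
    r
  }))
  selected <- stage("overlap", {
    sel <- if (length(reports) >= 2)
      overlap_filter(reports, min_cohorts = config$min_cohorts)
    else reports[[1]]$selected
    if (length(sel) < 2)
      stop("fewer than 2 signatures replicate across cohorts")
    tsv(data.frame(signature = sel), "selected_signatures.tsv")
    sel
  })
  res$selected <- selected

  ## -- consensus clustering of the discovery cohort ----------------------
  disc <- names(cohorts)[1]
  cons <- stage("consensus", consensus_run(
    scores[[disc]][selected, , drop = FALSE],
    k_range = seq(config$k_range[1], config$k_range[2]),
    n_resamples = config$n_resamples, frac = config$frac,
    seed = stage_seed(config$seed, 20)))
  tsv(data.frame(k = cons$k_range, A = unname(cons$A),
                 delta = unname(cons$delta),
                 suggested = cons$k_range == suggest_k(cons)),
      "consensus_metrics.tsv")
  res$consensus <- cons

  assign_disc <- stage("labels", {
    a <- final_labels(cons, config$k)
    a <- order_by_prognosis(a, cohorts[[disc]]$survival)
    tsv(data.frame(sample_id = names(a), subtype = a),
        paste0("assignment_", disc, ".tsv"))
    a
  })
  res$assignment <- assign_disc

  ## -- validation cohorts: projection, IGP, centroid match ---------------
  centroids <- subtype_centroids(scores[[disc]][selected, , drop = FALSE],
                                 assign_disc)
  res$validation <- stage("validate", lapply(
    setdiff(names(cohorts), disc), function(id) {
      sv <- scores[[id]][selected, , drop = FALSE]
      proj <- project_nearest_centroid(sv, centroids)
      tsv(data.frame(sample_id = names(proj), subtype = proj),
          paste0("assignment_", id, ".tsv"))
      ig <- igp(sv, proj, metric = config$igp_metric)
      tsv(ig, paste0("igp_", id, ".tsv"))
      cen_v <- subtype_centroids(sv, proj)
      cm <- centroid_correlation(centroids, cen_v)
      tsv(cm$matching, paste0("centroid_match_", id, ".tsv"))
      list(id = id, projection = proj, igp = ig, matching = cm$matching)
    }))

  ## -- characterization ---------------------------------------------------
  res$characterize <- stage("characterize", {
    km <- km_logrank(cohorts[[disc]]$survival, assign_disc,
                     min_days = config$min_days)
    tsv(km$curves, paste0("km_curves_", disc, ".tsv"))
    out <- list(km = km)
    if (!is.null(cohorts[[disc]]$mutations) &&
        nrow(cohorts[[disc]]$mutations) > 0) {
      tm <- tmb(cohorts[[disc]]$mutations, names(assign_disc))
      tsv(data.frame(sample_id = names(tm), tmb = unname(tm),
                     subtype = assign_disc[names(tm)]),
          paste0("tmb_", disc, ".tsv"))
      ms <- mutation_frequency_test(cohorts[[disc]]$mutations, assign_disc)
      tsv(ms, paste0("mutation_screen_", disc, ".tsv"))
      out$tmb <- tm
      out$mutation_screen <- ms
    }
    cmp <- compare_across_subtypes(scores[[disc]], selected, assign_disc)
    tsv(cmp, "signature_comparison.tsv")
    out$score_comparison <- cmp
    out
  })

  ## -- co-expression modules ----------------------------------------------
  cx <- config$coexpression
  if (isTRUE(cx$enabled)) {
    res$coexpression <- stage("coexpress", {
      x <- log_transform(filter_expressed_genes(cohorts[[disc]]$expression))
      xf <- mad_filter(x, top_prop = cx$mad_top_prop %||% 0.5)
      net <- build_network(xf, beta = cx$beta %||% 10,
                           signed = isTRUE(cx$signed))
      mods <- detect_modules(net, xf, min_size = cx$min_size %||% 60,
                             deep_split = cx$deep_split %||% 4,
                             merge_height = cx$merge_height %||% 0.25)
      tsv(data.frame(gene = names(mods$modules), module = mods$modules),
          "modules.tsv")
      out <- list(modules = mods)
      if (nrow(mods$eigengenes) > 0) {
        mt <- module_trait_correlation(mods, assign_disc)
        tsv(mt, "module_trait.tsv")
        biggest <- names(sort(table(mods$modules[mods$modules != "grey"]),
                              decreasing = TRUE))[1]
        hb <- hub_genes(xf, mods, biggest, cohorts[[disc]]$survival,
                        kme_thresh = cx$kme_thresh %||% 0.85,
                        p_thresh = cx$cox_p_thresh %||% 0.05)
        tsv(hb, "hub_genes.tsv")
        out$trait <- mt
        out$hubs <- hb
      }
      out
    })
  }

  ## -- manifest ------------------------------------------------------------
  files <- setdiff(list.files(out_dir), c("manifest.json", "INCOMPLETE"))
  manifest <- list(
    config = config,
    stage_seeds = list(structure = stage_seed(config$seed, 1),
                       consensus = stage_seed(config$seed, 20)),
    decisions = list(alpha = config$alpha,
                     normalize = isTRUE(config$normalize),
                     k = config$k, igp_metric = config$igp_metric,
                     validation_mode = config$validation_mode),
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(files)))))
  names(manifest$outputs) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.remove(file.path(out_dir, "INCOMPLETE"))
  invisible(res)
}
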