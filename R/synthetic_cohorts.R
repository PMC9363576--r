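#' Configuration for a synthetic multi-cohort simulation
#'
#' Defines the planted structure of a synthetic tumor cohort: K latent
#' subtypes leaving subtype-specific mean shifts on disjoint signature gene
#' sets over a log-normal expression background, exponential disease-free
#' survival with subtype-dependent hazards and independent censoring, and
#' subtype-dependent mutation counts.
#'
#' Defaults mirror a mid-sized discovery cohort: 2,000 genes, 150 samples,
#' K = 3 subtypes of equal prevalence, 17 signatures of 20 genes each with a
#' one-log2-unit shift in their "up" subtype over unit log-normal noise, a
#' baseline hazard of 1/1000 per day with hazard ratio 2.5 between the worst
#' and best subtype, 30% censoring, and mean nonsilent mutation counts of
#' (8, 8, 30) so the best-prognosis subtype is hypermutated.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param K Number of planted subtypes.
#' @param n_signatures Number of signature gene sets.
#' @param genes_per_signature Genes per signature (signatures are disjoint).
#' @param effect_size Mean log2 shift of signature genes in their "up"
#'   subtype.
#' @param noise_sd Standard deviation of the log2 expression noise.
#' @param prevalences Subtype prevalences (length K, sums to 1).
#' @param hazard_scale Baseline event rate per day.
#' @param subtype_log_hr Per-subtype log hazard ratio (length K).
#' @param censor_rate Target overall censoring fraction, in \[0, 1).
#' @param tmb_means Mean nonsilent mutation count per subtype (length K).
#' @param seed Integer seed for the planted structure and, by default, the
#'   sample draws.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_samples = 150, K = 3,
                              n_signatures = 17, genes_per_signature = 20,
                              effect_size = 1.0, noise_sd = 1.0,
                              prevalences = rep(1 / K, K),
                              hazard_scale = 1 / 1000,
                              subtype_log_hr = seq(log(2.5), 0, length.out = K),
                              censor_rate = 0.3,
                              tmb_means = c(rep(8, K - 1), 30),
                              seed = 1) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples, K = K,
              n_signatures = n_signatures,
              genes_per_signature = genes_per_signature,
              effect_size = effect_size, noise_sd = noise_sd,
              prevalences = prevalences, hazard_scale = hazard_scale,
              subtype_log_hr = subtype_log_hr, censor_rate = censor_rate,
              tmb_means = tmb_means, seed = seed)
  if (n_genes < n_signatures * genes_per_signature)
    stop("n_genes must cover the signature genes")
  if (K > n_signatures) stop("need at least one signature per subtype")
  if (abs(sum(prevalences) - 1) > 1e-8) stop("prevalences must sum to 1")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  if (length(subtype_log_hr) != K || length(tmb_means) != K ||
      length(prevalences) != K)
    stop("subtype_log_hr, tmb_means, prevalences must have length K")
  structure(cfg, class = "sim_config")
}

# planted structure shared between paired cohorts: gene means, signature
# membership, and each signature's "up" subtype (round-robin over subtypes)
sim_structure <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  mu <- stats::runif(cfg$n_genes, 2, 8)
  names(mu) <- genes
  sig_genes <- split(genes[seq_len(cfg$n_signatures * cfg$genes_per_signature)],
                     rep(seq_len(cfg$n_signatures),
                         each = cfg$genes_per_signature))
  names(sig_genes) <- sprintf("sig%02d", seq_len(cfg$n_signatures))
  up_subtype <- rep(seq_len(cfg$K), length.out = cfg$n_signatures)
  names(up_subtype) <- names(sig_genes)
  list(genes = genes, mu = mu,
       sets = gene_set_collection(sig_genes,
                                  provenance = paste0("planted; up in subtype ",
                                                      up_subtype)),
       up_subtype = up_subtype)
}

# censoring rate rc such that the prevalence-weighted probability of
# censoring before the event matches the target
censor_rate_solve <- function(cfg) {
  rates <- cfg$hazard_scale * exp(cfg$subtype_log_hr)
  if (cfg$censor_rate == 0) return(0)
  f <- function(rc) sum(cfg$prevalences * rc / (rc + rates)) - cfg$censor_rate
  stats::uniroot(f, c(1e-12, 1e6 * max(rates)))$root
}

#' Simulate one synthetic cohort
#'
#' Draws expression on the TPM scale (so the pipeline's own expression
#' filter and log transform are exercised), disease-free survival with
#' subtype-dependent exponential hazards and independent exponential
#' censoring tuned to the target censoring fraction, and a MAF-style
#' mutation table with subtype-dependent Poisson mutation counts.
#' Fully reproducible from the configuration seed(s).
#'
#' @param cfg A `sim_config`.
#' @param sample_seed Seed for the sample-level draws (defaults to
#'   `cfg$seed`; the planted structure always comes from `cfg$seed`, so two
#'   cohorts with different `sample_seed` share centroids).
#' @param prefix Sample-id prefix.
#' @return A `synthetic_cohort`: list with `expression` (TPM
#'   `expr_matrix`), `survival`, `mutations`, `truth` (named character,
#'   sample -> planted subtype "S1".."SK"), `signature_sets`, `config`.
#' @export
simulate_cohort <- function(cfg, sample_seed = cfg$seed, prefix = "SA") {
  stopifnot(inherits(cfg, "sim_config"))
  st <- sim_structure(cfg)
  set.seed(sample_seed)
  n <- cfg$n_samples
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  subtype <- sample.int(cfg$K, n, replace = TRUE, prob = cfg$prevalences)

  logx <- matrix(stats::rnorm(cfg$n_genes * n, mean = st$mu, sd = cfg$noise_sd),
                 nrow = cfg$n_genes, ncol = n,
                 dimnames = list(st$genes, ids))
  for (s in names(st$sets)) {
    up <- st$up_subtype[[s]]
    cols <- which(subtype == up)
    if (length(cols))
      logx[st$sets[[s]], cols] <- logx[st$sets[[s]], cols] + cfg$effect_size
  }
  tpm <- pmax(2^logx - 1, 0)

  rates <- cfg$hazard_scale * exp(cfg$subtype_log_hr)
  t_event <- stats::rexp(n, rate = rates[subtype])
  rc <- censor_rate_solve(cfg)
  t_cens <- if (rc > 0) stats::rexp(n, rate = rc) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  surv <- data.frame(sample_id = ids,
                     time_days = pmax(time, 0.5),
                     event = as.integer(t_event <= t_cens))

  n_nonsilent <- stats::rpois(n, cfg$tmb_means[subtype])
  n_silent <- stats::rpois(n, 0.25 * cfg$tmb_means[subtype])
  nonsilent_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                         "Frame_Shift_Del", "Splice_Site")
  recs <- lapply(seq_len(n), function(i) {
    tot <- n_nonsilent[i] + n_silent[i]
    if (tot == 0) return(NULL)
    data.frame(sample_id = ids[i],
               gene = sample(st$genes, tot, replace = TRUE),
               variant_class = c(sample(nonsilent_classes, n_nonsilent[i],
                                        replace = TRUE),
                                 rep("Silent", n_silent[i])))
  })
  muts <- do.call(rbind, recs)
  if (is.null(muts))
    muts <- data.frame(sample_id = character(), gene = character(),
                       variant_class = character())

  truth <- paste0("S", subtype)
  names(truth) <- ids
  structure(list(expression = expression_matrix(tpm, "TPM"),
                 survival = surv, mutations = muts, truth = truth,
                 signature_sets = st$sets, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples, K = %d planted subtypes\n",
              nrow(x$expression), ncol(x$expression), x$config$K))
  invisible(x)
}

#' Simulate a discovery/validation cohort pair
#'
#' Both cohorts share the planted structure (gene means, signature sets,
#' subtype patterns, effect sizes) and differ only in their independent
#' sample and noise draws, emulating a discovery cohort and an independent
#' validation cohort profiled on the same biology.
#'
#' @param cfg A `sim_config`.
#' @param seed_a,seed_b Sample-level seeds for the two cohorts.
#' @return List with elements `a` and `b`, each a `synthetic_cohort`.
#' @export
simulate_pair <- function(cfg, seed_a, seed_b) {
  list(a = simulate_cohort(cfg, sample_seed = seed_a, prefix = "CA"),
       b = simulate_cohort(cfg, sample_seed = seed_b, prefix = "CB"))
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Emits `expression.tsv`, `survival.tsv`, `mutations.tsv`,
#' `signatures.gmt`, and `truth.tsv`, all readable by the package's own
#' readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mutations, file.path(dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_sets(cohort$signature_sets, file.path(dir, "signatures.gmt"))
  utils::write.table(data.frame(sample_id = names(cohort$truth),
                                subtype = cohort$truth),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
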