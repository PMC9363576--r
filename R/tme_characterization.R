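#' Kaplan-Meier curves and log-rank test across subtypes
#'
#' Product-limit survival estimate per subtype plus the K-group log-rank
#' statistic (chi-square on K - 1 degrees of freedom). Samples with
#' follow-up below `min_days` are excluded, mirroring the cohort-level
#' 30-day exclusion.
#'
#' @param surv Survival data frame (`sample_id`, `time_days`, `event`).
#' @param assign Named character vector, sample -> label.
#' @param min_days Exclusion threshold on follow-up time.
#' @return List: `curves` (data frame with `label`, `time`, `n_risk`,
#'   `n_event`, `survival`), `chisq`, `df`, `p_value`, `n`, `fit`
#'   (the underlying [survival::survfit()] object).
#' @export
km_logrank <- function(surv, assign, min_days = 30) {
  common <- intersect(surv$sample_id[surv$time_days >= min_days], names(assign))
  if (length(common) == 0) stop("no samples left after exclusion/overlap")
  s <- surv[match(common, surv$sample_id), ]
  g <- factor(assign[common])
  if (nlevels(g) < 2) stop("need at least 2 subtypes for a log-rank test")
  sobj <- survival::Surv(s$time_days, s$event)
  fit <- survival::survfit(sobj ~ g)
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) rep(levels(g)[1], length(sm$time)) else
    sub("^g=", "", as.character(sm$strata))
  curves <- data.frame(label = strata, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv)
  sd <- survival::survdiff(sobj ~ g)
  df <- length(sd$n) - 1
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  list(curves = curves, chisq = unname(sd$chisq), df = df, p_value = p,
       n = length(common), fit = fit)
}

#' Tumor mutational burden per sample
#'
#' Counts each sample's mutation records whose variant class is in
#' `nonsilent_classes`; optionally divided by a capture size in megabases
#' to give mutations/Mb. Samples absent from the mutation table get TMB 0
#' and are flagged.
#'
#' @param muts Mutation data frame (`sample_id`, `gene`, `variant_class`).
#' @param samples Character vector of sample ids to report.
#' @param nonsilent_classes Variant classes counted as nonsynonymous.
#' @param denominator_mb Optional exome size in Mb.
#' @return Named numeric vector of TMB values; attribute `flagged` lists
#'   samples with no mutation records.
#' @export
tmb <- function(muts, samples,
                nonsilent_classes = maf_nonsilent_classes(),
                denominator_mb = NULL) {
  hits <- muts[muts$variant_class %in% nonsilent_classes, ]
  counts <- table(factor(hits$sample_id, levels = samples))
  out <- as.numeric(counts)
  names(out) <- samples
  if (!is.null(denominator_mb)) out <- out / denominator_mb
  attr(out, "flagged") <- setdiff(samples, unique(muts$sample_id))
  out
}

#' Mutation-frequency screen across subtypes
#'
#' For every gene mutated strictly more than `min_count` times in at least
#' one subtype, tests the 2 x K table (mutated / not mutated by subtype)
#' with a chi-square test without continuity correction. Genes failing the
#' count filter are reported with `passes_min_count = FALSE` and no test.
#' No multiplicity correction is applied by default; the overlap with a
#' fixed p threshold is the screen.
#'
#' @param muts Mutation data frame.
#' @param assign Named character vector, sample -> label.
#' @param min_count A gene must be mutated in more than this many samples
#'   of at least one subtype to be tested.
#' @return Data frame: `gene`, one `mut_<label>` and `n_<label>` column per
#'   subtype, `chi_square_p`, `passes_min_count`.
#' @export
mutation_frequency_test <- function(muts, assign, min_count = 3) {
  labs <- sort(unique(assign))
  if (length(labs) < 2) stop("need at least 2 subtypes")
  n_per <- table(factor(assign, levels = labs))
  if (any(n_per == 0)) stop("subtype with zero samples")
  muts <- muts[muts$sample_id %in% names(assign), ]
  genes <- sort(unique(muts$gene))
  rows <- lapply(genes, function(gn) {
    carriers <- unique(muts$sample_id[muts$gene == gn])
    mut_counts <- table(factor(assign[carriers], levels = labs))
    passes <- any(mut_counts > min_count)
    p <- NA_real_
    if (passes) {
      tab <- rbind(mutated = as.integer(mut_counts),
                   wild = as.integer(n_per) - as.integer(mut_counts))
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    row <- data.frame(gene = gn, chi_square_p = p, passes_min_count = passes)
    for (l in labs) {
      row[[paste0("mut_", l)]] <- as.integer(mut_counts[l])
      row[[paste0("n_", l)]] <- as.integer(n_per[l])
    }
    row
  })
  do.call(rbind, rows)
}

#' Compare feature values across subtypes
#'
#' Kruskal-Wallis test per feature across all subtypes, plus two-sided
#' Wilcoxon rank-sum tests for every subtype pair; optional
#' Benjamini-Hochberg adjustment of the Kruskal-Wallis p-values within the
#' requested feature list.
#'
#' @param values Features x samples numeric matrix (expression or scores).
#' @param features Character vector of feature (row) names to test;
#'   missing features are skipped with a warning.
#' @param assign Named character vector, sample -> label; each subtype
#'   needs >= 2 scored samples.
#' @param adjust `"none"` or `"BH"`.
#' @return Data frame with `feature_id`, `kruskal_wallis_p`, one
#'   `p_<labelA>_vs_<labelB>` column per pair, and `adjusted`.
#' @export
compare_across_subtypes <- function(values, features, assign,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  common <- intersect(colnames(values), names(assign))
  g <- factor(assign[common])
  if (any(table(g) < 2)) stop("every subtype needs >= 2 samples")
  miss <- setdiff(features, rownames(values))
  if (length(miss)) {
    warning("skipping absent feature(s): ", paste(miss, collapse = ", "))
    features <- setdiff(features, miss)
  }
  labs <- levels(g)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- lapply(features, function(f) {
    v <- as.numeric(values[f, common])
    row <- data.frame(feature_id = f,
                      kruskal_wallis_p = stats::kruskal.test(v, g)$p.value)
    for (pr in pairs) {
      p <- suppressWarnings(stats::wilcox.test(v[g == pr[1]], v[g == pr[2]],
                                               exact = FALSE)$p.value)
      row[[paste0("p_", pr[1], "_vs_", pr[2])]] <- p
    }
    row
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH")
    out$kruskal_wallis_p <- stats::p.adjust(out$kruskal_wallis_p, "BH")
  out$adjusted <- adjust == "BH"
  out
}

#' Association between a categorical factor and subtype membership
#'
#' Fisher's exact test for 2 x 2 tables; larger tables use the chi-square
#' test, or a Monte-Carlo Fisher test (`simulate = TRUE`, seeded) when
#' expected counts are small. Empty categories are dropped with a warning;
#' a constant factor is degenerate and returns p = 1 with a warning.
#'
#' @param fac Named character vector, sample -> category.
#' @param assign Named character vector, sample -> label.
#' @param simulate Use Monte-Carlo Fisher for tables larger than 2 x 2.
#' @param B Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo test.
#' @return List: `table`, `method`, `p_value`.
#' @export
categorical_association <- function(fac, assign, simulate = FALSE,
                                    B = 10000, seed = 1) {
  common <- intersect(names(fac), names(assign))
  f <- factor(fac[common])
  g <- factor(assign[common])
  f <- droplevels(f)
  if (nlevels(f) < 2 || nlevels(g) < 2) {
    warning("degenerate table (a constant factor or single subtype); p = 1")
    return(list(table = table(f, g), method = "degenerate", p_value = 1))
  }
  tab <- table(f, g)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("dropping empty category level(s)")
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    res <- stats::fisher.test(tab)
    list(table = tab, method = "fisher_exact", p_value = res$p.value)
  } else if (simulate) {
    set.seed(seed)
    res <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
    list(table = tab, method = "fisher_montecarlo", p_value = res$p.value)
  } else {
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(table = tab, method = "chi_square", p_value = res$p.value)
  }
}
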