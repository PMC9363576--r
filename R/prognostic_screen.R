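#' Univariate Cox regression of one score against disease-free survival
#'
#' Fits a single-covariate proportional-hazards model by maximizing the
#' Breslow partial likelihood (Newton-Raphson from beta = 0, as implemented
#' in [survival::coxph()]), with the covariate standardized to unit variance
#' so coefficients are comparable across signatures. The p-value is the Wald
#' test.
#'
#' @param score Named numeric vector (names are sample ids).
#' @param surv Survival data frame with `sample_id`, `time_days`, `event`.
#' @param standardize Standardize the covariate to unit variance before
#'   fitting (default); the flag is recorded in the result.
#' @return One-row data frame: `feature_id`, `beta`, `hr`, `se`, `z`,
#'   `p_value`, `n_used`, `n_events`, `standardized`.
#' @export
cox_univariate <- function(score, surv, standardize = TRUE) {
  if (is.null(names(score))) stop("`score` must be named by sample id")
  common <- intersect(names(score), surv$sample_id)
  if (length(common) < 2) stop("fewer than 2 samples shared between score and survival")
  s <- surv[match(common, surv$sample_id), ]
  v <- score[common]
  if (anyNA(v)) {
    keep <- !is.na(v)
    v <- v[keep]; s <- s[keep, ]
  }
  n_events <- sum(s$event)
  if (n_events < 1) stop("no events; Cox model undefined")
  if (stats::sd(v) == 0) stop("zero-variance covariate")
  if (standardize) v <- (v - mean(v)) / stats::sd(v)
  fit <- survival::coxph(survival::Surv(s$time_days, s$event) ~ v,
                         ties = "breslow",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = " ")))
    stop("Cox fit did not converge in 100 iterations")
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  z <- beta / se
  data.frame(feature_id = attr(score, "feature_id") %||% "score",
             beta = beta, hr = exp(beta), se = se, z = z,
             p_value = 2 * stats::pnorm(-abs(z)),
             n_used = length(v), n_events = n_events,
             standardized = standardize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a cohort's signature scores for survival association
#'
#' Drops samples with follow-up shorter than `min_days` (30-day exclusion),
#' fits a univariate Cox model per signature, and selects signatures with
#' unadjusted `p < p_thresh` -- deliberately no multiplicity correction, the
#' downstream cross-cohort overlap rule is the replication filter. A BH
#' adjustment is available via `adjust = "BH"`.
#'
#' @param scores Signatures x samples score matrix.
#' @param surv Survival data frame.
#' @param p_thresh Selection threshold on the p-value.
#' @param min_days Samples with `time_days < min_days` are excluded.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param cohort_id Free-text cohort label carried into the report.
#' @return A `screen_report`: list with `cohort_id`, `results` (data frame,
#'   one row per signature), and `selected` (character vector).
#' @export
screen_cohort <- function(scores, surv, p_thresh = 0.05, min_days = 30,
                          adjust = c("none", "BH"), cohort_id = "cohort") {
  adjust <- match.arg(adjust)
  surv <- surv[surv$time_days >= min_days, ]
  common <- intersect(colnames(scores), surv$sample_id)
  if (length(common) == 0)
    stop("no samples shared between scores and survival after exclusion")
  rows <- lapply(rownames(scores), function(f) {
    v <- scores[f, common]
    names(v) <- common
    attr(v, "feature_id") <- f
    tryCatch(cox_univariate(v, surv),
             error = function(e) data.frame(
               feature_id = f, beta = NA_real_, hr = NA_real_, se = NA_real_,
               z = NA_real_, p_value = NA_real_, n_used = NA_integer_,
               n_events = NA_integer_, standardized = NA))
  })
  res <- do.call(rbind, rows)
  p <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$selected <- !is.na(p) & p < p_thresh
  structure(list(cohort_id = cohort_id, results = res,
                 selected = res$feature_id[res$selected]),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen_report '%s': %d signature(s), %d selected\n",
              x$cohort_id, nrow(x$results), length(x$selected)))
  invisible(x)
}

#' Cross-cohort overlap filter
#'
#' Keeps the signatures selected in at least `min_cohorts` of the screening
#' reports, ordered by descending selection count and then by name. Used to
#' retain only survival associations that replicate across cohorts.
#'
#' @param reports List of `screen_report` objects (>= 2).
#' @param min_cohorts Minimum number of cohorts a signature must be
#'   selected in.
#' @return Character vector of replicating signature names (may be empty,
#'   with a warning).
#' @export
overlap_filter <- function(reports, min_cohorts = 2) {
  if (length(reports) < 2) stop("need at least 2 screening reports")
  counts <- table(unlist(lapply(reports, `[[`, "selected")))
  keep <- counts[counts >= min_cohorts]
  if (length(keep) == 0) {
    warning("no signature replicates in >= ", min_cohorts, " cohorts")
    return(character())
  }
  names(keep)[order(-as.integer(keep), names(keep))]
}
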