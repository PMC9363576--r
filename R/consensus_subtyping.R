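#' Partition around medoids with Euclidean distance
#'
#' Thin deterministic wrapper over [cluster::pam()] (BUILD followed by SWAP
#' to a local optimum of total distance to medoids). Duplicate points are
#' tolerated; given the same input order the result is reproducible.
#'
#' @param points Numeric matrix, items x features.
#' @param k Number of clusters, `2 <= k <= n`.
#' @return Integer vector of cluster labels (1..k), with attribute
#'   `medoids` (row indices) and `cost` (total Euclidean distance to
#'   assigned medoids).
#' @export
pam_cluster <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1 || k > n) stop("need 1 <= k <= n (n = ", n, ")")
  if (k == n) {
    lab <- seq_len(n)
    attr(lab, "medoids") <- seq_len(n)
    attr(lab, "cost") <- 0
    return(lab)
  }
  fit <- cluster::pam(points, k, metric = "euclidean", pamonce = 5)
  lab <- unname(fit$clustering)
  med <- fit$id.med
  d <- sqrt(rowSums((points - points[med[lab], , drop = FALSE])^2))
  attr(lab, "medoids") <- med
  attr(lab, "cost") <- sum(d)
  lab
}

#' Resampling consensus clustering of signature scores
#'
#' For each of `n_resamples` subsamples (a fraction `frac` of the samples
#' drawn without replacement), samples are clustered by PAM with Euclidean
#' distance at every k in `k_range`. The consensus matrix entry M_k(i, j) is
#' the number of times i and j co-clustered divided by the number of times
#' they were co-sampled; pairs never co-sampled (essentially impossible at
#' the defaults) are set to 0 and flagged. The empirical CDF of the
#' upper-triangle consensus values yields the area A(k) (exact integral of
#' the step function over [0, 1]) and the relative area increase
#' Delta(2) = A(2), Delta(k) = (A(k) - A(k-1)) / A(k-1).
#'
#' Signature rows are z-scored before clustering by default so every
#' signature contributes on the same Euclidean scale.
#'
#' @param scores Signatures x samples score matrix.
#' @param k_range Integer vector of cluster numbers to evaluate.
#' @param n_resamples Number of subsamples.
#' @param frac Fraction of samples per subsample, in (0, 1].
#' @param seed Integer seed controlling the resampling.
#' @param scale_features z-score each signature before clustering.
#' @return A `consensus_result`: list with `k_range`, `M` (named list of
#'   consensus matrices), `cdf` (list of step-CDF tables), `A`, `delta`,
#'   and `resample_log`.
#' @export
consensus_run <- function(scores, k_range = 2:10, n_resamples = 500,
                          frac = 0.8, seed = 1, scale_features = TRUE) {
  pts <- t(as.matrix(scores))                 # samples x signatures
  n <- nrow(pts)
  if (n < 10) stop("need at least 10 samples for consensus clustering")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  m_sub <- ceiling(frac * n)
  if (max(k_range) > m_sub)
    stop("largest k (", max(k_range), ") exceeds subsample size (", m_sub, ")")
  if (scale_features) pts <- scale(pts)
  ids <- rownames(pts) %||% as.character(seq_len(n))

  co_sample <- matrix(0, n, n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)

  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m_sub))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    sub <- pts[idx, , drop = FALSE]
    for (k in k_range) {
      lab <- pam_cluster(sub, k)
      same <- outer(lab, lab, "==") * 1
      kk <- as.character(k)
      co_cluster[[kk]][idx, idx] <- co_cluster[[kk]][idx, idx] + same
    }
  }

  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never))
    warning(sum(never), " sample pair(s) never co-sampled; consensus set to 0")

  M <- lapply(co_cluster, function(cc) {
    m <- ifelse(co_sample > 0, cc / pmax(co_sample, 1), 0)
    diag(m) <- 1
    m <- (m + t(m)) / 2
    dimnames(m) <- list(ids, ids)
    m
  })

  cdfs <- lapply(M, consensus_cdf)
  A <- vapply(cdfs, function(cd) cd$area, 0)
  delta <- numeric(length(k_range))
  delta[1] <- A[1]
  if (length(k_range) > 1)
    delta[-1] <- diff(A) / A[-length(A)]
  names(delta) <- names(A) <- as.character(k_range)

  structure(list(k_range = k_range, M = M, cdf = cdfs, A = A, delta = delta,
                 resample_log = list(n_resamples = n_resamples, frac = frac,
                                     seed = seed, never_cosampled = sum(never),
                                     scale_features = scale_features)),
            class = "consensus_result")
}

# empirical CDF of the upper-triangle consensus entries and the exact area
# under the step function on [0, 1]
consensus_cdf <- function(m) {
  v <- m[upper.tri(m)]
  xs <- sort(unique(c(0, v, 1)))
  F <- stats::ecdf(v)(xs)
  area <- sum(diff(xs) * F[-length(xs)])
  list(x = xs, F = F, area = area)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k =", paste(range(x$k_range), collapse = ".."),
      sprintf("(%d resamples, frac %.2f)\n",
              x$resample_log$n_resamples, x$resample_log$frac))
  print(round(rbind(A = x$A, delta = x$delta), 3))
  invisible(x)
}

#' Suggest a cluster number from the consensus diagnostics
#'
#' Picks the k >= 3 with the largest relative area increase Delta(k); if
#' even that increase is below `min_delta` the CDF has already flattened and
#' the smallest evaluated k is returned. The choice of k remains a user
#' decision -- this is the diagnostic summary, not a silent commitment.
#'
#' @param result A `consensus_result`.
#' @param min_delta Flatness threshold on Delta.
#' @return Integer suggested k.
#' @export
suggest_k <- function(result, min_delta = 0.05) {
  kr <- result$k_range
  cand <- kr[kr >= 3]
  if (length(cand) == 0) return(min(kr))
  d <- result$delta[as.character(cand)]
  best <- cand[which.max(d)]
  if (max(d) < min_delta) min(kr) else best
}

#' Final subtype labels from a consensus matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - M_k,
#' cut into k groups. Labels are provisional (`"C1"`..`"Ck"`, in order of
#' first appearance) until ordered by prognosis.
#'
#' @param result A `consensus_result`.
#' @param k Cluster number; must be in `result$k_range`.
#' @return Named character vector, sample id -> label, with attribute `k`.
#' @export
final_labels <- function(result, k) {
  if (!k %in% result$k_range) stop("k = ", k, " was not evaluated")
  m <- result$M[[as.character(k)]]
  hc <- stats::hclust(stats::as.dist(1 - m), method = "average")
  grp <- stats::cutree(hc, k = k)
  if (length(unique(grp)) < k)
    stop("consensus cut produced an empty group; k = ", k, " looks unstable")
  lab <- paste0("C", grp)
  names(lab) <- rownames(m)
  attr(lab, "k") <- k
  lab
}

#' Order subtype labels by prognosis
#'
#' Relabels clusters as IS1..ISK so that IS1 has the poorest and ISK the
#' best disease-free survival, measured by the restricted mean survival
#' time (RMST) with horizon at the largest observed time. RMST is used
#' because the median is undefined under heavy censoring. Exact RMST ties
#' are broken by the original label order, with a warning.
#'
#' @param assign Named character vector, sample id -> cluster label.
#' @param surv Survival data frame (`sample_id`, `time_days`, `event`).
#' @return Named character vector with labels IS1..ISK; attribute
#'   `ordering_basis` holds the per-label RMST table.
#' @export
order_by_prognosis <- function(assign, surv) {
  common <- intersect(names(assign), surv$sample_id)
  if (length(common) == 0) stop("no overlap between assignment and survival")
  s <- surv[match(common, surv$sample_id), ]
  g <- assign[common]
  labs <- sort(unique(assign))
  if (any(!labs %in% g)) stop("label(s) with zero surviving samples: ",
                              paste(setdiff(labs, g), collapse = ", "))
  ev <- tapply(s$event, g, sum)
  if (any(ev == 0))
    warning("label(s) with zero events: ", paste(names(ev)[ev == 0], collapse = ", "))
  horizon <- max(s$time_days)
  rmst <- vapply(labs, function(l) {
    sel <- g == l
    sf <- survival::survfit(survival::Surv(s$time_days[sel], s$event[sel]) ~ 1)
    unname(summary(sf, rmean = horizon)$table["rmean"])
  }, 0)
  if (anyDuplicated(rmst))
    warning("tied restricted-mean survival; breaking ties by original label order")
  ord <- order(rmst, seq_along(labs))           # IS1 = shortest RMST
  new_lab <- paste0("IS", seq_along(labs))
  map <- stats::setNames(new_lab, labs[ord])
  out <- unname(map[assign])
  names(out) <- names(assign)
  attr(out, "k") <- length(labs)
  attr(out, "ordering_basis") <- data.frame(original = labs[ord],
                                            label = new_lab,
                                            rmst_days = rmst[ord],
                                            row.names = NULL)
  out
}
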