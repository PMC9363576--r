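#' Per-subtype centroids of signature scores
#'
#' @param scores Signatures x samples score matrix.
#' @param assign Named character vector, sample id -> label.
#' @return Matrix, signatures x labels, each column the arithmetic mean
#'   score vector of that label's samples.
#' @export
subtype_centroids <- function(scores, assign) {
  common <- intersect(colnames(scores), names(assign))
  if (length(common) == 0) stop("no overlap between scores and assignment")
  g <- assign[common]
  labs <- sort(unique(g))
  cen <- vapply(labs, function(l)
    rowMeans(scores[, common[g == l], drop = FALSE]), numeric(nrow(scores)))
  if (!is.matrix(cen)) cen <- matrix(cen, nrow = nrow(scores),
                                     dimnames = list(rownames(scores), labs))
  colnames(cen) <- labs
  cen
}

#' Project samples onto subtype centroids
#'
#' Assigns each validation sample the label of the centroid with the
#' highest Pearson correlation to its score vector. Correlation is
#' scale- and shift-invariant, so cross-platform offsets do not matter.
#' A sample with a zero-variance score vector (correlation undefined) falls
#' back to minimal Euclidean distance and is flagged. Exact ties go to the
#' first label in column order, with a warning.
#'
#' @param scores_val Signatures x samples score matrix of the validation
#'   cohort; must share at least 80% of the centroid features.
#' @param centroids Signatures x labels matrix from [subtype_centroids()].
#' @return Named character vector, sample -> label; attribute `flagged`
#'   lists samples assigned by the Euclidean fallback.
#' @export
project_nearest_centroid <- function(scores_val, centroids) {
  shared <- intersect(rownames(scores_val), rownames(centroids))
  if (length(shared) < 0.8 * nrow(centroids))
    stop("validation cohort shares only ", length(shared), "/",
         nrow(centroids), " centroid features (< 80%)")
  sv <- scores_val[shared, , drop = FALSE]
  ce <- centroids[shared, , drop = FALSE]
  flagged <- character()
  lab <- vapply(seq_len(ncol(sv)), function(j) {
    v <- sv[, j]
    if (stats::sd(v) == 0) {
      flagged <<- c(flagged, colnames(sv)[j])
      d <- sqrt(colSums((ce - v)^2))
      return(colnames(ce)[which.min(d)])
    }
    r <- apply(ce, 2, function(cc) stats::cor(v, cc))
    if (sum(r == max(r)) > 1)
      warning("correlation tie for sample ", colnames(sv)[j],
              "; taking first label")
    colnames(ce)[which.max(r)]
  }, "")
  names(lab) <- colnames(sv)
  attr(lab, "flagged") <- flagged
  lab
}

#' In-group proportion (IGP)
#'
#' For each label, the fraction of its samples whose nearest neighbor
#' (self excluded) carries the same label. Values near 1 indicate that a
#' projected subtype forms a tight, reproducible group in the validation
#' cohort. Nearest-neighbor ties are broken by lowest sample index;
#' singleton labels get IGP = 0 with a flag.
#'
#' @param scores Signatures x samples score matrix.
#' @param assign Named character vector, sample -> label, covering the
#'   scored samples.
#' @param metric `"pearson"` (distance 1 - r, default) or `"euclidean"`.
#' @return Data frame: `label`, `igp`, `n`, `flag`.
#' @export
igp <- function(scores, assign, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  common <- intersect(colnames(scores), names(assign))
  if (length(common) < 2) stop("need at least 2 assigned, scored samples")
  x <- t(as.matrix(scores[, common, drop = FALSE]))   # samples x features
  g <- assign[common]
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[is.na(cc)] <- 0        # zero-variance vectors: maximal dissimilarity
    1 - cc
  }
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)                 # ties -> lowest index
  same <- g[nn] == g
  out <- do.call(rbind, lapply(sort(unique(g)), function(l) {
    sel <- g == l
    if (sum(sel) == 1)
      data.frame(label = l, igp = 0, n = 1L, flag = "singleton")
    else
      data.frame(label = l, igp = mean(same[sel]), n = sum(sel), flag = "")
  }))
  attr(out, "metric") <- metric
  out
}

#' Correlation matrix and greedy matching between two centroid sets
#'
#' Pearson correlation between every pair of label centroids from two
#' cohorts, plus a greedy maximal matching: the highest-correlation pair is
#' matched first, both labels removed, and so on. High matched correlations
#' indicate that the two cohorts recover the same subtype structure.
#'
#' @param c_a,c_b Signatures x labels centroid matrices sharing >= 2
#'   feature ids.
#' @return List with `correlation` (labels_a x labels_b matrix) and
#'   `matching` (data frame `label_a`, `label_b`, `r`).
#' @export
centroid_correlation <- function(c_a, c_b) {
  shared <- intersect(rownames(c_a), rownames(c_b))
  if (length(shared) < 2) stop("centroid sets share fewer than 2 features")
  a <- c_a[shared, , drop = FALSE]
  b <- c_b[shared, , drop = FALSE]
  if (any(apply(a, 2, stats::sd) == 0) || any(apply(b, 2, stats::sd) == 0))
    stop("constant centroid; correlation undefined")
  cm <- stats::cor(a, b)
  free_a <- rownames(cm); free_b <- colnames(cm)
  pairs <- list()
  while (length(free_a) && length(free_b)) {
    sub <- cm[free_a, free_b, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1]] <- data.frame(label_a = free_a[ij[1]],
                                             label_b = free_b[ij[2]],
                                             r = sub[ij[1], ij[2]])
    free_a <- free_a[-ij[1]]
    free_b <- free_b[-ij[2]]
  }
  list(correlation = cm, matching = do.call(rbind, pairs))
}
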