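# Independent brute-force oracles used to pin the package's statistics.
# These are deliberately naive re-derivations from first principles and
# share no code with the implementation.

# ssGSEA enrichment score by explicit enumeration over positions: for every
# position i in the decreasing-expression ordering, re-sum the weighted
# in-set mass and the out-of-set count from scratch.
ssgsea_walk_oracle <- function(v, set_genes, alpha) {
  stopifnot(!is.null(names(v)))
  N <- length(v)
  r <- rank(v, ties.method = "average")
  ord <- names(v)[order(v, decreasing = TRUE)]
  member <- stats::setNames(names(v) %in% set_genes, names(v))
  denom <- sum(r[names(v)[member]]^alpha)
  n_out <- N - sum(member)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- 0
    p_out <- 0
    for (j in seq_len(i)) {
      g <- ord[j]
      if (member[g]) p_in <- p_in + r[g]^alpha else p_out <- p_out + 1
    }
    es <- es + p_in / denom - p_out / n_out
  }
  unname(es)
}

# Breslow partial log-likelihood, coded directly from the definition: each
# event contributes its linear predictor minus the log of the risk-set sum
# (tied events share the same risk set).
breslow_loglik <- function(beta, time, event, x) {
  vapply(beta, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, 0)
}

# grid-search maximizer of the Breslow partial likelihood over [-5, 5] at
# step 1e-4; the partial log-likelihood is concave in beta, so a coarse
# pass followed by a fine pass around the coarse argmax visits the same
# maximizer as the full fine grid
cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  coarse <- seq(lo, hi, by = 0.01)
  b0 <- coarse[which.max(breslow_loglik(coarse, time, event, x))]
  fine <- seq(max(lo, b0 - 0.02), min(hi, b0 + 0.02), by = step)
  fine[which.max(breslow_loglik(fine, time, event, x))]
}

# in-group proportion by exhaustive all-pairs nearest-neighbor enumeration
igp_oracle <- function(pts, groups, metric = "euclidean") {
  n <- nrow(pts)
  nn_same <- logical(n)
  for (i in seq_len(n)) {
    best <- Inf
    best_j <- NA
    for (j in seq_len(n)) {
      if (i == j) next
      d <- if (metric == "euclidean") sqrt(sum((pts[i, ] - pts[j, ])^2))
      else 1 - stats::cor(pts[i, ], pts[j, ])
      if (d < best) { best <- d; best_j <- j }
    }
    nn_same[i] <- groups[best_j] == groups[i]
  }
  vapply(sort(unique(groups)), function(g) {
    sel <- groups == g
    if (sum(sel) == 1) 0 else mean(nn_same[sel])
  }, 0)
}

# topological overlap by explicit triple loop over the shared-neighbor sum
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- rowSums(a) - 1
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# small helper: wrap a bare numeric matrix as a log-scale expression matrix
as_log_expr <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  expression_matrix(m - min(m), "LOG2_TPM1")
}

# score a synthetic cohort with the pipeline's own preprocessing
score_cohort <- function(cohort, alpha = 0.25) {
  x <- log_transform(filter_expressed_genes(cohort$expression))
  ssgsea_scores(x, cohort$signature_sets, alpha = alpha)
}

# map cluster labels to planted subtypes by majority vote and return the
# per-sample agreement of a second labeling under that map
majority_map <- function(labels, truth) {
  tab <- table(labels, truth)
  stats::setNames(rownames(tab)[apply(tab, 2, which.max)], colnames(tab))
}

# recover each planted signature's "up" subtype from the generator's
# provenance notes
sim_struct_for_test <- function(co) {
  prov <- attr(co$signature_sets, "provenance")
  stats::setNames(as.integer(sub(".*subtype ", "", prov)),
                  names(co$signature_sets))
}
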