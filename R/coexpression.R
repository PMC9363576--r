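#' Keep the most variable genes by median absolute deviation
#'
#' Ranks genes by MAD across samples and keeps the top `top_prop` fraction.
#' Constant genes (MAD 0) are always removed when `top_prop < 1`.
#'
#' @param x An `expr_matrix` with >= 2 samples.
#' @param top_prop Fraction of genes to keep, in (0, 1].
#' @return The filtered `expr_matrix`.
#' @export
mad_filter <- function(x, top_prop = 0.5) {
  if (ncol(x) < 2) stop("need >= 2 samples to compute MAD")
  if (top_prop <= 0 || top_prop > 1) stop("top_prop must be in (0, 1]")
  mads <- apply(as.matrix(x), 1, stats::mad)
  if (all(mads == 0)) stop("all genes are constant")
  n_keep <- ceiling(top_prop * nrow(x))
  keep <- order(-mads, seq_along(mads))[seq_len(n_keep)]
  if (top_prop < 1) keep <- keep[mads[keep] > 0]
  x[sort(keep), , drop = FALSE]
}

#' Build a weighted co-expression network
#'
#' Adjacency is the soft-thresholded absolute Pearson correlation
#' \eqn{a_{ij} = |cor(g_i, g_j)|^\beta} (signed option:
#' \eqn{((1 + cor)/2)^\beta}); beta = 10 gives an approximately scale-free
#' topology for typical bulk expression. The topological overlap matrix is
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},\quad
#'  l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},\quad k_i = \sum_{j \ne i} a_{ij},}
#' with diagonal 1; it downweights spurious pairwise correlations that are
#' not supported by shared neighbors.
#'
#' @param x An `expr_matrix` (>= 3 genes, >= 4 samples), typically after
#'   [mad_filter()].
#' @param beta Soft-threshold power.
#' @param signed Use the signed adjacency transform.
#' @return A `coexpression_network`: list with `gene_ids`, `beta`,
#'   `signed`, `adjacency`, `tom`.
#' @export
build_network <- function(x, beta = 10, signed = FALSE) {
  xm <- as.matrix(x)
  if (nrow(xm) < 3 || ncol(xm) < 4)
    stop("need >= 3 genes and >= 4 samples")
  sds <- apply(xm, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(xm)[sds == 0], 5), collapse = ", "))
  cc <- stats::cor(t(xm))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 1
  structure(list(gene_ids = rownames(xm), beta = beta, signed = signed,
                 adjacency = a, tom = tom_from_adjacency(a)),
            class = "coexpression_network")
}

#' Topological overlap matrix from an adjacency matrix
#' @param a Symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @return TOM matrix with unit diagonal.
#' @export
tom_from_adjacency <- function(a) {
  diag(a) <- 1
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a          # removes the u = i and u = j terms (a_ii = 1)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %g (%s)\n",
              length(x$gene_ids), x$beta,
              if (x$signed) "signed" else "unsigned"))
  invisible(x)
}

# first principal component of a module's row-standardized expression; the
# eigengene sign is fixed so the mean correlation with member genes is
# positive, and the vector has unit norm
module_eigengene <- function(xm) {
  ys <- t(scale(t(xm)))
  sv <- svd(ys, nu = 0, nv = 1)
  e <- sv$v[, 1]
  kme <- apply(xm, 1, function(g) stats::cor(g, e))
  if (mean(kme, na.rm = TRUE) < 0) e <- -e
  e
}

# standard color sequence by module size rank; "grey" is reserved for
# unassigned genes
module_colors <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("module", seq_len(n - length(base))))
}

#' Detect co-expression modules from a network
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' with a simplified dynamic cut: the dendrogram is cut statically at the
#' (0.99 - 0.01 * `deep_split`) quantile of merge heights, branches of at
#' least `min_size` genes become modules, and genes on smaller branches are
#' reassigned to the module whose eigengene they correlate with best
#' (kME >= `kme_reassign`) or left unassigned ("grey"). Modules whose
#' eigengene dissimilarity 1 - cor falls below `merge_height` are then
#' merged iteratively. This static-cut-plus-reassignment scheme is a
#' deliberate simplification of the dynamic hybrid tree cut; the planted
#' block structure it must resolve is pinned by the test suite.
#'
#' @param net A `coexpression_network`.
#' @param x The `expr_matrix` the network was built from (needed for
#'   eigengenes).
#' @param min_size Minimum module size.
#' @param deep_split Cut-depth parameter (higher cuts deeper; 0-8).
#' @param merge_height Eigengene dissimilarity below which modules merge.
#' @param kme_reassign Minimum kME for rescuing a small-branch gene into a
#'   module.
#' @return A `module_set`: list with `modules` (named character vector,
#'   gene -> color, "grey" = unassigned), `eigengenes` (modules x samples,
#'   unit-norm rows), and the parameters.
#' @export
detect_modules <- function(net, x, min_size = 60, deep_split = 4,
                           merge_height = 0.25, kme_reassign = 0.3) {
  xm <- as.matrix(x)[net$gene_ids, , drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - net$tom), method = "average")
  cut_h <- stats::quantile(hc$height, max(0, min(1, 0.99 - 0.01 * deep_split)))
  grp <- stats::cutree(hc, h = cut_h)
  sizes <- table(grp)
  big <- names(sizes)[sizes >= min_size]
  genes <- net$gene_ids
  assignment <- rep(NA_integer_, length(genes))
  names(assignment) <- genes
  for (i in seq_along(big)) assignment[grp == as.integer(big[i])] <- i

  if (length(big) == 0) {
    warning("no branch reaches min_size = ", min_size, "; all genes unassigned")
    mods <- rep("grey", length(genes))
    names(mods) <- genes
    return(structure(list(modules = mods,
                          eigengenes = matrix(0, 0, ncol(xm),
                                              dimnames = list(NULL, colnames(xm))),
                          min_size = min_size, deep_split = deep_split,
                          merge_height = merge_height),
                     class = "module_set"))
  }

  eig <- t(vapply(seq_along(big), function(i)
    module_eigengene(xm[assignment %in% i, , drop = FALSE]), numeric(ncol(xm))))

  # rescue small-branch genes by best kME
  loose <- which(is.na(assignment))
  if (length(loose)) {
    kme <- stats::cor(t(xm[loose, , drop = FALSE]), t(eig))
    best <- max.col(kme, ties.method = "first")
    ok <- kme[cbind(seq_along(loose), best)] >= kme_reassign
    assignment[loose[ok]] <- best[ok]
  }

  # iteratively merge modules with near-identical eigengenes
  repeat {
    ids <- sort(unique(assignment[!is.na(assignment)]))
    if (length(ids) < 2) break
    eig <- t(vapply(ids, function(i)
      module_eigengene(xm[assignment %in% i, , drop = FALSE]), numeric(ncol(xm))))
    d <- 1 - stats::cor(t(eig))
    diag(d) <- Inf
    if (min(d) >= merge_height) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    assignment[assignment == ids[ij[2]]] <- ids[ij[1]]
  }

  ids <- sort(unique(assignment[!is.na(assignment)]))
  sizes <- vapply(ids, function(i) sum(assignment == i, na.rm = TRUE), 0L)
  ord <- ids[order(-sizes)]
  cols <- module_colors(length(ord))
  mods <- rep("grey", length(genes))
  names(mods) <- genes
  for (i in seq_along(ord)) mods[which(assignment == ord[i])] <- cols[i]
  eig <- t(vapply(cols, function(cl)
    module_eigengene(xm[mods == cl, , drop = FALSE]), numeric(ncol(xm))))
  rownames(eig) <- cols
  colnames(eig) <- colnames(xm)
  structure(list(modules = mods, eigengenes = eig, min_size = min_size,
                 deep_split = deep_split, merge_height = merge_height),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  tab <- table(x$modules)
  cat("module_set:", sum(names(tab) != "grey"), "module(s)\n")
  print(tab)
  invisible(x)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation (with two-sided p) of each module eigengene against
#' each trait. A character trait (e.g. a subtype assignment) is expanded
#' into one 0/1 indicator per level.
#'
#' @param modules A `module_set`.
#' @param traits Named numeric vector, named character vector (expanded to
#'   indicators), or a data frame / matrix of numeric traits with sample
#'   rownames.
#' @return Data frame: `module`, `trait`, `r`, `p_value`.
#' @export
module_trait_correlation <- function(modules, traits) {
  eig <- modules$eigengenes
  if (nrow(eig) == 0) stop("module set has no modules")
  if (is.character(traits) || is.factor(traits)) {
    labs <- sort(unique(as.character(traits)))
    tr <- vapply(labs, function(l) as.numeric(traits == l),
                 numeric(length(traits)))
    rownames(tr) <- names(traits)
  } else if (is.numeric(traits) && is.null(dim(traits))) {
    tr <- matrix(traits, ncol = 1, dimnames = list(names(traits), "trait"))
  } else {
    tr <- as.matrix(traits)
  }
  common <- intersect(colnames(eig), rownames(tr))
  if (length(common) < 3) stop("fewer than 3 samples shared with traits")
  rows <- list()
  for (m in rownames(eig)) for (t in colnames(tr)) {
    v <- tr[common, t]
    if (stats::sd(v) == 0) stop("constant trait: ", t)
    ct <- stats::cor.test(eig[m, common], v)
    rows[[length(rows) + 1]] <- data.frame(module = m, trait = t,
                                           r = unname(ct$estimate),
                                           p_value = ct$p.value)
  }
  do.call(rbind, rows)
}

#' Survival-filtered hub genes of a module
#'
#' Reports the genes of one module whose module membership
#' kME = cor(expression, eigengene) exceeds `kme_thresh` (strict) and whose
#' univariate Cox p-value against disease-free survival is below `p_thresh`.
#'
#' @param x The `expr_matrix` used for module detection.
#' @param modules A `module_set`.
#' @param module_id Module color to interrogate.
#' @param surv Survival data frame.
#' @param kme_thresh Strict lower bound on kME.
#' @param p_thresh Upper bound on the Cox p-value.
#' @return Data frame: `module`, `gene`, `kme`, `cox_p`, `selected`.
#' @export
hub_genes <- function(x, modules, module_id, surv,
                      kme_thresh = 0.85, p_thresh = 0.05) {
  member <- names(modules$modules)[modules$modules == module_id]
  if (length(member) == 0) stop("module '", module_id, "' is empty or unknown")
  eig <- modules$eigengenes[module_id, ]
  xm <- as.matrix(x)[member, , drop = FALSE]
  common <- intersect(colnames(xm), names(eig))
  rows <- lapply(member, function(gn) {
    kme <- stats::cor(xm[gn, common], eig[common])
    v <- xm[gn, ]
    attr(v, "feature_id") <- gn
    cp <- tryCatch(cox_univariate(v, surv)$p_value, error = function(e) NA_real_)
    data.frame(module = module_id, gene = gn, kme = kme, cox_p = cp)
  })
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$cox_p) & out$kme > kme_thresh & out$cox_p < p_thresh
  out
}
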