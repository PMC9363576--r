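#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (rank N for the highest,
#' ties receive the average rank) and walked in decreasing-expression order.
#' With gene set G of size m inside a universe of N genes, the in-set running
#' sum at position i is
#' \deqn{P_{in}(i) = \sum_{g \in G,\, pos(g) \le i} r_g^\alpha \Big/ \sum_{g \in G} r_g^\alpha,}
#' the out-of-set running sum is the fraction of non-members seen so far,
#' and the enrichment score is the sum over all N positions of
#' \eqn{P_{in}(i) - P_{out}(i)}. A positive score means the set's genes sit
#' near the top of the sample's expression ranking.
#'
#' Genes of a set absent from the matrix are dropped with a warning; a set
#' with fewer than two matching genes is scored as `NA` and reported; a set
#' covering the whole universe has no defined complement and is an error.
#'
#' @param x An `expr_matrix` on the LOG2_TPM1 scale.
#' @param sets A `gene_sets` collection (or a named list of gene vectors).
#' @param alpha Rank-weighting exponent; 0.25 is the common ssGSEA
#'   convention, 1 weights positions linearly by rank.
#' @param normalize If `TRUE`, all scores are divided by the global range
#'   (max ES - min ES) across the whole matrix, putting every signature on
#'   one comparable scale.
#' @return A numeric matrix, signatures x samples, with attributes `alpha`
#'   and `normalized`.
#' @export
ssgsea_scores <- function(x, sets, alpha = 0.25, normalize = FALSE) {
  if (inherits(x, "expr_matrix") && expr_scale(x) != "LOG2_TPM1")
    stop("ssGSEA expects log2(TPM+1) expression; run log_transform() first")
  xm <- as.matrix(x)
  genes <- rownames(xm)
  n_genes <- nrow(xm)
  set_idx <- lapply(names(sets), function(nm) {
    g <- sets[[nm]]
    hit <- match(g, genes)
    if (anyNA(hit))
      warning("set '", nm, "': dropping ", sum(is.na(hit)),
              " gene(s) absent from the expression matrix")
    hit <- hit[!is.na(hit)]
    if (length(hit) == n_genes)
      stop("set '", nm, "' covers every gene; complement is empty")
    hit
  })
  names(set_idx) <- names(sets)
  too_small <- vapply(set_idx, length, 0L) < 2
  if (any(too_small))
    warning("signature(s) with <2 matching genes scored as NA: ",
            paste(names(sets)[too_small], collapse = ", "))

  es <- matrix(NA_real_, length(sets), ncol(xm),
               dimnames = list(names(sets), colnames(xm)))
  for (j in seq_len(ncol(xm))) {
    v <- xm[, j]
    r <- rank(v, ties.method = "average")        # rank N = highest
    ord <- order(v, decreasing = TRUE)           # walk from top expression
    r_ord <- r[ord]
    for (s in seq_along(set_idx)) {
      if (too_small[s]) next
      member <- logical(n_genes)
      member[set_idx[[s]]] <- TRUE
      m_ord <- member[ord]
      w <- r_ord^alpha * m_ord
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!m_ord) / (n_genes - sum(m_ord))
      es[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(es, na.rm = TRUE)
    if (diff(rng) == 0) stop("cannot normalize: zero score range")
    es <- es / diff(rng)
  }
  attr(es, "alpha") <- alpha
  attr(es, "normalized") <- normalize
  es
}

#' Intratumoral cytolytic activity (CYT)
#'
#' The per-sample arithmetic mean of GZMA and PRF1 log2(TPM+1) expression.
#' The original cytolytic-activity literature uses a geometric mean of TPM;
#' `geometric = TRUE` switches to that convention.
#'
#' @param x An `expr_matrix` on the LOG2_TPM1 scale.
#' @param geometric Use the geometric mean of (2^value - 1) instead of the
#'   arithmetic mean of log values.
#' @return Named numeric vector of CYT scores, one per sample.
#' @export
cytolytic_activity <- function(x, geometric = FALSE) {
  if (inherits(x, "expr_matrix") && expr_scale(x) != "LOG2_TPM1")
    stop("CYT expects log2(TPM+1) expression")
  for (g in c("GZMA", "PRF1"))
    if (!g %in% rownames(x)) stop(g, " not found in expression matrix")
  gz <- as.matrix(x)["GZMA", ]
  pr <- as.matrix(x)["PRF1", ]
  if (geometric) {
    sqrt((2^gz - 1 + 0.01) * (2^pr - 1 + 0.01))
  } else {
    (gz + pr) / 2
  }
}

#' Stromal, immune, and combined microenvironment scores
#'
#' Unnormalized ssGSEA enrichment of a stromal and an immune signature; the
#' combined score is their per-sample sum and tracks overall non-tumor
#' content (lower combined score, higher tumor purity).
#'
#' @param x An `expr_matrix` on the LOG2_TPM1 scale.
#' @param stromal_set,immune_set Character vectors of signature genes.
#' @param alpha Rank-weighting exponent passed to [ssgsea_scores()].
#' @return A data frame with columns `sample_id`, `StromalScore`,
#'   `ImmuneScore`, `ESTIMATEScore`.
#' @export
estimate_scores <- function(x, stromal_set, immune_set, alpha = 0.25) {
  sc <- ssgsea_scores(x, gene_set_collection(
    list(StromalScore = stromal_set, ImmuneScore = immune_set)),
    alpha = alpha, normalize = FALSE)
  if (anyNA(sc)) stop("stromal/immune signature failed to score")
  data.frame(sample_id = colnames(sc),
             StromalScore = sc["StromalScore", ],
             ImmuneScore = sc["ImmuneScore", ],
             ESTIMATEScore = sc["StromalScore", ] + sc["ImmuneScore", ],
             row.names = NULL)
}

#' Bundled signature collections
#'
#' Names of the small surrogate GMT collections shipped with the package:
#' `metagenes7` (seven inflammation metagenes: HCK, IgG, LCK, MHC-I, MHC-II,
#' Interferon, STAT1), `immunecells28` (28 immune cell types),
#' `angiogenesis`, and `ifng` (Th1/IFN-gamma response). These are compact
#' surrogate marker lists for testing the scoring machinery; analyses of
#' real cohorts should substitute full published lists via
#' [read_gene_sets()].
#'
#' @return Character vector of collection names.
#' @export
bundled_collections <- function() {
  c("metagenes7", "immunecells28", "angiogenesis", "ifng",
    "estimate_stromal_immune")
}

#' Score a named bundled (or user-supplied) signature collection
#'
#' @param x An `expr_matrix` on the LOG2_TPM1 scale.
#' @param collection One of [bundled_collections()], or a path to a GMT file.
#' @param alpha,normalize Passed to [ssgsea_scores()].
#' @return Signature x sample score matrix with a `provenance` attribute.
#' @export
named_signature_scores <- function(x, collection, alpha = 0.25,
                                   normalize = FALSE) {
  if (file.exists(collection)) {
    sets <- read_gene_sets(collection)
    prov <- collection
  } else {
    if (!collection %in% bundled_collections())
      stop("unknown collection '", collection, "'; available: ",
           paste(bundled_collections(), collapse = ", "),
           " (or a path to a GMT file)")
    path <- system.file("extdata", paste0(collection, "_synthetic.gmt"),
                        package = "immclust", mustWork = TRUE)
    sets <- read_gene_sets(path)
    prov <- paste0("bundled surrogate collection '", collection, "'")
  }
  sc <- ssgsea_scores(x, sets, alpha = alpha, normalize = normalize)
  attr(sc, "provenance") <- prov
  sc
}

#' Write a signature score matrix as TSV
#' @param scores Signatures x samples matrix.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(signature = rownames(scores), scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
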