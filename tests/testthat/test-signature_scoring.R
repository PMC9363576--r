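test_that("the worked 4-gene enrichment walk gives ES = 4/3 at alpha = 1", {
  m <- matrix(c(4, 3, 2, 1), 4, 1,
              dimnames = list(paste0("g", 1:4), "s1"))
  x <- expression_matrix(m, "LOG2_TPM1")
  sets <- gene_set_collection(list(G = c("g1", "g3")))
  es <- ssgsea_scores(x, sets, alpha = 1, normalize = FALSE)
  expect_equal(unname(es["G", "s1"]), 4 / 3)
  expect_equal(es["G", "s1"], ssgsea_walk_oracle(m[, 1], c("g1", "g3"), 1))
})

test_that("ssGSEA matches the brute-force walk oracle on random matrices", {
  set.seed(101)
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(50 * 3, 5, 2), 50, 3)
    x <- as_log_expr(m)
    sets <- gene_set_collection(list(
      a = sample(rownames(x), 7),
      b = sample(rownames(x), 15),
      c = sample(rownames(x), 3)))
    for (alpha in c(0.25, 1)) {
      es <- ssgsea_scores(x, sets, alpha = alpha)
      for (nm in names(sets)) for (j in 1:3) {
        expect_equal(es[nm, j],
                     ssgsea_walk_oracle(as.matrix(x)[, j], sets[[nm]], alpha),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("enrichment is a rank statistic: determinism and monotone invariance", {
  set.seed(7)
  v <- stats::rnorm(40, 6, 2)
  m <- cbind(s1 = v, s2 = v, s3 = 2 * v + 10)   # s3: strictly monotone relabel
  rownames(m) <- sprintf("g%02d", 1:40)
  x <- as_log_expr(m)
  sets <- gene_set_collection(list(G = sample(rownames(m), 9)))
  es <- ssgsea_scores(x, sets, alpha = 0.25)
  expect_equal(es[1, "s1"], es[1, "s2"])
  expect_equal(es[1, "s1"], es[1, "s3"])
})

test_that("pushing a set gene to a higher rank never decreases the score", {
  set.seed(11)
  v <- sort(stats::rnorm(30, 5, 2))
  names(v) <- sprintf("g%02d", 1:30)
  set_genes <- c("g05", "g12", "g20")
  base <- ssgsea_scores(as_log_expr(matrix(v, dimnames = list(names(v), NULL))),
                        gene_set_collection(list(G = set_genes)), alpha = 0.25)[1, 1]
  for (rep in 1:20) {
    v2 <- v
    g <- sample(set_genes, 1)
    target <- sample(names(v)[v > v2[g]], 1)   # swap with a higher-ranked gene
    v2[c(g, target)] <- v2[c(target, g)]
    es2 <- ssgsea_scores(as_log_expr(matrix(v2, dimnames = list(names(v2), NULL))),
                         gene_set_collection(list(G = set_genes)), alpha = 0.25)[1, 1]
    expect_gte(es2, base - 1e-12)
  }
})

test_that("missing genes, tiny sets, and full-universe sets are handled", {
  set.seed(2)
  m <- matrix(stats::rnorm(20 * 2, 5), 20, 2)
  x <- as_log_expr(m)
  sets <- gene_set_collection(list(
    ok = rownames(x)[1:5],
    partial = c(rownames(x)[1:3], "NOT_A_GENE"),
    tiny = c(rownames(x)[1], "ALSO_MISSING")))
  w <- testthat::capture_warnings(es <- ssgsea_scores(x, sets))
  expect_true(any(grepl("absent", w)))
  expect_true(any(grepl("NA", w)))
  expect_false(anyNA(es["ok", ]))
  expect_false(anyNA(es["partial", ]))
  expect_true(all(is.na(es["tiny", ])))
  expect_error(
    ssgsea_scores(x, gene_set_collection(list(all = rownames(x)))),
    "complement")
})

test_that("global normalization divides by the matrix-wide score range", {
  set.seed(3)
  m <- matrix(stats::rnorm(30 * 4, 5), 30, 4)
  x <- as_log_expr(m)
  sets <- gene_set_collection(list(a = rownames(x)[1:6], b = rownames(x)[10:17]))
  raw <- ssgsea_scores(x, sets, normalize = FALSE)
  nrm <- ssgsea_scores(x, sets, normalize = TRUE)
  expect_equal(nrm, raw / diff(range(raw)), ignore_attr = TRUE)
  expect_true(attr(nrm, "normalized"))
})

test_that("cytolytic activity is the mean of GZMA and PRF1 log expression", {
  m <- rbind(GZMA = c(4, 2, 3), PRF1 = c(2, 2, 5), OTHER = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  x <- expression_matrix(m, "LOG2_TPM1")
  expect_equal(unname(cytolytic_activity(x)), c(3, 2, 4))
  x2 <- expression_matrix(m[-1, , drop = FALSE], "LOG2_TPM1")
  expect_error(cytolytic_activity(x2), "GZMA")
})

test_that("microenvironment scores satisfy the definitional sum identity", {
  set.seed(4)
  m <- matrix(stats::rnorm(40 * 3, 5), 40, 3)
  x <- as_log_expr(m)
  es <- estimate_scores(x, stromal_set = rownames(x)[1:8],
                        immune_set = rownames(x)[20:30])
  expect_equal(es$ESTIMATEScore, es$StromalScore + es$ImmuneScore)
})

test_that("stromal genes at top ranks score higher than at bottom ranks", {
  genes <- sprintf("g%02d", 1:30)
  stromal <- genes[1:6]
  top <- c(seq(10, 9, length.out = 6), seq(5, 1, length.out = 24))
  bottom <- rev(top)
  m <- cbind(top = top, bottom = bottom)
  rownames(m) <- genes
  x <- expression_matrix(m, "LOG2_TPM1")
  es <- estimate_scores(x, stromal_set = stromal, immune_set = genes[10:15])
  expect_gt(es$StromalScore[es$sample_id == "top"],
            es$StromalScore[es$sample_id == "bottom"])
})

test_that("bundled collections score with the expected cardinalities", {
  gmt7 <- read_gene_sets(system.file("extdata", "metagenes7_synthetic.gmt",
                                     package = "immclust"))
  gmt28 <- read_gene_sets(system.file("extdata", "immunecells28_synthetic.gmt",
                                      package = "immclust"))
  genes <- unique(c(unlist(gmt7), unlist(gmt28), sprintf("flr%02d", 1:20)))
  set.seed(5)
  m <- matrix(stats::rnorm(length(genes) * 3, 5, 2), length(genes), 3,
              dimnames = list(genes, paste0("s", 1:3)))
  x <- expression_matrix(m - min(m), "LOG2_TPM1")
  expect_equal(nrow(named_signature_scores(x, "metagenes7")), 7)
  expect_equal(nrow(named_signature_scores(x, "immunecells28")), 28)
  expect_error(named_signature_scores(x, "nope"), "available")
})
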