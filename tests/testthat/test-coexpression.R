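make_blocks <- function(sizes, rho, n = 100, factors = NULL, seed = 61,
                        noise_genes = 0) {
  set.seed(seed)
  if (is.null(factors))
    factors <- replicate(length(sizes), stats::rnorm(n), simplify = FALSE)
  rows <- mapply(function(m, f)
    sqrt(rho) * matrix(rep(f, each = m), m) +
      sqrt(1 - rho) * matrix(stats::rnorm(m * n), m),
    sizes, factors, SIMPLIFY = FALSE)
  xm <- do.call(rbind, rows)
  if (noise_genes > 0)
    xm <- rbind(xm, matrix(stats::rnorm(noise_genes * n), noise_genes))
  rownames(xm) <- sprintf("g%04d", seq_len(nrow(xm)))
  colnames(xm) <- sprintf("s%03d", seq_len(n))
  list(x = expression_matrix(xm - min(xm), "LOG2_TPM1"),
       block = rep(c(seq_along(sizes), if (noise_genes) 0),
                   c(sizes, if (noise_genes) noise_genes)))
}

test_that("the MAD filter keeps the top-variability quantile", {
  xm <- rbind(flat = rep(5, 6),
              lo = 5 + c(-.1, .1, 0, -.1, .1, 0),
              mid = 5 + c(-1, 1, 0, -1, 1, 0),
              hi = 5 + c(-3, 3, 0, -3, 3, 0))
  colnames(xm) <- paste0("s", 1:6)
  x <- expression_matrix(xm, "LOG2_TPM1")
  expect_identical(rownames(mad_filter(x, 0.5)), c("mid", "hi"))
  expect_identical(rownames(mad_filter(x, 1)), rownames(x))
  expect_false("flat" %in% rownames(mad_filter(x, 0.9)))
  allflat <- expression_matrix(matrix(1, 2, 6,
                                      dimnames = list(c("a", "b"),
                                                      paste0("s", 1:6))),
                               "LOG2_TPM1")
  expect_error(mad_filter(allflat), "constant")
})

test_that("TOM reproduces the printed 3-gene example and the 2-gene limit", {
  a <- rbind(c(1, .8, .2), c(.8, 1, .4), c(.2, .4, 1))
  tom <- tom_from_adjacency(a)
  expect_equal(tom[1, 2], (0.2 * 0.4 + 0.8) / (min(1, 1.2) + 1 - 0.8))
  expect_equal(tom[1, 2], 0.7333333333, tolerance = 1e-9)
  # two perfectly correlated genes
  tom2 <- tom_from_adjacency(rbind(c(1, 1), c(1, 1)))
  expect_equal(tom2[1, 2], 1)
})

test_that("TOM matches the triple-loop oracle and stays in [0, 1]", {
  set.seed(67)
  for (rep in 1:5) {
    a <- matrix(stats::runif(100), 10, 10)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_from_adjacency(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_lt(max(abs(tom - t(tom))), 1e-12)
  }
})

test_that("network construction validates input and powers the correlation", {
  b <- make_blocks(c(5, 5), rho = 0.9, n = 30)
  net <- build_network(b$x, beta = 6)
  cc <- stats::cor(t(as.matrix(b$x)))
  expect_equal(net$adjacency[1, 2], abs(cc[1, 2])^6)
  xm <- as.matrix(b$x)
  xm[1, ] <- 3
  expect_error(build_network(expression_matrix(xm, "LOG2_TPM1"), beta = 6),
               "zero-variance")
})

test_that("planted 80-gene blocks are recovered and noise yields no modules", {
  b <- make_blocks(c(80, 80), rho = 0.8, n = 100, seed = 71)
  net <- build_network(b$x, beta = 10)
  mods <- detect_modules(net, b$x, min_size = 60, deep_split = 4,
                         merge_height = 0.25)
  lab <- mods$modules
  expect_equal(sum(names(table(lab)) != "grey"), 2)
  acc <- max(mean((lab[1:80] == lab[1]) & (lab[81:160] == lab[81]) &
                    lab[1] != lab[81]), 0)
  expect_gte(mean(lab[1:80] == lab[1]), 0.95)
  expect_gte(mean(lab[81:160] == lab[81]), 0.95)
  expect_false(lab[1] == lab[81])

  noise <- make_blocks(integer(0), rho = 0.5, n = 100, seed = 73,
                       noise_genes = 300)
  netn <- build_network(noise$x, beta = 10)
  expect_warning(modn <- detect_modules(netn, noise$x, min_size = 60),
                 "unassigned")
  expect_true(all(modn$modules == "grey"))
})

test_that("blocks with highly correlated drivers merge below the merge height", {
  set.seed(79)
  n <- 100
  f1 <- stats::rnorm(n)
  f2 <- 0.95 * f1 + sqrt(1 - 0.95^2) * stats::rnorm(n)  # driver cor ~ 0.95
  b <- make_blocks(c(80, 80), rho = 0.85, n = n, factors = list(f1, f2),
                   seed = 79)
  net <- build_network(b$x, beta = 10)
  mods <- detect_modules(net, b$x, min_size = 60, merge_height = 0.25)
  expect_equal(sum(names(table(mods$modules)) != "grey"), 1)
})

test_that("eigengenes are unit-norm with a positive mean member correlation", {
  b <- make_blocks(c(70, 70), rho = 0.8, n = 80, seed = 83)
  net <- build_network(b$x, beta = 10)
  mods <- detect_modules(net, b$x, min_size = 60)
  for (m in rownames(mods$eigengenes)) {
    e <- mods$eigengenes[m, ]
    expect_equal(sum(e^2), 1)
    member <- as.matrix(b$x)[mods$modules == m, , drop = FALSE]
    kme <- apply(member, 1, function(g) stats::cor(g, e))
    expect_gt(mean(kme), 0)
  }
})

test_that("module detection is invariant under gene-order permutation", {
  b <- make_blocks(c(65, 65), rho = 0.8, n = 80, seed = 89, noise_genes = 30)
  net <- build_network(b$x, beta = 10)
  mods <- detect_modules(net, b$x, min_size = 60)
  set.seed(91)
  perm <- sample(nrow(b$x))
  xp <- as.matrix(b$x)[perm, ]
  xpe <- expression_matrix(xp, "LOG2_TPM1")
  modsp <- detect_modules(build_network(xpe, beta = 10), xpe, min_size = 60)
  agree <- table(mods$modules[rownames(xp)], modsp$modules)
  # every original module maps entirely onto one permuted module
  expect_true(all(apply(agree, 1, function(r) sum(r > 0)) == 1))
})

test_that("eigengene-trait correlation handles indicators and degenerate traits", {
  ind <- stats::setNames(rep(c(1, 0), each = 10), paste0("s", 1:20))
  fake <- structure(list(
    modules = stats::setNames("turquoise", "g1"),
    eigengenes = matrix(ind / sqrt(sum(ind^2)), 1,
                        dimnames = list("turquoise", names(ind)))),
    class = "module_set")
  out <- module_trait_correlation(fake, ind)
  expect_equal(out$r, 1)
  orth <- stats::setNames(rep(c(1, -1), 10), names(ind))  # orthogonal trait
  expect_lt(abs(module_trait_correlation(fake, orth)$r), 1e-8)
  expect_error(module_trait_correlation(
    fake, stats::setNames(rep(1, 20), names(ind))), "constant")
})

test_that("hub genes require both strict kME and a survival association", {
  set.seed(97)
  b <- make_blocks(c(70), rho = 0.9, n = 120, seed = 97, noise_genes = 10)
  net <- build_network(b$x[1:70, ], beta = 10)
  mods <- detect_modules(net, b$x[1:70, ], min_size = 60)
  mod_id <- rownames(mods$eigengenes)[1]
  e <- mods$eigengenes[mod_id, ]
  # survival driven by the eigengene: member genes are hazard-linked
  risk <- scale(e)[, 1]
  surv <- data.frame(sample_id = names(e),
                     time_days = pmax(stats::rexp(120, exp(1.2 * risk) / 500), 31),
                     event = 1)
  hb <- hub_genes(b$x, mods, mod_id, surv, kme_thresh = 0.85, p_thresh = 0.05)
  expect_gt(sum(hb$selected), 0)
  expect_true(all(hb$kme[hb$selected] > 0.85))
  expect_true(all(hb$cox_p[hb$selected] < 0.05))
  # strictness of the kME bound: a gene at exactly the threshold is excluded
  hb1 <- hub_genes(b$x, mods, mod_id, surv, kme_thresh = 1, p_thresh = 0.5)
  expect_equal(sum(hb1$selected), 0)
  expect_error(hub_genes(b$x, mods, "ghost", surv), "empty or unknown")
})
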