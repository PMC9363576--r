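test_that("log-rank behaves at the null and under dominance", {
  # two identical groups: statistic ~ 0, p ~ 1
  surv <- data.frame(sample_id = paste0("s", 1:8),
                     time_days = rep(c(100, 200, 300, 400), 2),
                     event = rep(1, 8))
  assign <- stats::setNames(rep(c("A", "B"), each = 4), surv$sample_id)
  out <- km_logrank(surv, assign)
  expect_lt(out$chisq, 1e-10)
  expect_gt(out$p_value, 0.999)

  # dominated group: its curve reaches 0 while the other stays at 1
  surv2 <- data.frame(sample_id = paste0("s", 1:6),
                      time_days = c(31, 32, 33, 1000, 1000, 1000),
                      event = c(1, 1, 1, 0, 0, 0))
  assign2 <- stats::setNames(rep(c("A", "B"), each = 3), surv2$sample_id)
  out2 <- km_logrank(surv2, assign2)
  expect_equal(min(out2$curves$survival[out2$curves$label == "A"]), 0)
  expect_true(all(out2$curves$label != "B"))   # no events in B: curve stays 1
  expect_lt(out2$p_value, 0.05)
  expect_error(km_logrank(surv2, assign2[1:3]), "2 subtypes")
})

test_that("the KM estimator without censoring equals the empirical survivor function", {
  set.seed(41)
  t1 <- sort(sample(31:500, 20))
  surv <- data.frame(sample_id = paste0("s", 1:40),
                     time_days = c(t1, t1 + 3), event = 1)
  assign <- stats::setNames(rep(c("A", "B"), each = 20), surv$sample_id)
  out <- km_logrank(surv, assign)
  ca <- out$curves[out$curves$label == "A", ]
  expect_equal(ca$survival,
               vapply(ca$time, function(tt) mean(t1 > tt), 0))
})

test_that("TMB counts the configured nonsilent classes and is additive", {
  muts <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s3"),
    gene = c("TP53", "KRAS", "APC", "TP53", "BRAF"),
    variant_class = c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                      "Missense_Mutation", "Silent"))
  out <- tmb(muts, c("s1", "s2", "s3", "s4"),
             nonsilent_classes = c("Missense_Mutation", "Nonsense_Mutation"))
  expect_equal(as.numeric(out), c(2, 1, 0, 0))
  expect_identical(attr(out, "flagged"), "s4")

  empty <- tmb(muts[0, ], c("s1", "s2"))
  expect_equal(as.numeric(empty), c(0, 0))

  per_mb <- tmb(data.frame(sample_id = rep("s1", 76), gene = "G",
                           variant_class = "Missense_Mutation"),
                "s1", denominator_mb = 38)
  expect_equal(as.numeric(per_mb), 2)

  # additivity over a disjoint partition of the record table
  part1 <- tmb(muts[1:2, ], c("s1", "s2", "s3"))
  part2 <- tmb(muts[3:5, ], c("s1", "s2", "s3"))
  full <- tmb(muts, c("s1", "s2", "s3"))
  expect_equal(as.numeric(part1) + as.numeric(part2), as.numeric(full))
})

test_that("the mutation screen reproduces a hand-computed 2x3 chi-square", {
  assign <- stats::setNames(rep(c("IS1", "IS2", "IS3"), each = 20),
                            paste0("s", 1:60))
  muts <- data.frame(sample_id = paste0("s", 1:10), gene = "GENEX",
                     variant_class = "Missense_Mutation")
  out <- mutation_frequency_test(muts, assign)
  # observed table: mutated (10, 0, 0), wild (10, 20, 20)
  obs <- rbind(c(10, 0, 0), c(10, 20, 20))
  expect_col <- rowSums(obs) %o% colSums(obs) / sum(obs)
  stat <- sum((obs - expect_col)^2 / expect_col)
  expect_equal(out$chi_square_p, stats::pchisq(stat, 2, lower.tail = FALSE))
  expect_true(out$passes_min_count)
})

test_that("the strict >3 count filter and the null behave as specified", {
  assign <- stats::setNames(rep(c("IS1", "IS2"), each = 30), paste0("s", 1:60))
  # exactly 3 carriers in each subtype: excluded by the strict rule
  muts3 <- data.frame(sample_id = c(paste0("s", 1:3), paste0("s", 31:33)),
                      gene = "LOWFREQ", variant_class = "Missense_Mutation")
  out3 <- mutation_frequency_test(muts3, assign)
  expect_false(out3$passes_min_count)
  expect_true(is.na(out3$chi_square_p))

  # identical rates across subtypes: p near 1
  muts_eq <- data.frame(sample_id = c(paste0("s", 1:10), paste0("s", 31:40)),
                        gene = "EQ", variant_class = "Missense_Mutation")
  out_eq <- mutation_frequency_test(muts_eq, assign)
  expect_gt(out_eq$chi_square_p, 0.99)
})

test_that("group comparisons match the hand-ranked Kruskal-Wallis statistic", {
  vals <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 1,
                 dimnames = list("f", paste0("s", 1:9)))
  assign <- stats::setNames(rep(c("A", "B", "C"), each = 3), paste0("s", 1:9))
  out <- compare_across_subtypes(vals, "f", assign)
  # ranks within ties: groups occupy average ranks 2, 5, 8
  stat <- 12 / (9 * 10) * 3 * ((2 - 5)^2 + 0 + (8 - 5)^2)
  stat <- stat / (1 - (3 * (27 - 3)) / (9^3 - 9))   # tie correction
  expect_equal(out$kruskal_wallis_p, stats::pchisq(stat, 2, lower.tail = FALSE))
  expect_true(all(grepl("^p_", names(out)[3:5])))
})

test_that("identical groups are non-significant and absent features are skipped", {
  set.seed(43)
  v <- stats::rnorm(30)
  vals <- matrix(c(v, v), 2, byrow = TRUE,
                 dimnames = list(c("fa", "fb"), paste0("s", 1:30)))
  assign <- stats::setNames(rep(c("A", "B", "C"), 10), paste0("s", 1:30))
  expect_warning(out <- compare_across_subtypes(vals, c("fa", "ghost"), assign),
                 "ghost")
  expect_equal(nrow(out), 1)
  expect_gt(out$kruskal_wallis_p, 0.05)
  bh <- compare_across_subtypes(vals, c("fa", "fb"), assign, adjust = "BH")
  expect_true(all(bh$adjusted))
})

test_that("Kruskal-Wallis holds its nominal type-I error rate", {
  set.seed(47)
  assign <- stats::setNames(rep(c("A", "B", "C"), each = 15), paste0("s", 1:45))
  rej <- 0
  nrep <- 400
  for (r in seq_len(nrep)) {
    vals <- matrix(stats::rnorm(45), 1, dimnames = list("f", names(assign)))
    rej <- rej + (compare_across_subtypes(vals, "f", assign)$kruskal_wallis_p < 0.05)
  }
  expect_gt(rej / nrep, 0.02)
  expect_lt(rej / nrep, 0.08)
})

test_that("Fisher's exact p equals exhaustive hypergeometric enumeration", {
  fac <- stats::setNames(rep(c("x", "y"), c(10, 10)), paste0("s", 1:20))
  assign <- stats::setNames(rep("IS1", 20), paste0("s", 1:20))
  assign[c(paste0("s", 1:8), "s11")] <- "IS2"   # table [[8,2],[1,9]]
  out <- categorical_association(fac, assign)
  expect_identical(out$method, "fisher_exact")
  # enumerate all tables with the observed margins
  tab <- table(fac, assign)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  probs <- vapply(0:min(rs[1], cs[1]), function(a) {
    stats::dhyper(a, rs[1], rs[2], cs[1])
  }, 0)
  p_hand <- sum(probs[probs <= probs[tab[1, 1] + 1] * (1 + 1e-7)])
  expect_equal(out$p_value, p_hand)
})

test_that("larger tables use chi-square or seeded Monte-Carlo Fisher", {
  set.seed(53)
  fac <- stats::setNames(sample(c("x", "y", "z"), 90, replace = TRUE),
                         paste0("s", 1:90))
  assign <- stats::setNames(sample(c("IS1", "IS2", "IS3"), 90, replace = TRUE),
                            paste0("s", 1:90))
  out <- categorical_association(fac, assign)
  expect_identical(out$method, "chi_square")
  m1 <- categorical_association(fac, assign, simulate = TRUE, seed = 7)
  m2 <- categorical_association(fac, assign, simulate = TRUE, seed = 7)
  expect_identical(m1$p_value, m2$p_value)
  expect_identical(m1$method, "fisher_montecarlo")

  expect_warning(deg <- categorical_association(
    stats::setNames(rep("x", 90), names(fac)), assign), "degenerate")
  expect_equal(deg$p_value, 1)
})
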