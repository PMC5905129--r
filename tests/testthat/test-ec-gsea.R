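test_that("snr_metric matches the floored formula and is antisymmetric", {
  # hand evaluation: sd_a = max(0, 0.2*1, 0.005) = 0.2; sd_b = 0.005
  expect_equal(snr_metric(c(1, 1, 1), c(0, 0, 0)), 1 / (0.2 + 0.005))
  a <- c(2.1, 2.5, 1.9, 2.3); b <- c(1.1, 0.7, 1.4)
  expect_equal(snr_metric(a, b),
               (mean(a) - mean(b)) /
                 (max(sd(a), 0.2 * mean(a), 0.005) +
                    max(sd(b), 0.2 * mean(b), 0.005)))
  expect_equal(snr_metric(a, a), 0)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(7, 1)
    expect_equal(snr_metric(x, y), -snr_metric(y, x))
  }
  expect_error(snr_metric(1, c(1, 2)), ">= 2")
})

make_tiny_dataset <- function(X, probe_gene, gene_ec,
                              classes = rep(c("MUT", "WT"), each = 3)) {
  expression_dataset(X, factor(classes, unique(classes)), probe_gene, gene_ec)
}

test_that("collapse_to_nodes retains the max-|SNR| probeset per EC", {
  # two probes on one EC with metrics of opposite sign: the larger |SNR| wins
  set.seed(4)
  X <- rbind(p1 = c(1, 1.1, 0.9, 0.5, 0.6, 0.4),   # positive SNR
             p2 = c(0.1, 0.2, 0.0, 1.5, 1.6, 1.4), # strong negative SNR
             p3 = rnorm(6))
  ds <- make_tiny_dataset(
    X,
    data.frame(probe = c("p1", "p2", "p3"), gene = c("gA", "gA", "gB")),
    data.frame(gene = c("gA", "gB"), ec = c("ec1", "ec2")))
  ranked <- collapse_to_nodes(ds)
  cls <- ds$classes
  m1 <- snr_metric(X["p1", cls == "MUT"], X["p1", cls == "WT"])
  m2 <- snr_metric(X["p2", cls == "MUT"], X["p2", cls == "WT"])
  expect_true(abs(m2) > abs(m1))
  expect_equal(ranked$metric[ranked$node == "ec1"], m2)  # signed value kept
  # single-probe EC keeps its own metric
  m3 <- snr_metric(X["p3", cls == "MUT"], X["p3", cls == "WT"])
  expect_equal(ranked$metric[ranked$node == "ec2"], m3)
})

test_that("multi-EC genes contribute probesets to every EC", {
  set.seed(9)
  X <- matrix(rnorm(3 * 6), 3, dimnames = list(paste0("p", 1:3), NULL))
  ds <- make_tiny_dataset(
    X,
    data.frame(probe = paste0("p", 1:3), gene = c("gA", "gA", "gB")),
    data.frame(gene = c("gA", "gA", "gB"), ec = c("ec1", "ec2", "ec2")))
  ranked <- collapse_to_nodes(ds)
  expect_setequal(ranked$node, c("ec1", "ec2"))
  # ec2 candidates are p1, p2 (via gA) and p3 (via gB)
  cls <- ds$classes
  mets <- apply(X, 1, function(v) snr_metric(v[cls == "MUT"], v[cls == "WT"]))
  expect_equal(ranked$metric[ranked$node == "ec2"],
               mets[which.max(abs(mets))][[1]])
})

test_that("collapse_to_nodes is invariant to probe row order", {
  set.seed(21)
  X <- matrix(rnorm(8 * 8), 8, dimnames = list(paste0("p", 1:8), NULL))
  pg <- data.frame(probe = paste0("p", 1:8),
                   gene = rep(c("gA", "gB", "gC", "gD"), each = 2))
  ge <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                   ec = c("ec1", "ec1", "ec2", "ec3"))
  cls <- rep(c("MUT", "WT"), each = 4)
  r1 <- collapse_to_nodes(make_tiny_dataset(X, pg, ge, cls))
  perm <- sample(nrow(X))
  r2 <- collapse_to_nodes(make_tiny_dataset(X[perm, ], pg[rev(seq_len(8)), ],
                                            ge, cls))
  expect_equal(r1, r2)
})

test_that("enrichment_score equals the brute-force walk on random instances", {
  set.seed(101)
  for (i in 1:60) {
    N <- sample(5:50, 1)
    ranked <- random_ranked(N)
    k <- sample(seq_len(N - 1), 1)
    set <- sample(ranked$node, k)
    q <- sample(c(0, 1, 2), 1)
    expect_equal(enrichment_score(ranked, set, q),
                 brute_force_es(ranked, set, q), tolerance = 1e-12)
  }
})

test_that("enrichment_score handles the documented edge cases", {
  ranked <- ranked_node_list(paste0("n", 1:5), c(5, 4, 3, 2, 1))
  # top-k prefix with unweighted statistic peaks at 1
  expect_equal(enrichment_score(ranked, c("n1", "n2"), 0), 1)
  # hand-checkable 5-node walk, hits at ranks 1 and 4, weight exponent 1
  expect_equal(enrichment_score(ranked, c("n1", "n4"), 1),
               brute_force_es(ranked, c("n1", "n4"), 1))
  # all nodes hit: defined as 1
  expect_equal(enrichment_score(ranked, ranked$node), 1)
  expect_error(enrichment_score(ranked, "absent"), "not represented")
  # |ES| never exceeds 1, and q = 0 is invariant to a constant metric shift
  set.seed(33)
  for (i in 1:25) {
    ranked <- random_ranked(20)
    set <- sample(ranked$node, 6)
    es <- enrichment_score(ranked, set, 1)
    expect_lte(abs(es), 1)
    shifted <- ranked_node_list(ranked$node, ranked$metric + 7.3)
    expect_equal(enrichment_score(shifted, set, 0),
                 enrichment_score(ranked, set, 0), tolerance = 1e-12)
  }
})

test_that("filter_modules applies inclusive 3..500 bounds and is idempotent", {
  ranked <- ranked_node_list(sprintf("ec%03d", 1:30), rnorm(30))
  sets <- node_set_collection(list(
    two = sprintf("ec%03d", 1:2),
    three = sprintf("ec%03d", 1:3),
    six_half_missing = c(sprintf("ec%03d", 1:3), "x1", "x2", "x3"),
    big = c(sprintf("ec%03d", 1:30), sprintf("zz%03d", 1:480))))
  kept <- filter_modules(sets, ranked)
  expect_setequal(names(kept), c("three", "six_half_missing", "big"))
  # "represented" counts only nodes present in the ranked list
  expect_equal(sum(kept$six_half_missing %in% ranked$node), 3L)
  expect_equal(filter_modules(kept, ranked), kept)
  # above max: 501 represented nodes excluded
  ranked_big <- ranked_node_list(sprintf("ec%04d", 1:501), rnorm(501))
  expect_length(filter_modules(node_set_collection(
    list(huge = sprintf("ec%04d", 1:501))), ranked_big), 0L)
})

test_that("permutation NES preserves the ES sign and is seed-deterministic", {
  ns <- make_collection(6, 8, 60)
  ds <- gen_expression_dataset(200, c(10, 10), ns,
                               expression_truth(setNames(1, names(ns)[1]),
                                                effect_size = 2, seed = 5))
  r1 <- run_gsea(ds, ns, n_perm = 100, seed = 17)
  r2 <- run_gsea(ds, ns, n_perm = 100, seed = 17)
  expect_identical(r1, r2)
  expect_true(all(sign(r1$nes[!r1$flagged]) == sign(r1$es[!r1$flagged])))
  expect_true(all(r1$p >= 0 & r1$p <= 1))
  expect_equal(r1$enriched_in[r1$es >= 0][1], "MUT")
  # the planted module should rise to the top here
  expect_equal(r1$module[which.max(r1$nes)], names(ns)[1])
  expect_error(run_gsea(ds, ns, n_perm = 50), ">= 100")
})

test_that("node-set permutation engages when a class is small", {
  ns <- make_collection(4, 6, 40)
  ds <- gen_expression_dataset(150, c(4, 12), ns,
                               expression_truth(seed = 2))
  res <- run_gsea(ds, ns, n_perm = 100, seed = 3)  # auto -> nodeset (4 < 7)
  expect_true(all(is.finite(res$p)))
  res2 <- run_gsea(ds, ns, n_perm = 100, seed = 3, perm_mode = "nodeset")
  expect_identical(res, res2)
})

test_that("cross_dataset_concordance handles identity and antisymmetry", {
  enr <- data.frame(module = paste0("m", 1:6),
                    nes = c(2.1, -1.8, 0.4, 1.3, -0.2, -1.25))
  self <- cross_dataset_concordance(enr, enr, tau = 1.2)
  expect_equal(self$pearson, 1)
  expect_setequal(self$shared_up, c("m1", "m4"))
  expect_setequal(self$shared_down, c("m2", "m6"))
  flipped <- enr; flipped$nes <- -flipped$nes
  anti <- cross_dataset_concordance(enr, flipped, tau = 1.2)
  expect_equal(anti$pearson, -1)
  expect_length(anti$shared_up, 0)
  expect_length(anti$shared_down, 0)
  # intersection only, and a minimum of 3 common modules
  expect_error(cross_dataset_concordance(enr[1:2, ], enr), ">= 3")
  sub <- cross_dataset_concordance(enr, enr[c(1, 3, 5), ])
  expect_equal(nrow(sub$pairs), 3L)
})
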