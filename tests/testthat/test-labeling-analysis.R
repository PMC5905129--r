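sim_index <- function(n_met, groups, delta = 0, noise = 0.02, base = 0.3,
                      seed = 1) {
  withr::with_seed(seed, {
    n <- length(groups)
    shift <- ifelse(groups == groups[1], delta / 2, -delta / 2)
    mat <- matrix(base + rnorm(n_met * n, 0, noise), n_met, n, byrow = FALSE)
    mat <- sweep(mat, 2, shift, "+")
    dimnames(mat) <- list(sprintf("met%03d", seq_len(n_met)),
                          sprintf("s%02d", seq_len(n)))
    structure(mat, valid = rep(TRUE, n_met),
              class = c("labeling_index", "matrix"))
  })
}

test_that("cluster_partition separates shifted groups and respects duplicates", {
  groups <- rep(c("MUT", "WT"), each = 3)
  idx <- sim_index(15, groups, delta = 0.2, noise = 0.02, seed = 5)
  part <- cluster_partition(idx, k = 2, labels = groups)
  expect_equal(part$ari, 1)
  pam_part <- cluster_partition(idx, k = 2, method = "kmedoids",
                                labels = groups, seed = 9)
  expect_equal(pam_part$ari, 1)
  # duplicated samples always co-cluster
  dup <- cbind(idx, idx)
  colnames(dup) <- paste0("s", seq_len(ncol(dup)))
  pd <- cluster_partition(structure(dup, valid = attr(idx, "valid"),
                                    class = class(idx)), k = 2)
  expect_equal(pd$assignment[1:6], pd$assignment[7:12], ignore_attr = TRUE)
  expect_error(cluster_partition(idx, k = 10), "exceeds")
  # metabolites with invalid values are dropped listwise
  idx2 <- idx; idx2[1, 1] <- NA
  p2 <- cluster_partition(idx2, k = 2, labels = groups)
  expect_equal(p2$n_metabolites_used, 14L)
  expect_equal(p2$ari, 1)
})

test_that("adjusted_rand_index is invariant to relabeling and sample order", {
  a <- c(1, 1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c("z", "z", "z", "q", "q", "k")), 1)
  set.seed(14)
  for (i in 1:10) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:3, 12, replace = TRUE)
    o <- sample(12)
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(x[o], y[o]))
    expect_equal(adjusted_rand_index(x, y),
                 adjusted_rand_index(x, c(9, 7, 5)[y]))
  }
})

test_that("differential_labeling matches the textbook pooled-t oracle", {
  groups <- rep(c("A", "B"), each = 3)
  idx <- sim_index(10, groups, delta = 0.05, seed = 8)
  res <- differential_labeling(idx, groups)
  for (m in rownames(idx)) {
    o <- pooled_t_oracle(idx[m, 1:3], idx[m, 4:6])
    row <- res[res$metabolite == m, ]
    expect_equal(row$t, o$t, tolerance = 1e-10)
    expect_equal(row$p, o$p, tolerance = 1e-10)
    # cross-check against the independent base implementation
    tt <- t.test(idx[m, 1:3], idx[m, 4:6], var.equal = TRUE)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
  expect_true(all(res$significant == (res$p < 0.05)))
})

test_that("differential_labeling is invariant to group relabeling", {
  groups <- rep(c("A", "B"), each = 4)
  idx <- sim_index(8, groups, delta = 0.1, seed = 3)
  r1 <- differential_labeling(idx, groups)
  r2 <- differential_labeling(idx, rev(groups))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$t, -r2$t)
  # degenerate inputs: identical values -> t = 0, p = 1
  idx0 <- sim_index(2, groups, noise = 0, seed = 1)
  r0 <- differential_labeling(idx0, groups)
  expect_equal(r0$t, c(0, 0))
  expect_equal(r0$p, c(1, 1))
  # zero variance but unequal means -> p -> 0, flagged degenerate
  idxc <- idx0; idxc[1, groups == "A"] <- 0.5
  rc <- differential_labeling(idxc, groups)
  expect_equal(rc$p[1], 0)
  expect_true(rc$degenerate[1])
})

test_that("chi-square over-representation matches the contingency oracle", {
  set.seed(6)
  universe <- sprintf("met%03d", 1:159)
  for (i in 1:15) {
    sig <- sample(universe, sample(10:50, 1))
    cat_set <- sample(universe, sample(10:50, 1))
    enr <- category_overrepresentation(sig, cat_set, universe)
    a <- length(intersect(sig, cat_set)); b <- length(setdiff(sig, cat_set))
    cc <- length(setdiff(cat_set, sig)); d <- 159 - a - b - cc
    expect_equal(enr$chi2, chi2_oracle(a, b, cc, d), tolerance = 1e-10)
    # and against the independent base implementation
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (all(tab > 0)) {
      expect_equal(enr$chi2,
                   unname(suppressWarnings(
                     chisq.test(tab, correct = FALSE)$statistic)),
                   tolerance = 1e-10)
    }
  }
})

test_that("chi-square edge behaviour: independence, perfect overlap, Yates", {
  universe <- sprintf("m%02d", 1:40)
  # proportional margins => exact independence => statistic 0
  enr0 <- category_overrepresentation(universe[1:20], universe[c(1:10, 21:30)],
                                      universe)
  expect_equal(enr0$chi2, 0)
  # perfect overlap attains the margin-fixed maximum (= N)
  enr1 <- category_overrepresentation(universe[1:10], universe[1:10], universe)
  expect_equal(enr1$chi2, 40)
  yates <- category_overrepresentation(universe[1:10], universe[1:10],
                                       universe, correction = "yates")
  expect_lt(yates$chi2, enr1$chi2)
  expect_warning(
    category_overrepresentation(universe[1], universe[2], universe[1:8]),
    "expected cell")
  expect_error(category_overrepresentation("zzz", universe[1], universe),
               "universe")
})
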