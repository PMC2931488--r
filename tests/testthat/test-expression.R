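test_that("quantile normalization maps columns onto the mean quantile distribution", {
  # hand example: columns (1,3) and (2,6) both become (1.5, 4.5)
  m <- cbind(a = c(1, 3), b = c(2, 6))
  qn <- quantile_normalize(m, log2 = FALSE)
  expect_equal(unname(qn[, "a"]), c(1.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 4.5))

  # identical columns are unchanged up to the log2 transform
  m2 <- cbind(x = c(2, 8, 4), y = c(2, 8, 4))
  expect_equal(quantile_normalize(m2), log2(m2))

  # post-condition: all columns share the same sorted values
  set.seed(9)
  m3 <- matrix(2^rnorm(600, 9, 2), 100, 6)
  qn3 <- quantile_normalize(m3)
  ref <- sort(qn3[, 1])
  for (j in 2:6) expect_equal(sort(qn3[, j]), ref, tolerance = 1e-12)
  # ranks preserved within columns
  expect_equal(apply(qn3, 2, rank), apply(m3, 2, rank))
  expect_error(quantile_normalize(cbind(c(1, -2), c(3, 4))), "positive")
})

test_that("probe filtering applies the outlier and 30% presence rules", {
  m <- matrix(2, 3, 11, dimnames = list(c("p1", "p2", "p3"), NULL))
  f <- matrix(0, 3, 11, dimnames = dimnames(m))
  expect_identical(filter_probes(m, f), m)

  # present in 3 of 11 samples (27%) -> removed; 4 of 11 (36%) -> kept
  f2 <- f
  f2["p2", 1:8] <- 1   # present in 3/11
  f2["p3", 1:7] <- 1   # present in 4/11
  # p2/p3 exceed the 50% probe-flag rule too, so isolate the presence rule
  kept <- filter_probes(m, f2, probe_flag_threshold = 1)
  expect_false("p2" %in% rownames(kept))
  expect_true("p3" %in% rownames(kept))
  # flagged cells of retained probes become missing
  expect_equal(sum(is.na(kept["p3", ])), 7L)

  # a probe flagged in most samples is dropped outright
  f3 <- f
  f3["p1", 1:6] <- 1
  expect_false("p1" %in% rownames(filter_probes(m, f3)))

  expect_warning(out <- filter_probes(m, matrix(1, 3, 11)), "all probes")
  expect_equal(nrow(out), 0L)
})

test_that("probe collapsing averages duplicates and keeps the highest-IQR probe", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene = c("A", "B", "B"))
  m <- rbind(p1 = c(1, 2, 3, 4),
             p2 = c(5, 5.5, 6, 6.5),     # IQR 0.75
             p3 = c(1, 3, 5, 7))         # IQR 3
  out <- collapse_probes(m, ann)
  expect_equal(rownames(out), c("A", "B"))
  expect_equal(unname(out["B", ]), unname(m["p3", ]))
  expect_equal(attr(out, "probe_id")[["B"]], "p3")

  # identical probe ids are averaged row-wise
  m2 <- rbind(p1 = c(1, 2, 3, 4), p1 = c(3, 4, 5, 6))
  out2 <- collapse_probes(m2, data.frame(probe_id = "p1", gene = "A"))
  expect_equal(unname(out2["A", ]), c(2, 3, 4, 5))

  # one probe per transcript is the identity
  out3 <- collapse_probes(m["p1", , drop = FALSE],
                          data.frame(probe_id = "p1", gene = "A"))
  expect_equal(unname(out3["A", ]), unname(m["p1", ]))
})

test_that("moderated t reduces to the ordinary pooled t without shrinkage", {
  set.seed(14)
  mat <- matrix(rnorm(40 * 9, 8, 1), 40, 9,
                dimnames = list(sprintf("g%02d", 1:40), NULL))
  groups <- c(rep("A", 5), rep("B", 4))
  off <- fit_moderated_t(mat, groups, prior_df = 0)
  for (g in c(1, 7, 40)) {
    ref <- pooled_t_test(mat[g, 1:5], mat[g, 6:9])
    expect_equal(off$results$moderated_t[g], ref$t_statistic,
                 tolerance = 1e-10)
    expect_equal(off$results$p_value[g], ref$p_value, tolerance = 1e-10)
    expect_equal(off$results$df_total[g], ref$df)
  }
})

test_that("infinite prior degrees of freedom give every gene the common variance", {
  set.seed(15)
  mat <- matrix(rnorm(30 * 9, 8, 1), 30, 9)
  groups <- c(rep("A", 5), rep("B", 4))
  fit <- fit_moderated_t(mat, groups, prior_df = Inf, prior_var = 0.8)
  se <- fit$results$log2fc / fit$results$moderated_t
  expect_equal(se, rep(sqrt(0.8 * (1 / 5 + 1 / 4)), 30), tolerance = 1e-10)
  expect_true(all(is.infinite(fit$results$df_total)))
})

test_that("the empirical-Bayes fit matches the established reference implementation", {
  set.seed(42)
  mat <- matrix(rnorm(200 * 11, 9, 1), 200, 11,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  mat[1:10, 1:6] <- mat[1:10, 1:6] + 1
  # heterogeneous gene variances so the prior df is finite
  mat[101:200, ] <- mat[101:200, ] * 3
  groups <- c(rep("A", 6), rep("B", 5))
  ours <- fit_moderated_t(mat, groups)
  design <- cbind(A = as.numeric(groups == "A"),
                  B = as.numeric(groups == "B"))
  lf <- limma::contrasts.fit(limma::lmFit(mat, design),
                             limma::makeContrasts(A - B, levels = c("A", "B")))
  eb <- limma::eBayes(lf)
  expect_true(is.finite(ours$prior_df))
  expect_equal(ours$prior_df, eb$df.prior, tolerance = 0.05)
  expect_equal(ours$prior_var, eb$s2.prior, tolerance = 0.05)
  expect_equal(coef(ours), eb$coefficients[, 1], tolerance = 1e-10)
  expect_lt(max(abs(ours$results$moderated_t - eb$t[, 1])), 0.05)
  expect_lt(max(abs(ours$results$p_value - eb$p.value[, 1])), 0.005)
})

test_that("moderated-t preconditions are enforced", {
  mat <- matrix(rnorm(5 * 6), 5, 6)
  expect_error(fit_moderated_t(mat, rep(c("A", "B"), each = 3)),
               "at least 10 genes")
  mat2 <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fit_moderated_t(mat2, c("A", "A", "B")), "at least 2")
  expect_error(fit_moderated_t(matrix(rnorm(40), 10, 4),
                               rep("A", 4)), "two groups")
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("panel selection keeps exactly the panel genes present on the array", {
  res <- data.frame(gene = sprintf("G%03d", 1:150),
                    log2fc = rnorm(150), p_value = runif(150))
  panel <- c(sprintf("G%03d", 1:117), "ABSENT1", "ABSENT2")  # 119 listed
  sel <- select_panel(res, panel)
  expect_equal(nrow(sel), 117L)
  expect_equal(attr(sel, "n_found"), 117L)
  expect_equal(select_panel(res, res$gene)$gene, res$gene)
  expect_error(select_panel(res, c("NOPE1", "NOPE2")), "no panel genes")
})

test_that("hierarchical clustering uses complete linkage on centered rows", {
  # two identical genes merge at height zero
  m <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3), g3 = c(9, 1, 4))
  cl <- cluster_heatmap(m)
  expect_equal(min(cl$row_hclust$height), 0)

  # three collinear points 0, 1, 10 (duplicated columns): first merge
  # (0, 1), second at Euclidean height 10 * sqrt(2)
  m2 <- rbind(a = c(0, 0), b = c(1, 1), c = c(10, 10))
  cl2 <- cluster_heatmap(m2, center = FALSE)
  expect_equal(cl2$row_hclust$height, c(sqrt(2), 10 * sqrt(2)))
  expect_equal(sort(cl2$row_hclust$merge[1, ]), c(-2, -1))

  # row centering
  set.seed(6)
  m3 <- matrix(rnorm(60, 5), 10, 6,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  cl3 <- cluster_heatmap(m3)
  expect_lt(max(abs(rowMeans(cl3$matrix))), 1e-12)
  # Newick serializations carry all leaves
  expect_true(all(vapply(sprintf("g%02d", 1:10), grepl, logical(1),
                         x = cl3$row_newick, fixed = TRUE)))
  expect_error(cluster_heatmap(m3[1, , drop = FALSE]), "at least 2")
})

test_that("differential-expression results are invariant to probe order", {
  spec <- expression_sim_spec(n_genes = 60, true_log2fc = c(PLA2G4A = 2),
                              flagged_fraction = 0.02, seed = 12)
  sim <- simulate_expression(spec)
  run <- function(perm) {
    ints <- sim$intensities[perm, , drop = FALSE]
    norm <- quantile_normalize(ints)
    filt <- filter_probes(norm, sim$flags[rownames(norm), , drop = FALSE])
    coll <- collapse_probes(filt, sim$annotation)
    fit <- fit_moderated_t(coll, sim$groups)
    fit$results[order(fit$results$gene), ]
  }
  set.seed(77)
  perm <- sample(nrow(sim$intensities))
  straight <- run(seq_len(nrow(sim$intensities)))
  shuffled <- run(perm)
  expect_equal(shuffled, straight, tolerance = 1e-12)
})

test_that("null simulations keep the family-wise detection rate near alpha", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    base <- rnorm(117, 9, 2)
    mat <- matrix(rnorm(117 * 11, 0, 0.25), 117, 11,
                  dimnames = list(sprintf("g%03d", 1:117), NULL)) + base
    fit <- fit_moderated_t(mat, c(rep("A", 6), rep("B", 5)))
    if (any(fit$results$significant)) hits <- hits + 1L
  }
  rate <- hits / 200
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("planted strong effects are all detected at 5% FDR", {
  fx <- strong_panel_effects()
  out <- run_expression_pipeline(list(seed = 2, true_log2fc = fx))
  r <- out$fit$results
  expect_equal(sum(r$significant[r$gene %in% names(fx)]), 67L)
})
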