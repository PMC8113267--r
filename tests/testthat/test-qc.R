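mk_totals_matrix <- function(totals) {
  # one gene per library carrying the full total, plus padding genes
  G <- length(totals) + 1
  m <- matrix(0L, G, length(totals),
              dimnames = list(sprintf("g%02d", seq_len(G)),
                              sprintf("L%02d", seq_along(totals))))
  for (j in seq_along(totals)) m[j, j] <- totals[j]
  count_matrix(m)
}

test_that("UMI classifier reproduces the 35,000 / 9,500 thresholds bit-exactly", {
  totals <- c(40000, 9499, 20000, 35000, 35001, 9500, 1)
  ann <- classify_library_kind(mk_totals_matrix(totals))
  expect_identical(ann$kind, c("cluster", "single", "ambiguous",
                               "ambiguous", "cluster", "ambiguous",
                               "single"))
  # monotone in thresholds: loosening the cluster gate only adds clusters
  ann2 <- classify_library_kind(mk_totals_matrix(totals),
                                qc_thresholds(cluster_umi_min = 30000))
  expect_true(all(ann$kind != "cluster" | ann2$kind == "cluster"))
  expect_error(qc_thresholds(cluster_umi_min = 5000, single_umi_max = 9500),
               "cluster_umi_min")
})

test_that("basic_filters removes low-gene and high-mito libraries and is idempotent", {
  set.seed(8)
  m <- rand_counts(300, 6, lambda = 2)
  gt <- gene_table(rownames(m), mitochondrial = seq_len(300) <= 5)
  raw <- as.matrix(m)
  raw[, 2] <- 0; raw[1:150, 2] <- 1L          # 150 detected genes -> out
  raw[, 4] <- 0; raw[6:300, 4] <- 1L          # clean library
  raw[1:5, 5] <- 60L                          # mito-heavy -> out
  m <- count_matrix(raw)
  res <- basic_filters(m, thresholds = qc_thresholds(), gene_table = gt)
  expect_setequal(res$report$library_id, colnames(m)[c(2, 5)])
  expect_identical(sort(res$report$reason[order(res$report$library_id)]),
                   sort(c("low_genes", "high_mito")))
  res2 <- basic_filters(res$counts, res$annotation,
                        gene_table = gt)
  expect_identical(as.matrix(res2$counts), as.matrix(res$counts))
  expect_equal(nrow(res2$report), 0)
  # all failing -> explicit error
  tiny <- count_matrix(matrix(1L, 2, 2, dimnames = list(c("a", "b"),
                                                        c("x", "y"))))
  expect_error(basic_filters(tiny), "empty after QC")
})

test_that("estimate_cluster_sizes applies the ratio rule with floor 2", {
  totals <- c(rep(6000, 11), 36000, 8000)
  m <- mk_totals_matrix(totals)
  ann <- library_annotation(m)
  ann$kind <- c(rep("single", 11), "cluster", "cluster")
  out <- estimate_cluster_sizes(m, ann)
  expect_equal(out$est_cells[12], 6L)
  expect_equal(out$est_cells[13], 2L)         # 1.33 rounds to 1, floored
  expect_true(all(is.na(out$est_cells[1:11])))
  ann$kind <- rep("cluster", 13)
  expect_error(estimate_cluster_sizes(m, ann), "no single libraries")
})

test_that("est_cells tracks the true member count on simulated data", {
  d <- generate_dataset(tissue_model(), 150, 120, seed = 17)
  ann <- d$annotation
  ann <- estimate_cluster_sizes(d$counts, ann)
  cl <- ann$kind == "cluster"
  expect_lt(abs(mean(ann$est_cells[cl]) -
                  mean(d$truth$n_members[d$truth$kind == "cluster"])), 1.0)
})

test_that("simulated single/cluster kinds are recovered from UMI totals", {
  d <- generate_dataset(tissue_model(), 300, 150, seed = 23)
  ann <- classify_library_kind(d$counts)
  confident <- ann$kind != "ambiguous"
  acc <- mean(ann$kind[confident] == d$truth$kind[confident])
  expect_gte(acc, 0.99)
  expect_gt(mean(confident), 0.7)             # ambiguity is the minority
})

test_that("remove_blacklisted_genes drops exactly the flagged rows", {
  m <- rand_counts(10, 4)
  gt <- gene_table(rownames(m), sex_linked = seq_len(10) == 5)
  out <- remove_blacklisted_genes(m, gt)
  expect_equal(nrow(out), 9)
  expect_false(rownames(m)[5] %in% rownames(out))
  expect_identical(as.matrix(remove_blacklisted_genes(m, gt,
                                                      character(0))),
                   as.matrix(m))
  gt_all <- gene_table(rownames(m), sex_linked = TRUE)
  expect_error(remove_blacklisted_genes(m, gt_all), "empty gene axis")
})

test_that("gene_set_score matches a hand computation and its sign cases", {
  m <- count_matrix(matrix(c(0, 0, 4, 6,
                             0, 0, 5, 5,
                             8, 2, 1, 9) * 1L, 4, 3,
                           dimnames = list(c("gs1", "gs2", "c1", "c2"),
                                           c("L1", "L2", "L3"))))
  norm <- normalize_log1p(m)
  # forced control set: score = mean(set rows) - mean(control rows)
  sc <- gene_set_score(norm, c("gs1", "gs2"),
                       control_genes = c("c1", "c2"))
  hand <- colMeans(as.matrix(norm[c("gs1", "gs2"), ])) -
    colMeans(as.matrix(norm[c("c1", "c2"), ]))
  expect_equal(sc, hand, tolerance = 1e-12)
  expect_lte(sc[["L1"]], 0)                    # set all zero, controls not
  # self-control gives exactly zero
  expect_equal(unname(gene_set_score(norm, c("gs1", "gs2"),
                                     control_genes = c("gs1", "gs2"))),
               rep(0, 3))
  expect_error(gene_set_score(norm, character(0)), "empty")
})

test_that("regress_out matches a normal-equations oracle and retains means", {
  set.seed(3)
  Y <- matrix(rnorm(4 * 5), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("L", 1:5)))
  cov <- cbind(x = c(0.1, 0.9, -0.4, 0.3, 0.5))
  out <- regress_out(Y, cov)
  for (g in 1:4) {
    X <- cbind(1, cov)
    beta <- solve(t(X) %*% X, t(X) %*% Y[g, ])
    resid <- Y[g, ] - X %*% beta
    # the gene's mean level is retained: residuals + mean(Y)
    expect_equal(unname(out[g, ]), as.numeric(resid + mean(Y[g, ])),
                 tolerance = 1e-10)
    # orthogonal to the centred covariate
    cc <- cov[, 1] - mean(cov[, 1])
    expect_lt(abs(sum((out[g, ] - mean(out[g, ])) * cc)),
              1e-8 * sqrt(sum(out[g, ]^2) * sum(cc^2)))
  }
  # zero covariate: identity (up to numeric representation)
  expect_warning(out0 <- regress_out(Y, cbind(rep(0, 5))), "collinear")
  expect_equal(out0, Y, tolerance = 1e-12)
  # gene equal to a covariate collapses to its mean
  Y2 <- Y; Y2[1, ] <- cov[, 1]
  out2 <- regress_out(Y2, cov)
  expect_equal(unname(out2[1, ]), rep(mean(cov[, 1]), 5), tolerance = 1e-10)
})

test_that("gate_by_markers applies strict thresholds", {
  norm <- matrix(c(0.6, 0.9, 0.6,
                   0.4, 0.9, 0.6,
                   0.6, 0.8, 0.6), 3, 3,
                 dimnames = list(c("Pax2", "EGFP", "Lhx1"),
                                 c("sp1", "sp2", "sp3")))
  rules <- c(Pax2 = 0.5, EGFP = 0.8, Lhx1 = 0.5)
  expect_identical(gate_by_markers(norm, rules), "sp1")
  expect_identical(gate_by_markers(norm, numeric(0)),
                   c("sp1", "sp2", "sp3"))
  expect_error(gate_by_markers(norm, c(Nope = 1)), "unknown gene")
})
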