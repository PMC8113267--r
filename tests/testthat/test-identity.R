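test_that("correlate_to_reference matches a hand Pearson oracle", {
  q <- matrix(c(1, 3, 2, 5), 4, 1, dimnames = list(paste0("g", 1:4), "q1"))
  r <- matrix(c(1, 3, 2, 5, 5, 2, 3, 1), 4, 2,
              dimnames = list(paste0("g", 1:4), c("r1", "r2")))
  co <- correlate_to_reference(q, r, c("sA", "sB"), paste0("g", 1:4),
                               row_standardize = FALSE)
  expect_equal(co$r_cells[1, "r1"], 1, tolerance = 1e-12)
  expect_equal(co$r_cells[1, "r2"], pearson_hand(q[, 1], r[, 2]),
               tolerance = 1e-12)
  # mean over a state's cells
  r2 <- cbind(r, r3 = c(2, 2, 1, 6))
  co2 <- correlate_to_reference(q, r2, c("sA", "sB", "sA"),
                                paste0("g", 1:4), row_standardize = FALSE)
  expect_equal(co2$r_state[1, "sA"],
               mean(c(1, pearson_hand(q[, 1], r2[, 3]))),
               tolerance = 1e-12)
  # negated profile anti-correlates (centred query)
  qn <- matrix(-(q - mean(q)), 4, 1,
               dimnames = list(paste0("g", 1:4), "q1"))
  con <- correlate_to_reference(qn, r, c("sA", "sB"), paste0("g", 1:4),
                                row_standardize = FALSE)
  expect_equal(con$r_cells[1, "r1"], -1, tolerance = 1e-12)
  expect_error(correlate_to_reference(q[1:2, , drop = FALSE], r,
                                      c("sA", "sB"), paste0("g", 1:2)),
               ">= 3 genes")
})

test_that("row standardisation and centroids behave as documented", {
  set.seed(12)
  q <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("q", 1:4)))
  r <- matrix(rnorm(30), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("r", 1:6)))
  lab <- rep(c("a", "b"), each = 3)
  co <- correlate_to_reference(q, r, lab, paste0("g", 1:5),
                               ref_summary = "centroid",
                               row_standardize = FALSE)
  expect_identical(colnames(co$r_cells), c("a", "b"))
  expect_equal(co$r_cells[2, "a"],
               pearson_hand(q[, 2], rowMeans(r[, 1:3])), tolerance = 1e-12)
  # constant query profile -> r = 0 with a warning
  qc <- q; qc[, 1] <- 2
  expect_warning(coc <- correlate_to_reference(qc, r, lab, paste0("g", 1:5),
                                               row_standardize = FALSE),
                 "constant")
  expect_equal(unname(coc$r_cells[1, ]), rep(0, 6))
})

test_that("group_queries recovers separated blobs and handles edge cases", {
  set.seed(4)
  # two blobs with centres (0.85, 0.15, 0.5) and (0.15, 0.85, 0.5):
  # centre distance ~1.0, opposite shapes, sigma = 0.01
  blob <- rbind(matrix(rep(c(0.85, 0.15, 0.5), each = 20), 20, 3),
                matrix(rep(c(0.15, 0.85, 0.5), each = 20), 20, 3)) +
    matrix(rnorm(120, 0, 0.01), 40, 3)
  rownames(blob) <- sprintf("q%02d", 1:40)
  grp <- group_queries(blob, n_groups = 2)
  expect_equal(length(unique(grp[1:20])), 1)
  expect_equal(length(unique(grp[21:40])), 1)
  expect_false(grp[1] == grp[21])
  # identical vectors collapse to one group
  same <- matrix(1, 6, 3, dimnames = list(sprintf("q%d", 1:6), NULL))
  expect_equal(nlevels(droplevels(group_queries(same, n_groups = 1))), 1)
  # singletons when n_groups = n
  expect_equal(nlevels(group_queries(blob, n_groups = 40)), 40)
  expect_error(group_queries(blob, n_groups = 41), "exceeds")
})

test_that("permutation test agrees with exhaustive enumeration (4 queries, 2 groups)", {
  rc <- matrix(c(0.9, 0.8, 0.1, 0.0,
                 0.2, 0.1, 0.9, 0.8), 4, 2,
               dimnames = list(paste0("q", 1:4), c("c1", "c2")))
  grp <- factor(c("a", "a", "b", "b"))
  p <- permutation_test(rc, grp, factor(c("s1", "s2")), exhaustive = TRUE)
  # independent oracle: enumerate the 6 distinct assignments
  Q <- rc                                      # one ref cell per state
  combs <- utils::combn(4, 2)
  T_a <- apply(combs, 2, function(ix) colMeans(Q[ix, , drop = FALSE]))
  obs <- colMeans(Q[1:2, ])
  p_manual <- rowMeans(T_a >= obs - 1e-12)
  expect_equal(unname(p["a", ]), unname(p_manual))
  expect_equal(attr(p, "n_perm"), 6)
  # p is never 0 and never below 1/(n_perm + 1) in sampling mode
  ps <- permutation_test(rc, grp, factor(c("s1", "s2")), n_perm = 99,
                         seed = 1)
  expect_true(all(ps >= 1 / 100) && all(ps <= 1))
})

test_that("constant r matrix gives p = 1 everywhere, single group errors", {
  rc <- matrix(0.5, 6, 4, dimnames = list(paste0("q", 1:6),
                                          paste0("c", 1:4)))
  grp <- factor(rep(c("a", "b"), 3))
  lab <- factor(rep(c("s1", "s2"), each = 2))
  for (st in c("mean", "welch")) {
    p <- permutation_test(rc, grp, lab, n_perm = 50, seed = 2,
                          statistic = st)
    expect_true(all(p == 1))
  }
  expect_error(permutation_test(rc, factor(rep("a", 6)), lab),
               "permutation null undefined")
})

test_that("permutation p-values are super-uniform under a null (calibration)", {
  set.seed(99)
  ps <- replicate(500, {
    rc <- matrix(rnorm(8 * 6), 8, 6,
                 dimnames = list(paste0("q", 1:8), paste0("c", 1:6)))
    p <- permutation_test(rc, factor(rep(c("a", "b"), each = 4)),
                          factor(rep(c("s1", "s2", "s3"), each = 2)),
                          n_perm = 199, seed = sample.int(1e6, 1))
    as.vector(p)
  })
  expect_lte(mean(ps <= 0.01), 0.02)
  expect_gte(min(ps), 1 / 200)
})

test_that("assign_identities applies both thresholds and is monotone", {
  r <- rbind(q1 = c(0.8, 0.2, 0.1, 0.0),
             q2 = c(0.7, 0.65, 0.1, 0.0),
             q3 = c(0.5, 0.4, 0.3, 0.2))
  colnames(r) <- as.character(1:4)
  p <- rbind(q1 = c(0.001, 0.5, 0.9, 0.9),
             q2 = c(0.002, 0.004, 0.6, 0.8),
             q3 = c(0.001, 0.001, 0.5, 0.5))
  colnames(p) <- as.character(1:4)
  out <- assign_identities(r, p)
  expect_identical(out$call, c("pure", "mixed", "unassigned"))
  expect_identical(out$call_states, c("1", "1,2", ""))
  # monotone: tightening thresholds never enlarges a call set
  for (i in 1:20) {
    set.seed(i)
    rr <- matrix(runif(8, -1, 1), 2, 4, dimnames = dimnames(r[1:2, ]))
    pp <- matrix(runif(8), 2, 4, dimnames = dimnames(r[1:2, ]))
    loose <- assign_identities(rr, pp, r_min = 0.3, p_max = 0.2)
    tight <- assign_identities(rr, pp, r_min = 0.5, p_max = 0.1)
    for (k in 1:2) {
      sl <- strsplit(loose$call_states[k], ",")[[1]]
      st <- strsplit(tight$call_states[k], ",")[[1]]
      expect_true(all(st %in% sl))
    }
  }
})

test_that("score_cells calls pure, hybrid and unassigned cells", {
  genes <- sprintf("g%02d", 1:12)
  mk <- list(a = genes[1:4], b = genes[5:8])
  base <- matrix(rnorm(12 * 30, 1, 0.05), 12, 30,
                 dimnames = list(genes, sprintf("c%02d", 1:30)))
  base[1:4, 1:10] <- 4                         # pure a cells
  base[5:8, 11:20] <- 4                        # pure b cells
  base[1:8, 21:25] <- 4                        # hybrid cells
  sig <- structure(list(states = c("a", "b"), markers = mk,
                        profile = matrix(0, 8, 2,
                                         dimnames = list(genes[1:8],
                                                         c("a", "b")))),
                   class = "state_signatures")
  sc <- score_cells(Matrix::Matrix(base, sparse = TRUE), sig, tau = 0.25)
  expect_true(all(sc$call[1:10] == "pure" & sc$primary[1:10] == "a"))
  expect_true(all(sc$call[11:20] == "pure" & sc$primary[11:20] == "b"))
  expect_true(all(sc$call[21:25] == "hybrid"))
  expect_true(all(vapply(strsplit(sc$call_states[21:25], ","),
                         function(v) setequal(v, c("a", "b")), TRUE)))
  expect_true(all(sc$call[26:30] == "unassigned"))
  expect_error(score_cells(Matrix::Matrix(base[1:6, ], sparse = TRUE), sig),
               "missing")
})

test_that("compare_composition counts, tests and flags absent states", {
  asg <- data.frame(
    id = sprintf("q%02d", 1:40),
    call = "pure",
    call_states = c(rep("1", 10), rep("2", 6), rep("4", 4),
                    rep("1", 12), rep("2", 8)),
    stringsAsFactors = FALSE)
  cond <- rep(c("ctrl", "ko"), c(20, 20))
  out <- compare_composition(asg, cond, states = as.character(1:4))
  expect_equal(unname(out$counts["ko", "4"]), 0)
  expect_equal(unname(rowSums(out$proportions)), c(1, 1))
  t4 <- out$tests[out$tests$state == "4", ]
  expect_true(t4$absent)
  expect_equal(t4$odds_ratio, 0)
  # Fisher p matches hypergeometric enumeration for a 2x2 table
  ft <- out$tests[out$tests$state == "2", "p_value"]
  # x11 ~ Hypergeometric(row totals 20/20, first-column total 14)
  probs <- dhyper(0:14, 20, 20, 14)
  p_manual <- sum(probs[probs <= dhyper(8, 20, 20, 14) * (1 + 1e-7)])
  expect_equal(ft, p_manual, tolerance = 1e-9)
  # identical compositions -> all adjusted p = 1
  asg2 <- asg; asg2$call_states <- rep(c("1", "2"), 20)
  out2 <- compare_composition(asg2, rep(c("A", "B"), each = 20),
                              states = c("1", "2"))
  expect_true(all(out2$tests$p_adjusted > 0.999))
  expect_error(compare_composition(asg, factor(rep("A", 40),
                                               levels = c("A", "B"))),
               "empty condition")
})

test_that("fisher.test orientation: (3,7;9,1) matches enumeration", {
  ft <- stats::fisher.test(matrix(c(3, 7, 9, 1), 2, byrow = TRUE))
  pr <- dhyper(0:10, 10, 10, 12)               # row sums 10/10, col1 = 12
  p_manual <- sum(pr[pr <= dhyper(3, 10, 10, 12) * (1 + 1e-7)])
  expect_equal(ft$p.value, p_manual, tolerance = 1e-9)
})
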