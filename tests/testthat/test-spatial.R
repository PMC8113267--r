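mk_assign <- function(mixed_sets, pure_states = character(0)) {
  data.frame(
    id = sprintf("q%02d", seq_len(length(mixed_sets) + length(pure_states))),
    call = c(rep("mixed", length(mixed_sets)),
             rep("pure", length(pure_states))),
    call_states = c(vapply(mixed_sets, paste, character(1), collapse = ","),
                    pure_states),
    stringsAsFactors = FALSE)
}

test_that("build_adjacency reproduces the star-on-state-2 pattern", {
  sets <- c(rep(list(c("1", "2")), 3), rep(list(c("2", "3")), 3),
            rep(list(c("2", "4")), 3))
  g <- build_adjacency(mk_assign(sets, pure_states = as.character(1:4)),
                       states = as.character(1:4))
  expect_identical(paste(g$edges$a, g$edges$b),
                   c("1 2", "2 3", "2 4"))
  expect_identical(paste(g$forbidden$a, g$forbidden$b),
                   c("1 3", "1 4", "3 4"))
  expect_equal(g$edges$support, c(3, 3, 3))
})

test_that("build_adjacency respects min_support and empty inputs", {
  g1 <- build_adjacency(mk_assign(list(c("1", "2"))),
                        states = as.character(1:3), min_support = 2)
  expect_equal(nrow(g1$edges), 0)
  g0 <- build_adjacency(mk_assign(list(), pure_states = c("1", "2")),
                        states = c("1", "2"))
  expect_equal(nrow(g0$edges), 0)
  expect_equal(nrow(g0$forbidden), 1)
  # support totals: sum of supports at min_support 1 = sum of C(|set|,2)
  set.seed(31)
  sets <- replicate(25, sample(as.character(1:5),
                               sample(2:4, 1)), simplify = FALSE)
  g <- build_adjacency(mk_assign(sets), states = as.character(1:5),
                       min_support = 1)
  expect_equal(sum(g$edges$support),
               sum(vapply(sets, function(v) choose(length(unique(v)), 2),
                          numeric(1))))
  # monotone sparsification
  g2 <- build_adjacency(mk_assign(sets), states = as.character(1:5),
                        min_support = 3)
  expect_true(all(paste(g2$edges$a, g2$edges$b) %in%
                    paste(g$edges$a, g$edges$b)))
})

test_that("seriate_states finds exact optimal orders", {
  path <- build_adjacency(mk_assign(c(rep(list(c("A", "B")), 2),
                                      rep(list(c("B", "C")), 2))),
                          states = c("A", "B", "C"))
  o <- seriate_states(path)
  expect_equal(o$cost, 0)
  expect_equal(length(o$orders), 1)
  expect_true(identical(o$orders[[1]], c("A", "B", "C")) ||
                identical(rev(o$orders[[1]]), c("A", "B", "C")))

  star <- build_adjacency(mk_assign(c(rep(list(c("1", "2")), 2),
                                      rep(list(c("2", "3")), 2),
                                      rep(list(c("2", "4")), 2))),
                          states = as.character(1:4))
  os <- seriate_states(star)
  expect_equal(os$cost, 1)
  for (ord in os$orders) {
    pos <- match(c("1", "3", "4"), ord)
    expect_true(abs(match("2", ord) - pos[1]) == 1 ||
                  abs(match("2", ord) - pos[2]) == 1)
    expect_true(sum(abs(match("2", ord) - pos) == 1) == 2)
  }

  cyc <- build_adjacency(mk_assign(c(rep(list(c("1", "2")), 2),
                                     rep(list(c("2", "3")), 2),
                                     rep(list(c("3", "4")), 2),
                                     rep(list(c("1", "4")), 2))),
                         states = as.character(1:4))
  expect_equal(seriate_states(cyc)$cost, 1)
})

test_that("seriate cost agrees with an independent brute-force scorer (S <= 6)", {
  set.seed(17)
  for (S in c(4, 5, 6)) {
    states <- as.character(seq_len(S))
    pairs <- utils::combn(states, 2)
    keep <- sample(ncol(pairs), ceiling(ncol(pairs) / 2))
    sets <- lapply(keep, function(k) rep(list(pairs[, k]), 2))
    g <- build_adjacency(mk_assign(unlist(sets, recursive = FALSE)),
                         states = states)
    o <- seriate_states(g)
    # brute force over every permutation
    perms <- as.matrix(expand.grid(rep(list(seq_len(S)), S)))
    perms <- perms[apply(perms, 1, function(v) length(unique(v)) == S), ,
                   drop = FALSE]
    cost_bf <- apply(perms, 1, function(idx) {
      pos <- integer(S); pos[idx] <- seq_len(S)
      sum(abs(pos[match(g$edges$a, states)] -
                pos[match(g$edges$b, states)]) > 1)
    })
    expect_equal(o$cost, min(cost_bf))
    # every reported order attains the minimum under the brute scorer
    for (ord in o$orders) {
      pos <- match(states, ord)
      expect_equal(sum(abs(pos[match(g$edges$a, states)] -
                             pos[match(g$edges$b, states)]) > 1), o$cost)
    }
  }
})

test_that("orders are reported modulo reversal", {
  g <- build_adjacency(mk_assign(rep(list(c("A", "B")), 2)),
                       states = c("A", "B"))
  o <- seriate_states(g)
  keys <- vapply(o$orders, paste, character(1), collapse = "|")
  rev_keys <- vapply(o$orders, function(x) paste(rev(x), collapse = "|"),
                     character(1))
  expect_false(any(rev_keys %in% keys))
  expect_error(seriate_states(structure(list(states = as.character(1:10),
                                             edges = data.frame(),
                                             forbidden = data.frame(),
                                             support = matrix(0, 10, 10)),
                                        class = "state_adjacency")),
               "more than 9 states")
})

test_that("evaluate_against_truth checks edges and order against the layout", {
  model <- small_model()
  g <- build_adjacency(mk_assign(c(rep(list(c("1", "2")), 2),
                                   rep(list(c("2", "3")), 2),
                                   rep(list(c("3", "4")), 2))),
                       states = as.character(1:4))
  o <- seriate_states(g)
  ev <- evaluate_against_truth(g, o, model)
  expect_true(ev$edges_match)
  expect_true(ev$order_match)
  # reversal counts as a match
  o_rev <- o; o_rev$orders <- list(c("4", "3", "2", "1"))
  expect_true(evaluate_against_truth(g, o_rev, model)$order_match)
  # wrong graph
  g2 <- build_adjacency(mk_assign(rep(list(c("1", "4")), 2)),
                        states = as.character(1:4))
  expect_false(evaluate_against_truth(g2, seriate_states(g2),
                                      model)$edges_match)
  g3 <- build_adjacency(mk_assign(rep(list(c("8", "9")), 2)))
  expect_error(evaluate_against_truth(g3, seriate_states(g3), model),
               "state universe")
})

test_that("render_report round-trips and mirrors the adjacency table", {
  asg <- mk_assign(c(rep(list(c("1", "2")), 3)),
                   pure_states = c("1", "2", "3"))
  g <- build_adjacency(asg, states = as.character(1:3))
  o <- seriate_states(g)
  f <- withr::local_tempfile(fileext = ".json")
  render_report(asg, g, o, f, params = list(seed = 7))
  rep_ <- read_report(f)
  expect_equal(rep_$call_counts$mixed, 3)
  expect_equal(rep_$call_counts$pure, 3)
  expect_equal(rep_$edges$support, g$edges$support)
  expect_equal(rep_$ordering_cost, o$cost)
  # empty assignment set still renders
  empty <- mk_assign(list())
  g0 <- build_adjacency(empty, states = c("1", "2"))
  f0 <- withr::local_tempfile(fileext = ".json")
  render_report(empty, g0, seriate_states(g0), f0)
  rep0 <- read_report(f0)
  expect_equal(rep0$n_assignments, 0)
  expect_equal(rep0$call_counts$mixed, 0)
})
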