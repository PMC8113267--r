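#' Build the state-adjacency graph from mixed-identity calls
#'
#' Every mixed call contributes one support count to each unordered pair of
#' states in its call set. Edges with support below `min_support` are
#' dropped (a single mixed call may be a sticky-cell artefact). Pairs of
#' observed states with zero support are recorded as forbidden — the
#' computational form of "these states are never found in physical
#' proximity".
#'
#' @param assignments data frame with `call` and `call_states` columns (see
#'   [assign_identities()]).
#' @param states state universe (character); defaults to every state seen
#'   in any call.
#' @param min_support minimum mixed-call support to keep an edge
#'   (default 2).
#' @return object of class `state_adjacency`: list with `states`, `edges`
#'   (data frame a, b, support), `forbidden` (data frame a, b) and the full
#'   `support` matrix.
#' @export
build_adjacency <- function(assignments, states = NULL, min_support = 2) {
  sets <- strsplit(assignments$call_states[assignments$call == "mixed"],
                   ",", fixed = TRUE)
  observed <- unique(unlist(c(
    strsplit(assignments$call_states[assignments$call != "unassigned"],
             ",", fixed = TRUE))))
  if (is.null(states)) states <- sort(observed)
  S <- length(states)
  supp <- matrix(0, S, S, dimnames = list(states, states))
  for (cs in sets) {
    cs <- sort(unique(cs))
    if (length(cs) < 2) next
    pr <- utils::combn(cs, 2)
    for (k in seq_len(ncol(pr)))
      supp[pr[1, k], pr[2, k]] <- supp[pr[1, k], pr[2, k]] + 1
  }
  supp <- supp + t(supp)
  if (S < 2) {
    empty <- data.frame(a = character(0), b = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(states = states,
                          edges = cbind(empty, support = numeric(0)),
                          forbidden = empty, support = supp,
                          min_support = min_support),
                     class = "state_adjacency"))
  }
  pairs <- utils::combn(states, 2)
  sup_vec <- supp[t(pairs)]
  keep <- sup_vec >= min_support
  edges <- data.frame(a = pairs[1, keep], b = pairs[2, keep],
                      support = sup_vec[keep], stringsAsFactors = FALSE)
  zero <- sup_vec == 0 & (pairs[1, ] %in% observed) &
    (pairs[2, ] %in% observed)
  forbidden <- data.frame(a = pairs[1, zero], b = pairs[2, zero],
                          stringsAsFactors = FALSE)
  structure(list(states = states, edges = edges, forbidden = forbidden,
                 support = supp, min_support = min_support),
            class = "state_adjacency")
}

#' @exportS3Method base::print
print.state_adjacency <- function(x, ...) {
  cat("state_adjacency:", length(x$states), "states,", nrow(x$edges),
      "edges (min_support", x$min_support, "),", nrow(x$forbidden),
      "forbidden pairs\n")
  if (nrow(x$edges))
    cat(paste(sprintf("  %s--%s (%d)", x$edges$a, x$edges$b,
                      x$edges$support), collapse = "\n"), "\n")
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9 guarded upstream
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, setdiff(seq_len(n), pos)] <- sub
    out[row:(row + nrow(sub) - 1L), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Exhaustive 1D seriation of the state-adjacency graph
#'
#' Searches all orderings of the states (modulo reversal — a 1D axis has no
#' intrinsic direction) for those minimising the cost: the number of
#' supported edges whose endpoint states are not adjacent in the order.
#' Optionally a penalty is added for forbidden pairs placed adjacent. All
#' minimum-cost orders are returned, lexicographically sorted.
#'
#' @param graph a `state_adjacency` (see [build_adjacency()]).
#' @param forbidden_penalty per-violation penalty for forbidden pairs that
#'   end up adjacent in the order; 0 (default) disables it.
#' @param heuristic allow > 9 states via spectral seriation of the support
#'   matrix (single order, not guaranteed optimal).
#' @return object of class `ordering_result`: list with `orders` (list of
#'   state vectors), `cost` and `exhaustive`.
#' @export
seriate_states <- function(graph, forbidden_penalty = 0,
                           heuristic = FALSE) {
  states <- graph$states
  S <- length(states)
  if (S < 2)
    return(structure(list(orders = list(states), cost = 0,
                          exhaustive = TRUE), class = "ordering_result"))
  if (S > 9 && !heuristic)
    stop("more than 9 states: exhaustive search refused; set heuristic = TRUE")
  cost_of <- function(pos) {
    # pos[s] = rank of state s in the order
    cost <- 0
    if (nrow(graph$edges))
      cost <- sum(abs(pos[graph$edges$a] - pos[graph$edges$b]) > 1)
    if (forbidden_penalty > 0 && nrow(graph$forbidden))
      cost <- cost + forbidden_penalty *
        sum(abs(pos[graph$forbidden$a] - pos[graph$forbidden$b]) == 1)
    cost
  }
  if (S > 9) {
    L <- diag(rowSums(graph$support)) - graph$support
    ev <- eigen(L, symmetric = TRUE)
    ord <- states[order(ev$vectors[, S - 1])]
    pos <- stats::setNames(seq_len(S), ord)
    return(structure(list(orders = list(ord), cost = cost_of(pos),
                          exhaustive = FALSE), class = "ordering_result"))
  }
  perms <- all_permutations(S)
  perms <- perms[perms[, 1] < perms[, S], , drop = FALSE]  # modulo reversal
  costs <- apply(perms, 1, function(idx) {
    pos <- stats::setNames(integer(S), states[idx])
    pos[states[idx]] <- seq_len(S)
    cost_of(pos)
  })
  best <- which(costs == min(costs))
  orders <- lapply(best, function(i) states[perms[i, ]])
  key <- vapply(orders, paste, character(1), collapse = "\r")
  orders <- orders[order(key)]
  structure(list(orders = orders, cost = min(costs), exhaustive = TRUE),
            class = "ordering_result")
}

#' @exportS3Method base::print
print.ordering_result <- function(x, ...) {
  cat("ordering_result: cost", x$cost,
      if (x$exhaustive) "(exhaustive)" else "(heuristic)", "\n")
  for (o in x$orders) cat(" ", paste(o, collapse = " - "), "\n")
  invisible(x)
}

# true domain-adjacency edges and state order implied by a tissue layout
layout_adjacency <- function(model) {
  lay <- model$domain_layout
  ord <- as.character(lay$state)[!duplicated(lay$state)]
  n <- nrow(lay)
  pairs <- cbind(as.character(lay$state[-n]), as.character(lay$state[-1]))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- t(apply(pairs, 1, sort))
  n_bound <- table(paste(pairs[, 1], pairs[, 2], sep = "--"))
  pairs <- unique(as.data.frame(pairs, stringsAsFactors = FALSE))
  names(pairs) <- c("a", "b")
  pairs$n_boundaries <- as.integer(n_bound[paste(pairs$a, pairs$b,
                                                 sep = "--")])
  list(edges = pairs, order = ord)
}

#' Score an inferred graph and ordering against simulation truth
#'
#' Derives the true domain-adjacency edge set and domain order from the
#' tissue layout and reports whether the inferred edge set matches exactly,
#' whether any optimal order equals the true order or its reversal, and the
#' per-pair support table.
#'
#' @param graph inferred `state_adjacency`.
#' @param ordering inferred `ordering_result`.
#' @param model the generating [tissue_model()].
#' @return list with `edges_match`, `order_match`, `true_edges`,
#'   `true_order` and `support`.
#' @export
evaluate_against_truth <- function(graph, ordering, model) {
  truth <- layout_adjacency(model)
  model_states <- as.character(sort(unique(model$domain_layout$state)))
  if (!all(graph$states %in% model_states))
    stop("input error: graph states not in the model's state universe")
  edge_key <- function(df) if (nrow(df)) sort(paste(pmin(df$a, df$b),
                                                    pmax(df$a, df$b)))
                           else character(0)
  edges_match <- identical(edge_key(graph$edges), edge_key(truth$edges))
  order_match <- any(vapply(ordering$orders, function(o)
    identical(o, truth$order) || identical(rev(o), truth$order),
    logical(1)))
  list(edges_match = edges_match, order_match = order_match,
       true_edges = truth$edges, true_order = truth$order,
       support = graph$support)
}

#' Write a structured JSON run report
#'
#' Collects parameters, QC summary, identity-call counts, the adjacency
#' edge table, the optimal orders and (when available) the
#' truth-evaluation booleans into one JSON file that round-trips through
#' [read_report()].
#'
#' @param assignments per-library assignment table (may have zero rows).
#' @param graph a `state_adjacency`.
#' @param ordering an `ordering_result`.
#' @param out_path output JSON path.
#' @param params,qc_summary,evaluation optional named lists merged into the
#'   report.
#' @return `out_path`, invisibly.
#' @export
render_report <- function(assignments, graph, ordering, out_path,
                          params = NULL, qc_summary = NULL,
                          evaluation = NULL) {
  dir_ <- dirname(out_path)
  if (!dir.exists(dir_) &&
      !dir.create(dir_, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create ", dir_)
  calls <- table(factor(assignments$call,
                        levels = c("pure", "mixed", "unassigned")))
  rep_ <- list(
    params = params,
    qc_summary = qc_summary,
    n_assignments = nrow(assignments),
    call_counts = as.list(calls),
    edges = graph$edges,
    forbidden = graph$forbidden,
    min_support = graph$min_support,
    orders = lapply(ordering$orders, as.character),
    ordering_cost = ordering$cost,
    exhaustive = ordering$exhaustive,
    evaluation = if (!is.null(evaluation))
      evaluation[c("edges_match", "order_match")])
  jsonlite::write_json(rep_, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(out_path)
}

#' @rdname render_report
#' @param path report JSON path.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
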