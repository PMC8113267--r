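#' Pearson correlation of query libraries to a labelled reference
#'
#' Query and reference profiles are restricted to the correlation gene set
#' (conventionally the union of per-state top markers), jointly
#' row-standardised (each gene z-scored across all query + reference
#' libraries), and Pearson-correlated query-by-reference-cell. Constant
#' profiles yield r defined as 0 with a warning. Per-state correlations are
#' the mean r over that state's reference cells.
#'
#' With `ref_summary = "centroid"` each state's reference cells are first
#' averaged into one mean profile and queries are correlated to the
#' centroids instead; this removes the reference-side sampling noise that
#' otherwise attenuates every r (a query identical to a state's mean
#' profile correlates ~1 with the centroid but only ~E\[r(cell, centroid)\]
#' with the individual cells). `row_standardize = FALSE` correlates the
#' normalised expression directly (z-scoring of coefficient matrices for
#' display is then a separate concern).
#'
#' @param query_norm normalised query matrix (e.g. cluster libraries or
#'   spatial spots).
#' @param ref_norm normalised reference matrix of labelled single cells.
#' @param ref_labels state label per reference cell.
#' @param gene_set character vector of >= 3 genes present in both matrices.
#' @param row_standardize z-score each gene across all query + reference
#'   libraries before correlating (default TRUE).
#' @param ref_summary correlate to every reference `"cells"` (default) or
#'   to per-state mean profiles (`"centroid"`).
#' @return list with `r_cells` (query x reference cell, or query x state
#'   centroid), `r_state` (query x state mean r) and `ref_labels` (one
#'   entry per `r_cells` column).
#' @export
correlate_to_reference <- function(query_norm, ref_norm, ref_labels,
                                   gene_set, row_standardize = TRUE,
                                   ref_summary = c("cells", "centroid")) {
  ref_summary <- match.arg(ref_summary)
  gene_set <- unique(gene_set)
  if (length(gene_set) < 3) stop("input error: need >= 3 genes")
  missing <- setdiff(gene_set, intersect(rownames(query_norm),
                                         rownames(ref_norm)))
  if (length(missing))
    stop("input error: gene_set absent from matrices: ",
         paste(missing, collapse = ", "))
  ref_labels <- factor(ref_labels)
  if (length(ref_labels) != ncol(ref_norm))
    stop("ref_labels must align with reference columns")
  Q <- as.matrix(query_norm[gene_set, , drop = FALSE])
  R <- as.matrix(ref_norm[gene_set, , drop = FALSE])
  if (ref_summary == "centroid") {
    R <- vapply(levels(ref_labels), function(s)
      rowMeans(R[, ref_labels == s, drop = FALSE]),
      numeric(length(gene_set)))
    if (length(gene_set) == 1) R <- matrix(R, nrow = 1)
    colnames(R) <- levels(ref_labels)
    ref_labels <- factor(levels(ref_labels), levels = levels(ref_labels))
  }
  comb <- cbind(Q, R)
  if (row_standardize) {
    mu <- rowMeans(comb)
    sd_ <- apply(comb, 1, stats::sd)
    sd_[sd_ == 0] <- 1                        # constant gene rows -> all 0
    comb <- (comb - mu) / sd_
  }
  qz <- comb[, seq_len(ncol(Q)), drop = FALSE]
  rz <- comb[, ncol(Q) + seq_len(ncol(R)), drop = FALSE]
  const_q <- apply(qz, 2, stats::sd) == 0
  const_r <- apply(rz, 2, stats::sd) == 0
  if (any(const_q) || any(const_r))
    warning("constant profile(s) over the gene set; their r set to 0")
  qz[, const_q] <- 0
  rz[, const_r] <- 0
  suppressWarnings(rc <- stats::cor(qz, rz))
  rc[const_q, ] <- 0
  rc[, const_r] <- 0
  rc[is.na(rc)] <- 0
  rownames(rc) <- colnames(Q)
  r_state <- vapply(levels(ref_labels), function(s)
    rowMeans(rc[, ref_labels == s, drop = FALSE]), numeric(nrow(rc)))
  if (nrow(rc) == 1)
    r_state <- matrix(r_state, nrow = 1,
                      dimnames = list(rownames(rc), levels(ref_labels)))
  list(r_cells = rc, r_state = r_state, ref_labels = ref_labels)
}

#' Group query libraries by their state-correlation fingerprints
#'
#' Average-linkage agglomerative clustering on `1 - Pearson` distance
#' between the queries' state-correlation vectors; deterministic given the
#' input order. Identical vectors always end up in one group.
#'
#' @param r_state query x state correlation matrix (see
#'   [correlate_to_reference()]).
#' @param n_groups desired number of groups (<= number of queries), or NULL
#'   to cut at `height`.
#' @param height dendrogram cut height when `n_groups` is NULL.
#' @return factor of group labels (`grp01`, ...) named by query id.
#' @export
group_queries <- function(r_state, n_groups = NULL, height = NULL) {
  nq <- nrow(r_state)
  if (nq < 2) stop("input error: need >= 2 queries")
  if (!is.null(n_groups) && n_groups > nq)
    stop("input error: n_groups exceeds number of queries")
  cc <- suppressWarnings(stats::cor(t(r_state)))
  eq <- as.matrix(stats::dist(r_state)) == 0
  cc[is.na(cc)] <- 0
  cc[eq] <- 1                                  # constant-vector duplicates
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  cl <- if (!is.null(n_groups)) stats::cutree(hc, k = n_groups)
        else stats::cutree(hc, h = if (is.null(height)) 0.5 else height)
  factor(sprintf("grp%02d", cl), levels = sprintf("grp%02d",
                                                  sort(unique(cl))))
}

# distinct permutations of a label vector (for the exhaustive null)
distinct_label_permutations <- function(labels, cap = 20000) {
  labels <- as.character(labels)
  rec <- function(remaining) {
    if (!length(remaining)) return(list(character(0)))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      for (tail in rec(rest)) out[[length(out) + 1]] <- c(u, tail)
    }
    out
  }
  n_arr <- round(exp(lfactorial(length(labels)) -
                       sum(lfactorial(table(labels)))))
  if (n_arr > cap) stop("too many distinct label permutations (", n_arr, ")")
  rec(labels)
}

#' Barcode-permutation test for group-vs-state mean correlation
#'
#' The observed statistic is `T(g, s)`, the mean correlation between the
#' queries of group `g` and the reference cells of state `s`. The null
#' permutes the group labels across queries (the "barcode shuffle"); the
#' one-sided p-value counts permuted statistics at least as large:
#' `p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm)`, so p is never 0 and
#' never below `1/(n_perm + 1)`. With `exhaustive = TRUE` all distinct label
#' assignments are enumerated instead and `p = #\{T_perm >= T_obs\} / n_arr`
#' (the identity assignment is included, keeping p positive).
#'
#' The statistic is the plain group mean by default. `statistic = "welch"`
#' studentises it — `(mean_g - mean_rest) / sqrt(s_g^2/n_g +
#' s_rest^2/n_rest)` (with `s_g` replaced by `s_rest` for groups smaller
#' than 3) — which retains power when the null distribution of the mean has
#' a heavy tail from large blocks of high-correlation queries: a coherent
#' group with a tight internal spread then scores far higher than any
#' random label assignment of the same size.
#'
#' @param r_cells query x reference-cell correlation matrix.
#' @param groups group label per query (>= 2 distinct groups).
#' @param ref_labels state label per reference cell.
#' @param n_perm number of random shuffles (default 1000).
#' @param seed RNG seed for the shuffles.
#' @param statistic `"mean"` (default) or `"welch"`.
#' @param exhaustive enumerate all distinct label assignments (small
#'   problems only).
#' @return matrix of p-values (groups x states) with the observed statistics
#'   attached as attribute `"T_obs"` and the observed group-mean r as
#'   `"group_r"`.
#' @export
permutation_test <- function(r_cells, groups, ref_labels, n_perm = 1000,
                             seed = 1, statistic = c("mean", "welch"),
                             exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  groups <- factor(groups)
  ref_labels <- factor(ref_labels)
  if (nlevels(groups) < 2)
    stop("permutation null undefined: need >= 2 groups")
  if (length(groups) != nrow(r_cells))
    stop("groups must align with query rows")
  # per-query mean r to each state
  Q <- vapply(levels(ref_labels), function(s)
    rowMeans(r_cells[, ref_labels == s, drop = FALSE]),
    numeric(nrow(r_cells)))
  if (nrow(r_cells) == 1) Q <- matrix(Q, nrow = 1)
  glev <- sort(unique(as.character(groups)))
  n_tot <- nrow(Q)
  sum_all <- colSums(Q)
  ss_all <- colSums(Q^2)
  group_means <- function(lab) {
    rowsum(Q, lab, reorder = TRUE) / as.vector(table(lab)[glev])
  }
  group_stat <- if (statistic == "mean") group_means else function(lab) {
    ng <- as.vector(table(lab)[glev])
    sm <- rowsum(Q, lab, reorder = TRUE)
    ss <- rowsum(Q^2, lab, reorder = TRUE)
    mg <- sm / ng
    nr <- n_tot - ng
    mr <- sweep(-sm, 2, sum_all, `+`) / nr
    vr <- (sweep(-ss, 2, ss_all, `+`) - nr * mr^2) / pmax(nr - 1, 1)
    vg <- (ss - ng * mg^2) / pmax(ng - 1, 1)
    vg[ng < 3, ] <- vr[ng < 3, ]            # tiny groups borrow the rest's
    se <- sqrt(pmax(vg / ng + vr / nr, 0))
    out <- (mg - mr) / se
    out[se == 0] <- 0
    out
  }
  T_obs <- group_stat(groups)
  cnt <- matrix(0, nrow(T_obs), ncol(T_obs))
  if (exhaustive) {
    perms <- distinct_label_permutations(groups)
    for (pl in perms) {
      Tp <- group_stat(factor(pl, levels = levels(groups)))
      cnt <- cnt + (Tp >= T_obs - 1e-12)
    }
    p <- cnt / length(perms)
    n_used <- length(perms)
  } else {
    local_seed(seed, for (i in seq_len(n_perm)) {
      Tp <- group_stat(sample(groups))
      cnt <- cnt + (Tp >= T_obs - 1e-12)
    })
    p <- (1 + cnt) / (1 + n_perm)
    n_used <- n_perm
  }
  dimnames(p) <- list(rownames(T_obs), levels(ref_labels))
  gr <- group_means(groups)
  dimnames(gr) <- dimnames(p)
  attr(p, "T_obs") <- T_obs
  attr(p, "group_r") <- gr
  attr(p, "n_perm") <- n_used
  p
}

#' Call pure / mixed / unassigned identities
#'
#' A state belongs to a call set iff `r > r_min` and `p < p_max` (defaults
#' r > 0.6, permutation p < 0.01). One passing state gives a pure call, two
#' or more a mixed call, none leaves the library (or group) unassigned.
#'
#' @param r_state rows x states correlation matrix (per library, or
#'   group-level `T_obs`).
#' @param p_perm matching matrix of permutation p-values.
#' @param r_min,p_max the call thresholds.
#' @return data frame with id, call (`pure` / `mixed` / `unassigned`),
#'   call_states (comma-joined, ordered by decreasing r) and the per-state
#'   r and p columns.
#' @export
assign_identities <- function(r_state, p_perm, r_min = 0.6, p_max = 0.01) {
  stopifnot(all(dim(r_state) == dim(p_perm)))
  states <- colnames(r_state)
  calls <- character(nrow(r_state))
  call_states <- character(nrow(r_state))
  for (i in seq_len(nrow(r_state))) {
    pass <- which(r_state[i, ] > r_min & p_perm[i, ] < p_max)
    pass <- pass[order(-r_state[i, pass])]
    calls[i] <- if (!length(pass)) "unassigned"
                else if (length(pass) == 1) "pure" else "mixed"
    call_states[i] <- paste(states[pass], collapse = ",")
  }
  out <- data.frame(id = rownames(r_state), call = calls,
                    call_states = call_states, stringsAsFactors = FALSE,
                    row.names = NULL)
  rs <- as.data.frame(r_state); names(rs) <- paste0("r_", states)
  ps <- as.data.frame(p_perm); names(ps) <- paste0("p_", states)
  cbind(out, rs, ps)
}

#' End-to-end identity assignment of query libraries
#'
#' Convenience wrapper: correlate queries to the reference over the
#' signature gene set, group them (group-level calls are the default
#' granularity; pass `n_groups = NULL, per_library = TRUE` for per-library
#' calls), run the barcode-permutation test, threshold, and expand group
#' calls back to the member libraries.
#'
#' The default correlation variant is `row_standardize = FALSE,
#' ref_summary = "centroid"`: Pearson r on normalised expression against
#' per-state mean reference profiles. This is the variant under which the
#' conventional call thresholds (r > 0.6, permutation p < 0.01) are
#' calibrated; correlating against individual noisy reference cells
#' attenuates every r by the cells' own reliability and pushes even perfect
#' matches below such absolute thresholds (see
#' [correlate_to_reference()]).
#'
#' Grouping (`grouping = "pattern"`, the default) pools queries sharing the
#' same *candidate identity pattern*: the set of states whose r exceeds
#' `r_min - pattern_margin`. Boundary clusters of one state pair thus form
#' one group large enough for the permutation null to have power, while
#' artefactual ("sticky") aggregates fall into small odd-pattern groups
#' that fail it. `grouping = "hclust"` uses [group_queries()];
#' `grouping = "per_library"` makes every query its own group.
#'
#' @param query_norm,ref_norm,ref_labels,gene_set,row_standardize,ref_summary
#'   see [correlate_to_reference()].
#' @param grouping `"pattern"`, `"hclust"` or `"per_library"`.
#' @param n_groups group count for `grouping = "hclust"` (default
#'   `3 * n_states`).
#' @param pattern_margin relaxation below `r_min` when forming candidate
#'   patterns (default 0.1).
#' @param n_perm,seed,r_min,p_max see [permutation_test()] and
#'   [assign_identities()].
#' @param statistic permutation statistic (see [permutation_test()];
#'   default `"welch"` here).
#' @param ambiguous_guard drop calls from groups that also exceed `r_min`
#'   for states outside the call set (the correlation fingerprint of a
#'   sticky-cell aggregate, which resembles every state at once).
#' @return list with `assignments` (per library), `group_assignments`,
#'   `groups`, `r_state`, `p_perm`.
#' @export
identify_queries <- function(query_norm, ref_norm, ref_labels, gene_set,
                             grouping = c("pattern", "hclust",
                                          "per_library"),
                             n_groups = NULL, pattern_margin = 0.1,
                             n_perm = 1000, seed = 1, r_min = 0.6,
                             p_max = 0.01, row_standardize = FALSE,
                             ref_summary = "centroid",
                             statistic = "welch",
                             ambiguous_guard = TRUE) {
  grouping <- match.arg(grouping)
  co <- correlate_to_reference(query_norm, ref_norm, ref_labels, gene_set,
                               row_standardize = row_standardize,
                               ref_summary = ref_summary)
  nq <- nrow(co$r_state)
  if (grouping == "per_library") {
    groups <- factor(rownames(co$r_state), levels = rownames(co$r_state))
  } else if (grouping == "pattern") {
    thr <- r_min - pattern_margin
    key <- apply(co$r_state > thr, 1, function(v)
      if (any(v)) paste(colnames(co$r_state)[v], collapse = "+")
      else "none")
    groups <- factor(key)
    names(groups) <- rownames(co$r_state)
  } else {
    if (is.null(n_groups))
      n_groups <- min(nq, 3 * nlevels(co$ref_labels))
    groups <- group_queries(co$r_state, n_groups = n_groups)
    names(groups) <- rownames(co$r_state)
  }
  if (nlevels(droplevels(groups)) < 2)
    groups <- factor(rownames(co$r_state),
                     levels = rownames(co$r_state))   # degenerate fallback
  p <- permutation_test(co$r_cells, groups, co$ref_labels, n_perm = n_perm,
                        seed = seed, statistic = statistic)
  # thresholds apply to the group-mean r (the interpretable scale); the
  # permutation p may come from the studentised statistic
  grp_assign <- assign_identities(attr(p, "group_r"), p, r_min = r_min,
                                  p_max = p_max)
  if (ambiguous_guard) {
    # a call is only interpretable when the states *outside* it are clearly
    # uncorrelated; a group exceeding r_min for extra, non-significant
    # states matches the profile of an artefactual ("sticky") aggregate
    gr <- attr(p, "group_r")
    for (i in seq_len(nrow(grp_assign))) {
      called <- strsplit(grp_assign$call_states[i], ",", fixed = TRUE)[[1]]
      extra <- setdiff(colnames(gr)[gr[i, ] > r_min], called)
      if (grp_assign$call[i] != "unassigned" && length(extra)) {
        grp_assign$call[i] <- "unassigned"
        grp_assign$call_states[i] <- ""
      }
    }
  }
  idx <- match(as.character(groups), grp_assign$id)
  assignments <- grp_assign[idx, , drop = FALSE]
  assignments$id <- rownames(co$r_state)
  assignments$group <- as.character(groups)
  rownames(assignments) <- NULL
  list(assignments = assignments, group_assignments = grp_assign,
       groups = groups, r_state = co$r_state, r_cells = co$r_cells,
       p_perm = p)
}

#' Per-cell state scores and hybrid-identity calls
#'
#' Each gene of the union signature set is z-scored across cells; a cell's
#' score for state `s` is the mean z over `s`'s marker list. The primary
#' call is the argmax score; a cell is `hybrid` when its top *two* scores
#' both exceed `tau`, and `unassigned` when no score does.
#'
#' @param norm normalised matrix of cells.
#' @param signatures a `state_signatures` object (see
#'   [build_signatures()]).
#' @param tau score threshold (default 0.25).
#' @return data frame with cell id, per-state scores, primary state and
#'   call (`pure` / `hybrid` / `unassigned`) plus `call_states`.
#' @export
score_cells <- function(norm, signatures, tau = 0.25) {
  markers <- signatures$markers
  union_genes <- unique(unlist(markers, use.names = FALSE))
  missing <- setdiff(union_genes, rownames(norm))
  if (length(missing))
    stop("input error: marker gene(s) missing: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(norm[union_genes, , drop = FALSE])
  mu <- rowMeans(X); s <- apply(X, 1, stats::sd); s[s == 0] <- 1
  Z <- (X - mu) / s
  sts <- names(markers)                        # states with a marker list
  scores <- vapply(sts, function(st)
    colMeans(Z[markers[[st]], , drop = FALSE]), numeric(ncol(Z)))
  if (ncol(Z) == 1) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- sts
  prim <- sts[max.col(scores, ties.method = "first")]
  ord2 <- t(apply(scores, 1, function(v) sort(v, decreasing = TRUE)[1:2]))
  call <- ifelse(ord2[, 2] > tau, "hybrid",
                 ifelse(ord2[, 1] > tau, "pure", "unassigned"))
  call_states <- vapply(seq_len(nrow(scores)), function(i) {
    if (call[i] == "unassigned") return("")
    k <- if (call[i] == "hybrid") 2 else 1
    paste(sts[order(-scores[i, ])][seq_len(k)], collapse = ",")
  }, character(1))
  data.frame(cell = colnames(norm), scores, primary = prim, call = call,
             call_states = call_states, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Compare state composition between conditions
#'
#' Counts assigned libraries per condition and state (a library counts
#' toward its highest-correlation called state; unassigned libraries are
#' excluded), reports per-condition proportions, and — with exactly two
#' conditions — tests each state with a two-sided Fisher exact test on the
#' 2x2 table (state vs rest) x (condition A vs B), BH-adjusted across
#' states. States absent from one condition are flagged.
#'
#' @param assignments data frame from [assign_identities()] (or the
#'   per-library table of [identify_queries()]).
#' @param conditions condition label per assignment row.
#' @param states optional state universe (defaults to states seen in calls).
#' @return list with `counts`, `proportions` and `tests` (NULL unless two
#'   conditions).
#' @export
compare_composition <- function(assignments, conditions, states = NULL) {
  if (!is.factor(conditions)) conditions <- factor(conditions)
  if (any(table(conditions) == 0) || nlevels(conditions) < 1)
    stop("input error: empty condition")
  called <- assignments$call != "unassigned"
  primary <- vapply(strsplit(assignments$call_states, ","), function(v)
    if (length(v)) v[1] else NA_character_, character(1))
  if (is.null(states))
    states <- sort(unique(stats::na.omit(primary)))
  counts <- table(condition = conditions[called],
                  state = factor(primary[called], levels = states))
  counts <- unclass(counts)
  props <- counts / pmax(rowSums(counts), 1)
  tests <- NULL
  if (nlevels(conditions) == 2) {
    tests <- do.call(rbind, lapply(states, function(s) {
      a <- counts[1, s]; b <- sum(counts[1, ]) - a
      c_ <- counts[2, s]; d <- sum(counts[2, ]) - c_
      # odds ratio oriented as odds of the state in condition 2 vs 1,
      # so a state absent from condition 2 reports OR = 0
      ft <- stats::fisher.test(matrix(c(c_, d, a, b), 2, byrow = TRUE))
      data.frame(state = s, p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 absent = (a == 0) != (c_ == 0),
                 stringsAsFactors = FALSE)
    }))
    tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "BH")
  }
  list(counts = counts, proportions = props, tests = tests)
}
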