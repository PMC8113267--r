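#' End-to-end simulation benchmark of the identity pipeline
#'
#' Generates one synthetic dataset, derives signatures from the single-cell
#' libraries (using the simulation's true state labels as the reference
#' labelling), assigns every cluster library an identity, builds the
#' state-adjacency graph and seriates it, then scores everything against
#' the simulation truth. Used by the acceptance checks and by
#' `scripts/acceptance.R`.
#'
#' @param model a [tissue_model()].
#' @param seed seed for this run (generation, permutation test).
#' @param n_singles,n_clusters dataset size.
#' @param n_perm permutation count for the barcode-shuffle test.
#' @param min_support adjacency support threshold.
#' @return list of per-run counts: `n_pure`, `pure_ok` (pure-member
#'   clusters whose call is pure with the correct state), `n_two`,
#'   `two_ok` (two-state clusters called mixed with exactly that pair),
#'   `edges_match`, `order_match`, `kind_acc` (single/cluster recovery on
#'   confidently classified libraries), plus the assignment table.
#' @export
benchmark_run <- function(model = tissue_model(), seed = 1,
                          n_singles = 600, n_clusters = 200,
                          n_perm = 999, min_support = 2) {
  ds <- generate_dataset(model, n_singles, n_clusters, seed = seed)
  norm <- normalize_log1p(ds$counts)
  singles <- ds$truth$library_id[ds$truth$kind == "single"]
  clusters <- ds$truth$library_id[ds$truth$kind == "cluster"]
  labels <- ds$truth$member_states[ds$truth$kind == "single"]

  de <- find_markers(norm[, singles, drop = FALSE], labels)
  top <- top_markers(de)
  gene_set <- unique(unlist(top, use.names = FALSE))
  res <- identify_queries(norm[, clusters, drop = FALSE],
                          norm[, singles, drop = FALSE], labels, gene_set,
                          n_perm = n_perm, seed = child_seed(seed, 777))
  asg <- res$assignments

  ms <- strsplit(ds$truth$member_states[ds$truth$kind == "cluster"], ",")
  n_states <- vapply(ms, function(v) length(unique(v)), integer(1))
  truth_state <- vapply(ms, function(v) v[1], character(1))
  pair <- vapply(ms, function(v) paste(sort(unique(v)), collapse = ","),
                 character(1))
  got <- vapply(strsplit(asg$call_states, ",", fixed = TRUE),
                function(v) paste(sort(v), collapse = ","), character(1))
  pure_idx <- n_states == 1
  two_idx <- n_states == 2
  pure_ok <- asg$call[pure_idx] == "pure" &
    asg$call_states[pure_idx] == truth_state[pure_idx]
  two_ok <- asg$call[two_idx] == "mixed" & got[two_idx] == pair[two_idx]

  g <- build_adjacency(asg, states = as.character(seq_len(model$n_states)),
                       min_support = min_support)
  ordering <- seriate_states(g)
  ev <- evaluate_against_truth(g, ordering, model)

  ann <- classify_library_kind(ds$counts)
  conf <- ann$kind != "ambiguous"
  kind_acc <- mean(ann$kind[conf] == ds$truth$kind[conf])

  list(n_pure = sum(pure_idx), pure_ok = sum(pure_ok),
       n_two = sum(two_idx), two_ok = sum(two_ok),
       edges_match = ev$edges_match, order_match = ev$order_match,
       kind_acc = kind_acc, n_confident = sum(conf),
       assignments = asg, graph = g, ordering = ordering,
       marker_de = de)
}

#' Marker-recovery benchmark on a labelled reference panel
#'
#' Generates `singles_per_state` reference cells per state, runs
#' [find_markers()] at the given thresholds and reports per-state
#' sensitivity for the true marker genes and the realized false-discovery
#' proportion.
#'
#' @param model a [tissue_model()].
#' @param seed generation seed.
#' @param singles_per_state reference cells per state.
#' @param logfc_min,padj_max marker thresholds.
#' @return list with `sensitivity` (per state), `fdp` (overall) and the DE
#'   table.
#' @export
benchmark_markers <- function(model = tissue_model(), seed = 1,
                              singles_per_state = 150, logfc_min = 0.25,
                              padj_max = 0.05) {
  ds <- generate_dataset(model, n_clusters = 0, seed = seed,
                         singles_per_state = singles_per_state)
  norm <- normalize_log1p(ds$counts)
  de <- find_markers(norm, ds$truth$member_states, logfc_min = logfc_min,
                     padj_max = padj_max)
  sens <- vapply(seq_len(model$n_states), function(s)
    mean(model$markers[[s]] %in%
           de$gene_id[de$is_marker & de$state == as.character(s)]),
    numeric(1))
  called <- de[de$is_marker, ]
  fdp <- if (nrow(called) == 0) 0 else
    mean(!mapply(function(g, s) g %in% model$markers[[as.integer(s)]],
                 called$gene_id, called$state))
  list(sensitivity = sens, fdp = fdp, de = de)
}

#' Knockout-scenario benchmark
#'
#' Runs matched control and knockout simulations, builds signatures from
#' the control reference, and reports (i) the number of knockout cluster
#' libraries called pure for the removed state and (ii) the hybrid-pair
#' cell fraction in both conditions.
#'
#' @param removed_state,hybrid_pair knockout configuration.
#' @param seed base seed.
#' @param n_singles,n_clusters per-condition sizes.
#' @param n_perm permutation count.
#' @param tau hybrid score threshold for [score_cells()].
#' @return list with `n_pure_removed`, `hybrid_frac_ko`,
#'   `hybrid_frac_ctrl` and the score tables.
#' @export
benchmark_knockout <- function(removed_state = 4, hybrid_pair = c(1, 2),
                               seed = 1, n_singles = 400, n_clusters = 80,
                               n_perm = 499, tau = 0.25) {
  base <- tissue_model(knockout = list(removed_state = removed_state,
                                       hybrid_pair = hybrid_pair))
  ko <- apply_knockout(base)
  ctrl <- generate_dataset(base, n_singles, n_clusters,
                           seed = child_seed(seed, 1))
  mut <- generate_dataset(ko, n_singles, n_clusters,
                          seed = child_seed(seed, 2), condition = "ko")
  norm_c <- normalize_log1p(ctrl$counts)
  norm_m <- normalize_log1p(mut$counts)
  sc_ids <- ctrl$truth$library_id[ctrl$truth$kind == "single"]
  sm_ids <- mut$truth$library_id[mut$truth$kind == "single"]
  lab <- ctrl$truth$member_states[ctrl$truth$kind == "single"]

  de <- find_markers(norm_c[, sc_ids, drop = FALSE], lab)
  top <- top_markers(de)
  sig <- build_signatures(norm_c[, sc_ids, drop = FALSE], lab, top)

  hyb_frac <- function(scores) {
    want <- as.character(sort(hybrid_pair))
    mean(scores$call == "hybrid" &
           vapply(strsplit(scores$call_states, ",", fixed = TRUE),
                  function(v) identical(sort(v), want), logical(1)))
  }
  sc_ctrl <- score_cells(norm_c[, sc_ids, drop = FALSE], sig, tau = tau)
  sc_ko <- score_cells(norm_m[, sm_ids, drop = FALSE], sig, tau = tau)

  cl_ids <- mut$truth$library_id[mut$truth$kind == "cluster"]
  res <- identify_queries(norm_m[, cl_ids, drop = FALSE],
                          norm_c[, sc_ids, drop = FALSE], lab,
                          unique(unlist(top, use.names = FALSE)),
                          n_perm = n_perm, seed = child_seed(seed, 3))
  n_pure_removed <- sum(res$assignments$call == "pure" &
                          res$assignments$call_states ==
                          as.character(removed_state))
  list(n_pure_removed = n_pure_removed,
       hybrid_frac_ko = hyb_frac(sc_ko),
       hybrid_frac_ctrl = hyb_frac(sc_ctrl),
       scores_ko = sc_ko, scores_ctrl = sc_ctrl)
}
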