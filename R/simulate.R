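#' Synthetic 1D tissue model
#'
#' Describes a one-dimensional tissue (axis scaled to \[0,1\]) tiled by cell
#' state domains, with logistic mixing at domain boundaries, state-specific
#' marker genes, a negative-binomial expression model, and the library types
#' of a mixed single-cell / cluster experiment. All gene-level quantities
#' (log-normal baseline expression, marker assignment, QC flags) are drawn
#' once at construction under `model_seed`, so a model object is a fixed
#' "world" that [generate_dataset()] samples from.
#'
#' Defaults encode a four-state tissue whose broad second domain touches all
#' other states while the two end states never touch, cluster sizes of
#' `2 + Poisson(4)` cells (mean 6), and library sizes that separate single
#' and cluster UMI totals across the conventional 9,500 / 35,000 thresholds.
#'
#' @param n_states number of cell states `S`.
#' @param domain_layout data frame with columns `state`, `start`, `end`
#'   tiling \[0,1\] without overlap (a state may occupy several intervals).
#' @param mixing_width logistic softening width `w >= 0` of domain
#'   boundaries, in axis units.
#' @param n_genes number of genes `G`.
#' @param markers_per_state number of marker genes per state `M`
#'   (`M * S <= G`).
#' @param marker_fold_change fold change `f > 1` applied to a state's
#'   markers before renormalisation.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline relative expression.
#' @param nb_dispersion negative-binomial dispersion `theta > 0`
#'   (`Inf` gives the Poisson limit).
#' @param single_umi_median median UMI total of a single cell.
#' @param libsize_sdlog sdlog of the per-cell log-normal library-size law.
#' @param cluster_size_mean,cluster_size_min cluster size is
#'   `cluster_size_min + Poisson(cluster_size_mean - cluster_size_min)`.
#' @param cluster_window max positional spread `delta` of cluster members
#'   around the anchor (truncated-normal scale; 0 = all members at anchor).
#' @param sticky_rate probability `epsilon` that a cluster is an artefactual
#'   "sticky" aggregate whose members ignore position.
#' @param knockout optional `list(removed_state =, hybrid_pair = c(a, b))`;
#'   armed by [apply_knockout()].
#' @param model_seed seed for the gene-level draws of this world.
#' @return an object of class `tissue_model`.
#' @export
tissue_model <- function(n_states = 4,
                         domain_layout = data.frame(
                           state = 1:4,
                           start = c(0, 0.25, 0.55, 0.70),
                           end   = c(0.25, 0.55, 0.70, 1)),
                         mixing_width = 0.02,
                         n_genes = 2000,
                         markers_per_state = 30,
                         marker_fold_change = 4,
                         baseline_meanlog = 0,
                         baseline_sdlog = 1,
                         nb_dispersion = 2,
                         single_umi_median = 6000,
                         libsize_sdlog = 0.25,
                         cluster_size_mean = 6,
                         cluster_size_min = 2,
                         cluster_window = 0.03,
                         sticky_rate = 0.02,
                         knockout = NULL,
                         model_seed = 1) {
  lay <- domain_layout[order(domain_layout$start), , drop = FALSE]
  if (abs(lay$start[1]) > 1e-12 || abs(lay$end[nrow(lay)] - 1) > 1e-12 ||
      (nrow(lay) > 1 && any(abs(lay$start[-1] - lay$end[-nrow(lay)]) > 1e-12)))
    stop("domain_layout intervals must tile [0,1] without gaps or overlap")
  if (!all(lay$state %in% seq_len(n_states)))
    stop("domain_layout states must be in 1..n_states")
  if (markers_per_state * n_states > n_genes)
    stop("markers_per_state * n_states must not exceed n_genes")
  if (sticky_rate < 0 || sticky_rate > 1) stop("sticky_rate must be in [0,1]")
  if (mixing_width < 0) stop("mixing_width must be >= 0")
  if (marker_fold_change <= 1) stop("marker_fold_change must be > 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  baseline <- local_seed(model_seed, stats::rlnorm(n_genes, baseline_meanlog,
                                                   baseline_sdlog))
  markers <- lapply(seq_len(n_states), function(s)
    gene_ids[((s - 1) * markers_per_state + 1):(s * markers_per_state)])
  names(markers) <- paste0("state", seq_len(n_states))
  profiles <- lapply(seq_len(n_states), function(s) {
    p <- baseline
    p[((s - 1) * markers_per_state + 1):(s * markers_per_state)] <-
      p[((s - 1) * markers_per_state + 1):(s * markers_per_state)] *
      marker_fold_change
    p / sum(p)
  })

  free <- markers_per_state * n_states
  mito_idx <- if (n_genes >= free + 13) free + 1:13 else integer(0)
  sex_idx <- if (n_genes >= free + 23) free + 14:23 else integer(0)
  cc_idx <- if (n_genes >= free + 43) free + 24:43 else integer(0)
  gt <- gene_table(gene_ids,
                   mitochondrial = seq_len(n_genes) %in% mito_idx,
                   sex_linked = seq_len(n_genes) %in% sex_idx,
                   cell_cycle = seq_len(n_genes) %in% cc_idx,
                   marker = seq_len(n_genes) <= free)

  structure(list(n_states = n_states, domain_layout = lay,
                 mixing_width = mixing_width, n_genes = n_genes,
                 markers_per_state = markers_per_state,
                 marker_fold_change = marker_fold_change,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 nb_dispersion = nb_dispersion,
                 single_umi_median = single_umi_median,
                 libsize_sdlog = libsize_sdlog,
                 cluster_size_mean = cluster_size_mean,
                 cluster_size_min = cluster_size_min,
                 cluster_window = cluster_window,
                 sticky_rate = sticky_rate,
                 knockout = knockout, knockout_active = FALSE,
                 model_seed = model_seed,
                 gene_ids = gene_ids, baseline = baseline,
                 markers = markers, profiles = profiles,
                 gene_table = gt),
            class = "tissue_model")
}

#' @exportS3Method base::print
print.tissue_model <- function(x, ...) {
  cat("tissue_model:", x$n_states, "states,", x$n_genes, "genes,",
      x$markers_per_state, "markers/state, fold change",
      x$marker_fold_change, "\n")
  cat("  layout:",
      paste(sprintf("%d:[%.2f,%.2f)", x$domain_layout$state,
                    x$domain_layout$start, x$domain_layout$end),
            collapse = " "), "\n")
  if (x$knockout_active)
    cat("  knockout: state", x$knockout$removed_state, "-> hybrid(",
        paste(x$knockout$hybrid_pair, collapse = ","), ")\n")
  invisible(x)
}

# run code under a temporary seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# per-library child seed so subsetting a run is reproducible; kept < 2^31
child_seed <- function(seed, idx) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(idx) * 10007) %%
               2147483629 + 1)
}

#' State membership probabilities along the tissue axis
#'
#' With `mixing_width = 0` this is the indicator of the containing domain
#' (intervals are closed on the left, and the last is closed on the right).
#' With `w > 0` the probability leaks to the state across the *nearest*
#' domain boundary, decaying logistically: at signed distance `d` from that
#' boundary the neighbour receives `1 / (1 + exp(d / w))`, so a position
#' exactly on a boundary splits 0.5 / 0.5.
#'
#' @param model a [tissue_model()].
#' @param position numeric vector of positions in \[0,1\].
#' @return matrix `length(position) x n_states` of probabilities, rows
#'   summing to 1.
#' @export
state_probabilities <- function(model, position) {
  if (any(position < 0 | position > 1))
    stop("input error: position must be in [0,1]")
  lay <- model$domain_layout
  n_int <- nrow(lay)
  k <- findInterval(position, lay$start)
  out <- matrix(0, length(position), model$n_states)
  self <- lay$state[k]
  w <- model$mixing_width
  if (w == 0) {
    out[cbind(seq_along(position), self)] <- 1
    return(out)
  }
  d_left <- position - lay$start[k]
  d_right <- lay$end[k] - position
  has_left <- k > 1
  has_right <- k < n_int
  use_left <- has_left & (!has_right | d_left <= d_right)
  d <- ifelse(use_left, d_left, d_right)
  nb_int <- ifelse(use_left, k - 1, k + 1)
  nb_int[!(has_left | has_right)] <- NA
  q <- ifelse(is.na(nb_int), 0, stats::plogis(-d / w))
  neighbour <- ifelse(is.na(nb_int), self, lay$state[pmin(pmax(nb_int, 1), n_int)])
  q[neighbour == self] <- 0
  out[cbind(seq_along(position), self)] <- 1 - q
  out[cbind(seq_along(position), neighbour)] <-
    out[cbind(seq_along(position), neighbour)] + q
  out
}

# relative-expression profile for an integer state or the "hybrid" program
state_profile <- function(model, state) {
  if (identical(state, "hybrid")) {
    pair <- model$knockout$hybrid_pair
    p <- (model$profiles[[pair[1]]] + model$profiles[[pair[2]]]) / 2
    return(p / sum(p))
  }
  model$profiles[[as.integer(state)]]
}

#' Sample one cell's UMI count vector
#'
#' Gene `g` is drawn negative-binomially with mean
#' `libsize * p_g(state)` and dispersion `theta`, where `p_g(state)` is the
#' baseline relative expression multiplied by the marker fold change for the
#' state's markers and renormalised to sum to 1. `theta = Inf` gives Poisson
#' counts. `state = "hybrid"` (knockout scenario) uses the average of the
#' hybrid pair's relative-expression vectors.
#'
#' @param model a [tissue_model()].
#' @param state integer state in `1..S`, or `"hybrid"`.
#' @param libsize target expected UMI total (> 0).
#' @return integer vector of length `n_genes`, named by gene id.
#' @export
sample_cell <- function(model, state, libsize) {
  if (!identical(state, "hybrid")) {
    state <- as.integer(state)
    if (is.na(state) || state < 1 || state > model$n_states)
      stop("state must be in 1..S or \"hybrid\"")
  } else if (is.null(model$knockout))
    stop("\"hybrid\" state requires a configured knockout")
  if (libsize <= 0) stop("libsize must be > 0")
  mu <- libsize * state_profile(model, state)
  cnt <- if (is.infinite(model$nb_dispersion)) stats::rpois(model$n_genes, mu)
         else stats::rnbinom(model$n_genes, size = model$nb_dispersion, mu = mu)
  names(cnt) <- model$gene_ids
  cnt
}

# offsets ~ Normal(0, delta) truncated at +/- delta (rejection sampling)
trunc_offsets <- function(n, delta) {
  if (delta == 0 || n == 0) return(rep(0, n))
  out <- numeric(0)
  while (length(out) < n) {
    z <- stats::rnorm(2 * n, 0, delta)
    out <- c(out, z[abs(z) <= delta])
  }
  out[seq_len(n)]
}

# draw one member state at a position, honouring an armed knockout
draw_state <- function(model, position) {
  pr <- state_probabilities(model, position)[1, ]
  s <- sample.int(model$n_states, 1, prob = pr)
  if (model$knockout_active && s == model$knockout$removed_state) "hybrid"
  else as.character(s)
}

#' Generate a synthetic mixed single-cell / cluster dataset
#'
#' Single libraries hold one cell at a uniform random position with state
#' drawn from [state_probabilities()]. Cluster libraries take an anchor
#' `~ Uniform[0,1]`, a size from the shifted-Poisson law, member positions
#' `anchor + TruncatedNormal(0, delta)` clipped to \[0,1\], member states
#' drawn locally, and counts equal to the elementwise sum of the member
#' cells' draws. With probability `sticky_rate` a cluster is a "sticky"
#' artefact whose member positions are instead i.i.d. uniform. Each library
#' draws from its own child RNG stream of `seed`, so output is deterministic
#' and per-library reproducible.
#'
#' @param model a [tissue_model()] (possibly knockout-armed, see
#'   [apply_knockout()]).
#' @param n_singles,n_clusters library counts (>= 0).
#' @param seed integer master seed.
#' @param singles_per_state optional integer; when given, overrides
#'   `n_singles` with `singles_per_state * S` reference cells whose
#'   positions are drawn uniformly *within* each state's own domain and
#'   whose labels are fixed to that state (a labelled reference panel).
#' @param condition condition label stored in the annotations.
#' @param keep_member_counts if TRUE, record each cluster's member-cell
#'   count vectors in the truth object (memory-heavy; used for conservation
#'   checks).
#' @return list with `counts` (sparse matrix), `annotation`, `truth`
#'   (data frame: library_id, kind, anchor, is_sticky, n_members,
#'   member_states, member_positions), `gene_table`, and `model`.
#' @export
generate_dataset <- function(model, n_singles = 600, n_clusters = 200,
                             seed = 1, singles_per_state = NULL,
                             condition = "control",
                             keep_member_counts = FALSE) {
  stopifnot(n_singles >= 0, n_clusters >= 0)
  S <- model$n_states
  lay <- model$domain_layout
  if (!is.null(singles_per_state)) {
    ref_states <- rep(seq_len(S), each = singles_per_state)
    n_singles <- length(ref_states)
  }
  n_lib <- n_singles + n_clusters
  counts <- matrix(0L, model$n_genes, n_lib,
                   dimnames = list(model$gene_ids, NULL))
  truth <- data.frame(library_id = character(n_lib),
                      kind = character(n_lib), anchor = numeric(n_lib),
                      is_sticky = logical(n_lib),
                      n_members = integer(n_lib),
                      member_states = character(n_lib),
                      member_positions = character(n_lib),
                      stringsAsFactors = FALSE)
  member_counts <- if (keep_member_counts) vector("list", n_lib)

  for (i in seq_len(n_singles)) {
    cs <- child_seed(seed, i)
    res <- local_seed(cs, {
      if (is.null(singles_per_state)) {
        pos <- stats::runif(1)
        st <- draw_state(model, pos)
      } else {
        st_i <- ref_states[i]
        iv <- lay[lay$state == st_i, , drop = FALSE]
        wid <- iv$end - iv$start
        j <- if (nrow(iv) > 1) sample.int(nrow(iv), 1, prob = wid) else 1L
        pos <- stats::runif(1, iv$start[j], iv$end[j])
        st <- if (model$knockout_active &&
                  st_i == model$knockout$removed_state) "hybrid"
              else as.character(st_i)
      }
      ls <- stats::rlnorm(1, log(model$single_umi_median), model$libsize_sdlog)
      list(pos = pos, st = st, cnt = sample_cell(model, st, ls))
    })
    counts[, i] <- res$cnt
    truth[i, ] <- list(sprintf("S%04d", i), "single", res$pos, FALSE, 1L,
                       res$st, sprintf("%.6f", res$pos))
    if (keep_member_counts) member_counts[[i]] <- matrix(res$cnt, ncol = 1)
  }

  for (j in seq_len(n_clusters)) {
    i <- n_singles + j
    cs <- child_seed(seed, i)
    res <- local_seed(cs, {
      anchor <- stats::runif(1)
      k <- model$cluster_size_min +
        stats::rpois(1, model$cluster_size_mean - model$cluster_size_min)
      sticky <- stats::runif(1) < model$sticky_rate
      pos <- if (sticky) stats::runif(k)
             else pmin(pmax(anchor + trunc_offsets(k, model$cluster_window),
                            0), 1)
      sts <- vapply(pos, function(p) draw_state(model, p), character(1))
      mc <- vapply(seq_len(k), function(m) {
        ls <- stats::rlnorm(1, log(model$single_umi_median),
                            model$libsize_sdlog)
        sample_cell(model, sts[m], ls)
      }, numeric(model$n_genes))
      list(anchor = anchor, k = k, sticky = sticky, pos = pos, sts = sts,
           mc = mc)
    })
    counts[, i] <- as.integer(rowSums(res$mc))
    truth[i, ] <- list(sprintf("C%04d", j), "cluster", res$anchor,
                       res$sticky, res$k,
                       paste(res$sts, collapse = ","),
                       paste(sprintf("%.6f", res$pos), collapse = ","))
    if (keep_member_counts) member_counts[[i]] <- res$mc
  }

  colnames(counts) <- truth$library_id
  m <- count_matrix(counts)
  ann <- library_annotation(m, model$gene_table, condition = condition)
  ann$kind <- truth$kind
  if (keep_member_counts) attr(truth, "member_counts") <-
    stats::setNames(member_counts, truth$library_id)
  list(counts = m, annotation = ann, truth = truth,
       gene_table = model$gene_table, model = model)
}

#' Arm the knockout scenario of a tissue model
#'
#' Returns a model in which the configured `removed_state`'s domain is
#' reassigned to a hybrid program: cells drawn there express the average of
#' the `hybrid_pair` states' relative-expression vectors, and no cell is
#' ever labelled `removed_state` in the simulation truth (such members carry
#' the label `"hybrid"`).
#'
#' @param model a [tissue_model()] whose `knockout` field is configured.
#' @return the knockout-armed model.
#' @export
apply_knockout <- function(model) {
  ko <- model$knockout
  if (is.null(ko) || is.null(ko$removed_state) || is.null(ko$hybrid_pair))
    stop("model$knockout must supply removed_state and hybrid_pair")
  if (!(ko$removed_state %in% seq_len(model$n_states)))
    stop("input error: removed_state not in 1..S")
  if (length(ko$hybrid_pair) != 2 ||
      !all(ko$hybrid_pair %in% seq_len(model$n_states)))
    stop("input error: hybrid_pair must name two states")
  model$knockout_active <- TRUE
  model
}

#' @rdname generate_dataset
#' @param truth truth data frame to write.
#' @param path TSV file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname generate_dataset
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(member_states = "character",
                                   member_positions = "character"))
}
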