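#' Library-size log-normalisation
#'
#' `x_gc = ln(1 + count_gc * scale / total_c)`, the standard depth
#' normalisation upstream of marker detection and correlation.
#'
#' @param m count matrix.
#' @param scale target library size (default 10,000).
#' @return sparse normalised matrix of the same shape.
#' @export
normalize_log1p <- function(m, scale = 1e4) {
  validate_counts(m)
  tot <- Matrix::colSums(m)
  if (any(tot == 0))
    stop("input error: zero-total library: ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  out <- m
  if (length(out@x)) {
    j <- rep(seq_len(ncol(m)), diff(m@p))
    out@x <- log1p(m@x * scale / tot[j])
  }
  out
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For each state, every gene is tested state-vs-rest with a two-sided
#' Wilcoxon rank-sum test: the normal approximation with tie correction in
#' general, and exact enumeration (no ties, both group sizes <= 10).
#' P-values are Benjamini-Hochberg adjusted across genes within each state.
#' The log fold change is `ln((A + 1) / (B + 1))` where `A` and `B` are the
#' group means of `expm1(normalised expression)`. A gene is a marker of a
#' state iff `log_fc > logfc_min` and `p_adjusted < padj_max`.
#'
#' @param norm normalised matrix (see [normalize_log1p()]).
#' @param labels state label per library (>= 2 states, each with >= 3
#'   libraries).
#' @param logfc_min,padj_max marker thresholds (defaults 0.25 and 0.05).
#' @return data frame with gene_id, state, log_fc, p_value, p_adjusted,
#'   is_marker.
#' @export
find_markers <- function(norm, labels, logfc_min = 0.25, padj_max = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("input error: need >= 2 states")
  sizes <- table(labels)
  if (any(sizes < 3))
    stop("input error: state(s) with < 3 libraries: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  X <- as.matrix(norm)
  n <- ncol(X)
  G <- nrow(X)
  E <- expm1(X)
  R <- matrix(0, G, n)
  tiesum <- numeric(G)
  for (g in seq_len(G)) {
    v <- X[g, ]
    R[g, ] <- rank(v)
    nt <- rle(sort(v))$lengths
    tiesum[g] <- sum(nt^3 - nt)
  }
  has_ties <- tiesum > 0

  out <- vector("list", nlevels(labels))
  for (si in seq_len(nlevels(labels))) {
    s <- levels(labels)[si]
    idx <- labels == s
    n1 <- sum(idx); n2 <- n - n1
    W <- rowSums(R[, idx, drop = FALSE])
    U <- W - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiesum / (n * (n - 1)))
    z <- (U - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
    p <- 2 * stats::pnorm(-abs(z))
    p[sigma2 <= 0] <- 1
    p <- pmin(p, 1)
    if (n1 <= 10 && n2 <= 10) {
      for (g in which(!has_ties)) {
        p[g] <- if (U[g] > mu)
          2 * stats::pwilcox(U[g] - 1, n1, n2, lower.tail = FALSE)
        else 2 * stats::pwilcox(U[g], n1, n2)
      }
      p <- pmin(p, 1)
    }
    A <- rowMeans(E[, idx, drop = FALSE])
    B <- rowMeans(E[, !idx, drop = FALSE])
    lfc <- log((A + 1) / (B + 1))
    padj <- stats::p.adjust(p, method = "BH")
    out[[si]] <- data.frame(gene_id = rownames(X), state = s, log_fc = lfc,
                            p_value = p, p_adjusted = padj,
                            is_marker = lfc > logfc_min & padj < padj_max,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Select the top-N markers per state
#'
#' Passing markers are sorted by ascending adjusted p, ties broken by
#' descending log fold change, then lexicographic gene id, and truncated to
#' `top_n` (default 20) per state.
#'
#' @param de_results output of [find_markers()].
#' @param top_n markers to keep per state.
#' @return named list of character vectors, one per state.
#' @export
top_markers <- function(de_results, top_n = 20) {
  de <- de_results[de_results$is_marker, , drop = FALSE]
  states <- unique(de_results$state)
  out <- lapply(states, function(s) {
    d <- de[de$state == s, , drop = FALSE]
    d <- d[order(d$p_adjusted, -d$log_fc, d$gene_id), , drop = FALSE]
    utils::head(d$gene_id, top_n)
  })
  stats::setNames(out, states)
}

#' Row-standardised state signature profiles
#'
#' Over the union of the per-state marker lists, computes the mean
#' normalised expression of each gene in each state and z-scores each gene
#' row across states (constant rows become all zeros).
#'
#' @param norm normalised matrix.
#' @param labels state label per library.
#' @param gene_lists named list of per-state marker gene vectors (states
#'   must be levels of `labels`; lists non-empty). The profile is z-scored
#'   across *all* states in `labels`, even states without their own marker
#'   list.
#' @return object of class `state_signatures`: list with `states` (all
#'   label states), `markers` and `profile` (genes x states z matrix).
#' @export
build_signatures <- function(norm, labels, gene_lists) {
  labels <- factor(labels)
  if (!length(gene_lists) || any(!lengths(gene_lists)))
    stop("gene lists must be non-empty")
  if (!all(names(gene_lists) %in% levels(labels)))
    stop("gene list names must be states present in labels")
  union_genes <- unique(unlist(gene_lists, use.names = FALSE))
  missing <- setdiff(union_genes, rownames(norm))
  if (length(missing))
    stop("input error: gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  states <- levels(labels)
  means <- vapply(states, function(s)
    Matrix::rowMeans(norm[union_genes, labels == s, drop = FALSE]),
    numeric(length(union_genes)))
  if (length(union_genes) == 1) means <- matrix(means, nrow = 1)
  rownames(means) <- union_genes
  profile <- t(apply(means, 1, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(profile) <- states
  structure(list(states = states, markers = gene_lists, profile = profile),
            class = "state_signatures")
}

#' @exportS3Method base::print
print.state_signatures <- function(x, ...) {
  cat("state_signatures:", length(x$states), "states,",
      nrow(x$profile), "genes in union signature set\n")
  for (s in x$states)
    cat(" ", s, ":", length(x$markers[[s]]), "markers\n")
  invisible(x)
}

#' @rdname build_signatures
#' @param sig a `state_signatures` object.
#' @param path TSV path for the gene x state z matrix.
#' @export
write_signatures <- function(sig, path) {
  df <- data.frame(gene_id = rownames(sig$profile), sig$profile,
                   check.names = FALSE)
  mstates <- names(sig$markers)
  markers <- vapply(mstates, function(s)
    paste(sig$markers[[s]], collapse = ","), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("# markers\t", paste(mstates, unname(markers),
                                         sep = "=", collapse = "\t")),
             paste0(path, ".markers"))
  invisible(path)
}

#' @rdname build_signatures
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  profile <- as.matrix(df[, -1, drop = FALSE])
  rownames(profile) <- df$gene_id
  mline <- readLines(paste0(path, ".markers"))
  fields <- strsplit(sub("^# markers\t", "", mline), "\t")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  markers <- lapply(kv, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
  names(markers) <- vapply(kv, `[`, character(1), 1)
  structure(list(states = colnames(profile), markers = markers,
                 profile = profile), class = "state_signatures")
}
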