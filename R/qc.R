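#' Library- and gene-level QC thresholds
#'
#' Defaults follow the conventional cluster RNA-seq gates: libraries with
#' fewer than 200 detected genes or more than 5% mitochondrial counts are
#' dropped; libraries with UMI totals above 35,000 are treated as cluster
#' (multi-cell) libraries and those below 9,500 as single cells, with the
#' band in between marked ambiguous and excluded downstream.
#'
#' @param min_genes minimum detected genes per library.
#' @param max_mito_fraction maximum mitochondrial count fraction.
#' @param cluster_umi_min UMI total strictly above which a library is
#'   called a cluster.
#' @param single_umi_max UMI total strictly below which a library is
#'   called a single cell.
#' @export
qc_thresholds <- function(min_genes = 200, max_mito_fraction = 0.05,
                          cluster_umi_min = 35000, single_umi_max = 9500) {
  if (!(cluster_umi_min > single_umi_max && single_umi_max > 0))
    stop("need cluster_umi_min > single_umi_max > 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stop("max_mito_fraction must be in [0,1]")
  list(min_genes = min_genes, max_mito_fraction = max_mito_fraction,
       cluster_umi_min = cluster_umi_min, single_umi_max = single_umi_max)
}

#' Classify libraries as single, cluster or ambiguous by UMI total
#'
#' `total_umi > cluster_umi_min` gives `cluster`; `total_umi <
#' single_umi_max` gives `single`; anything in between (inclusive of both
#' thresholds) is `ambiguous` and meant to be excluded from analysis.
#'
#' @param m count matrix.
#' @param thresholds a [qc_thresholds()] list.
#' @param annotation optional annotation to update; built from `m` when
#'   absent.
#' @return annotation data frame with `kind` set.
#' @export
classify_library_kind <- function(m, thresholds = qc_thresholds(),
                                  annotation = NULL) {
  if (is.null(annotation)) annotation <- library_annotation(m)
  tot <- Matrix::colSums(m)
  annotation <- annotation[match(colnames(m), annotation$library_id), ,
                           drop = FALSE]
  annotation$total_umi <- as.integer(tot)
  annotation$kind <- ifelse(tot > thresholds$cluster_umi_min, "cluster",
                            ifelse(tot < thresholds$single_umi_max, "single",
                                   "ambiguous"))
  annotation
}

#' Remove libraries failing basic per-library filters
#'
#' Drops libraries with fewer than `min_genes` detected genes or a
#' mitochondrial count fraction above `max_mito_fraction` (both computed on
#' raw counts). Idempotent.
#'
#' @inheritParams classify_library_kind
#' @param gene_table gene table flagging mitochondrial genes.
#' @return list with `counts`, `annotation` (survivors) and `report`, a data
#'   frame of removed library ids and reasons.
#' @export
basic_filters <- function(m, annotation = NULL,
                          thresholds = qc_thresholds(), gene_table = NULL) {
  full <- library_annotation(m, gene_table)
  if (is.null(annotation)) annotation <- full
  else annotation <- annotation[match(colnames(m), annotation$library_id), ,
                                drop = FALSE]
  low_genes <- full$n_genes_detected < thresholds$min_genes
  high_mito <- full$mito_fraction > thresholds$max_mito_fraction
  fail <- low_genes | high_mito
  report <- data.frame(
    library_id = full$library_id[fail],
    reason = ifelse(low_genes[fail] & high_mito[fail], "low_genes;high_mito",
                    ifelse(low_genes[fail], "low_genes", "high_mito")),
    stringsAsFactors = FALSE)
  if (all(fail)) stop("empty after QC: no library passes the basic filters")
  list(counts = m[, !fail, drop = FALSE],
       annotation = annotation[!fail, , drop = FALSE],
       report = report)
}

#' Estimate cells per cluster from UMI totals
#'
#' `est_cells = round(total_umi / median single-cell total)`, floored at 2,
#' for every cluster library. Requires single libraries as the denominator
#' reference (errors with none, warns below 10).
#'
#' @param m count matrix.
#' @param annotation annotation with `kind` set (see
#'   [classify_library_kind()]).
#' @return the annotation with `est_cells` filled for clusters.
#' @export
estimate_cluster_sizes <- function(m, annotation) {
  annotation <- annotation[match(colnames(m), annotation$library_id), ,
                           drop = FALSE]
  singles <- annotation$kind == "single"
  if (!any(singles)) stop("estimation error: no single libraries present")
  if (sum(singles) < 10)
    warning("fewer than 10 single libraries; size estimate is unstable")
  med <- stats::median(annotation$total_umi[singles])
  cl <- annotation$kind == "cluster"
  annotation$est_cells[cl] <-
    pmax(2L, as.integer(round(annotation$total_umi[cl] / med)))
  annotation
}

#' Drop genes carrying any of the given blacklist flags
#'
#' @param m count matrix.
#' @param gene_table gene table (see [gene_table()]).
#' @param flags character subset of
#'   `c("mitochondrial", "sex_linked", "cell_cycle", "marker")`; empty is a
#'   no-op.
#' @export
remove_blacklisted_genes <- function(m, gene_table,
                                     flags = c("sex_linked")) {
  ok <- c("mitochondrial", "sex_linked", "cell_cycle", "marker")
  if (length(flags) && !all(flags %in% ok))
    stop("unknown flag(s): ", paste(setdiff(flags, ok), collapse = ", "))
  if (!length(flags)) return(m)
  bad_ids <- gene_table$gene_id[
    Reduce(`|`, lapply(flags, function(f) gene_table[[f]]))]
  keep <- !(rownames(m) %in% bad_ids)
  if (!any(keep)) stop("empty gene axis after blacklisting")
  m[keep, , drop = FALSE]
}

#' Expression-bin-matched gene-set score
#'
#' For each library, the mean log-normalised expression over `gene_set`
#' minus the mean over a control set matched on overall expression: genes
#' are binned by dataset-mean expression into `n_bins` bins and one random
#' control gene (never the set gene itself) is drawn from each set gene's
#' bin. Used e.g. for cell-cycle program scores that can then be regressed
#' out.
#'
#' @param norm log-normalised matrix (see [normalize_log1p()]).
#' @param gene_set character vector of gene ids (non-empty, present in
#'   `norm`).
#' @param n_bins number of expression bins.
#' @param seed seed for the control draw.
#' @param control_genes optional explicit control set overriding the
#'   binned draw (e.g. for self-control checks).
#' @return named numeric vector of per-library scores.
#' @export
gene_set_score <- function(norm, gene_set, n_bins = 25, seed = 1,
                           control_genes = NULL) {
  if (!length(gene_set)) stop("input error: gene_set is empty")
  if (!all(gene_set %in% rownames(norm)))
    stop("input error: gene_set genes missing from matrix")
  if (is.null(control_genes)) {
    means <- Matrix::rowMeans(norm)
    rk <- rank(means, ties.method = "first")
    bin <- ceiling(rk / length(means) * n_bins)
    names(bin) <- rownames(norm)
    control_genes <- local_seed(seed, vapply(gene_set, function(g) {
      pool <- setdiff(names(bin)[bin == bin[g]], g)
      if (!length(pool)) g else sample(pool, 1)
    }, character(1)))
  }
  set_mean <- Matrix::colMeans(norm[gene_set, , drop = FALSE])
  ctl_mean <- Matrix::colMeans(norm[control_genes, , drop = FALSE])
  set_mean - ctl_mean
}

#' Regress per-library covariates out of a normalised matrix
#'
#' Per gene, ordinary least squares of expression on the covariates (with
#' intercept; covariates are centred internally). The output is the OLS
#' residuals plus the fitted intercept, so the gene's mean level is retained
#' while the covariate directions are removed. Collinear covariate columns
#' are dropped with a warning.
#'
#' @param norm normalised matrix (genes x libraries).
#' @param covariates numeric matrix or data frame, libraries x covariates.
#' @return dense matrix of the same shape as `norm`.
#' @export
regress_out <- function(norm, covariates) {
  X <- as.matrix(covariates)
  if (nrow(X) != ncol(norm))
    stop("covariate rows must align with libraries")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    drop_cols <- qrX$pivot[seq.int(qrX$rank + 1, ncol(Xc))]
    warning("dropping collinear covariate column(s): ",
            paste(drop_cols, collapse = ", "))
    Xc <- Xc[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  Y <- t(as.matrix(norm))                    # libraries x genes
  mu <- colMeans(Y)
  if (ncol(Xc) == 0) return(as.matrix(norm)) # nothing to remove
  beta <- qr.coef(qr(Xc), sweep(Y, 2, mu))   # centred fit, no intercept term
  resid <- sweep(Y, 2, mu) - Xc %*% beta
  out <- t(sweep(resid, 2, mu, `+`))
  dimnames(out) <- dimnames(norm)
  out
}

#' Gate libraries on strict marker-expression thresholds
#'
#' A library is retained iff it strictly exceeds every rule's threshold
#' (e.g. the conventional duct-spot gate Pax2 > 0.5, EGFP > 0.8,
#' Lhx1 > 0.5 on normalised expression). An empty rule set retains
#' everything.
#'
#' @param norm normalised matrix on the same scale as the thresholds.
#' @param rules named numeric vector (`gene = min_value`) or data frame
#'   with columns `gene`, `min_value`.
#' @return character vector of retained library ids.
#' @export
gate_by_markers <- function(norm, rules) {
  if (is.data.frame(rules)) rules <- stats::setNames(rules$min_value,
                                                     rules$gene)
  if (!length(rules)) return(colnames(norm))
  unknown <- setdiff(names(rules), rownames(norm))
  if (length(unknown))
    stop("input error: unknown gene(s) in rules: ",
         paste(unknown, collapse = ", "))
  keep <- rep(TRUE, ncol(norm))
  for (g in names(rules))
    keep <- keep & (as.numeric(norm[g, ]) > rules[[g]])
  colnames(norm)[keep]
}
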