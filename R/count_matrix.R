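#' Construct a validated UMI count matrix
#'
#' The package's count container is a sparse `dgCMatrix` (genes x libraries)
#' with unique rownames (gene ids) and colnames (library barcodes). All
#' entries must be non-negative integers (UMI counts). Indices are 0-based in
#' memory only in the sense of R's usual conventions; on disk the
#' MatrixMarket format is 1-based.
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   genes in rows, libraries in columns.
#' @param gene_ids character vector of unique gene identifiers (rows).
#'   Defaults to existing rownames.
#' @param library_ids character vector of unique library barcodes (columns).
#'   Defaults to existing colnames.
#' @return a `dgCMatrix` with dimnames set, explicit zeros dropped.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         library_ids = colnames(counts)) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m * 1)
  if (is.null(gene_ids) || is.null(library_ids))
    stop("gene_ids and library_ids are required (or set as dimnames)")
  dimnames(m) <- list(as.character(gene_ids), as.character(library_ids))
  validate_counts(m)
  m
}

#' Validate the count-matrix invariants
#'
#' Checks non-negativity, integrality and uniqueness of gene and library
#' identifiers. Returns the matrix invisibly so it can be used in pipes.
#'
#' @param m a genes x libraries sparse count matrix.
#' @export
validate_counts <- function(m) {
  if (!methods::is(m, "CsparseMatrix")) stop("counts must be a sparse CsparseMatrix")
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    stop("counts must be non-negative integers")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("gene_ids must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("library_ids must be present and unique")
  invisible(m)
}

#' Read a 10x-convention MatrixMarket triplet directory
#'
#' Expects `matrix.mtx` (coordinate, 1-based indices), `barcodes.tsv` (one
#' library barcode per line) and `features.tsv` (one gene id per line; extra
#' tab-separated columns such as a symbol are allowed and ignored beyond the
#' first).
#'
#' @param dir_path directory containing the three files.
#' @return a validated sparse count matrix (see [count_matrix()]).
#' @export
read_counts_triplet <- function(dir_path) {
  paths <- file.path(dir_path, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(basename(missing), collapse = ", "))
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  feats <- read.delim(paths[3], header = FALSE, colClasses = "character")
  genes <- feats[[1]]
  if (nrow(m) != length(genes))
    stop("format error: features.tsv has ", length(genes),
         " rows but matrix declares ", nrow(m), " genes")
  if (ncol(m) != length(barcodes))
    stop("format error: barcodes.tsv has ", length(barcodes),
         " rows but matrix declares ", ncol(m), " libraries")
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (length(m@x) && (any(m@x < 0) || any(m@x != round(m@x))))
    stop("format error: negative or non-integer entries in matrix.mtx")
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m)
  m
}

#' Write a count matrix as a MatrixMarket triplet directory
#'
#' Emits `matrix.mtx` with header `%%MatrixMarket matrix coordinate integer
#' general` and 1-based indices, plus `barcodes.tsv` and `features.tsv`
#' sidecars (one identifier per line). Explicit zeros are never written, so
#' the declared nnz equals the number of nonzero counts.
#' [read_counts_triplet()] inverts this exactly.
#'
#' @param m a validated count matrix.
#' @param dir_path output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_counts_triplet <- function(m, dir_path) {
  validate_counts(m)
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", dir_path)
  m <- Matrix::drop0(m)
  trip <- Matrix::summary(m)
  con <- file(file.path(dir_path, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip))), con)
  if (nrow(trip))
    writeLines(sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x)), con)
  writeLines(colnames(m), file.path(dir_path, "barcodes.tsv"))
  writeLines(rownames(m), file.path(dir_path, "features.tsv"))
  invisible(dir_path)
}

#' Merge count matrices over a common gene axis
#'
#' The gene axis of the result is the intersection of the inputs' gene ids,
#' kept in the order of the first input (or the union with zero fill when
#' `genes = "union"`). Library axes are concatenated; barcodes that collide
#' across inputs are disambiguated with a `-<source index>` suffix.
#' Annotations, when given, are subset/reordered to the merged libraries with
#' library ids rewritten accordingly.
#'
#' @param matrices list of count matrices.
#' @param annotations optional list of annotation data frames (one per
#'   matrix, see [library_annotation()]).
#' @param genes `"intersect"` (default) or `"union"`.
#' @return list with `counts` and (if supplied) `annotation`.
#' @export
merge_datasets <- function(matrices, annotations = NULL,
                           genes = c("intersect", "union")) {
  genes <- match.arg(genes)
  stopifnot(length(matrices) >= 1)
  lapply(matrices, validate_counts)
  gene_sets <- lapply(matrices, rownames)
  if (genes == "intersect") {
    keep <- Reduce(intersect, gene_sets)
    keep <- gene_sets[[1]][gene_sets[[1]] %in% keep]
    if (!length(keep)) stop("input error: empty gene intersection")
  } else {
    keep <- unique(unlist(gene_sets))
  }
  aligned <- lapply(matrices, function(m) {
    if (genes == "union") {
      miss <- setdiff(keep, rownames(m))
      if (length(miss)) {
        pad <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0),
                                    dims = c(length(miss), ncol(m)),
                                    dimnames = list(miss, colnames(m)))
        m <- rbind(m, pad)
      }
    }
    m[keep, , drop = FALSE]
  })
  ids <- lapply(aligned, colnames)
  all_ids <- unlist(ids)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup)) {
    ids <- lapply(seq_along(ids), function(k) {
      v <- ids[[k]]
      hit <- v %in% dup
      v[hit] <- paste0(v[hit], "-", k)
      v
    })
    for (k in seq_along(aligned)) colnames(aligned[[k]]) <- ids[[k]]
  }
  out <- do.call(cbind, aligned)
  validate_counts(out)
  res <- list(counts = out)
  if (!is.null(annotations)) {
    stopifnot(length(annotations) == length(matrices))
    ann <- lapply(seq_along(annotations), function(k) {
      a <- annotations[[k]]
      a <- a[match(colnames(matrices[[k]]), a$library_id), , drop = FALSE]
      a$library_id <- ids[[k]]
      a
    })
    res$annotation <- do.call(rbind, c(ann, list(make.row.names = FALSE)))
  }
  res
}

#' Build per-library annotations from a count matrix
#'
#' Computes `total_umi`, `n_genes_detected` and (when a gene table flags
#' mitochondrial genes) `mito_fraction` on raw counts, the QC convention.
#'
#' @param m count matrix.
#' @param gene_table optional gene table (see [gene_table()]); used for the
#'   mitochondrial fraction.
#' @param kind library kind, one of `"single"`, `"cluster"`, `"spot"`,
#'   `"ambiguous"`; recycled.
#' @param condition free condition label; recycled.
#' @return data frame with columns library_id, kind, condition, total_umi,
#'   n_genes_detected, mito_fraction, est_cells (NA until estimated).
#' @export
library_annotation <- function(m, gene_table = NULL, kind = "ambiguous",
                               condition = NA_character_) {
  validate_counts(m)
  kind <- match.arg(kind, c("single", "cluster", "spot", "ambiguous"),
                    several.ok = FALSE)
  tot <- Matrix::colSums(m)
  mito <- rep(0, ncol(m))
  if (!is.null(gene_table)) {
    mg <- gene_table$gene_id[gene_table$mitochondrial]
    mg <- intersect(mg, rownames(m))
    if (length(mg)) {
      ms <- Matrix::colSums(m[mg, , drop = FALSE])
      mito <- ifelse(tot > 0, ms / tot, 0)
    }
  }
  data.frame(library_id = colnames(m),
             kind = rep(kind, ncol(m)),
             condition = rep(condition, ncol(m)),
             total_umi = as.integer(tot),
             n_genes_detected = as.integer(Matrix::colSums(m > 0)),
             mito_fraction = mito,
             est_cells = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Gene metadata table with QC flags
#'
#' One row per gene id with logical flag columns drawn from
#' mitochondrial / sex_linked / cell_cycle / marker.
#'
#' @param gene_id unique gene identifiers.
#' @param gene_symbol display symbols; defaults to the ids.
#' @param mitochondrial,sex_linked,cell_cycle,marker logical flags, recycled.
#' @export
gene_table <- function(gene_id, gene_symbol = gene_id,
                       mitochondrial = FALSE, sex_linked = FALSE,
                       cell_cycle = FALSE, marker = FALSE) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  data.frame(gene_id = as.character(gene_id),
             gene_symbol = as.character(gene_symbol),
             mitochondrial = rep_len(mitochondrial, length(gene_id)),
             sex_linked = rep_len(sex_linked, length(gene_id)),
             cell_cycle = rep_len(cell_cycle, length(gene_id)),
             marker = rep_len(marker, length(gene_id)),
             stringsAsFactors = FALSE)
}

#' @rdname library_annotation
#' @param annotation annotation data frame to write.
#' @param path TSV file path.
#' @export
write_annotations <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname library_annotation
#' @export
read_annotations <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
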