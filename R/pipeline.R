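#' Default run configuration
#'
#' One nested list drives the whole pipeline. A single global seed fans out
#' to named per-stage substreams, so adding a stage never perturbs an
#' earlier stage's draws. Thresholds mirror each module's defaults.
#'
#' @param seed global integer seed.
#' @param out_dir artifact directory.
#' @param stages stages to run, in pipeline order.
#' @return a validated config list.
#' @export
default_config <- function(seed = 1, out_dir = "clrseq_run",
                           stages = c("simulate", "qc", "signatures",
                                      "assign", "graph")) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    stages = stages,
    simulate = list(n_singles = 600, n_clusters = 200,
                    singles_per_state = NULL),
    model = list(),                      # overrides for tissue_model()
    qc = list(min_genes = 200, max_mito_fraction = 0.05,
              cluster_umi_min = 35000, single_umi_max = 9500),
    signatures = list(logfc_min = 0.25, padj_max = 0.05, top_n = 20),
    assign = list(r_min = 0.6, p_max = 0.01, n_perm = 1000,
                  n_groups = NULL, per_library = FALSE),
    graph = list(min_support = 2))
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Rejects unknown keys and thresholds outside their documented domains,
#' before any stage runs.
#'
#' @param cfg config list (see [default_config()]).
#' @return the config, invisibly usable.
#' @export
validate_config <- function(cfg) {
  known <- c("seed", "out_dir", "stages", "simulate", "model", "qc",
             "signatures", "assign", "graph")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("validation error: unknown config key(s): ",
         paste(extra, collapse = ", "))
  base <- default_config_skeleton()
  for (blk in c("simulate", "qc", "signatures", "assign", "graph")) {
    extra <- setdiff(names(cfg[[blk]]), names(base[[blk]]))
    if (length(extra))
      stop("validation error: unknown key(s) in ", blk, ": ",
           paste(extra, collapse = ", "))
    cfg[[blk]] <- utils::modifyList(base[[blk]], cfg[[blk]] %||% list())
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("validation error: seed must be an integer")
  bad_stage <- setdiff(cfg$stages,
                       c("simulate", "qc", "signatures", "assign", "graph"))
  if (length(bad_stage))
    stop("validation error: unknown stage(s): ",
         paste(bad_stage, collapse = ", "))
  with(cfg$signatures, {
    if (padj_max <= 0 || padj_max > 1)
      stop("validation error: padj_max must be in (0,1]")
    if (logfc_min < 0) stop("validation error: logfc_min must be >= 0")
  })
  with(cfg$assign, {
    if (r_min < -1 || r_min > 1)
      stop("validation error: r_min must be in [-1,1]")
    if (p_max <= 0 || p_max > 1)
      stop("validation error: p_max must be in (0,1]")
    if (n_perm < 1) stop("validation error: n_perm must be >= 1")
  })
  do.call(qc_thresholds, cfg$qc)             # validates the QC block
  if (cfg$graph$min_support < 1)
    stop("validation error: min_support must be >= 1")
  cfg
}

default_config_skeleton <- function() {
  list(simulate = list(n_singles = 600, n_clusters = 200,
                       singles_per_state = NULL),
       qc = list(min_genes = 200, max_mito_fraction = 0.05,
                 cluster_umi_min = 35000, single_umi_max = 9500),
       signatures = list(logfc_min = 0.25, padj_max = 0.05, top_n = 20),
       assign = list(r_min = 0.6, p_max = 0.01, n_perm = 1000,
                     n_groups = NULL, per_library = FALSE),
       graph = list(min_support = 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a config file (YAML or JSON)
#'
#' @param path config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(utils::modifyList(default_config(), cfg))
}

# stage substream seeds: stable name hash folded into the global seed
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  child_seed(seed, 7919 * h)
}

log_line <- function(stage, msg, level = "INFO", t0 = NULL) {
  el <- if (is.null(t0)) "" else
    sprintf(" elapsed=%.1fs", as.numeric(Sys.time()) - t0)
  message(sprintf("[%s] %s: %s%s", level, stage, msg, el))
}

#' Run the pipeline stages
#'
#' Executes the requested stages in the fixed order simulate -> qc ->
#' signatures -> assign -> graph inside `out_dir`. Each stage reads only
#' prior-stage artifacts; a stage whose outputs already exist is skipped,
#' so deleting a late artifact and re-running regenerates only downstream
#' stages. A manifest records the config hash, seed and per-stage file
#' checksums; identical configs reproduce identical checksums.
#'
#' @param cfg a validated config (see [default_config()],
#'   [read_config()]).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  order_ <- c("simulate", "qc", "signatures", "assign", "graph")
  stages <- order_[order_ %in% cfg$stages]
  t0 <- as.numeric(Sys.time())
  artifacts <- list(
    simulate = file.path(out, c("sim/matrix.mtx", "sim/annotations.tsv",
                                "sim/truth.tsv")),
    qc = file.path(out, c("qc/matrix.mtx", "qc/annotations.tsv",
                          "qc/qc_report.json")),
    signatures = file.path(out, c("signatures/markers.tsv",
                                  "signatures/signatures.tsv")),
    assign = file.path(out, "assign/assignments.tsv"),
    graph = file.path(out, c("graph/edges.tsv", "graph/orders.json",
                             "graph/report.json")))
  done <- function(st) all(file.exists(artifacts[[st]]))
  need <- function(st) {
    pred <- switch(st, qc = "simulate", signatures = "qc",
                   assign = "signatures", graph = "assign", NULL)
    if (!is.null(pred) && !done(pred))
      stop("dependency error: stage '", st, "' needs artifacts of '", pred,
           "' (missing: ",
           paste(basename(artifacts[[pred]][
             !file.exists(artifacts[[pred]])]), collapse = ", "), ")")
  }

  for (st in stages) {
    if (done(st)) { log_line(st, "outputs present, skipping", t0 = t0); next }
    need(st)
    log_line(st, "running", t0 = t0)
    switch(st,
      simulate = {
        model <- do.call(tissue_model, cfg$model)
        ds <- generate_dataset(model,
                               n_singles = cfg$simulate$n_singles,
                               n_clusters = cfg$simulate$n_clusters,
                               singles_per_state =
                                 cfg$simulate$singles_per_state,
                               seed = stage_seed(cfg$seed, "simulate"))
        write_counts_triplet(ds$counts, file.path(out, "sim"))
        write_annotations(ds$annotation, file.path(out,
                                                   "sim/annotations.tsv"))
        write_truth(ds$truth, file.path(out, "sim/truth.tsv"))
        utils::write.table(ds$gene_table,
                           file.path(out, "sim/gene_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      qc = {
        m <- read_counts_triplet(file.path(out, "sim"))
        gt <- utils::read.delim(file.path(out, "sim/gene_table.tsv"),
                                stringsAsFactors = FALSE)
        thr <- do.call(qc_thresholds, cfg$qc)
        ann <- read_annotations(file.path(out, "sim/annotations.tsv"))
        bf <- basic_filters(m, ann, thr, gt)
        ann2 <- classify_library_kind(bf$counts, thr, bf$annotation)
        keep <- ann2$kind != "ambiguous"
        m2 <- bf$counts[, keep, drop = FALSE]
        ann2 <- estimate_cluster_sizes(m2, ann2[keep, , drop = FALSE])
        m2 <- remove_blacklisted_genes(m2, gt, flags = "sex_linked")
        write_counts_triplet(m2, file.path(out, "qc"))
        write_annotations(ann2, file.path(out, "qc/annotations.tsv"))
        jsonlite::write_json(list(
          n_input = ncol(m), n_removed_filters = nrow(bf$report),
          removed = bf$report, n_ambiguous = sum(!keep),
          n_output = ncol(m2)),
          file.path(out, "qc/qc_report.json"), auto_unbox = TRUE)
      },
      signatures = {
        m <- read_counts_triplet(file.path(out, "qc"))
        ann <- read_annotations(file.path(out, "qc/annotations.tsv"))
        truth <- read_truth(file.path(out, "sim/truth.tsv"))
        singles <- ann$library_id[ann$kind == "single"]
        labels <- truth$member_states[match(singles, truth$library_id)]
        norm <- normalize_log1p(m[, singles, drop = FALSE])
        de <- find_markers(norm, labels,
                           logfc_min = cfg$signatures$logfc_min,
                           padj_max = cfg$signatures$padj_max)
        top <- top_markers(de, top_n = cfg$signatures$top_n)
        sig <- build_signatures(norm, labels, top[lengths(top) > 0])
        dir.create(file.path(out, "signatures"), showWarnings = FALSE)
        utils::write.table(de[de$is_marker, ],
                           file.path(out, "signatures/markers.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        write_signatures(sig, file.path(out, "signatures/signatures.tsv"))
      },
      assign = {
        m <- read_counts_triplet(file.path(out, "qc"))
        ann <- read_annotations(file.path(out, "qc/annotations.tsv"))
        truth <- read_truth(file.path(out, "sim/truth.tsv"))
        sig <- read_signatures(file.path(out,
                                         "signatures/signatures.tsv"))
        singles <- ann$library_id[ann$kind == "single"]
        clusters <- ann$library_id[ann$kind == "cluster"]
        labels <- truth$member_states[match(singles, truth$library_id)]
        norm <- normalize_log1p(m)
        res <- identify_queries(
          norm[, clusters, drop = FALSE], norm[, singles, drop = FALSE],
          labels, unique(unlist(sig$markers)),
          grouping = if (isTRUE(cfg$assign$per_library)) "per_library"
                     else "pattern",
          n_groups = cfg$assign$n_groups,
          n_perm = cfg$assign$n_perm,
          seed = stage_seed(cfg$seed, "assign"),
          r_min = cfg$assign$r_min, p_max = cfg$assign$p_max)
        dir.create(file.path(out, "assign"), showWarnings = FALSE)
        utils::write.table(res$assignments,
                           file.path(out, "assign/assignments.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      graph = {
        asg <- utils::read.delim(file.path(out, "assign/assignments.tsv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = c(call_states = "character"))
        g <- build_adjacency(asg, min_support = cfg$graph$min_support)
        ordering <- seriate_states(g)
        dir.create(file.path(out, "graph"), showWarnings = FALSE)
        utils::write.table(g$edges, file.path(out, "graph/edges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(orders = lapply(ordering$orders,
                                                  as.character),
                                  cost = ordering$cost),
                             file.path(out, "graph/orders.json"),
                             auto_unbox = TRUE)
        render_report(asg, g, ordering, file.path(out, "graph/report.json"),
                      params = list(seed = cfg$seed,
                                    min_support = cfg$graph$min_support))
      })
    log_line(st, "done", t0 = t0)
  }
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                   checksums = file_checksums(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL                # paths are not scientific parameters
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

file_checksums <- function(dir_) {
  files <- list.files(dir_, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  cs <- tools::md5sum(files)
  stats::setNames(as.list(unname(cs)),
                  sub(paste0("^", dir_, "/?"), "", files))
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline from a config file), `simulate`,
#' `qc`, `signatures`, `assign`, `graph` (individual stages against an
#' artifact directory). Exit codes: 0 success, 2 validation error,
#' 3 dependency error, 4 I/O error.
#'
#' @param argv character vector of arguments (e.g.
#'   `c("run", "--config", "cfg.yaml")`).
#' @return integer exit status.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: clrseq <run|simulate|qc|signatures|assign|graph>",
    "[--config FILE] [--out DIR] [--seed K]",
    "[--n-singles N] [--n-clusters M]")
  if (!length(argv)) { message(usage); return(2L) }
  sub <- argv[1]
  opt <- list(config = NULL, out = "clrseq_run", seed = 1,
              `n-singles` = NULL, `n-clusters` = NULL)
  args <- argv[-1]
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) { message("unknown option: ", args[i],
                                        "\n", usage); return(2L) }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    cfg <- if (!is.null(opt$config)) read_config(opt$config)
           else default_config()
    cfg$out_dir <- opt$out
    cfg$seed <- as.numeric(opt$seed)
    if (!is.null(opt$`n-singles`))
      cfg$simulate$n_singles <- as.integer(opt$`n-singles`)
    if (!is.null(opt$`n-clusters`))
      cfg$simulate$n_clusters <- as.integer(opt$`n-clusters`)
    cfg$stages <- if (sub == "run")
      c("simulate", "qc", "signatures", "assign", "graph") else sub
    run_pipeline(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("validation error", conditionMessage(e))) 2L
    else if (grepl("dependency error", conditionMessage(e))) 3L
    else if (grepl("I/O error", conditionMessage(e))) 4L
    else 1L
  })
  status
}
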