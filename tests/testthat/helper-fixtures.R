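# small deterministic fixtures shared across test files

rand_counts <- function(G = 20, n = 10, seed = 1, lambda = 2,
                        gene_ids = sprintf("g%03d", seq_len(G)),
                        library_ids = sprintf("lib%03d", seq_len(n))) {
  set.seed(seed)
  count_matrix(matrix(rpois(G * n, lambda), G, n,
                      dimnames = list(gene_ids, library_ids)))
}

# compact tissue world for fast unit tests
small_model <- function(...) {
  tissue_model(n_genes = 300, markers_per_state = 10, ...)
}

# per-cluster truth summaries used in several files
truth_pairs <- function(truth) {
  ms <- strsplit(truth$member_states, ",", fixed = TRUE)
  list(states = ms,
       n_distinct = vapply(ms, function(v) length(unique(v)), integer(1)),
       pair = vapply(ms, function(v) paste(sort(unique(v)), collapse = ","),
                     character(1)))
}

# independent brute-force Benjamini-Hochberg step-up (test oracle)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# hand Pearson correlation (test oracle)
pearson_hand <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
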