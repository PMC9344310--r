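# small builders shared across the suite

# symmetric zero-diagonal matrix with given upper-triangle values (by column)
sym_from_upper <- function(n, upper) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- upper
  w + t(w)
}

random_connectome <- function(n, subject = "s", tp = 1L,
                              modality = "structural") {
  m <- n * (n - 1) / 2
  connectome(sym_from_upper(n, stats::runif(m)), subject, tp, modality)
}

# matched timepoint lists from perturbed copies of per-subject matrices
toy_cohort_matrices <- function(n_sub, n_nodes, noise = 0, seed = 42) {
  set.seed(seed)
  m <- n_nodes * (n_nodes - 1) / 2
  base <- lapply(seq_len(n_sub), function(i) stats::runif(m, 0.1, 1))
  ids <- sprintf("s%02d", seq_len(n_sub))
  make <- function(tp) lapply(seq_len(n_sub), function(i) {
    u <- pmax(base[[i]] + stats::rnorm(m, sd = noise), 0)
    connectome(sym_from_upper(n_nodes, u), ids[i], tp, "structural")
  })
  list(tp1 = make(1L), tp2 = make(2L), ids = ids)
}

toy_panel <- function(n, seed = 1) {
  set.seed(seed)
  pma1 <- stats::runif(n, 30, 37)
  as_cohort_panel(data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    ga_birth = pma1 - stats::runif(n, 1, 3),
    pma_scan1 = pma1,
    pma_scan2 = stats::runif(n, 39, 44)))
}

# wrap a bare numeric matrix as a similarity_matrix
list_to_sim <- function(v) {
  structure(list(values = v,
                 subjects = as.character(seq_len(nrow(v))),
                 density = NULL, modality = "structural"),
            class = "similarity_matrix")
}

# independent oracle: Spearman via explicit average ranks + Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
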