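# Independent brute-force oracles used across test files. These re-derive
# quantities from first principles (explicit loops, direct grouping) and
# must stay independent of the package's own code paths.

# ordered level-pair counts for two coded columns, by explicit loop
count_pairs <- function(colA, colB) {
  counts <- matrix(0L, 3, 3)
  for (i in seq_along(colA))
    counts[colA[i], colB[i]] <- counts[colA[i], colB[i]] + 1L
  counts
}

# level means of v grouped by a coded column, by explicit subsetting
group_means <- function(v, column) {
  vapply(1:3, function(l) mean(v[column == l]), numeric(1))
}

# non-additivity residual straight from its definition
resid_matrix <- function(m) {
  g <- mean(m)
  r <- rowMeans(m)
  cl <- colMeans(m)
  out <- m
  for (i in 1:3) for (j in 1:3) out[i, j] <- m[i, j] - (r[i] + cl[j] - g)
  out
}

# a random valid long-format response table
random_response_table <- function(n_params = 3, species = "lettuce") {
  params <- paste0("p", seq_len(n_params))
  data.frame(species = species,
             run = rep(1:27, times = n_params),
             parameter = rep(params, each = 27),
             value = round(runif(27 * n_params, 0.5, 100), 4))
}
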