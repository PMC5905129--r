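# Independent brute-force oracle for the running-sum enrichment score:
# walks the full ranked list step by step and takes the signed maximum
# deviation from zero (ties between |max| and |min| resolve positive).
brute_force_es <- function(ranked, node_set, weight_exponent = 1) {
  hit <- ranked$node %in% node_set
  N <- nrow(ranked)
  k <- sum(hit)
  if (k == N) return(1)
  w <- abs(ranked$metric)^weight_exponent
  sw <- sum(w[hit])
  if (sw == 0) { w[hit] <- 1; sw <- k }
  step <- ifelse(hit, w / sw, -1 / (N - k))
  rs <- cumsum(step)
  hi <- max(rs); lo <- min(rs)
  if (hi >= -lo - 1e-12) hi else lo
}

# random ranked list of N nodes with continuous metrics (no ties)
random_ranked <- function(N) {
  ranked_node_list(sprintf("n%03d", seq_len(N)), rnorm(N))
}

# small module collection over a shared EC pool
make_collection <- function(n_modules, nodes_per_module, pool_size,
                            prefix = "mod") {
  pool <- sprintf("ec%04d", seq_len(pool_size))
  sets <- lapply(seq_len(n_modules), function(i) {
    sample(pool, nodes_per_module)
  })
  names(sets) <- sprintf("%s%03d", prefix, seq_len(n_modules))
  node_set_collection(sets)
}

# direct textbook pooled-variance two-sample t statistic and p-value
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# contingency-formula chi-square oracle: N (ad - bc)^2 / product of margins
chi2_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
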