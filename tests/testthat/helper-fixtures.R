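# shared fixtures, built in code at test time

# path graph a - b - c
path3_net <- function() gene_network(rbind(c("a", "b"), c("b", "c")))

# star: center h, leaves x, y, z
star_net <- function() {
  gene_network(rbind(c("h", "x"), c("h", "y"), c("h", "z")))
}

# the standard synthetic study (100-node PA network, 8 diseases x 12 drugs,
# 16 planted associations, p_in = 0.9, seed 42), computed once per test run
.std_cache <- new.env(parent = emptyenv())
std_study <- function() {
  if (is.null(.std_cache$study)) {
    .std_cache$study <- simulate_study(synthetic_config())
  }
  .std_cache$study
}

# random connected network of about n nodes (largest component of a G(n, 2n)
# random graph), for property sweeps
random_connected_net <- function(n) {
  g <- igraph::sample_gnm(n, 2L * n)
  el <- igraph::as_edgelist(g)
  largest_component(
    gene_network(cbind(sprintf("n%04d", el[, 1L]), sprintf("n%04d", el[, 2L]))))
}

# brute-force AUC oracle: count concordant positive/negative pairs, ties 0.5
auc_brute <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force Pearson oracle from the covariance formula
pearson_brute <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
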