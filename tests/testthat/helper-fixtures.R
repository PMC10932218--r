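# Small builders used across the test files.

make_ct <- function(values, genes, samples, groups, group_levels = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  ct_table(m, groups = stats::setNames(groups, samples),
           group_levels = group_levels)
}

# A tiny 3-gene x 4-sample, 2-group table with simple values.
tiny_table <- function() {
  make_ct(c(20, 20.5, 21, 21.5,
            22, 22.5, 23, 23.5,
            19, 19.2, 19.4, 19.6),
          genes = c("A", "B", "C"),
          samples = c("S1", "S2", "S3", "S4"),
          groups = c("G1", "G1", "G2", "G2"))
}

# Independent brute-force oracle for the pairwise delta-Ct statistic:
# plain loops, stats::sd on explicit difference vectors.
pairwise_dct_oracle <- function(m) {
  G <- nrow(m)
  out <- rep(NA_real_, G)
  names(out) <- rownames(m)
  for (i in seq_len(G)) {
    sds <- c()
    for (j in seq_len(G)) {
      if (j == i) next
      d <- m[i, ] - m[j, ]
      d <- d[!is.na(d)]
      if (length(d) >= 2) sds <- c(sds, stats::sd(d))
    }
    if (length(sds)) out[i] <- mean(sds)
  }
  out
}

# Random Ct table generator for property tests (optionally with holes).
random_ct <- function(n_genes, n_samples, seed, miss = 0) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, 25, 2), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  if (miss > 0) m[stats::runif(length(m)) < miss] <- NA
  groups <- rep(c("x", "y"), length.out = n_samples)
  ct_table(m, groups = stats::setNames(groups, colnames(m)))
}

# Vectorized Brown-Forsythe modified-F p-value for a null-simulation
# matrix: rows = observations, columns = replicates; balanced groups.
bf_pvals_matrix <- function(Y, group_sizes) {
  gidx <- rep(seq_along(group_sizes), group_sizes)
  n <- group_sizes
  N <- sum(n)
  G <- length(n)
  gs <- rowsum(Y, gidx)              # G x P group sums
  m <- gs / n
  ss <- rowsum(Y^2, gidx)
  v <- (ss - n * m^2) / (n - 1)      # group variances
  grand <- colSums(gs) / N
  num <- colSums(n * (m - rep(grand, each = G))^2)
  den <- colSums((1 - n / N) * v)
  Fs <- num / den
  cg <- (1 - n / N) * v / rep(den, each = G)
  df2 <- 1 / colSums(cg^2 / (n - 1))
  stats::pf(Fs, G - 1, df2, lower.tail = FALSE)
}

# Classic one-way F p-values on the same layout.
anova_pvals_matrix <- function(Y, group_sizes) {
  gidx <- rep(seq_along(group_sizes), group_sizes)
  n <- group_sizes
  N <- sum(n)
  G <- length(n)
  gs <- rowsum(Y, gidx)
  m <- gs / n
  grand <- colSums(gs) / N
  ssb <- colSums(n * (m - rep(grand, each = G))^2)
  sst <- colSums(Y^2) - N * grand^2
  ssw <- sst - ssb
  Fs <- (ssb / (G - 1)) / (ssw / (N - G))
  stats::pf(Fs, G - 1, N - G, lower.tail = FALSE)
}
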