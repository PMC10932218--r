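# Internal helpers shared across modules.

# Significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds.
sig_class <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns"))))
  out
}

# Ranks ascending by statistic; exact ties get average ranks. The display
# ordering (not the rank values) resolves residual ties alphabetically.
stability_rank <- function(stat, genes) {
  r <- rank(stat, ties.method = "average", na.last = "keep")
  names(r) <- genes
  r
}

# Deterministic ordering: ascending statistic, alphabetical within ties.
stability_order <- function(stat, genes) {
  order(stat, genes)
}

fmt4 <- function(x) sprintf("%.4f", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
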