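#' Mean and standard deviation of raw Ct per gene
#'
#' The simplest stability screen: arithmetic mean and sample standard
#' deviation (n-1 denominator) of the raw Ct values of each gene, pooling
#' all samples across groups. Lower SD = more stable. Missing wells are
#' skipped per gene; a gene with fewer than two observed values is
#' excluded from ranking and reported in the `excluded` attribute.
#'
#' @param t a [ct_table()]
#' @return data frame with columns `gene`, `mean_ct`, `sd_ct`, `n_obs`;
#'   attribute `excluded` names genes with < 2 values.
#' @export
mean_sd_stability <- function(t) {
  stopifnot(inherits(t, "ct_table"))
  n <- rowSums(!is.na(t$ct))
  excl <- rownames(t$ct)[n < 2]
  if (length(excl))
    warning("gene(s) with < 2 Ct values excluded: ", paste(excl, collapse = ", "))
  keep <- n >= 2
  m <- t$ct[keep, , drop = FALSE]
  out <- data.frame(
    gene = rownames(m),
    mean_ct = rowMeans(m, na.rm = TRUE),
    sd_ct = apply(m, 1, stats::sd, na.rm = TRUE),
    n_obs = n[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excl
  out
}

#' Coefficient of variation of linearized expression per gene
#'
#' Ct values are transformed to the linear scale as `2^-Ct` (exact
#' doubling per cycle, no efficiency correction) and the per-gene CV is
#' `100 * sd / mean` of those linear quantities across all samples pooled.
#' The CV is invariant under per-gene Ct shifts, so it measures relative
#' spread irrespective of expression level. Lower CV = more stable.
#'
#' @param t a [ct_table()]
#' @return data frame with columns `gene`, `cv_pct`, `n_obs`; attribute
#'   `excluded` as in [mean_sd_stability()].
#' @export
cv_stability <- function(t) {
  stopifnot(inherits(t, "ct_table"))
  n <- rowSums(!is.na(t$ct))
  excl <- rownames(t$ct)[n < 2]
  if (length(excl))
    warning("gene(s) with < 2 Ct values excluded: ", paste(excl, collapse = ", "))
  keep <- n >= 2
  e <- 2^(-t$ct[keep, , drop = FALSE])
  out <- data.frame(
    gene = rownames(e),
    cv_pct = 100 * apply(e, 1, stats::sd, na.rm = TRUE) /
      rowMeans(e, na.rm = TRUE),
    n_obs = n[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excl
  out
}

#' Pairwise delta-Ct stability per gene
#'
#' For each gene i, the statistic is the mean over all partner genes j of
#' the sample standard deviation of the per-sample differences
#' `Ct_i - Ct_j`. Per-sample global shifts (loading / RNA-input
#' variation) cancel in the differences, so this statistic is immune to
#' them. Only samples where both genes of a pair are observed enter a
#' pair's SD; a pair with fewer than two complete samples is dropped, and
#' a gene that loses every pair is excluded with a warning.
#'
#' @param t a [ct_table()] with at least two genes.
#' @return data frame with columns `gene`, `pairwise_avg_sd`, `n_pairs`;
#'   attribute `excluded` names genes with no usable pair.
#' @export
pairwise_dct_stability <- function(t) {
  stopifnot(inherits(t, "ct_table"))
  m <- t$ct
  G <- nrow(m)
  if (G < 2) stop("pairwise delta-Ct needs at least two genes")
  sdmat <- matrix(NA_real_, G, G, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      d <- m[i, ] - m[j, ]
      d <- d[!is.na(d)]
      if (length(d) >= 2) sdmat[i, j] <- sdmat[j, i] <- stats::sd(d)
    }
  }
  avg <- rowMeans(sdmat, na.rm = TRUE)
  npair <- rowSums(!is.na(sdmat))
  excl <- rownames(m)[npair == 0]
  if (length(excl))
    warning("gene(s) with no complete pair excluded: ",
            paste(excl, collapse = ", "))
  keep <- npair > 0
  out <- data.frame(gene = rownames(m)[keep],
                    pairwise_avg_sd = avg[keep],
                    n_pairs = npair[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}

#' Model-based (NormFinder-family) stability score
#'
#' Implements the model-based variance-components estimator for candidate
#' reference genes. Ct is a (negated) log2 abundance; since variances are
#' sign-invariant the analysis runs on Ct directly. The model for gene
#' \eqn{i}, group \eqn{g}, sample \eqn{j} is
#' \deqn{Ct_{igj} = a_i + d_{ig} + h_j + \varepsilon_{igj}}
#' with per-sample shifts \eqn{h_j} (loading variation), intergroup
#' deviations \eqn{d_{ig}} (centered over genes within each group) and
#' heteroscedastic noise \eqn{\varepsilon \sim N(0, \sigma^2_{ig})}.
#'
#' Per group the genes x samples submatrix is double-centered (gene and
#' sample means removed); the residual mean squares are corrected for the
#' centering-induced mixing of gene variances, giving the unbiased
#' intragroup estimate
#' \deqn{\hat\sigma^2_{ig} = \frac{G}{G-2}\left(v_{ig} - \frac{\bar v_g}{G-1}\right)}
#' (negative estimates truncated to zero), where \eqn{v_{ig}} is the
#' residual mean square of gene \eqn{i} in group \eqn{g} and
#' \eqn{\bar v_g} its average over genes. Intergroup deviations
#' \eqn{\hat d_{ig}} come from the gene-by-group means after removal of
#' sample effects, and are shrunk towards zero by an empirical-Bayes
#' factor \eqn{\gamma^2/(\gamma^2 + c_{ig})} where \eqn{c_{ig}} is the
#' sampling variance of \eqn{\hat d_{ig}} and \eqn{\gamma^2} the estimated
#' variance of the true \eqn{d}. The stability value of gene \eqn{i} is
#' \deqn{S_i = \frac{1}{n_{grp}}\sum_g \left(|\tilde d_{ig}| + \sqrt{c_{ig}}\right)}
#' the average over groups of the shrunken intergroup deviation magnitude
#' plus the sampling standard error of the deviation estimate — a
#' systematic-plus-random error summary in log2 (cycle) units, so both a
#' gene that moves between groups and a gene that is merely noisy score
#' badly. Lower S = more stable.
#'
#' With `use_groups = FALSE` (or a single group) the score reduces to the
#' estimated within-set standard deviation of the gene,
#' \eqn{S_i = \hat\sigma_i}, from the same double-centered model with one
#' group.
#'
#' @param t a [ct_table()] with a complete matrix (no missing wells): the
#'   two-way centering has no unique solution with holes, so missing cells
#'   are reported as an error listing them.
#' @param use_groups use the group labels (default `TRUE`). Requires at
#'   least 2 groups with at least 2 samples each and at least 3 genes;
#'   otherwise an error instructs `use_groups = FALSE`.
#' @return object of class `normfinder` — a list with `stability` (data
#'   frame: `gene`, `normfinder_S`, `normfinder_se`), `sigma2` (genes x
#'   groups intragroup variance estimates), `d` (genes x groups shrunken
#'   intergroup deviations), `d_raw` (unshrunk), `n_g` (group sizes),
#'   `gamma2`, and `degenerate` (logical: all-equal S).
#' @export
normfinder_stability <- function(t, use_groups = TRUE) {
  stopifnot(inherits(t, "ct_table"))
  m <- t$ct
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("NormFinder needs a complete Ct matrix; missing cells: ",
         paste(utils::head(paste(rownames(m)[bad[, 1]],
                                 colnames(m)[bad[, 2]], sep = "/"), 5),
               collapse = ", "))
  }
  G <- nrow(m)
  if (G < 3) stop("NormFinder needs at least 3 genes")
  grp <- t$groups
  if (!use_groups || nlevels(grp) < 2) {
    grp <- factor(rep("all", ncol(m)))
    use_groups <- FALSE
  }
  n_g <- table(grp)
  if (use_groups && any(n_g < 2))
    stop("every group needs >= 2 samples for the grouped analysis; ",
         "rerun with use_groups = FALSE")
  if (!use_groups && ncol(m) < 2) stop("need >= 2 samples")
  lev <- levels(grp)
  I <- length(lev)

  sigma2 <- matrix(0, G, I, dimnames = list(rownames(m), lev))
  d_raw <- matrix(0, G, I, dimnames = list(rownames(m), lev))
  a_gi <- matrix(0, G, I)  # gene-centered gene-by-group means
  for (k in seq_along(lev)) {
    sub <- m[, grp == lev[k], drop = FALSE]
    n <- ncol(sub)
    gene_mean <- rowMeans(sub)
    samp_mean <- colMeans(sub)
    grand <- mean(sub)
    resid <- sub - outer(gene_mean, rep(1, n)) -
      outer(rep(1, G), samp_mean) + grand
    v <- rowSums(resid^2) / (n - 1)
    s2 <- (v - mean(v) / (G - 1)) * G / (G - 2)
    sigma2[, k] <- pmax(s2, 0)
    a_gi[, k] <- gene_mean - grand
  }
  # intergroup deviation: gene-centered group means, centered over groups
  d_hat <- a_gi - rowMeans(a_gi)
  d_raw[] <- d_hat

  if (use_groups) {
    # sampling variance of d_hat (gene-centering terms included; the
    # additional over-groups centering term of order 1/I is neglected)
    nrep <- matrix(rep(as.numeric(n_g), each = G), G, I)
    c_gi <- ((1 - 1 / G)^2 * sigma2 +
               (matrix(rep(colSums(sigma2), each = G), G, I) - sigma2) / G^2) /
      nrep
    gamma2 <- max(0, sum(d_hat^2) / ((G - 1) * (I - 1)) - mean(c_gi))
    shrink <- if (gamma2 > 0) gamma2 / (gamma2 + c_gi) else matrix(0, G, I)
    d_tilde <- d_hat * shrink
    per_group <- abs(d_tilde) + sqrt(c_gi)
    S <- rowMeans(per_group)
    se <- apply(per_group, 1, stats::sd) / sqrt(I)
    d_out <- d_tilde
  } else {
    gamma2 <- 0
    S <- sqrt(sigma2[, 1])
    # se of a sd estimate, normal approximation
    se <- S / sqrt(2 * (ncol(m) - 1))
    d_out <- d_raw
    d_tilde <- d_raw
  }
  degenerate <- isTRUE(all(abs(S - S[1]) < 1e-12))
  structure(list(
    stability = data.frame(gene = rownames(m), normfinder_S = unname(S),
                           normfinder_se = unname(se),
                           row.names = NULL, stringsAsFactors = FALSE),
    sigma2 = sigma2, d = d_tilde, d_raw = d_raw,
    n_g = as.numeric(n_g), groups = lev, gamma2 = gamma2,
    use_groups = use_groups, degenerate = degenerate
  ), class = "normfinder")
}

#' @export
print.normfinder <- function(x, ...) {
  cat("Model-based stability (",
      if (x$use_groups) paste0(length(x$groups), " groups") else "no groups",
      ")\n", sep = "")
  if (x$degenerate) cat("NOTE: degenerate input — all stability values equal\n")
  df <- x$stability[stability_order(x$stability$normfinder_S, x$stability$gene), ]
  df$normfinder_S <- fmt4(df$normfinder_S)
  df$normfinder_se <- fmt4(df$normfinder_se)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Aggregate per-method stability ranks
#'
#' Combines the per-method ranks of a stability table into one aggregate
#' score: the geometric mean of the selected per-method ranks. Final
#' ordering is ascending in the score with alphabetical tie-break.
#'
#' @param ranks data frame or matrix: one row per gene, one column per
#'   method, entries = ranks (1 = most stable); rownames or a `gene`
#'   column give the gene names.
#' @param methods columns to aggregate (default: all).
#' @return data frame with `gene`, `aggregate_score`, `aggregate_rank`.
#' @export
rank_aggregate <- function(ranks, methods = NULL) {
  if (is.data.frame(ranks) && "gene" %in% colnames(ranks)) {
    genes <- ranks$gene
    ranks <- as.matrix(ranks[, setdiff(colnames(ranks), "gene"), drop = FALSE])
    rownames(ranks) <- genes
  }
  ranks <- as.matrix(ranks)
  if (is.null(methods)) methods <- colnames(ranks)
  if (length(methods) == 0) stop("empty method set")
  if (!all(methods %in% colnames(ranks)))
    stop("unknown method(s): ",
         paste(setdiff(methods, colnames(ranks)), collapse = ", "))
  sel <- ranks[, methods, drop = FALSE]
  if (anyNA(sel)) stop("every gene must be ranked by every selected method")
  score <- exp(rowMeans(log(sel)))
  out <- data.frame(gene = rownames(ranks), aggregate_score = unname(score),
                    aggregate_rank = unname(stability_rank(score, rownames(ranks))),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[stability_order(out$aggregate_score, out$gene), , drop = FALSE]
}

#' Fit all reference-gene stability estimators to a Ct table
#'
#' The main entry point of the package: runs the four stability
#' estimators — model-based (NormFinder-family) score, mean ± SD of raw
#' Ct, CV of linearized expression, and pairwise delta-Ct — ranks the
#' genes under each method (ascending statistic, average ranks for exact
#' ties), and aggregates the ranks by geometric mean.
#'
#' @param t a [ct_table()]
#' @param use_groups group-aware model-based score (default `TRUE` when
#'   the table has >= 2 groups with >= 2 samples each).
#' @param methods methods to include in the aggregate rank; subset of
#'   `c("normfinder", "sd", "cv", "dct")`.
#' @return object of class `gene_stability`: list with `table` (one row
#'   per gene: statistics, per-method ranks, aggregate), `normfinder`
#'   (the full [normfinder_stability()] fit, or `NULL` if skipped) and
#'   `methods`.
#' @examples
#' spec <- scenario_paperlike(seed = 1)
#' sim <- generate_ct_data(spec)
#' fit <- gene_stability(sim$ct)
#' summary(fit)
#' @export
gene_stability <- function(t, use_groups = TRUE,
                           methods = c("normfinder", "sd", "cv", "dct")) {
  stopifnot(inherits(t, "ct_table"))
  methods <- match.arg(methods, several.ok = TRUE)
  msd <- mean_sd_stability(t)
  cv <- cv_stability(t)
  dct <- pairwise_dct_stability(t)
  nf <- tryCatch(normfinder_stability(t, use_groups = use_groups),
                 error = function(e) NULL)
  tab <- merge(msd[, c("gene", "mean_ct", "sd_ct")], cv[, c("gene", "cv_pct")],
               by = "gene", all = TRUE)
  tab <- merge(tab, dct[, c("gene", "pairwise_avg_sd")], by = "gene", all = TRUE)
  if (!is.null(nf)) tab <- merge(tab, nf$stability, by = "gene", all = TRUE)
  else { tab$normfinder_S <- NA_real_; tab$normfinder_se <- NA_real_ }

  tab$rank_sd <- stability_rank(tab$sd_ct, tab$gene)
  tab$rank_cv <- stability_rank(tab$cv_pct, tab$gene)
  tab$rank_dct <- stability_rank(tab$pairwise_avg_sd, tab$gene)
  tab$rank_normfinder <- stability_rank(tab$normfinder_S, tab$gene)

  rank_cols <- c(normfinder = "rank_normfinder", sd = "rank_sd",
                 cv = "rank_cv", dct = "rank_dct")[methods]
  rank_cols <- rank_cols[!vapply(rank_cols, function(cn) anyNA(tab[[cn]]), TRUE)]
  if (length(rank_cols)) {
    rmat <- as.matrix(tab[, rank_cols, drop = FALSE])
    rownames(rmat) <- tab$gene
    agg <- rank_aggregate(rmat)
    tab$rank_aggregate <- agg$aggregate_rank[match(tab$gene, agg$gene)]
    tab$aggregate_score <- agg$aggregate_score[match(tab$gene, agg$gene)]
  } else {
    tab$rank_aggregate <- NA_real_
    tab$aggregate_score <- NA_real_
  }
  tab <- tab[stability_order(tab$aggregate_score, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  cols <- c("gene", "normfinder_S", "normfinder_se", "mean_ct", "sd_ct",
            "cv_pct", "pairwise_avg_sd", "rank_normfinder", "rank_sd",
            "rank_cv", "rank_dct", "rank_aggregate", "aggregate_score")
  structure(list(table = tab[, cols], normfinder = nf, methods = methods),
            class = "gene_stability")
}

#' @export
print.gene_stability <- function(x, digits = 4, ...) {
  cat("Reference-gene stability (", nrow(x$table), " genes)\n", sep = "")
  df <- x$table
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(z) round(z, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gene_stability <- function(object, n_top = 4, ...) {
  tab <- object$table
  top_of <- function(stat) {
    ok <- !is.na(tab[[stat]])
    tab$gene[ok][order(tab[[stat]][ok], tab$gene[ok])][1]
  }
  cat("Most stable gene per method:\n")
  cat("  model-based (S):", top_of("normfinder_S"), "\n")
  cat("  mean +/- SD:    ", top_of("sd_ct"), "\n")
  cat("  CV analysis:    ", top_of("cv_pct"), "\n")
  cat("  pairwise dCt:   ", top_of("pairwise_avg_sd"), "\n")
  sel <- utils::head(tab$gene[order(tab$rank_aggregate, tab$gene)], n_top)
  cat("Top", n_top, "by aggregate rank:", paste(sel, collapse = ", "), "\n")
  invisible(object)
}

#' @export
as.data.frame.gene_stability <- function(x, row.names = NULL, optional = FALSE,
                                         ...) {
  x$table
}

#' @export
plot.gene_stability <- function(x, ...) {
  tab <- x$table[order(x$table$rank_aggregate, x$table$gene), ]
  graphics::barplot(tab$aggregate_score, names.arg = tab$gene, las = 2,
                    ylab = "aggregate rank score (geometric mean)",
                    main = "Reference-gene stability", ...)
  invisible(x)
}

#' Write a stability fit as a Table-2-shaped TSV
#'
#' One row per gene with the four statistics and the per-method plus
#' aggregate ranks; tab-separated, floats at 4 decimals.
#'
#' @param x a [gene_stability()] fit.
#' @param path output TSV path.
#' @export
write_stability <- function(x, path) {
  stopifnot(inherits(x, "gene_stability"))
  write_results(x$table[, setdiff(colnames(x$table), "aggregate_score")], path)
}
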