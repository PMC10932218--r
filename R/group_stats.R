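#' Brown-Forsythe one-way ANOVA (modified F test for unequal variances)
#'
#' Tests equality of group means without assuming equal group variances.
#' This is the "Brown-Forsythe one-way ANOVA" in the sense used by common
#' statistics software for comparing means — the modified-F statistic
#' \deqn{F^* = \frac{\sum_g n_g (\bar y_g - \bar y)^2}
#'                  {\sum_g (1 - n_g/N)\, s_g^2}}
#' with `df1 = G - 1` and a fractional Satterthwaite-type `df2` computed
#' from the group variances — \emph{not} the Levene/Brown-Forsythe test
#' for equality of variances.
#'
#' @param values numeric response vector.
#' @param groups group label per value.
#' @return object of class `group_test`: list with `statistic`, `df1`,
#'   `df2`, `p_value`, `method = "brown_forsythe"`, `stars` (significance
#'   class at 0.05 / 0.01 / 0.001) and `degenerate` flag.
#' @examples
#' brown_forsythe_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
brown_forsythe_anova <- function(values, groups) {
  g <- validate_groups(values, groups)
  ok <- !is.na(values)
  values <- values[ok]; g <- droplevels(g[ok])
  ng <- as.numeric(table(g))
  if (any(ng < 2)) stop("every group needs >= 2 observations")
  m <- tapply(values, g, mean)
  v <- tapply(values, g, stats::var)
  N <- sum(ng)
  grand <- sum(ng * m) / N
  num <- sum(ng * (m - grand)^2)
  den <- sum((1 - ng / N) * v)
  G <- length(ng)
  degenerate <- FALSE
  if (den <= 0) {
    degenerate <- TRUE
    if (num <= 1e-12) { Fstar <- 0; p <- 1; df2 <- N - G }
    else { Fstar <- Inf; p <- .Machine$double.xmin; df2 <- N - G }
  } else {
    Fstar <- num / den
    cg <- (1 - ng / N) * v / den
    df2 <- 1 / sum(cg^2 / (ng - 1))
    p <- stats::pf(Fstar, G - 1, df2, lower.tail = FALSE)
  }
  group_test(Fstar, G - 1, df2, p, "brown_forsythe", degenerate)
}

#' Classic one-way ANOVA
#'
#' Equal-variance one-way ANOVA (`F`, `df1 = G - 1`, `df2 = N - G`),
#' computed via [stats::oneway.test()] with `var.equal = TRUE`, wrapped
#' into the same result container as [brown_forsythe_anova()].
#'
#' @inheritParams brown_forsythe_anova
#' @return a `group_test` object with `method = "one_way"`.
#' @export
one_way_anova <- function(values, groups) {
  g <- validate_groups(values, groups)
  ok <- !is.na(values)
  values <- values[ok]; g <- droplevels(g[ok])
  ng <- as.numeric(table(g))
  if (any(ng < 2)) stop("every group needs >= 2 observations")
  G <- length(ng); N <- sum(ng)
  v <- tapply(values, g, stats::var)
  if (all(v <= 1e-24)) {
    m <- tapply(values, g, mean)
    if (max(m) - min(m) <= 1e-12)
      return(group_test(0, G - 1, N - G, 1, "one_way", TRUE))
    return(group_test(Inf, G - 1, N - G, .Machine$double.xmin, "one_way", TRUE))
  }
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  group_test(unname(ow$statistic), unname(ow$parameter[1]),
             unname(ow$parameter[2]), ow$p.value, "one_way", FALSE)
}

group_test <- function(statistic, df1, df2, p, method, degenerate) {
  structure(list(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p, method = method, stars = sig_class(p),
                 degenerate = degenerate),
            class = "group_test")
}

validate_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("`values` and `groups` must have equal length")
  g <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  g
}

#' @export
print.group_test <- function(x, ...) {
  lab <- c(brown_forsythe = "Brown-Forsythe one-way ANOVA (modified F)",
           one_way = "One-way ANOVA")[x$method]
  cat(lab, "\n",
      "F = ", fmt4(x$statistic), ", df = (", x$df1, ", ", fmt4(x$df2),
      "), p = ", format(x$p_value, digits = 4), " [", x$stars, "]\n", sep = "")
  if (x$degenerate) cat("NOTE: degenerate input (zero within-group variance)\n")
  invisible(x)
}

#' Tukey honestly-significant-difference post-hoc comparisons
#'
#' All pairwise group comparisons with studentized-range adjusted
#' p-values, via [stats::TukeyHSD()] on a one-way [stats::aov()] fit.
#'
#' @inheritParams brown_forsythe_anova
#' @return data frame of class `posthoc` with columns `group_a`,
#'   `group_b`, `estimate` (mean difference a - b), `p_adj`, `stars`,
#'   `method = "tukey_hsd"`; attribute `degenerate` when the pooled
#'   variance is zero.
#' @export
tukey_hsd <- function(values, groups) {
  g <- validate_groups(values, groups)
  ok <- !is.na(values)
  values <- values[ok]; g <- droplevels(g[ok])
  if (any(table(g) < 2)) stop("every group needs >= 2 observations")
  v <- tapply(values, g, stats::var)
  degenerate <- all(v <= 1e-24)
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group_a = vapply(pairs, `[`, "", 1),
    group_b = vapply(pairs, `[`, "", 2),
    estimate = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  if (degenerate) out$p_adj <- ifelse(abs(out$estimate) <= 1e-12, 1, 0)
  out$stars <- sig_class(out$p_adj)
  out$method <- "tukey_hsd"
  structure(out, class = c("posthoc", "data.frame"), degenerate = degenerate)
}

#' Welch tests of every group against a calibrator, Holm-adjusted
#'
#' Calibrator-referenced post-hoc contrasts: each non-calibrator group is
#' compared to the calibrator group with a two-sided Welch two-sample
#' t-test, and the G - 1 p-values are Holm-adjusted.
#'
#' @inheritParams brown_forsythe_anova
#' @param calibrator calibrator group label.
#' @return data frame of class `posthoc` with columns `group_a` (the
#'   group), `group_b` (the calibrator), `estimate` (mean difference
#'   group - calibrator), `p_raw`, `p_adj`, `stars`,
#'   `method = "welch_holm_vs_calibrator"`.
#' @export
posthoc_vs_calibrator <- function(values, groups, calibrator) {
  g <- validate_groups(values, groups)
  ok <- !is.na(values)
  values <- values[ok]; g <- droplevels(g[ok])
  if (!calibrator %in% levels(g)) stop("calibrator group not present: ", calibrator)
  ycal <- values[g == calibrator]
  if (length(ycal) < 2) stop("calibrator group needs >= 2 observations")
  others <- setdiff(levels(g), calibrator)
  rows <- lapply(others, function(lv) {
    y <- values[g == lv]
    if (length(y) < 2 || (stats::var(y) == 0 && stats::var(ycal) == 0)) {
      est <- mean(y) - mean(ycal)
      p <- if (abs(est) <= 1e-12) 1 else 0
    } else {
      tt <- stats::t.test(y, ycal)
      est <- mean(y) - mean(ycal)
      p <- tt$p.value
    }
    data.frame(group_a = lv, group_b = calibrator, estimate = est,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "holm")
  out$stars <- sig_class(out$p_adj)
  out$method <- "welch_holm_vs_calibrator"
  structure(out, class = c("posthoc", "data.frame"))
}

#' @export
print.posthoc <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(z) signif(z, digits))
  print(df, row.names = FALSE)
  invisible(x)
}
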