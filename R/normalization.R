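#' Per-sample multi-reference normalization index
#'
#' The reference index of a sample is the arithmetic mean of the Ct
#' values of the chosen reference genes — which equals the negated log2
#' of the geometric mean of their linearized quantities `2^-Ct`, i.e. the
#' classic geometric-mean multi-reference normalizer expressed in cycles.
#'
#' @param t a [ct_table()]
#' @param refs non-empty character vector of reference genes, all present
#'   in `t`.
#' @return named numeric vector, one index per sample; a sample missing
#'   any reference value gets `NA` with a warning.
#' @export
reference_index <- function(t, refs) {
  stopifnot(inherits(t, "ct_table"))
  if (length(refs) == 0) stop("`refs` must be non-empty")
  missing_refs <- setdiff(refs, rownames(t$ct))
  if (length(missing_refs))
    stop("reference gene(s) not in table: ", paste(missing_refs, collapse = ", "))
  sub <- t$ct[refs, , drop = FALSE]
  idx <- colMeans(sub)
  if (anyNA(idx))
    warning("sample(s) missing a reference value excluded: ",
            paste(colnames(sub)[is.na(idx)], collapse = ", "))
  idx
}

#' Calibrator-relative delta-delta-Ct quantification
#'
#' Normalizes a target gene against a (multi-)reference index and
#' expresses each sample relative to a calibrator group:
#' \deqn{\Delta Ct_j = Ct_{target,j} - \mathrm{refindex}_j,\qquad
#'       RQ_j = 2^{-\Delta Ct_j}}
#' \deqn{\log_2 FC_j = -(\Delta Ct_j - \overline{\Delta Ct}_{cal})}
#' where \eqn{\overline{\Delta Ct}_{cal}} is the arithmetic mean
#' \eqn{\Delta Ct} of the calibrator group (equivalently the geometric
#' mean of the calibrator RQs on the linear scale; `calibrator_agg =
#' "median"` swaps in the median). With a single reference gene this is
#' exactly the classic `2^-ddCt` method. The calibrator group's log2 fold
#' changes average zero by construction.
#'
#' @param t a [ct_table()]
#' @param target target gene (must not be in `refs`).
#' @param refs reference gene(s).
#' @param calibrator_group calibrator group label; default = first level
#'   of the table's group ordering.
#' @param calibrator_agg `"mean"` (default) or `"median"` aggregation of
#'   the calibrator-group delta-Ct.
#' @return object of class `relquant`: a data frame with one row per
#'   usable sample and columns `sample_id`, `group`, `target`,
#'   `ref_index`, `delta_ct`, `rq`, `log2fc`, `fold_change`; attributes
#'   `refs`, `calibrator_group`, `calibrator_mean_dct`.
#' @export
delta_delta_ct <- function(t, target, refs,
                           calibrator_group = ct_group_levels(t)[1],
                           calibrator_agg = c("mean", "median")) {
  stopifnot(inherits(t, "ct_table"))
  calibrator_agg <- match.arg(calibrator_agg)
  if (target %in% refs) stop("`target` must not be one of `refs`")
  if (!target %in% rownames(t$ct)) stop("target gene not in table: ", target)
  if (!calibrator_group %in% levels(t$groups))
    stop("unknown calibrator group: ", calibrator_group)
  idx <- suppressWarnings(reference_index(t, refs))
  dct <- t$ct[target, ] - idx
  ok <- !is.na(dct)
  grp <- as.character(t$groups)
  cal <- dct[ok & grp == calibrator_group]
  if (length(cal) == 0)
    stop("no complete calibrator sample for target ", target)
  cal_ref <- if (calibrator_agg == "mean") mean(cal) else stats::median(cal)
  log2fc <- -(dct - cal_ref)
  out <- data.frame(
    sample_id = colnames(t$ct)[ok],
    group = grp[ok],
    target = target,
    ref_index = idx[ok],
    delta_ct = dct[ok],
    rq = 2^(-dct[ok]),
    log2fc = log2fc[ok],
    fold_change = 2^(log2fc[ok]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, class = c("relquant", "data.frame"),
            refs = refs, calibrator_group = calibrator_group,
            calibrator_mean_dct = cal_ref,
            group_levels = levels(t$groups))
}

#' @export
print.relquant <- function(x, digits = 4, ...) {
  cat("Relative quantification of ", x$target[1], " vs refs {",
      paste(attr(x, "refs"), collapse = ", "), "}, calibrator ",
      attr(x, "calibrator_group"), "\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(z) round(z, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-group fold-change profile of a quantification
#'
#' Collapses a [delta_delta_ct()] result to one row per group: the
#' arithmetic mean (and SD) of the per-sample log2 fold changes, plus
#' both aggregations of the relative quantity — the geometric mean
#' (`2^mean(log2fc)`-flavoured) and the arithmetic mean of RQ — clearly
#' labelled, since summaries of skewed linear-scale quantities differ.
#'
#' @param x a [delta_delta_ct()] result.
#' @return object of class `fc_profile`: data frame with columns `gene`,
#'   `group`, `mean_log2fc`, `sd_log2fc`, `n`, `rq_geomean`,
#'   `rq_arithmean`, `source` (= "qPCR"); groups in the table's declared
#'   order. Attribute `calibrator_group`.
#' @export
fold_change_profile <- function(x) {
  stopifnot(inherits(x, "relquant"))
  lev <- intersect(attr(x, "group_levels"), unique(x$group))
  rows <- lapply(lev, function(g) {
    s <- x[x$group == g, ]
    data.frame(gene = x$target[1], group = g,
               mean_log2fc = mean(s$log2fc),
               sd_log2fc = if (nrow(s) > 1) stats::sd(s$log2fc) else NA_real_,
               n = nrow(s),
               rq_geomean = 2^mean(log2(s$rq)),
               rq_arithmean = mean(s$rq),
               source = "qPCR", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("fc_profile", "data.frame"),
            calibrator_group = attr(x, "calibrator_group"),
            group_levels = attr(x, "group_levels"))
}

#' Read an externally computed log2 fold-change profile
#'
#' Ingests a per-gene, per-group log2 fold-change table (for example from
#' an RNA-seq differential-expression pipeline) for concordance analysis
#' against qPCR profiles. Expected columns: `gene`, `group`, `log2fc`
#' (tab- or comma-separated, sniffed from the header line).
#'
#' @param path input path.
#' @param source label recorded in the `source` column (default
#'   `"RNAseq"`).
#' @param group_levels optional declared group order.
#' @return `fc_profile` data frame with columns `gene`, `group`,
#'   `mean_log2fc`, `source`.
#' @export
read_fc_profile <- function(path, source = "RNAseq", group_levels = NULL) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("gene", "group", "log2fc")
  if (!all(need %in% colnames(df)))
    stop("profile file requires columns: ", paste(need, collapse = ", "))
  out <- data.frame(gene = df$gene, group = df$group,
                    mean_log2fc = as.numeric(df$log2fc),
                    source = source, stringsAsFactors = FALSE)
  structure(out, class = c("fc_profile", "data.frame"),
            group_levels = group_levels %||% unique(out$group))
}

#' Concordance of two fold-change profiles
#'
#' Per gene shared by the two profiles, computes Pearson and Spearman
#' correlations of the per-group mean log2 fold changes over the common
#' groups (ordered by the declared group order). A gene with fewer than
#' three common groups, or with zero variance in either profile, is
#' reported as not assessable (with the reason) rather than given a
#' silent `NA`.
#'
#' @param a,b `fc_profile` objects (e.g. qPCR vs RNA-seq).
#' @param min_groups minimum number of common groups (default 3).
#' @return data frame with columns `gene`, `pearson_r`, `spearman_rho`,
#'   `n_groups`, `assessable`, `reason`.
#' @export
profile_concordance <- function(a, b, min_groups = 3) {
  stopifnot(inherits(a, "fc_profile"), inherits(b, "fc_profile"))
  lev <- unique(c(attr(a, "group_levels"), attr(b, "group_levels")))
  genes <- intersect(unique(a$gene), unique(b$gene))
  rows <- lapply(genes, function(g) {
    sa <- a[a$gene == g, ]; sb <- b[b$gene == g, ]
    common <- intersect(sa$group, sb$group)
    common <- lev[lev %in% common]
    n <- length(common)
    res <- data.frame(gene = g, pearson_r = NA_real_, spearman_rho = NA_real_,
                      n_groups = n, assessable = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    if (n < min_groups) {
      res$reason <- sprintf("only %d common group(s)", n)
      return(res)
    }
    va <- sa$mean_log2fc[match(common, sa$group)]
    vb <- sb$mean_log2fc[match(common, sb$group)]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      res$reason <- "zero variance in a profile"
      return(res)
    }
    res$pearson_r <- stats::cor(va, vb)
    res$spearman_rho <- stats::cor(va, vb, method = "spearman")
    res$assessable <- TRUE
    res
  })
  do.call(rbind, rows)
}
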