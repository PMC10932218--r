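#' Ct table: genes x samples threshold-cycle matrix with group labels
#'
#' The central data container of the package: a matrix of RT-qPCR
#' threshold-cycle (Ct) values, one row per gene and one column per sample,
#' together with one group label per sample (for example the gestational
#' week of a developmental series). Missing wells are carried as `NA` and
#' never imputed; each downstream statistic documents its own missing-data
#' rule.
#'
#' @param ct numeric matrix (genes x samples) with unique, non-empty
#'   rownames (gene ids) and colnames (sample ids). Entries must be finite
#'   and strictly positive, or `NA`.
#' @param groups group label per sample: either a named vector (names =
#'   sample ids) or a vector in column order of `ct`.
#' @param group_levels optional explicit ordering of the group labels. When
#'   omitted, groups are ordered by first appearance across the samples;
#'   the first ordered group is the default calibrator downstream.
#' @return an object of class `ct_table`: a list with elements `ct`
#'   (numeric matrix) and `groups` (factor, one level set shared by all
#'   samples, names = sample ids).
#' @examples
#' m <- matrix(c(20, 21, 20.5, 22), 2, 2,
#'             dimnames = list(c("B2M", "GAPDH"), c("S1", "S2")))
#' ct_table(m, groups = c(S1 = "GW11", S2 = "GW12"))
#' @export
ct_table <- function(ct, groups, group_levels = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)")
  gn <- rownames(ct); sn <- colnames(ct)
  if (is.null(gn) || is.null(sn) || any(!nzchar(gn)) || any(!nzchar(sn)))
    stop("`ct` must have non-empty rownames (genes) and colnames (samples)")
  if (anyDuplicated(gn)) stop("duplicate gene ids: ",
                              paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(sn)) stop("duplicate sample ids: ",
                              paste(unique(sn[duplicated(sn)]), collapse = ", "))
  bad <- which(!is.na(ct) & (!is.finite(ct) | ct <= 0))
  if (length(bad))
    stop("Ct values must be finite and > 0 (or NA); offending cells: ",
         paste(utils::head(paste(gn[(bad - 1) %% nrow(ct) + 1],
                                 sn[(bad - 1) %/% nrow(ct) + 1], sep = "/"), 5),
               collapse = ", "))
  if (!is.null(names(groups))) {
    missing_meta <- setdiff(sn, names(groups))
    if (length(missing_meta))
      stop("sample(s) without group label: ", paste(missing_meta, collapse = ", "))
    groups <- groups[sn]
  } else {
    if (length(groups) != ncol(ct))
      stop("`groups` must be named by sample id or have one entry per column")
    names(groups) <- sn
  }
  if (anyNA(groups)) stop("sample(s) without group label: ",
                          paste(sn[is.na(groups)], collapse = ", "))
  groups <- as.character(groups)
  lev <- group_levels %||% unique(groups)
  if (!all(groups %in% lev))
    stop("group label(s) outside `group_levels`: ",
         paste(setdiff(groups, lev), collapse = ", "))
  out <- structure(list(ct = ct,
                        groups = factor(groups, levels = lev)),
                   class = "ct_table")
  names(out$groups) <- sn
  out
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table: ", nrow(x$ct), " genes x ", ncol(x$ct), " samples\n", sep = "")
  tab <- table(x$groups)
  cat("groups (ordered): ",
      paste(sprintf("%s(n=%d)", names(tab), tab), collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$ct))
  if (nmiss) cat("missing wells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ct_table <- function(object, ...) {
  rng <- range(object$ct, na.rm = TRUE)
  cat("Ct range: ", fmt4(rng[1]), " - ", fmt4(rng[2]), " cycles\n", sep = "")
  print(object)
  invisible(object)
}

#' @rdname ct_table
#' @param x a `ct_table`
#' @export
ct_genes <- function(x) rownames(x$ct)

#' @rdname ct_table
#' @export
ct_samples <- function(x) colnames(x$ct)

#' @rdname ct_table
#' @export
ct_group_levels <- function(x) levels(x$groups)

#' Subset a Ct table by genes and/or samples
#'
#' @param x a [ct_table()]
#' @param genes,samples character vectors of ids to keep (default: all).
#'   Group levels and their ordering are preserved.
#' @return a [ct_table()]
#' @export
ct_subset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ct_table"))
  genes <- genes %||% rownames(x$ct)
  samples <- samples %||% colnames(x$ct)
  missing_g <- setdiff(genes, rownames(x$ct))
  if (length(missing_g)) stop("unknown gene(s): ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(samples, colnames(x$ct))
  if (length(missing_s)) stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  grp <- stats::setNames(as.character(x$groups), colnames(x$ct))[samples]
  ct_table(x$ct[genes, samples, drop = FALSE], groups = grp,
           group_levels = levels(x$groups))
}

#' Convert a Ct table to a long-format data frame
#'
#' One row per (sample, gene) cell, columns `sample_id`, `group`, `gene`,
#' `ct`. Missing wells are kept as `NA` rows so the wide and long layouts
#' are bijective on non-missing cells.
#'
#' @param x a [ct_table()]
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @export
as.data.frame.ct_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    sample_id = rep(colnames(x$ct), each = nrow(x$ct)),
    group = rep(as.character(x$groups), each = nrow(x$ct)),
    gene = rep(rownames(x$ct), times = ncol(x$ct)),
    ct = as.vector(x$ct),
    stringsAsFactors = FALSE
  )
}

#' Read a Ct table from delimited text
#'
#' Reads comma-separated Ct data in either layout:
#' \describe{
#'   \item{wide}{first column = gene id, remaining columns = sample ids;
#'     group labels come from a companion sample metadata table
#'     (columns `sample_id`, `group`) passed as `meta`.}
#'   \item{long}{columns `sample_id`, `group`, `gene`, `ct`.}
#' }
#' Cells matching one of `na_tokens` (for instance the instrument's
#' `"Undetermined"`) become missing values. Any other non-numeric Ct cell
#' is a hard error reporting the offending line; a duplicated
#' (sample, gene) pair is a hard error naming the pair.
#'
#' @param path path of the CSV file.
#' @param layout `"wide"` or `"long"`.
#' @param meta for the wide layout: path of the sample metadata CSV or a
#'   data frame with columns `sample_id`, `group`.
#' @param na_tokens character vector of cell values treated as missing.
#' @param group_levels optional explicit group ordering (see [ct_table()]).
#' @return a validated [ct_table()]; row and column order as read.
#' @export
read_ct_table <- function(path, layout = c("wide", "long"), meta = NULL,
                          na_tokens = c("", "NA", "Undetermined"),
                          group_levels = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "wide") {
    raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 2) stop("wide layout needs a gene column plus sample columns")
    genes <- raw[[1]]
    samples <- colnames(raw)[-1]
    if (is.null(meta)) stop("wide layout requires `meta` (sample_id,group)")
    if (is.character(meta)) meta <- utils::read.csv(meta, colClasses = "character")
    if (!all(c("sample_id", "group") %in% colnames(meta)))
      stop("`meta` must have columns sample_id and group")
    if (anyDuplicated(genes))
      stop("duplicate gene row(s): ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      m[, j] <- parse_ct_column(raw[[j + 1]], na_tokens,
                                context = paste0("column ", samples[j]))
    }
    grp <- stats::setNames(meta$group, meta$sample_id)
    ct_table(m, groups = grp, group_levels = group_levels)
  } else {
    raw <- utils::read.csv(path, colClasses = "character")
    need <- c("sample_id", "group", "gene", "ct")
    if (!all(need %in% colnames(raw)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    key <- paste(raw$sample_id, raw$gene, sep = "/")
    if (anyDuplicated(key))
      stop("duplicate (sample, gene) pair(s): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    ctv <- parse_ct_column(raw$ct, na_tokens, lines = seq_len(nrow(raw)) + 1L)
    genes <- unique(raw$gene)
    samples <- unique(raw$sample_id)
    m <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(raw$gene, genes), match(raw$sample_id, samples))] <- ctv
    # one group per sample; conflicting labels are an error
    grp_tab <- unique(raw[, c("sample_id", "group")])
    if (anyDuplicated(grp_tab$sample_id))
      stop("conflicting group labels for sample(s): ",
           paste(unique(grp_tab$sample_id[duplicated(grp_tab$sample_id)]),
                 collapse = ", "))
    grp <- stats::setNames(grp_tab$group, grp_tab$sample_id)
    ct_table(m, groups = grp, group_levels = group_levels)
  }
}

# Parse one character vector of Ct cells; na_tokens -> NA, anything else
# non-numeric is a hard error citing the file line (long) or column (wide).
parse_ct_column <- function(x, na_tokens, lines = NULL, context = NULL) {
  x <- trimws(x)
  isna <- x %in% na_tokens
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!isna & is.na(out))
  if (length(bad)) {
    where <- if (!is.null(lines)) paste0("line ", lines[bad[1]])
             else paste0(context, ", entry ", bad[1])
    stop("non-numeric Ct value ", shQuote(x[bad[1]]), " at ", where)
  }
  out[isna] <- NA_real_
  out
}

#' Write a Ct table as CSV (wide layout plus sample metadata)
#'
#' Writes two comma-separated files readable by [read_ct_table()]: the wide
#' genes x samples matrix at `path` and the companion `sample_id,group`
#' metadata at `meta_path`. Missing wells are written as empty cells.
#'
#' @param x a [ct_table()]
#' @param path output CSV path for the Ct matrix.
#' @param meta_path output CSV path for the sample metadata.
#' @param digits decimal places for Ct values (default 4).
#' @export
write_ct_table <- function(x, path, meta_path, digits = 4) {
  m <- x$ct
  chr <- ifelse(is.na(m), "", sprintf(paste0("%.", digits, "f"), m))
  dim(chr) <- dim(m)
  df <- data.frame(gene = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  meta <- data.frame(sample_id = colnames(m), group = as.character(x$groups))
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write a result table as TSV
#'
#' Tab-separated, UTF-8, `.` decimal mark, floats at 4 decimals, fixed
#' column order as held by the data frame. Used for the stability
#' (Table-2-shaped) and normalization outputs.
#'
#' @param result a non-empty data frame.
#' @param path output path.
#' @export
write_results <- function(result, path) {
  if (!is.data.frame(result) || nrow(result) == 0)
    stop("`result` must be a non-empty data frame")
  out <- result
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt4(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
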