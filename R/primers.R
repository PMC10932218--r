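#' Primer records and reference-gene panel descriptions
#'
#' A primer record holds the forward and reverse primer sequences for one
#' RT-qPCR target plus, optionally, the declared amplicon length. By
#' default validation is strict: sequences must be non-empty and use only
#' the unambiguous DNA alphabet A/C/G/T. A lenient mode accepts the full
#' IUPAC ambiguity alphabet.
#'
#' @param target gene name the primer pair amplifies.
#' @param forward_seq,reverse_seq primer sequences, 5' to 3'.
#' @param amplicon_length optional declared amplicon length in base pairs;
#'   when given it must be at least the summed primer lengths.
#' @param strict if `TRUE` (default) only A/C/G/T are accepted; otherwise
#'   IUPAC ambiguity codes are allowed too.
#' @return an object of class `primer_record`.
#' @examples
#' primer_record("TECTA", "AGTTCTCCTACACCCTCCTG", "TGCCTCCTATCTTGACCTCC", 147)
#' @export
primer_record <- function(target, forward_seq, reverse_seq,
                          amplicon_length = NA_integer_, strict = TRUE) {
  check_dna(forward_seq, strict, "forward_seq")
  check_dna(reverse_seq, strict, "reverse_seq")
  if (!is.na(amplicon_length) &&
      amplicon_length < nchar(forward_seq) + nchar(reverse_seq))
    stop("declared amplicon_length (", amplicon_length,
         " bp) shorter than the summed primer lengths")
  structure(list(target = target,
                 forward_seq = toupper(forward_seq),
                 reverse_seq = toupper(reverse_seq),
                 amplicon_length = as.integer(amplicon_length)),
            class = "primer_record")
}

check_dna <- function(seq, strict, what) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq))
    stop(what, " must be a non-empty DNA string")
  alphabet <- if (strict) "ACGT" else "ACGTRYSWKMBDHVN"
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!chars %in% strsplit(alphabet, "")[[1]])
  if (length(bad))
    stop("invalid character ", shQuote(chars[bad[1]]), " in ", what,
         " at position ", bad[1])
  invisible(TRUE)
}

#' @export
print.primer_record <- function(x, ...) {
  cat("primer_record for ", x$target, "\n",
      "  forward: 5'-", x$forward_seq, "-3' (", nchar(x$forward_seq), " bp)\n",
      "  reverse: 5'-", x$reverse_seq, "-3' (", nchar(x$reverse_seq), " bp)\n",
      sep = "")
  if (!is.na(x$amplicon_length))
    cat("  amplicon: ", x$amplicon_length, " bp\n", sep = "")
  invisible(x)
}

#' Length of one primer of a record
#'
#' @param p a [primer_record()]
#' @param which `"forward"` or `"reverse"`
#' @return primer length in base pairs (integer).
#' @export
primer_length <- function(p, which = c("forward", "reverse")) {
  which <- match.arg(which)
  stopifnot(inherits(p, "primer_record"))
  nchar(if (which == "forward") p$forward_seq else p$reverse_seq)
}

#' Read a primer CSV into a list of primer records
#'
#' Expects columns `target`, `forward_seq`, `reverse_seq` and optionally
#' `amplicon_length`.
#'
#' @param path CSV path.
#' @param strict strict A/C/G/T validation (default `TRUE`).
#' @return named list of [primer_record()]s.
#' @export
read_primers <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "forward_seq", "reverse_seq")
  if (!all(need %in% colnames(df)))
    stop("primer CSV requires columns: ", paste(need, collapse = ", "))
  amp <- if ("amplicon_length" %in% colnames(df)) df$amplicon_length
         else rep(NA_integer_, nrow(df))
  out <- lapply(seq_len(nrow(df)), function(i)
    primer_record(df$target[i], df$forward_seq[i], df$reverse_seq[i],
                  amp[i], strict = strict))
  stats::setNames(out, df$target)
}

#' Read a reference-gene panel description
#'
#' A panel table describes the candidate reference genes: columns `gene`,
#' `full_name`, `function.` (cellular role), `amplicon_length`,
#' `accession`. Gene names must be unique.
#'
#' @param path CSV path.
#' @return data frame with one row per panel gene.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% colnames(df)) stop("panel CSV requires a `gene` column")
  if (anyDuplicated(df$gene))
    stop("duplicate panel gene(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df
}
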