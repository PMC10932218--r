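#' Generative specification for synthetic Ct data
#'
#' Describes a grouped RT-qPCR experiment under the variance-components
#' model
#' \deqn{Ct_{igj} = a_i + d_{ig} + h_j + \varepsilon_{igj}}
#' for gene \eqn{i}, group \eqn{g}, sample \eqn{j}: per-gene baseline Ct
#' \eqn{a_i} (cycles), fixed intergroup effects \eqn{d_{ig}} (log2 units
#' = cycles), a per-sample loading shift \eqn{h_j \sim N(0, \tau^2)}
#' shared by all genes of the sample (RNA-input variation), and
#' heteroscedastic noise \eqn{\varepsilon_{igj} \sim N(0, \sigma^2_{ig})}.
#' Target genes ride on the same sample shifts with Ct
#' \eqn{a_t - trajectory_g + h_j + \varepsilon}, so that a rising log2
#' trajectory lowers Ct.
#'
#' @param baselines named numeric vector: baseline Ct per gene (cycles).
#' @param groups ordered group labels.
#' @param n_per_group sample count per group (recycled to the number of
#'   groups).
#' @param group_effects genes x groups matrix of intergroup effects in
#'   log2 units (default all zero). Dimnames, when present, must match.
#' @param noise_sd genes x groups matrix, per-gene vector, or scalar of
#'   noise SDs (cycles).
#' @param sample_shift_sd SD tau of the shared per-sample shift (cycles).
#' @param targets named list of target genes; each element is
#'   `list(baseline =, trajectory =, noise_sd =)` with `trajectory` a
#'   per-group log2 fold-change vector whose calibrator (first-group)
#'   entry is 0.
#' @param seed mandatory integer seed: generation is fully deterministic.
#' @return object of class `synthetic_spec`.
#' @seealso [generate_ct_data()], [scenario_paperlike()]
#' @export
synthetic_spec <- function(baselines, groups, n_per_group,
                           group_effects = NULL, noise_sd = 0.3,
                           sample_shift_sd = 0, targets = list(), seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("`seed` is mandatory (no silent nondeterminism)")
  genes <- names(baselines)
  problems <- character()
  if (is.null(genes) || any(!nzchar(genes)) || anyDuplicated(genes))
    problems <- c(problems, "baselines: must be named uniquely by gene")
  G <- length(baselines); K <- length(groups)
  if (K < 1 || anyDuplicated(groups)) problems <- c(problems, "groups: non-empty, unique")
  n_per_group <- rep(as.integer(n_per_group), length.out = K)
  if (any(n_per_group < 1)) problems <- c(problems, "n_per_group: sizes >= 1")
  if (is.null(group_effects)) group_effects <- matrix(0, G, K)
  if (!is.matrix(group_effects) || !all(dim(group_effects) == c(G, K)))
    problems <- c(problems, "group_effects: must be a genes x groups matrix")
  noise_sd <- expand_sd(noise_sd, G, K)
  if (any(noise_sd < 0)) problems <- c(problems, "noise_sd: SDs >= 0")
  if (sample_shift_sd < 0) problems <- c(problems, "sample_shift_sd: SD >= 0")
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    if (nm %in% genes) problems <- c(problems, paste0("targets: name collision with gene ", nm))
    if (length(tg$trajectory) != K)
      problems <- c(problems, paste0("targets$", nm, ": trajectory must cover all groups"))
    else if (abs(tg$trajectory[1]) > 1e-12)
      problems <- c(problems, paste0("targets$", nm, ": calibrator entry must be 0"))
    if (is.null(tg$noise_sd) || tg$noise_sd < 0)
      problems <- c(problems, paste0("targets$", nm, ": noise_sd >= 0 required"))
  }
  if (length(problems))
    stop("invalid synthetic spec:\n  ", paste(problems, collapse = "\n  "))
  dimnames(group_effects) <- dimnames(noise_sd) <- list(genes, groups)
  structure(list(baselines = baselines, groups = as.character(groups),
                 n_per_group = n_per_group, group_effects = group_effects,
                 noise_sd = noise_sd, sample_shift_sd = sample_shift_sd,
                 targets = targets, seed = as.integer(seed)),
            class = "synthetic_spec")
}

expand_sd <- function(x, G, K) {
  if (is.matrix(x)) { stopifnot(all(dim(x) == c(G, K))); return(x) }
  if (length(x) == 1) return(matrix(x, G, K))
  if (length(x) == G) return(matrix(x, G, K))
  stop("noise_sd: scalar, per-gene vector, or genes x groups matrix")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec: ", length(x$baselines), " reference genes, ",
      length(x$targets), " target(s), groups ",
      paste(x$groups, collapse = " < "), " (n = ",
      paste(x$n_per_group, collapse = ", "), "), tau = ",
      x$sample_shift_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ground-truth stability ordering of a spec
#'
#' The declared stability functional is NormFinder-flavoured:
#' `mean_g(|d_ig|) + mean_g(sigma_ig)` per gene (lower = more stable),
#' with alphabetical tie-break, computed from the generating parameters —
#' never from data.
#'
#' @param spec a [synthetic_spec()]
#' @return data frame `gene`, `true_instability`, `true_rank`.
#' @export
true_stability <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  s <- rowMeans(abs(spec$group_effects)) + rowMeans(spec$noise_sd)
  genes <- names(spec$baselines)
  out <- data.frame(gene = genes, true_instability = unname(s),
                    stringsAsFactors = FALSE)
  out <- out[stability_order(out$true_instability, out$gene), ]
  out$true_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic Ct table with known ground truth
#'
#' Draws a complete Ct matrix under the model of [synthetic_spec()]
#' (reference genes and declared target genes alike, sharing the same
#' per-sample loading shifts). The random-number contract: one
#' Mersenne-Twister stream seeded from `spec$seed`; draw order is sample
#' shifts first (sample-major), then reference-gene noise (gene-major),
#' then target-gene noise in declared target order. Identical spec +
#' seed gives bit-identical output.
#'
#' @param spec a [synthetic_spec()]
#' @param mask_rate optional missing-data injection: fraction of wells
#'   (reference genes only) masked to `NA` uniformly at random (default
#'   0 = complete matrix).
#' @return list with `ct` (a [ct_table()]), `truth` (list: the spec, the
#'   declared-true stability ordering from [true_stability()], the true
#'   per-group target trajectories, and the drawn per-sample shifts `h`).
#' @export
generate_ct_data <- function(spec, mask_rate = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  stopifnot(mask_rate >= 0, mask_rate < 1)
  genes <- names(spec$baselines)
  G <- length(genes); K <- length(spec$groups)
  N <- sum(spec$n_per_group)
  grp <- rep(spec$groups, spec$n_per_group)
  samples <- sprintf("S%02d_%s", seq_len(N), grp)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  h <- stats::rnorm(N, 0, spec$sample_shift_sd)
  gidx <- match(grp, spec$groups)
  m <- matrix(NA_real_, G, N, dimnames = list(genes, samples))
  for (i in seq_len(G)) {
    eps <- stats::rnorm(N, 0, spec$noise_sd[i, gidx])
    m[i, ] <- spec$baselines[i] + spec$group_effects[i, gidx] + h + eps
  }
  trajectories <- list()
  for (nm in names(spec$targets)) {
    tg <- spec$targets[[nm]]
    eps <- stats::rnorm(N, 0, tg$noise_sd)
    row <- tg$baseline - tg$trajectory[gidx] + h + eps
    m <- rbind(m, matrix(row, 1, N, dimnames = list(nm, samples)))
    trajectories[[nm]] <- stats::setNames(tg$trajectory, spec$groups)
  }
  if (mask_rate > 0) {
    nref <- G * N
    mask <- which(stats::runif(nref) < mask_rate)
    m[seq_len(G), ][mask] <- NA_real_
  }
  tab <- ct_table(m, groups = stats::setNames(grp, samples),
                  group_levels = spec$groups)
  truth <- list(spec = spec, stability = true_stability(spec),
                trajectories = trajectories,
                h = stats::setNames(h, samples))
  list(ct = tab, truth = truth)
}

#' Append a target gene with a known trajectory to a generated table
#'
#' Adds Ct rows for one target gene to an existing synthetic table,
#' reusing the table's drawn per-sample shifts so the target rides the
#' same loading variation as the reference genes:
#' `Ct = baseline - trajectory_g + h_j + noise`.
#'
#' @param tab a [ct_table()] produced by [generate_ct_data()].
#' @param truth the matching `truth` element (carries `h` and the spec).
#' @param name target gene name (must not collide with existing genes).
#' @param trajectory per-group log2 fold change vs the first group
#'   (calibrator entry 0), in the table's group order.
#' @param noise_sd noise SD in cycles.
#' @param baseline baseline Ct of the target.
#' @param seed seed for the target's noise draws.
#' @return list with extended `ct` and updated `truth`.
#' @export
generate_target_gene <- function(tab, truth, name, trajectory, noise_sd,
                                 baseline, seed) {
  stopifnot(inherits(tab, "ct_table"))
  if (name %in% rownames(tab$ct)) stop("gene already present: ", name)
  K <- nlevels(tab$groups)
  if (length(trajectory) != K) stop("trajectory must cover all ", K, " groups")
  if (abs(trajectory[1]) > 1e-12) stop("calibrator (first group) entry must be 0")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  gidx <- as.integer(tab$groups)
  eps <- stats::rnorm(ncol(tab$ct), 0, noise_sd)
  row <- baseline - trajectory[gidx] + truth$h[colnames(tab$ct)] + eps
  m <- rbind(tab$ct, matrix(row, 1, ncol(tab$ct),
                            dimnames = list(name, colnames(tab$ct))))
  truth$trajectories[[name]] <- stats::setNames(trajectory, levels(tab$groups))
  list(ct = ct_table(m, groups = tab$groups,
                     group_levels = levels(tab$groups)),
       truth = truth)
}

#' Study-like preset: 12-gene developmental panel
#'
#' A convenience spec emulating a 12-candidate reference-gene panel over
#' five ordered developmental groups (GW11 ... GW19, n = 6 each):
#' baselines span the realistic qPCR range with one very highly
#' expressed gene below 10 cycles (an 18S-rRNA-like candidate) and the
#' rest between 18 and 26 cycles; ten genes are stable (noise SD 0.2-0.5
#' cycles, no group effects), one gene carries deliberate intergroup
#' effects of +/-1 log2 (RRN18S) and one carries inflated noise of SD
#' 1.2 cycles (ACTB); shared per-sample loading shifts have SD 0.4
#' cycles. Two target genes (OTOF- and TECTA-like, names marked
#' synthetic) rise monotonically to +3 and +2.8 log2 over the course.
#' Group sizes reflect a power consideration: six samples per group is
#' the smallest size at which the model-based score reliably resolves
#' both designed instability modes from the stable background.
#'
#' @param seed integer seed for [generate_ct_data()].
#' @param n_per_group samples per group (default 6).
#' @return a [synthetic_spec()].
#' @export
scenario_paperlike <- function(seed, n_per_group = 6) {
  baselines <- c(ACTB = 23.2, RRN18S = 9.0, TUBB = 25.6, GAPDH = 18.8,
                 B2M = 20.4, RPLP = 18.3, TBP = 25.9, GUSB = 25.7,
                 HPRT1 = 25.8, PPIA = 19.8, UBC = 20.0, YWHAZ = 22.0)
  groups <- c("GW11", "GW13", "GW15", "GW17", "GW19")
  G <- length(baselines); K <- length(groups)
  eff <- matrix(0, G, K, dimnames = list(names(baselines), groups))
  eff["RRN18S", ] <- c(1, -1, 1, -1, 1)   # deliberate +/-1 log2 group effects
  sds <- c(ACTB = 1.2, RRN18S = 0.3, TUBB = 0.45, GAPDH = 0.30,
           B2M = 0.25, RPLP = 0.35, TBP = 0.50, GUSB = 0.40,
           HPRT1 = 0.20, PPIA = 0.30, UBC = 0.35, YWHAZ = 0.45)
  targets <- list(
    OTOF_syn = list(baseline = 27.5,
                    trajectory = c(0, 0.75, 1.5, 2.25, 3.0), noise_sd = 0.3),
    TECTA_syn = list(baseline = 28.0,
                     trajectory = c(0, 0.5, 1.2, 2.0, 2.8), noise_sd = 0.3)
  )
  synthetic_spec(baselines = baselines, groups = groups,
                 n_per_group = n_per_group,
                 group_effects = eff, noise_sd = sds[names(baselines)],
                 sample_shift_sd = 0.4, targets = targets, seed = seed)
}
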