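#' End-to-end pipeline runners
#'
#' Three high-level commands mirror a complete study workflow: simulate a
#' grouped Ct data set with known ground truth, evaluate reference-gene
#' stability, and normalize target genes against a reference set. Each
#' writes deterministic tab-/comma-separated outputs plus a JSON run
#' manifest (configuration echo, seed, package and R versions) so a run
#' can be reproduced exactly; rerunning with the same configuration and
#' inputs gives byte-identical files.
#'
#' @name pipeline
NULL

write_manifest <- function(out_dir, command, config) {
  manifest <- list(
    command = command,
    config = config,
    package = "qpcrstab",
    package_version = as.character(utils::packageVersion("qpcrstab")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

ensure_outdir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' @rdname pipeline
#' @param out_dir output directory (created if absent).
#' @param preset scenario preset; currently `"paperlike"`.
#' @param seed integer seed (mandatory).
#' @param n_per_group samples per group for the preset.
#' @param overwrite allow writing into a non-empty directory.
#' @return `run_simulate`: invisibly, a list with the written file paths
#'   and the generated objects.
#' @export
run_simulate <- function(out_dir, preset = "paperlike", seed,
                         n_per_group = 4, overwrite = FALSE) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("`seed` is mandatory")
  ensure_outdir(out_dir, overwrite)
  spec <- scenario_paperlike(seed = seed, n_per_group = n_per_group)
  sim <- generate_ct_data(spec)
  ct_path <- file.path(out_dir, "ct_wide.csv")
  meta_path <- file.path(out_dir, "samples.csv")
  write_ct_table(sim$ct, ct_path, meta_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  truth <- list(
    seed = spec$seed,
    groups = spec$groups, n_per_group = spec$n_per_group,
    baselines = as.list(spec$baselines),
    noise_sd = apply(spec$noise_sd, 1, as.list),
    group_effects = apply(spec$group_effects, 1, as.list),
    sample_shift_sd = spec$sample_shift_sd,
    stability = sim$truth$stability,
    trajectories = lapply(sim$truth$trajectories, as.list)
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest(out_dir, "simulate",
                 list(preset = preset, seed = seed, n_per_group = n_per_group))
  invisible(list(ct = ct_path, meta = meta_path, truth = truth_path,
                 sim = sim))
}

#' @rdname pipeline
#' @param ct_path Ct CSV path (see [read_ct_table()]).
#' @param meta_path sample metadata CSV (wide layout only).
#' @param layout `"wide"` or `"long"`.
#' @param group_levels optional explicit group order.
#' @param use_groups group-aware model-based score.
#' @return `run_stability`: invisibly, a list with the
#'   [gene_stability()] fit, the per-gene omnibus classification data
#'   frame, and the written paths. The significance table classifies each
#'   gene's Ct values across groups with the Brown-Forsythe one-way ANOVA
#'   into the ns / * / ** / *** bins.
#' @export
run_stability <- function(ct_path, meta_path = NULL, layout = "wide",
                          out_dir, group_levels = NULL, use_groups = TRUE,
                          overwrite = FALSE) {
  tab <- read_ct_table(ct_path, layout = layout, meta = meta_path,
                       group_levels = group_levels)
  ensure_outdir(out_dir, overwrite)
  fit <- gene_stability(tab, use_groups = use_groups)
  write_stability(fit, file.path(out_dir, "stability.tsv"))
  sig <- do.call(rbind, lapply(rownames(tab$ct), function(g) {
    y <- tab$ct[g, ]
    res <- tryCatch(brown_forsythe_anova(y, tab$groups),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(gene = g, f_star = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p_value = NA_real_,
                        stars = NA_character_, stringsAsFactors = FALSE))
    data.frame(gene = g, f_star = res$statistic, df1 = res$df1,
               df2 = res$df2, p_value = res$p_value, stars = res$stars,
               stringsAsFactors = FALSE)
  }))
  write_results(sig, file.path(out_dir, "group_significance.tsv"))
  write_manifest(out_dir, "stability",
                 list(ct = ct_path, meta = meta_path, layout = layout,
                      group_levels = group_levels %||% "first-appearance",
                      use_groups = use_groups))
  invisible(list(fit = fit, significance = sig, out_dir = out_dir))
}

#' @rdname pipeline
#' @param refs reference gene set (combined index); each reference is
#'   additionally used alone so the influence of the reference choice on
#'   the profile can be inspected.
#' @param targets target gene(s), disjoint from `refs`.
#' @param calibrator_group calibrator; default = first ordered group.
#' @param posthoc post-hoc choice for the per-target group test:
#'   `"tukey"`, `"vs-calibrator"`, or `"none"`.
#' @return `run_normalize`: invisibly, a list with per-target results:
#'   the combined-set [delta_delta_ct()] quantification, per-reference
#'   profiles, the omnibus `group_test` on per-sample log2fc, and the
#'   post-hoc table.
#' @export
run_normalize <- function(ct_path, meta_path = NULL, layout = "wide",
                          out_dir, refs, targets,
                          calibrator_group = NULL, group_levels = NULL,
                          posthoc = c("tukey", "vs-calibrator", "none"),
                          overwrite = FALSE) {
  posthoc <- match.arg(posthoc)
  tab <- read_ct_table(ct_path, layout = layout, meta = meta_path,
                       group_levels = group_levels)
  if (length(intersect(refs, targets)))
    stop("targets must be disjoint from refs")
  calibrator_group <- calibrator_group %||% ct_group_levels(tab)[1]
  ensure_outdir(out_dir, overwrite)
  results <- list()
  for (tg in targets) {
    rq <- delta_delta_ct(tab, tg, refs, calibrator_group)
    prof <- fold_change_profile(rq)
    # one profile per single reference, mirroring per-reference panels
    per_ref <- lapply(refs, function(r)
      fold_change_profile(delta_delta_ct(tab, tg, r, calibrator_group)))
    names(per_ref) <- refs
    omni <- brown_forsythe_anova(rq$log2fc, rq$group)
    ph <- switch(posthoc,
                 tukey = tukey_hsd(rq$log2fc, rq$group),
                 `vs-calibrator` = posthoc_vs_calibrator(rq$log2fc, rq$group,
                                                         calibrator_group),
                 none = NULL)
    write_results(as.data.frame(rq),
                  file.path(out_dir, paste0("normalized_", tg, ".tsv")))
    all_prof <- do.call(rbind, c(list(cbind(ref_set = paste(refs, collapse = "+"),
                                            as.data.frame(prof))),
                                 lapply(refs, function(r)
                                   cbind(ref_set = r,
                                         as.data.frame(per_ref[[r]])))))
    write_results(all_prof, file.path(out_dir, paste0("profile_", tg, ".tsv")))
    omni_df <- data.frame(target = tg, method = omni$method,
                          statistic = omni$statistic, df1 = omni$df1,
                          df2 = omni$df2, p_value = omni$p_value,
                          stars = omni$stars, stringsAsFactors = FALSE)
    write_results(omni_df, file.path(out_dir, paste0("group_test_", tg, ".tsv")))
    if (!is.null(ph))
      write_results(as.data.frame(ph),
                    file.path(out_dir, paste0("posthoc_", tg, ".tsv")))
    results[[tg]] <- list(rq = rq, profile = prof, per_ref = per_ref,
                          omnibus = omni, posthoc = ph)
  }
  write_manifest(out_dir, "normalize",
                 list(ct = ct_path, meta = meta_path, layout = layout,
                      refs = refs, targets = targets,
                      calibrator = calibrator_group, posthoc = posthoc))
  invisible(results)
}
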