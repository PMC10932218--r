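test_that("mean and SD of raw Ct match hand arithmetic", {
  tab <- make_ct(c(20, 20, 20,
                   20, 22, 21),
                 genes = c("A", "B"), samples = c("S1", "S2", "S3"),
                 groups = c("G1", "G1", "G2"))
  res <- mean_sd_stability(tab)
  expect_equal(res$mean_ct[res$gene == "A"], 20)
  expect_equal(res$sd_ct[res$gene == "A"], 0)
  tab2 <- make_ct(c(20, 22, 25, 25), c("A", "B"), c("S1", "S2"),
                  groups = c("G1", "G1"))
  res2 <- mean_sd_stability(tab2)
  expect_equal(res2$mean_ct[res2$gene == "A"], 21)
  expect_equal(res2$sd_ct[res2$gene == "A"], sqrt(2), tolerance = 1e-12)
})

test_that("a gene with fewer than two values is excluded with a warning", {
  m <- matrix(c(20, NA, NA, 22, 23, 24), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  tab <- ct_table(m, groups = c(S1 = "G", S2 = "G", S3 = "G"))
  expect_warning(res <- mean_sd_stability(tab), "A")
  expect_false("A" %in% res$gene)
  expect_identical(attr(res, "excluded"), "A")
})

test_that("CV of linearized expression matches the direct arithmetic oracle", {
  tab <- make_ct(c(20, 20, 20), "A", c("S1", "S2", "S3"), rep("G", 3))
  expect_equal(cv_stability(tab)$cv_pct, 0)
  # Ct {20, 21}: linear quantities a = 2b, CV = 100*sqrt(2)*(a-b)/(a+b)
  tab2 <- make_ct(c(20, 21), "A", c("S1", "S2"), rep("G", 2))
  a <- 2^-20; b <- 2^-21
  oracle <- 100 * stats::sd(c(a, b)) / mean(c(a, b))
  expect_equal(cv_stability(tab2)$cv_pct, oracle, tolerance = 1e-12)
  expect_equal(oracle, 47.1405, tolerance = 1e-4)
})

test_that("CV is invariant under per-gene Ct shifts", {
  tab <- random_ct(5, 8, seed = 31)
  shifted <- ct_table(tab$ct + 3, groups = tab$groups)
  expect_equal(cv_stability(shifted)$cv_pct, cv_stability(tab)$cv_pct,
               tolerance = 1e-9)
  # gene-specific shifts too
  shifted2 <- ct_table(tab$ct + (1:5), groups = tab$groups)
  expect_equal(cv_stability(shifted2)$cv_pct, cv_stability(tab)$cv_pct,
               tolerance = 1e-9)
})

test_that("pairwise delta-Ct matches enumerated pair SDs", {
  # two genes offset by a constant: all differences constant, M = 0
  tab <- make_ct(c(20, 21, 22,
                   22, 23, 24), c("A", "B"), c("S1", "S2", "S3"), rep("G", 3))
  res <- pairwise_dct_stability(tab)
  expect_equal(res$pairwise_avg_sd, c(0, 0))

  # designed instance: pair SDs are sqrt(2), sqrt(2), 0
  tab2 <- make_ct(c(20, 20,
                    21, 23,
                    20, 22), c("A", "B", "C"), c("S1", "S2"), rep("G", 2))
  res2 <- pairwise_dct_stability(tab2)
  expect_equal(res2$pairwise_avg_sd[res2$gene == "A"], sqrt(2), tolerance = 1e-9)
  expect_equal(res2$pairwise_avg_sd[res2$gene == "B"], sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(res2$pairwise_avg_sd[res2$gene == "C"], sqrt(2) / 2, tolerance = 1e-9)
})

test_that("pairwise delta-Ct is invariant under per-sample global shifts", {
  tab <- random_ct(6, 10, seed = 17)
  h <- stats::rnorm(10, 0, 2)
  shifted <- ct_table(sweep(tab$ct, 2, h, `+`), groups = tab$groups)
  expect_equal(pairwise_dct_stability(shifted)$pairwise_avg_sd,
               pairwise_dct_stability(tab)$pairwise_avg_sd, tolerance = 1e-9)
})

test_that("pairs with fewer than two complete samples are dropped", {
  m <- matrix(c(20, 21, 22,
                20, NA, NA,
                19, 20, 21), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3")))
  tab <- ct_table(m, groups = c(S1 = "G", S2 = "G", S3 = "G"))
  expect_warning(res <- pairwise_dct_stability(tab), "B")
  expect_false("B" %in% res$gene)
  expect_equal(res$n_pairs, c(1, 1))
})

test_that("model-based stability flags degenerate input and zero intergroup effects", {
  # identical constant matrix: everything zero, degenerate flag
  m <- matrix(20, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  tab <- ct_table(m, groups = stats::setNames(rep(c("a", "b"), each = 3),
                                              colnames(m)))
  nf <- normfinder_stability(tab)
  expect_true(nf$degenerate)
  expect_true(all(nf$sigma2 == 0))
  expect_true(all(nf$d == 0))

  # zero noise, equal group means per gene: d-hat identically zero
  m2 <- matrix(rep(c(20, 22, 25, 19), 6), 4, 6,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  tab2 <- ct_table(m2, groups = stats::setNames(rep(c("a", "b"), each = 3),
                                                colnames(m2)))
  nf2 <- normfinder_stability(tab2)
  expect_true(all(abs(nf2$d_raw) < 1e-12))
})

test_that("model-based stability errors guide towards use_groups = FALSE", {
  tab <- make_ct(c(20, 21, 22, 21,
                   22, 23, 24, 23,
                   19, 20, 21, 20), c("A", "B", "C"),
                 paste0("S", 1:4), groups = c("a", "a", "a", "b"))
  expect_error(normfinder_stability(tab, use_groups = TRUE), "use_groups")
  expect_s3_class(normfinder_stability(tab, use_groups = FALSE), "normfinder")
})

test_that("model-based stability reports blocking missing cells", {
  tab <- tiny_table()
  tab$ct["A", "S2"] <- NA
  expect_error(normfinder_stability(tab), "A/S2")
})

test_that("intragroup variances and intergroup deviations are recovered with error shrinking in n", {
  G <- 8; K <- 3
  sigma <- matrix(rep(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.3, 0.4, 0.5), K), G, K)
  d <- matrix(0, G, K)
  d[1, ] <- c(1, -1, 0); d[2, ] <- c(-1, 1, 0)  # centered over genes and groups
  err_sigma <- err_d <- numeric(0)
  for (n_g in c(5, 20, 100)) {
    es <- ed <- c()
    for (rep in 1:12) {
      spec <- synthetic_spec(
        baselines = stats::setNames(rep(25, G), paste0("g", 1:G)),
        groups = paste0("grp", 1:K), n_per_group = n_g,
        group_effects = d, noise_sd = sigma, sample_shift_sd = 0.5,
        seed = 7000 + n_g * 37 + rep)
      sim <- generate_ct_data(spec)
      nf <- normfinder_stability(sim$ct)
      es <- c(es, mean(abs(nf$sigma2 - sigma^2)))
      ed <- c(ed, mean(abs(nf$d_raw - d)))
    }
    err_sigma <- c(err_sigma, mean(es))
    err_d <- c(err_d, mean(ed))
  }
  expect_true(all(diff(err_sigma) < 0))
  expect_true(all(diff(err_d) < 0))
  # at n = 100 the estimates are close to the generating values
  expect_lt(err_sigma[3], 0.05)
  expect_lt(err_d[3], 0.05)
})

test_that("all estimators agree on the extremes of a designed instance", {
  set.seed(404)
  G <- 6; N <- 24
  genes <- c("ZEROVAR", paste0("mid", 1:4), "INFLATED")
  m <- rbind(rep(20, N),
             matrix(stats::rnorm(4 * N, 22, 0.3), 4, N),
             stats::rnorm(N, 24, 3))
  # give the zero-variance gene a hair of noise so CV/SD stay defined ranks
  m[1, ] <- 20 + stats::rnorm(N, 0, 1e-4)
  dimnames(m) <- list(genes, paste0("s", 1:N))
  # single group: the pooled designed instance ranks by pure variability
  tab <- ct_table(m, groups = stats::setNames(rep("all", N), colnames(m)))
  fit <- gene_stability(tab)
  tt <- fit$table
  for (col in c("normfinder_S", "sd_ct", "cv_pct", "pairwise_avg_sd")) {
    expect_equal(tt$gene[which.min(tt[[col]])], "ZEROVAR", label = col)
    expect_equal(tt$gene[which.max(tt[[col]])], "INFLATED", label = col)
  }
})

test_that("rank aggregation is the geometric mean with documented tie handling", {
  r <- matrix(c(1, 2,
                2, 1,
                3, 3), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  agg <- rank_aggregate(r)
  expect_equal(agg$aggregate_score[agg$gene == "a"], sqrt(2), tolerance = 1e-12)
  expect_equal(agg$aggregate_score[agg$gene == "b"], sqrt(2), tolerance = 1e-12)
  # exact tie in score -> average ranks, alphabetical display order
  expect_equal(agg$gene, c("a", "b", "c"))
  expect_equal(agg$aggregate_rank[1:2], c(1.5, 1.5))
  # single method: aggregate equals that method's ranks
  agg1 <- rank_aggregate(r, methods = "m1")
  expect_equal(agg1$aggregate_score, unname(sort(r[, "m1"])))
  expect_error(rank_aggregate(r, methods = character(0)), "empty")
})

test_that("when all methods agree the aggregate ordering is identical", {
  tab <- random_ct(5, 12, seed = 88)
  # inflate genes in a known order: add gene-specific noise scaling
  m <- tab$ct
  for (i in 1:5) m[i, ] <- 25 + scale(m[i, ])[, 1] * (0.1 * i)
  tab2 <- ct_table(m, groups = tab$groups)
  fit <- gene_stability(tab2, use_groups = FALSE)
  tt <- fit$table
  expect_equal(order(tt$rank_aggregate), order(tt$sd_ct))
  expect_equal(order(tt$rank_cv), order(tt$sd_ct))
})

test_that("the stability TSV has the documented Table-2-shaped columns", {
  sim <- generate_ct_data(scenario_paperlike(seed = 3))
  fit <- gene_stability(sim$ct)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "stab.tsv")
  write_stability(fit, p)
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(colnames(back),
               c("gene", "normfinder_S", "normfinder_se", "mean_ct", "sd_ct",
                 "cv_pct", "pairwise_avg_sd", "rank_normfinder", "rank_sd",
                 "rank_cv", "rank_dct", "rank_aggregate"))
  expect_equal(nrow(back), 14L)
})
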