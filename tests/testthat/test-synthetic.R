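test_that("generation is deterministic under a fixed seed", {
  spec <- scenario_paperlike(seed = 11)
  a <- generate_ct_data(spec)
  b <- generate_ct_data(spec)
  expect_identical(a$ct$ct, b$ct$ct)
  expect_identical(a$truth$h, b$truth$h)
  # a different seed changes the matrix but not the schema
  c2 <- generate_ct_data(scenario_paperlike(seed = 12))
  expect_false(identical(a$ct$ct, c2$ct$ct))
  expect_identical(dimnames(a$ct$ct), dimnames(c2$ct$ct))
})

test_that("the seed is mandatory and invalid fields are listed", {
  expect_error(synthetic_spec(c(A = 20), "G1", 2), "seed")
  err <- tryCatch(
    synthetic_spec(c(A = 20, B = 21), c("G1", "G2"), n_per_group = c(2, 2),
                   noise_sd = -1, sample_shift_sd = -2, seed = 1),
    error = conditionMessage)
  expect_match(err, "noise_sd")
  expect_match(err, "sample_shift_sd")
})

test_that("zero noise, zero shifts and zero effects give constant rows", {
  spec <- synthetic_spec(baselines = c(A = 20, B = 25),
                         groups = c("G1", "G2"), n_per_group = 3,
                         noise_sd = 0, sample_shift_sd = 0, seed = 4)
  sim <- generate_ct_data(spec)
  expect_true(all(sim$ct$ct["A", ] == 20))
  expect_true(all(sim$ct$ct["B", ] == 25))
})

test_that("per-gene sample SD approaches the generating noise SD", {
  spec <- synthetic_spec(baselines = c(A = 22, B = 24, C = 26),
                         groups = "G1", n_per_group = 1000,
                         noise_sd = 0.5, sample_shift_sd = 0, seed = 909)
  sim <- generate_ct_data(spec)
  sds <- apply(sim$ct$ct, 1, stats::sd)
  expect_true(all(abs(sds - 0.5) < 0.02))
})

test_that("target genes follow the declared trajectory with the right sign", {
  spec <- synthetic_spec(
    baselines = c(R1 = 20, R2 = 21, R3 = 22),
    groups = paste0("G", 1:4), n_per_group = 2,
    noise_sd = 0, sample_shift_sd = 0,
    targets = list(TG = list(baseline = 27, trajectory = c(0, 1, 2, 3),
                             noise_sd = 0)),
    seed = 2)
  sim <- generate_ct_data(spec)
  gm <- tapply(sim$ct$ct["TG", ], sim$ct$groups, mean)
  # +1 log2 per group step lowers Ct by exactly one cycle per step
  expect_equal(as.vector(gm), c(27, 26, 25, 24))
  # zero trajectory, zero noise behaves as a reference gene
  spec2 <- synthetic_spec(
    baselines = c(R1 = 20, R2 = 21, R3 = 22),
    groups = paste0("G", 1:4), n_per_group = 2,
    noise_sd = 0, sample_shift_sd = 0.7,
    targets = list(TG = list(baseline = 27, trajectory = rep(0, 4),
                             noise_sd = 0)),
    seed = 3)
  sim2 <- generate_ct_data(spec2)
  d <- sim2$ct$ct["TG", ] - sim2$ct$ct["R1", ]
  expect_true(all(abs(d - d[1]) < 1e-12))
})

test_that("targets can be appended post hoc, sharing the drawn sample shifts", {
  spec <- synthetic_spec(baselines = c(R1 = 20, R2 = 21, R3 = 22),
                         groups = c("G1", "G2"), n_per_group = 3,
                         noise_sd = 0.2, sample_shift_sd = 1.5, seed = 21)
  sim <- generate_ct_data(spec)
  ext <- generate_target_gene(sim$ct, sim$truth, "TG", c(0, 1),
                              noise_sd = 0, baseline = 27, seed = 77)
  expect_true("TG" %in% ct_genes(ext$ct))
  # with zero target noise, TG minus the shared shift is exactly deterministic
  resid <- ext$ct$ct["TG", ] - ext$truth$h
  gm <- tapply(resid, ext$ct$groups, mean)
  expect_equal(as.vector(gm), c(27, 26), tolerance = 1e-12)
  expect_error(generate_target_gene(ext$ct, ext$truth, "TG", c(0, 1),
                                    0, 27, 1), "already present")
})

test_that("ground-truth ordering comes from the spec, not the data", {
  spec <- scenario_paperlike(seed = 5)
  truth <- true_stability(spec)
  expect_equal(nrow(truth), 12L)
  # worst two by the declared functional are the designed unstable genes
  expect_setequal(utils::tail(truth$gene, 2), c("ACTB", "RRN18S"))
  expect_equal(truth$true_rank, seq_len(12))
})

test_that("the study-like preset matches its declared shape", {
  spec <- scenario_paperlike(seed = 1)
  expect_s3_class(spec, "synthetic_spec")
  b <- spec$baselines
  expect_equal(sum(b < 10), 1L)             # one very high expressor
  expect_true(all(b[b >= 10] >= 18 & b[b >= 10] <= 26))
  expect_length(spec$groups, 5L)
  expect_length(spec$targets, 2L)
  expect_true(all(vapply(spec$targets,
                         function(t) all(diff(t$trajectory) > 0), TRUE)))
})

test_that("pairwise delta-Ct statistics are unaffected by the loading-shift scale", {
  base <- function(tau, seed) {
    spec <- synthetic_spec(baselines = c(A = 20, B = 22, C = 24, D = 26),
                           groups = c("G1", "G2"), n_per_group = 30,
                           noise_sd = 0.4, sample_shift_sd = tau, seed = seed)
    pairwise_dct_stability(generate_ct_data(spec)$ct)$pairwise_avg_sd
  }
  # tau = 0 and tau = 2 give estimates differing only by Monte-Carlo noise
  d0 <- rowMeans(sapply(1:8, function(s) base(0, 300 + s)))
  d2 <- rowMeans(sapply(1:8, function(s) base(2, 600 + s)))
  expect_lt(max(abs(d0 - d2)), 0.05)
})

test_that("random masking injects missing wells at roughly the requested rate", {
  spec <- synthetic_spec(baselines = stats::setNames(rep(25, 10), paste0("g", 1:10)),
                         groups = c("G1", "G2"), n_per_group = 50,
                         noise_sd = 0.3, sample_shift_sd = 0, seed = 8)
  sim <- generate_ct_data(spec, mask_rate = 0.1)
  rate <- mean(is.na(sim$ct$ct))
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.15)
})
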