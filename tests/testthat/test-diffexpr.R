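test_that("benjamini_hochberg matches the step-up definition", {
  # worked example
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  # ties and singletons
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(0.7), 0.7)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # property: random vectors vs the brute-force oracle and stats::p.adjust
  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
    expect_equal(benjamini_hochberg(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("mean-count filter keeps genes at the boundary and drops below", {
  m <- matrix(rep(c(9L, 10L, 50L), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  out <- filter_min_count(m, 10)
  expect_identical(rownames(out), c("g2", "g3"))  # 9 < 10, 10 kept (>=)
  expect_identical(filter_min_count(m, 0), m)
  set.seed(3)
  big <- toy_counts(rpois(200 * 4, 12), 200, 4)
  k <- sum(rowMeans(big) < 10)
  expect_equal(nrow(filter_min_count(big, 10)), 200 - k)
})

test_that("dispersion estimates track the truth", {
  samples <- two_group_samples(6)
  # Poisson counts: dispersion should be near zero
  set.seed(1)
  m <- toy_counts(rpois(2000 * 12, 100), 2000, 12,
                  samps = samples$sample_id)
  phi <- estimate_dispersions(m, samples$treatment)
  expect_lt(median(phi), 0.05)
  # NB with phi = 0.2 at high mean: recovered within a factor band
  set.seed(2)
  m2 <- toy_counts(rnbinom(2000 * 12, mu = 500, size = 1 / 0.2), 2000, 12,
                   samps = samples$sample_id)
  phi2 <- estimate_dispersions(m2, samples$treatment)
  expect_gt(mean(phi2), 0.1)
  expect_lt(mean(phi2), 0.3)
  # constant counts: raw moment estimate 0, shrunk toward the trend floor
  m3 <- toy_counts(rep(20, 40), 10, 4, samps = two_group_samples(2)$sample_id)
  phi3 <- estimate_dispersions(m3, two_group_samples(2)$treatment)
  expect_true(all(phi3 >= 1e-8))
  expect_error(estimate_dispersions(m, rep(c("A", "B", "C"), c(1, 1, 10))),
               ">= 2 replicates")
})

test_that("NB Wald calls obey the fold-change and significance gates", {
  set.seed(5)
  sim <- simulate_experiment(sim_config(
    n_genes = 1500, replicates_per_treatment = 4, n_terms = 10,
    planted_patterns = list(list(code = c(1L, 0L, 0L), n_genes = 200L,
                                 lfc_range = c(3, 3)),
                            list(code = c(-1L, 0L, 0L), n_genes = 100L,
                                 lfc_range = c(1, 1))),
    seed = 55))
  r <- nb_wald_test(sim$counts, sim$samples, "control", "W_W")
  planted_up <- names(sim$truth$gene_pattern)[sim$truth$gene_pattern == "1/0/0"]
  planted_small <- names(sim$truth$gene_pattern)[
    sim$truth$gene_pattern == "-1/0/0"]
  up_calls <- r$call[r$gene_id %in% planted_up]
  expect_gt(mean(up_calls == 1L), 0.9)  # power at lfc 3
  # |log2FC| = 1 sits under the 1.5 gate: never called however significant
  small_rows <- r[r$gene_id %in% planted_small, ]
  expect_true(all(small_rows$call == 0L))
  # invariants of the result table
  expect_true(all(r$padj >= r$p - 1e-12))
  expect_true(all(r$call %in% c(-1L, 0L, 1L)))
  expect_true(all(r$call[r$padj >= 0.05] == 0L))
  expect_true(all(abs(r$log2fc[r$call != 0L]) > 1.5))
})

test_that("swapping reference and test negates log2fc and calls", {
  sim <- simulate_experiment(small_sim_config(seed = 13, n_genes = 400,
                                              n_per_pattern = 20))
  a <- nb_wald_test(sim$counts, sim$samples, "control", "W_W")
  b <- nb_wald_test(sim$counts, sim$samples, "W_W", "control")
  expect_identical(a$gene_id, b$gene_id)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
  expect_identical(a$call, -b$call)
})

test_that("PCA separates constructed clusters and reports variance fractions", {
  set.seed(9)
  base <- matrix(rnorm(100 * 8), 100, 8,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  base[1:50, 1:4] <- base[1:50, 1:4] + 4  # two orthogonal sample clusters
  p <- pca_projection(base)
  expect_true(all(sign(p$scores[1:4, 1]) != sign(p$scores[5:8, 1])))
  expect_lte(sum(p$variance_fraction), 1 + 1e-8)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-8)
  const <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:4)))
  expect_error(pca_projection(const), "non-constant")
})

test_that("outlier flagging finds a shifted replicate and respects the limit", {
  set.seed(15)
  samples <- two_group_samples(4)
  e <- matrix(rnorm(400 * 8, 10, 1), 400, 8,
              dimnames = list(paste0("g", 1:400), samples$sample_id))
  none <- detect_outliers(e, samples)
  expect_length(none$flagged, 0)
  e2 <- e
  e2[1:200, 3] <- e2[1:200, 3] + 10  # 10 SD shift in half the genes
  out <- detect_outliers(e2, samples)
  expect_identical(out$flagged, samples$sample_id[3])
  expect_length(detect_outliers(e2, samples, c_mult = Inf)$flagged, 0)
  # < 3 replicates: skipped with a warning
  expect_warning(detect_outliers(e[, 1:5], samples[1:5, ]), "replicates")
})

test_that("RDPI closed forms and bounds hold", {
  samples <- two_group_samples(2, c("ctl", "trt"))
  # identical profiles: RDPI 0
  e <- matrix(c(10, 5, 10, 5, 10, 5, 10, 5), 2, 4,
              dimnames = list(c("g1", "g2"), samples$sample_id))
  expect_true(all(rdpi(e, samples, "ctl", "trt")$rdpi == 0))
  # single gene 10 vs 30 -> 20/40 = 0.5
  e1 <- matrix(c(10, 10, 30, 30), 1, 4,
               dimnames = list("g1", samples$sample_id))
  expect_equal(rdpi(e1, samples, "ctl", "trt")$rdpi, rep(0.5, 4))
  # x vs 2x for every gene -> 1/3 for all pairs
  set.seed(20)
  x <- runif(50, 1, 100)
  e2 <- cbind(x, x, 2 * x, 2 * x)
  dimnames(e2) <- list(paste0("g", 1:50), samples$sample_id)
  expect_equal(rdpi(e2, samples, "ctl", "trt")$rdpi, rep(1 / 3, 4))
  # bounds and pair count on noisy data
  e3 <- matrix(runif(50 * 4, 0, 50), 50, 4,
               dimnames = list(paste0("g", 1:50), samples$sample_id))
  r <- rdpi(e3, samples, "ctl", "trt")
  expect_equal(nrow(r), 4)  # 2 control x 2 treatment
  expect_true(all(r$rdpi >= 0 & r$rdpi <= 1))
  # gene relabelling leaves RDPI unchanged
  perm <- sample(50)
  expect_equal(rdpi(e3[perm, ], samples, "ctl", "trt")$rdpi, r$rdpi)
})

test_that("null simulation keeps the Wald test calibrated (small scale)", {
  cfg <- sim_config(n_genes = 2500, planted_patterns = list(), n_terms = 10,
                    seed = 77)
  sim <- simulate_experiment(cfg)
  r <- nb_wald_test(sim$counts, sim$samples, "control", "W_ABOS")
  expect_gt(mean(r$p < 0.05), 0.02)
  expect_lt(mean(r$p < 0.05), 0.08)
  expect_equal(sum(r$call != 0), 0)
})
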