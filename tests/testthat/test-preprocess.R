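make_det_case <- function(det_counts) {
  # det_counts: detected samples per group for one probe, in group order
  design <- toy_design(n_per_cell = 4, n_batches = 2)
  det <- matrix(0.5, 1, 16, dimnames = list("P1", design$sample_id))
  grp <- interaction(design$sex, design$genotype)
  for (g in seq_along(levels(grp))) {
    idx <- which(grp == levels(grp)[g])
    k <- det_counts[g]
    if (k > 0) det[1, idx[seq_len(k)]] <- 0.001
  }
  expr <- matrix(10, 1, 16, dimnames = dimnames(det))
  attr(expr, "scale") <- "raw"
  list(expr = expr, det = det, design = design)
}

test_that("detection filter keeps probes detected in at least one group", {
  full <- make_det_case(c(4, 0, 0, 0))
  expect_true(detection_filter(full$expr, full$det, full$design)$mask[["P1"]])
  sparse <- make_det_case(c(2, 2, 2, 2))
  expect_false(detection_filter(sparse$expr, sparse$det,
                                sparse$design)$mask[["P1"]])
  edge <- make_det_case(c(3, 0, 0, 0))
  expect_true(detection_filter(edge$expr, edge$det, edge$design)$mask[["P1"]])
  expect_error(detection_filter(edge$expr, edge$det, edge$design,
                                min_detected = 5), "config error")
})

test_that("filtering is idempotent and invariant to sample order", {
  sim <- simulate_experiment(effect_spec(n_probes = 120, seed = 6))
  f1 <- detection_filter(sim$expr, sim$det, sim$design)
  f2 <- detection_filter(f1$expr, f1$det, sim$design)
  expect_true(all(f2$mask))
  expect_identical(f1$expr, f2$expr)
  ord <- sample(ncol(sim$expr))
  ex <- sim$expr[, ord]; attr(ex, "scale") <- "raw"
  f3 <- detection_filter(ex, sim$det[, ord], sim$design)
  expect_equal(sum(f3$mask), sum(f1$mask))
})

test_that("spline normalization is a fixed point on identical columns", {
  v <- sort(rnorm(200, 8, 1.5))
  expr <- matrix(v, 200, 4, dimnames = list(paste0("P", 1:200),
                                            paste0("S", 1:4)))
  attr(expr, "scale") <- "log2"
  out <- cubic_spline_normalize(expr)
  expect_equal(out, expr, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a shifted column is mapped onto the reference at all anchors", {
  set.seed(8)
  base <- rnorm(500, 8, 1.5)
  expr <- cbind(S1 = base, S2 = base + 1, S3 = base - 0.5)
  rownames(expr) <- paste0("P", seq_len(nrow(expr)))
  attr(expr, "scale") <- "log2"
  out <- cubic_spline_normalize(expr, n_anchors = 13)
  probs <- seq(0, 1, length.out = 13)
  ref <- rowMeans(apply(expr, 2, sort))
  ref_anchor <- quantile(ref, probs, type = 1, names = FALSE)
  for (j in 1:3)
    expect_lt(max(abs(quantile(out[, j], probs, type = 1, names = FALSE) -
                        ref_anchor)), 1e-9)
  # monotone map preserves within-sample rank order
  for (j in 1:3)
    expect_identical(order(out[, j]), order(expr[, j]))
})

test_that("normalization is idempotent to within 1e-6", {
  sim <- simulate_experiment(effect_spec(n_probes = 300, seed = 12,
                                         batch_shift_sd = 0.3))
  lg <- log2_transform(sim$expr)
  n1 <- cubic_spline_normalize(lg)
  n2 <- cubic_spline_normalize(n1)
  expect_lt(max(abs(n2 - n1)), 1e-6)
})

test_that("normalization rejects non-finite input", {
  expr <- matrix(rnorm(20), 10, 2,
                 dimnames = list(paste0("P", 1:10), c("A", "B")))
  expr[3, 1] <- NA
  expect_error(cubic_spline_normalize(expr), "non-finite")
})

test_that("a forced chip shift is removed exactly by adjustment", {
  sim <- simulate_experiment(effect_spec(n_probes = 80, seed = 13,
                                         batch_shift_sd = 0))
  lg <- log2_transform(sim$expr)
  chip2 <- sim$design$batch == "chip2"
  lg[, chip2] <- lg[, chip2] + 0.5
  before_grand <- rowMeans(lg)
  adj <- assess_and_adjust_batch(lg, sim$design, force = "on")
  m1 <- rowMeans(adj$expr[, !chip2]); m2 <- rowMeans(adj$expr[, chip2])
  expect_lt(max(abs(m1 - m2)), 1e-9)
  # grand means preserved exactly
  expect_equal(rowMeans(adj$expr), before_grand)
  # and auto mode triggers on such a blatant shift
  auto <- assess_and_adjust_batch(lg, sim$design, force = "auto")
  expect_true(auto$report$adjusted)
})

test_that("force = off passes the matrix through untouched", {
  sim <- simulate_experiment(effect_spec(n_probes = 30, seed = 14))
  lg <- log2_transform(sim$expr)
  off <- assess_and_adjust_batch(lg, sim$design, force = "off")
  expect_identical(off$expr, lg)
  expect_false(off$report$adjusted)
})

test_that("without a real batch effect auto mode rarely adjusts", {
  triggers <- vapply(1:60, function(s) {
    sim <- simulate_experiment(effect_spec(n_probes = 250, seed = 1000 + s,
                                           batch_shift_sd = 0,
                                           undetected_fraction = 0))
    assess_and_adjust_batch(log2_transform(sim$expr),
                            sim$design)$report$adjusted
  }, logical(1))
  # trigger is calibrated at the 1% tail of the null binomial fraction
  expect_lt(mean(triggers), 0.1)
})

test_that("a batch confounded with the design cells is an error", {
  design <- toy_design(n_per_cell = 2)
  design$batch <- paste(design$sex, design$genotype)  # perfectly aliased
  expr <- matrix(rnorm(8 * 5), 5, 8,
                 dimnames = list(paste0("P", 1:5), design$sample_id))
  expect_error(assess_and_adjust_batch(expr, design), "alias")
})
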