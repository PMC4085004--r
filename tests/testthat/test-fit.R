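test_that("hand-computed sums of squares are reproduced on the 2x2 toy", {
  design <- toy_design(n_per_cell = 2, n_batches = 1)
  design$batch <- NULL
  # cells (sex.genotype): male.WT = 1, female.WT = 2, male.KO = 3, female.KO = 4
  cellval <- c(male.WT = 1, female.WT = 2, male.KO = 3, female.KO = 4)
  y <- cellval[paste(design$sex, design$genotype, sep = ".")]
  fit <- fit_probe_anova(unname(y), design, include_batch = FALSE)
  expect_equal(unname(fit$ss["genotype"]), 8)
  expect_equal(unname(fit$ss["sex"]), 2)
  expect_equal(unname(fit$ss["interaction"]), 0)
  expect_equal(fit$residual_ss, 0)
  # zero residual variance: p = 1 by convention
  expect_true(all(fit$p == 1))
})

test_that("constant responses and location shifts behave as conventions", {
  design <- toy_design(n_per_cell = 2)
  expect_true(all(fit_probe_anova(rep(5, 8), design)$p == 1))
  set.seed(1); y <- rnorm(8)
  f1 <- fit_probe_anova(y, design)
  f2 <- fit_probe_anova(y + 100, design)
  expect_equal(f1$f, f2$f, tolerance = 1e-8)
})

test_that("factor p-values match the explicit sums-of-squares oracle", {
  set.seed(42)
  for (i in 1:25) {
    design <- toy_design(n_per_cell = sample(2:3, 1))
    y <- rnorm(nrow(design), sd = runif(1, 0.2, 2))
    fit <- fit_probe_anova(y, design)
    orc <- oracle_anova(y, design)
    for (term in c("sex", "genotype", "interaction", "batch")) {
      expect_lt(abs(fit$ss[[term]] - orc[[term]]),
                1e-10 * max(1, abs(orc[[term]])))
      expect_lt(abs(fit$p[[term]] - oracle_anova_p(orc, term)), 1e-10)
    }
    expect_lt(abs(fit$residual_ss - orc$residual),
              1e-10 * max(1, orc$residual))
  }
})

test_that("a singular model names the aliased term", {
  design <- toy_design(n_per_cell = 2)
  design$batch <- design$genotype
  expect_error(fit_probe_anova(rnorm(8), design), "aliased")
})

test_that("LSD contrasts match closed-form pooled t statistics", {
  sim <- simulate_experiment(effect_spec(n_probes = 25, seed = 31))
  fit <- bead_anova(log2_transform(sim$expr), sim$design)
  ct <- lsd_contrast(fit, "KO", "WT")
  # closed form on probe 1: t = diff / sqrt(mse * (1/8 + 1/8))
  lg <- log2_transform(sim$expr)
  ko <- sim$design$genotype == "KO"
  d1 <- mean(lg[1, ko]) - mean(lg[1, !ko])
  expect_equal(ct$estimate[1], d1)
  expect_equal(ct$t[1], d1 / sqrt(unname(fit$mse[1]) * (1 / 8 + 1 / 8)))
  expect_equal(ct$p[1],
               2 * pt(abs(ct$t[1]), fit$df_res, lower.tail = FALSE))
  # antisymmetry
  rev <- lsd_contrast(fit, "WT", "KO")
  expect_equal(rev$t, -ct$t)
  expect_equal(rev$p, ct$p)
  expect_error(lsd_contrast(fit, "KO", "nosuch"), "empty group")
})

test_that("the textbook LSD case gives t = 2.828 on the pooled variance", {
  # mse = 1, n = 4 vs 4, mean difference 2
  se <- sqrt(1 * (1 / 4 + 1 / 4))
  expect_equal(2 / se, 2.828, tolerance = 1e-3)
})

test_that("equal group means give t = 0, p = 1", {
  design <- toy_design(n_per_cell = 2, n_batches = 1)
  design$batch <- NULL
  y <- rep(c(1, -1), 4)  # same mean in every cell, nonzero variance
  expr <- matrix(y, 1, 8, dimnames = list("P1", design$sample_id))
  fit <- bead_anova(expr, design, include_batch = FALSE)
  ct <- lsd_contrast(fit, "KO", "WT")
  expect_equal(ct$t, 0)
  expect_equal(ct$p, 1)
})

test_that("signed fold change follows the negative-reciprocal convention", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-1), -2)
  expect_equal(signed_fold_change(0), 1)
  expect_equal(signed_fold_change(log2(1.35)), 1.35)
  x <- rnorm(50)
  fc <- signed_fold_change(x)
  expect_true(all(abs(fc) >= 1))
  expect_equal(sign(fc[x != 0]), sign(x[x != 0]))
})

test_that("BH q-values equal the brute-force step-up on random draws", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "data error")
  expect_error(bh_fdr(c(0.1, NA)), "data error")
})

test_that("significant calls collapse probes to their best gene record", {
  res <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4"),
    symbol = c("GA", "GA", "GB", "GC"),
    factor = "genotype",
    log2fc = c(1, 2, -1, 0.1),
    fold_change = c(2, 4, -2, 1.07),
    t = c(5, 7, -5, 1),
    p_value = c(0.001, 0.0001, 0.002, 0.5),
    q_value = c(0.004, 0.0008, 0.005, 0.5))
  out <- call_significant(res, "genotype", fdr = 0.05)
  expect_identical(out$symbol, c("GA", "GB"))
  expect_equal(out$fold_change[out$symbol == "GA"], 4)  # best probe wins
  none <- res; none$q_value <- 1
  expect_equal(nrow(call_significant(none, "genotype")), 0L)
})

test_that("null contrast p-values are uniform", {
  set.seed(19)
  p <- unlist(lapply(1:8, function(s) {
    sim <- simulate_experiment(effect_spec(n_probes = 400, seed = 600 + s,
                                           undetected_fraction = 0))
    fit <- bead_anova(log2_transform(sim$expr), sim$design)
    fit$table$genotype_p
  }))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("stratified contrasts separate shared and sex-specific effects", {
  spikes <- data.frame(probe = c(1, 2),
                       factor = c("genotype", "interaction"),
                       fc = c(3, 3))
  sim <- simulate_experiment(effect_spec(n_probes = 300, seed = 77,
                                         spikes = spikes,
                                         undetected_fraction = 0))
  st <- stratified_contrasts(log2_transform(sim$expr), sim$design,
                             features = sim$features)
  expect_true("GENE00001" %in% st$intersection)   # same effect in both sexes
  expect_true("GENE00002" %in% st$female_only)    # female-KO cell only
  expect_false("GENE00002" %in% st$male_only)
  d2 <- sim$design[sim$design$sex == "male", ]
  expect_error(stratified_contrasts(log2_transform(sim$expr[, d2$sample_id]),
                                    d2), "both sexes|sexes must")
})

test_that("fit object methods expose coefficients, residuals and summaries", {
  sim <- simulate_experiment(effect_spec(n_probes = 60, seed = 23))
  lg <- log2_transform(sim$expr)
  fit <- bead_anova(lg, sim$design, features = sim$features)
  cf <- coef(fit)
  expect_identical(colnames(cf), c("genotype", "sex"))
  expect_equal(nrow(cf), 60L)
  r <- residuals(fit)
  expect_equal(dim(r), dim(lg))
  expect_lt(max(abs(rowMeans(r))), 1e-10)
  s <- summary(fit)
  expect_s3_class(s, "summary.bead_anova")
  expect_output(print(fit), "Factorial ANOVA")
  ys <- simulate(fit, nsim = 2, seed = 1)
  expect_length(ys, 2L)
  expect_equal(dim(ys[[1]]), dim(lg))
  pdf(NULL)
  plot(fit); plot(fit, "volcano")
  dev.off()
})
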