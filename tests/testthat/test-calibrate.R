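test_that("random combinations preserve group sizes and exclude the truth", {
  design <- toy_design(n_per_cell = 4)
  p1 <- random_combinations(design, k = 1, seed = 5)[[1]]
  expect_identical(p1, random_combinations(design, k = 1, seed = 5)[[1]])
  expect_false(identical(paste(p1$sex, p1$genotype),
                         paste(design$sex, design$genotype)))
  perms <- random_combinations(design, k = 20, seed = 2)
  keys <- vapply(perms, function(d) paste(d$sex, d$genotype, collapse = "|"),
                 "")
  expect_equal(length(unique(keys)), 20L)
  for (d in perms) {
    expect_true(all(table(d$sex, d$genotype) == 4L))
    expect_identical(as.character(d$batch), design$batch)  # chips stay put
  }
})

test_that("label assignment is exchangeable across samples", {
  design <- toy_design(n_per_cell = 4)
  draws <- random_combinations(design, k = 2000, seed = 77)
  hit <- vapply(draws, function(d)
    d$sex[1] == "male" && d$genotype[1] == "KO", logical(1))
  expect_lt(abs(mean(hit) - 0.25), 0.02)
})

test_that("impossible permutation requests are config errors", {
  design <- toy_design(n_per_cell = 1)
  expect_error(random_combinations(design, k = 24, seed = 1),
               "config error")
  expect_silent(random_combinations(design, k = 23, seed = 1))
  expect_error(random_combinations(design, k = 0), "config error")
})

small_ensemble <- function(seed = 101, spikes = NULL, k = 5, m = 200) {
  sim <- simulate_experiment(effect_spec(n_probes = m, seed = seed,
                                         spikes = spikes,
                                         undetected_fraction = 0))
  permutation_ensemble(log2_transform(sim$expr), sim$design, k = k,
                       seed = seed, features = sim$features)
}

test_that("the calibration ensemble is a pure function of its seed", {
  e1 <- small_ensemble(seed = 55, k = 3, m = 80)
  e2 <- small_ensemble(seed = 55, k = 3, m = 80)
  expect_identical(e1$real, e2$real)
  expect_identical(e1$perms, e2$perms)
})

test_that("fold-change histogram contracts hold", {
  ens <- small_ensemble(seed = 41, k = 3, m = 120)
  # p_cut = 0 admits nothing: all-zero histogram
  h0 <- fc_histogram(ens, "genotype", p_cut = 0)
  expect_true(all(h0$real == 0) && all(h0$perm_mean == 0))
  expect_error(fc_histogram(ens, "genotype", bin_edges = c(1.2, 1.1)),
               "config error")
  h <- fc_histogram(ens, "genotype")
  expect_equal(nrow(h), 21L)
  expect_equal(h$bin_lo[1], 1.0)
  expect_equal(h$bin_hi[nrow(h)], Inf)
  # every probe with p < cut is binned exactly once
  tab <- ens$real[ens$real$factor == "genotype", ]
  expect_equal(sum(h$real), sum(tab$p_value < 0.05))
})

test_that("null fold-change counts agree between real and permutations", {
  ens <- small_ensemble(seed = 71, k = 10, m = 400)
  h <- fc_histogram(ens, "genotype")
  tot_real <- sum(h$real); tot_perm <- sum(h$perm_mean)
  # Poisson-scale agreement of the overall count under the global null
  expect_lt(abs(tot_real - tot_perm), 3 * sqrt(max(tot_perm, 1)))
})

test_that("FDR sweep counts genes and recommends the conventional level", {
  ens <- small_ensemble(seed = 61, k = 4, m = 150)
  expect_error(fdr_sweep(ens, grid = numeric(0)), "config error")
  sw <- fdr_sweep(ens)
  expect_s3_class(sw, "fdr_sweep")
  expect_output(print(sw), "recommended")
  # cap rule: with q = 1 everywhere all levels qualify and 0.05 is picked
  mk_tab <- function() data.frame(
    probe_id = c("P1", "P2"), symbol = c("GA", "GB"), factor = "genotype",
    log2fc = 0, fold_change = 1, t = 0, p_value = 1, q_value = 1)
  fake <- structure(list(real = mk_tab(), perms = list(mk_tab(), mk_tab()),
                         k = 2, seed = 1), class = "perm_ensemble")
  sw0 <- fdr_sweep(fake, families = "genotype")
  expect_true(all(sw0$families$genotype$real == 0))
  expect_true(all(sw0$families$genotype$perm == 0))
  expect_equal(sw0$recommended, 0.05)
})

test_that("spiked data separate the real analysis from its permutations", {
  spikes <- data.frame(probe = 1:12, factor = "genotype",
                       fc = c(2, -2, 2.5, -2.5, 3, 3, 2, 2, -2, 2.2, 2.4, 2.6))
  ens <- small_ensemble(seed = 91, spikes = spikes, k = 8, m = 300)
  sw <- fdr_sweep(ens)
  expect_gt(sw$families$genotype$real[["0.05"]], 6)
  expect_lt(max(sw$families$genotype$perm[, "0.05"]), 3)
  h <- fc_histogram(ens, "genotype")
  spike_bins <- h$bin_lo >= 1.9 & h$bin_lo <= 3
  expect_gt(sum(h$real[spike_bins]), sum(h$perm_mean[spike_bins]))
})
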