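small_design <- function(...) {
  spike_in_design(n_background = 60, spike_accessions = sprintf("U%02d", 1:6),
                  ...)
}

test_that("spike-in simulation is seed-deterministic and truth-complete", {
  d <- small_design()
  s1 <- simulate_spike_in(d, seed = 4)
  s2 <- simulate_spike_in(d, seed = 4)
  s3 <- simulate_spike_in(d, seed = 5)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_false(identical(as.data.frame(s1$table), as.data.frame(s3$table)))
  expect_equal(nrow(s1$table), 66L)
  expect_equal(length(experiments(s1$table)), 5 * 4)
  expect_setequal(s1$truth$spike_accessions, sprintf("U%02d", 1:6))
  expect_equal(dim(s1$truth$dropout_mask), dim(lfq_matrix(s1$table)))
  # dropout mask matches the zeros of the table
  expect_equal(unname(lfq_matrix(s1$table) == 0), unname(s1$truth$dropout_mask))
  # fold-change truth reflects the amount ratios
  expect_equal(unname(s1$truth$fold_changes["20", "6.7"]), 20 / 6.7)
})

test_that("noiseless, dropout-free intensities are proportional to amounts", {
  d <- small_design(noise_cv = 0, dropout_midpoint = -Inf)
  s <- simulate_spike_in(d, seed = 1)
  lfq <- lfq_matrix(s$table)
  spikes <- s$truth$spike_accessions
  # within a spike protein, every replicate of a condition is identical and
  # ratios across conditions equal the amount ratios exactly
  r20 <- lfq[spikes, "20_r1"]
  expect_equal(lfq[spikes, "20_r2"], r20)
  expect_equal(unname(lfq[spikes, "2.2_r1"] / r20), rep(2.2 / 20, 6))
  # background proteins identical across all experiments
  bg <- setdiff(s$table$accession, spikes)
  expect_equal(apply(lfq[bg, ], 1, function(v) diff(range(v))),
               setNames(rep(0, length(bg)), bg))
})

test_that("the lowest spike condition falls below the valid-value filter", {
  d <- spike_in_design(n_background = 200)
  s <- simulate_spike_in(d, seed = 11)
  lfq <- lfq_matrix(s$table)[s$truth$spike_accessions, ]
  valid024 <- rowSums(lfq[, paste0("0.24_r", 1:4)] > 0)
  valid67 <- rowSums(lfq[, paste0("6.7_r", 1:4)] > 0)
  expect_gt(mean(valid024 < 3), 0.8)   # most spikes unquantifiable at 0.24 fmol
  expect_gt(mean(valid67 >= 3), 0.95)  # but well observed at 6.7 fmol
})

test_that("dilution series spans the grid and saturates count indices", {
  sim <- simulate_dilution_series(seed = 6)
  expect_equal(names(sim$tables), as.character(c(0.5, 5, 50, 500, 5e3, 5e4, 5e5)))
  expect_equal(length(sim$tables), 7L)
  expect_equal(diff(log10(range(sim$truth$amounts_fmol))), 6)
  # same seed reproduces, background off means spike proteins only
  sim2 <- simulate_dilution_series(seed = 6)
  expect_identical(lapply(sim$tables, as.data.frame),
                   lapply(sim2$tables, as.data.frame))
  expect_equal(nrow(sim$tables[[1]]), 2L)
  # spectral counts saturate: top-decade SC ratio far below the input ratio
  sc_top <- sim$tables[["5e+05"]]$sc
  sc_next <- sim$tables[["50000"]]$sc
  expect_lt(mean(sc_top / pmax(sc_next, 1)), 2)
  mq_top <- rowSums(mq_matrix(sim$tables[["5e+05"]]))
  mq_next <- rowSums(mq_matrix(sim$tables[["50000"]]))
  expect_gt(mean(mq_top / mq_next), 5)
})

test_that("accuracy metrics behave as definitions on engineered inputs", {
  sim <- simulate_dilution_series(noise_cv = 1e-6, response_log10_sd = 0,
                                  seed = 2)
  acc <- evaluate_accuracy(sim, "MQ")
  expect_equal(acc$pearson, 1, tolerance = 1e-4)
  expect_equal(acc$slope, 1, tolerance = 1e-3)
  expect_equal(acc$dynamic_range, 6, tolerance = 1e-3)
  # an index off by 100x at one point shows a ~2-order max outlier
  sim_bad <- sim
  sim_bad$tables[[1]] <- {
    t1 <- sim$tables[[1]]
    for (e in experiments(t1)) t1[[paste0("mq:", e)]] <-
        t1[[paste0("mq:", e)]] * c(1e-2, 1)
    t1
  }
  acc_bad <- evaluate_accuracy(sim_bad, "MQ")
  expect_gt(acc_bad$max_outlier, 1.5)
  expect_error(evaluate_accuracy(
    simulate_dilution_series(amounts_fmol = c(1), seed = 1), "MQ"), "3")
})

test_that("mass and molar comparisons coincide when lengths are equal", {
  prots <- data.frame(accession = c("A1", "A2", "A3"),
                      length = c(400L, 400L, 400L), po = c(16L, 16L, 16L))
  sim <- simulate_dilution_series(proteins = prots, seed = 9)
  for (idx in c("MQ", "iBAQ", "SC")) {
    molar <- evaluate_accuracy(sim, idx, versus = "molar")
    mass <- evaluate_accuracy(sim, idx, versus = "mass")
    expect_equal(mass$pearson, molar$pearson)
    expect_equal(mass$slope, molar$slope)
    expect_equal(mass$max_outlier, molar$max_outlier)
    expect_equal(mass$dynamic_range, molar$dynamic_range)
  }
})

test_that("count-based indices show poorer linearity than intensity-based ones", {
  sim <- simulate_dilution_series(seed = 10)
  r_ibaq <- evaluate_accuracy(sim, "iBAQ")
  r_mq <- evaluate_accuracy(sim, "MQ")
  r_sc <- evaluate_accuracy(sim, "SC")
  r_pn <- evaluate_accuracy(sim, "PN")
  expect_gt(r_ibaq$pearson, r_sc$pearson)
  expect_gt(r_mq$dynamic_range, r_sc$dynamic_range)
  expect_lt(r_ibaq$max_outlier, 1)
  expect_gte(r_pn$max_outlier, r_ibaq$max_outlier)
})
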