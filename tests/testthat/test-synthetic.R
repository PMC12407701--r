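test_that("experimental designs match the study layout", {
  wt <- experimental_design("WT")
  expect_equal(wt$times, c(0, 12, 24, 48, 60, 72))
  expect_equal(wt$replicates, 4L)
  expect_length(wt$genes, 3)
  ko <- experimental_design("eud1_KO")
  expect_equal(ko$replicates, 2L)
  expect_identical(ko$genes, c("nhr-40", "sult-1"))
  expect_error(experimental_design("nhr40_KO"))
  # observation counts: 3*6*4 = 72 (WT), 2*6*2 = 24 (KO)
  m <- named_models()$model_11574
  d <- generate_dataset(m, reference_params(m), wt$times, wt$replicates,
                        cv = 0.1, seed = 1)
  expect_equal(nrow(d), 72)
  mk <- reduce_for_knockout(m, "eud-1")
  dk <- generate_dataset(mk, reference_params(mk), ko$times, ko$replicates,
                         cv = 0.1, seed = 1)
  expect_equal(nrow(dk), 24)
})

test_that("generated data follow the multiplicative noise law", {
  m <- named_models()$model_11574
  p <- reference_params(m)
  # cv = 0: replicates equal the trajectory exactly
  d0 <- generate_dataset(m, p, quick_times, replicates = 3, cv = 0, seed = 4)
  traj <- simulate_model(m, p, quick_times)
  joined <- dplyr::left_join(d0, traj, by = c("gene", "time_h"),
                             suffix = c("", "_true"))
  expect_equal(joined$value, joined$value_true)
  # same seed is reproducible
  expect_identical(
    generate_dataset(m, p, quick_times, 2, 0.2, seed = 9),
    generate_dataset(m, p, quick_times, 2, 0.2, seed = 9)
  )
  # empirical sd/mean across many draws recovers cv within Monte-Carlo error
  cv <- 0.15
  big <- generate_dataset(m, p, c(0, 48), replicates = 10000, cv = cv,
                          seed = 12)
  one <- dplyr::filter(big, .data$gene == "nhr-40", .data$time_h == 48)
  x_true <- traj$value[traj$gene == "nhr-40" & traj$time_h == 48]
  se <- cv / sqrt(2 * 10000)
  expect_lt(abs(sd(one$value) / x_true - cv), 3 * se)
  # truncation at the floor is rare for moderate noise on bounded-away data
  big2 <- dplyr::filter(big, .data$time_h == 48)
  expect_lt(mean(big2$value == 1e-6), 0.001)
})

test_that("max scaling normalizes to 1 in the requested scope and is idempotent", {
  toy <- tibble::tibble(
    experiment = "t", gene = rep(c("eud-1", "nhr-40"), each = 2),
    time_h = rep(c(0, 12), 2), replicate = 1L,
    value = c(5, 10, 1, 2)
  )
  glob <- max_scale(toy)
  expect_equal(max(glob$value), 1)
  expect_equal(max(glob$value[glob$gene == "nhr-40"]), 0.2)
  per <- max_scale(toy, scope = "per_gene")
  expect_equal(as.numeric(tapply(per$value, per$gene, max)), c(1, 1))
  expect_equal(max_scale(glob)$value, glob$value)
  expect_error(max_scale(dplyr::mutate(toy, value = 0)), "positive")
  const <- dplyr::mutate(toy, value = 3)
  expect_true(all(max_scale(const)$value == 1))
})

test_that("sweep grids are complete Cartesian products with a flagged cell", {
  g <- sweep_grid(c(4, 73), c(0, 0.2))
  expect_equal(nrow(g), 4)
  expect_equal(g$times[[which(g$sampling_count == 73 & g$cv == 0)]],
               seq(0, 72, by = 1))
  full <- sweep_grid()
  expect_equal(sum(full$experimental_regime), 1)
  flagged <- full[full$experimental_regime, ]
  expect_equal(flagged$sampling_count, 6L)
  expect_equal(flagged$times[[1]], c(0, 12, 24, 48, 60, 72))
  expect_error(sweep_grid(1, 0.1), "at least 2")
})
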