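test_that("parameter layout follows the free/fixed rules", {
  m <- named_models()$model_11574
  spec <- parameter_spec(m)
  # 3 alpha + 3 ktmax + k_m + k_p + 3 m0 = 11 unscaled, all free
  expect_equal(sum(spec$role == "unscaled"), 11)
  expect_true(all(spec$free[spec$role == "unscaled"]))
  # K per Hill factor: 2 (eud-1 pair) + 1 (nhr-40) + 1 (sult-1 squared)
  expect_equal(sum(startsWith(spec$name, "K_")), 4)
  # N appears in terms, so the scaled NHR-40 initial condition is free;
  # EUD-1 and SULT-1 protein initial conditions fixed to the preset
  expect_true(spec$free[spec$name == "p0_nhr-40"])
  expect_false(spec$free[spec$name == "p0_eud-1"])
  expect_equal(spec$fixed_value[spec$name == "p0_sult-1"], 1e-3)
  # a model with no N regulator fixes the NHR-40 initial condition too
  fam <- build_family()
  no_n <- model_from_index(fam, 0) # all act(E)
  spec2 <- parameter_spec(no_n)
  expect_false(spec2$free[spec2$name == "p0_nhr-40"])
  # bounds as configured
  expect_equal(unique(spec$lower[spec$role == "unscaled"]), 1e-5)
  expect_equal(unique(spec$upper[spec$role == "unscaled"]), 1e4 + 1)
  expect_equal(unique(spec$lower[spec$role == "scaled"]), 1e-9)
  expect_equal(unique(spec$upper[spec$role == "scaled"]), 1e8 + 1)
})

test_that("Latin-hypercube starts are stratified, log-mapped and in-bounds", {
  m <- named_models()$model_11574
  spec <- parameter_spec(m)
  s <- lhs_starts(2, spec, seed = 5)
  free <- spec[spec$free, ]
  # with 2 starts, one sample in each half of every log-range
  for (j in seq_len(ncol(s))) {
    mid <- 10^((log10(free$lhs_lo[j]) + log10(free$lhs_hi[j])) / 2)
    expect_equal(sum(s[, j] < mid), 1)
  }
  big <- lhs_starts(50, spec, seed = 6)
  for (j in seq_len(ncol(big))) {
    expect_true(all(big[, j] >= free$lhs_lo[j] & big[, j] <= free$lhs_hi[j]))
    expect_true(all(big[, j] > free$lower[j] & big[, j] < free$upper[j]))
  }
  expect_identical(lhs_starts(10, spec, seed = 3), lhs_starts(10, spec, seed = 3))
})

test_that("fit_model returns a usable optimum on a small dataset", {
  m <- named_models()$model_11574
  d <- quick_dataset(cv = 0.1, replicates = 2, seed = 101)
  fit <- fit_model(m, d, n_starts = 8, seed = 2,
                   options = list(maxit = 25, n_polish = 2,
                                  maxit_polish = 150, n_hops = 0))
  expect_s3_class(fit, "grn_fit")
  expect_false(fit$failed)
  expect_true(is.finite(fit$nll))
  expect_gte(fit$sigma_hat, 1e-6)
  expect_equal(nrow(fit$predictions), 3 * length(quick_times))
  expect_true(all(fit$predictions$value > 0))
  # broom accessors
  expect_equal(nrow(tidy(fit)), nrow(fit$spec))
  expect_equal(glance(fit)$n_obs, nrow(d))
  aug <- augment(fit)
  expect_true(all(is.finite(aug$.resid_rel)))
  # uncertainty band arithmetic
  band <- uncertainty_band(fit)
  expect_equal(band$upper - band$lower,
               2 * fit$sigma_hat * band$value, tolerance = 1e-12)
})

test_that("the multistart optimum is monotone in the number of starts", {
  m <- named_models()$model_11574
  d <- quick_dataset(cv = 0.1, replicates = 2, seed = 101)
  fit <- fit_model(m, d, n_starts = 12, seed = 2,
                   options = list(maxit = 20, n_polish = 1,
                                  maxit_polish = 50, n_hops = 0))
  best_all <- min(fit$starts$nll)
  best_first4 <- min(fit$starts$nll[1:4])
  expect_lte(best_all, best_first4)
})

test_that("gene mismatch between model and data errors", {
  m <- reduce_for_knockout(named_models()$model_11574, "eud-1")
  d <- quick_dataset() # contains eud-1 data
  expect_error(fit_model(m, d, n_starts = 2, seed = 1), "match")
})

test_that("a degenerate structure with no regulated production still fits", {
  m <- named_models()$model_11574
  red <- reduce_for_knockout(m, "eud-1") # nhr-40 term act(N), sult-1 act(E) -> 0
  # craft a KO model whose production terms are all empty
  degen <- grnsets:::new_grn_model(
    list(`nhr-40` = grn_term(character(), character()),
         `sult-1` = grn_term(character(), character())),
    "eud-1", c("N", "S")
  )
  pk <- reference_params(red)
  dk <- dplyr::select(
    generate_dataset(red, pk, quick_times, 2, 0.2, seed = 7), -"experiment")
  fit <- fit_model(degen, dk, n_starts = 6, seed = 3,
                   options = list(maxit = 25, n_polish = 2,
                                  maxit_polish = 100, n_hops = 0))
  expect_false(fit$failed)
  expect_true(is.finite(fit$nll))
})

test_that("fit_family is sorted, reproducible and checkpointable", {
  fam <- knockout_family("eud-1")
  truth <- reduce_for_knockout(named_models()$model_11574, "eud-1")
  d <- dplyr::select(
    generate_dataset(truth, reference_params(truth), quick_times, 2, 0.2,
                     seed = 55), -"experiment")
  idx <- c(0, 5, 17, 60, 143)
  opts <- list(maxit = 15, n_polish = 1, maxit_polish = 60, n_hops = 0)
  tab <- fit_family(fam, d, n_starts = 4, seed = 9, indices = idx,
                    options = opts)
  expect_equal(nrow(tab), 5)
  expect_true(!is.unsorted(tab$nll))
  expect_setequal(tab$model_index, idx)
  tab2 <- fit_family(fam, d, n_starts = 4, seed = 9, indices = idx,
                     options = opts)
  expect_equal(tab$nll, tab2$nll)
  # checkpoints are written and reused
  ckpt <- withr::local_tempdir()
  tab3 <- fit_family(fam, d, n_starts = 4, seed = 9, indices = idx,
                     checkpoint_dir = ckpt, options = opts)
  expect_length(list.files(ckpt), 5)
  tab4 <- fit_family(fam, d, n_starts = 4, seed = 9, indices = idx,
                     checkpoint_dir = ckpt, options = opts)
  expect_equal(tab3$nll, tab4$nll)
})
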