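test_that("production_value reproduces the Hill-factor limits", {
  expect_equal(production_value(grn_term("N", "activation"), c(N = 0), 2), 0)
  expect_equal(production_value(grn_term("N", "repression"), c(N = 0), 2), 1)
  expect_equal(production_value(grn_term("E", "activation"), c(E = 3), 3), 0.5)
  expect_equal(
    production_value(grn_term("E", "activation", exponent = 2), c(E = 3), 3),
    0.25
  )
  two <- grn_term(c("N", "S"), c("activation", "repression"))
  expect_equal(production_value(two, c(N = 4, S = 0), c(4, 1)), 0.5 * 1)
  expect_error(production_value(two, c(N = 4, S = 0), 4), "every Hill factor")
  # every admissible term stays in [0, 1] at random levels
  set.seed(1)
  for (term in enumerate_terms()) {
    lv <- setNames(runif(3, 0, 100), grn_regulators())
    v <- production_value(term, lv, c(runif(1, 0.1, 50), runif(1, 0.1, 50)))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("rhs balances production and degradation", {
  m <- named_models()$model_11574
  p <- reference_params(m)
  # at protein levels 0 every activation factor vanishes
  d <- grn_rhs(m, m = setNames(c(2, 1, 1), grn_genes()),
               p = setNames(c(0, 0, 0), grn_genes()), params = p)
  expect_equal(unname(d$dm["eud-1"]), p$alpha[["eud-1"]] - p$k_m * 2)
  # protein equation: dP = M - k_p P (reduced system)
  p2 <- p
  p2$k_p <- 1
  d2 <- grn_rhs(m, m = setNames(c(1, 1, 1), grn_genes()),
                p = setNames(c(1, 1, 1), grn_genes()), params = p2)
  expect_equal(unname(d2$dp), c(0, 0, 0))
})

test_that("compiled integration agrees with an R-level right-hand side", {
  fam <- build_family()
  set.seed(7)
  for (idx in sample(0:13823, 3)) {
    model <- model_from_index(fam, idx)
    params <- random_params(model, seed = idx + 1)
    genes <- names(model$terms)
    rhs_r <- function(t, y, parms) {
      ng <- length(genes)
      d <- grn_rhs(model, m = setNames(y[1:ng], genes),
                   p = setNames(y[(ng + 1):(2 * ng)], genes), params)
      list(c(unname(d$dm), unname(d$dp)))
    }
    y0 <- grnsets:::pack_state(model, params)
    times <- seq(0, 72, by = 8)
    ref <- deSolve::lsoda(y0, times, rhs_r, NULL, rtol = 1e-10, atol = 1e-12)
    got <- simulate_model(model, params, times, include_proteins = TRUE,
                          rtol = 1e-10, atol = 1e-12)
    wide <- tidyr::pivot_wider(got, names_from = c("species", "gene"),
                               values_from = "value")
    ng <- length(genes)
    for (g in seq_len(ng)) {
      expect_equal(wide[[paste0("mRNA_", genes[g])]], unname(ref[, 1 + g]),
                   tolerance = 1e-7)
    }
  }
})

test_that("with no transcription the mRNA decays as Me0 * exp(-k_m t)", {
  m <- named_models()$model_11574
  p <- reference_params(m)
  p$alpha <- setNames(rep(0, 3), grn_genes())
  p$kt_max <- setNames(rep(0, 3), grn_genes())
  times <- seq(0, 72, by = 1)
  traj <- simulate_model(m, p, times)
  me <- traj$value[traj$gene == "eud-1"]
  expect_lt(max(abs(me - p$m0[["eud-1"]] * exp(-p$k_m * times))), 1e-6)
})

test_that("trajectories stay non-negative and bounded by the production cap", {
  fam <- build_family()
  set.seed(11)
  for (idx in sample(0:13823, 5)) {
    model <- model_from_index(fam, idx)
    params <- random_params(model, seed = idx + 100)
    traj <- simulate_model(model, params, seq(0, 72, by = 4))
    expect_true(all(traj$value >= -1e-9))
    for (g in names(model$terms)) {
      cap <- max(params$m0[[g]],
                 (params$alpha[[g]] + params$kt_max[[g]]) / params$k_m)
      expect_lte(max(traj$value[traj$gene == g]), cap * (1 + 1e-6))
    }
  }
})

test_that("a numerically located fixed point yields constant trajectories", {
  model <- named_models()$unified
  params <- reference_params(model)
  genes <- grn_genes()
  # steady state by fixed-point iteration on the R-level rhs:
  # M* = (alpha + kt F(P*)) / k_m, P* = M* / k_p
  m <- setNames(rep(1, 3), genes)
  p <- setNames(rep(1, 3), genes)
  for (i in 1:500) {
    prot <- setNames(as.numeric(p), grnsets:::gene_to_regulator(genes))
    Fv <- vapply(genes, function(g) {
      production_value(model$terms[[g]], prot, params$K[[g]])
    }, numeric(1))
    m <- (unlist(params$alpha) + unlist(params$kt_max) * Fv) / params$k_m
    p <- m / params$k_p
  }
  resid <- grn_rhs(model, m = m, p = p, params = params)
  expect_lt(max(abs(c(resid$dm, resid$dp))), 1e-10)
  params$m0 <- m
  params$p0 <- p
  traj <- simulate_model(model, params, seq(0, 72, by = 8),
                         include_proteins = TRUE)
  spread <- tapply(traj$value, paste(traj$gene, traj$species),
                   function(v) diff(range(v)) / max(abs(v)))
  expect_lt(max(spread), 1e-5)
})

test_that("observables exclude the hidden protein states by default", {
  m <- named_models()$model_11574
  traj <- simulate_model(m, reference_params(m), c(0, 36, 72))
  expect_identical(unique(traj$species), "mRNA")
})

test_that("scaling symmetry composes as a group and errors on bad input", {
  m <- named_models()$model_11574
  p <- random_params(m, seed = 5, unreduced = TRUE)
  p1 <- apply_scaling_symmetry(p, 1)
  expect_equal(unlist(p1$K), unlist(p$K))
  p23 <- apply_scaling_symmetry(apply_scaling_symmetry(p, 2), 3)
  p6 <- apply_scaling_symmetry(p, 6)
  expect_equal(unlist(p23$K), unlist(p6$K))
  expect_equal(p23$k_t, p6$k_t)
  expect_error(apply_scaling_symmetry(p, -1), "positive")
  expect_error(apply_scaling_symmetry(reference_params(m), 2), "unreduced")
})

test_that("reduced system equals the unreduced system at k_t = 1", {
  model <- named_models()$unified
  pr <- random_params(model, seed = 21)
  pu <- pr
  pu$k_t <- 1
  t_grid <- seq(0, 72, by = 6)
  a <- simulate_model(model, pr, t_grid)
  b <- simulate_model(model, pu, t_grid)
  expect_equal(a$value, b$value, tolerance = 1e-10)
})

test_that("integration failure is reported, not clipped", {
  m <- named_models()$model_11574
  p <- reference_params(m)
  p$kt_max <- setNames(rep(1e300, 3), grn_genes()) # force state overflow
  expect_error(
    suppressWarnings(simulate_model(m, p, c(0, 48))),
    class = "grn_integration_failure"
  )
})
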