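test_that("family sizes are terms_per_gene ^ n_genes", {
  expect_equal(build_family()$size, 13824)
  expect_equal(knockout_family("eud-1")$size, 144)
  expect_equal(knockout_family("sult-1")$size, 144)
  expect_equal(build_family("E", "eud-1")$size, 4)
  expect_equal(build_family(c("N", "S"), c("nhr-40", "sult-1"))$size, 144)
})

test_that("mixed-radix encoding round-trips and matches hand decompositions", {
  fam <- build_family()
  m0 <- model_from_index(fam, 0)
  expect_true(all(vapply(m0$terms, term_signature, character(1)) == "act(E)"))
  m_max <- model_from_index(fam, 13823)
  expect_true(all(vapply(m_max$terms, term_signature,
                         character(1)) == "rep(N)*rep(S)"))
  m25 <- model_from_index(fam, 25)
  # 25 = 0*576 + 1*24 + 1
  expect_identical(unname(vapply(m25$terms, term_signature, character(1))),
                   c("act(E)", "rep(E)", "rep(E)"))
  set.seed(99)
  for (idx in sample(0:13823, 1000)) {
    expect_equal(index_of_model(fam, model_from_index(fam, idx)), idx)
  }
  expect_error(model_from_index(fam, 13824), "index")
  expect_error(model_from_index(fam, -1), "index")
})

test_that("knock-out reduction drops equations and restricted terms", {
  fam <- build_family()
  ko <- reduce_for_knockout(fam, "eud-1")
  expect_equal(ko$size, 144)
  expect_identical(ko$genes, c("nhr-40", "sult-1"))
  expect_false("E" %in% ko$regulators)
  # unified structure: nhr-40 production reduces to single N activation
  red <- reduce_for_knockout(named_models()$unified, "eud-1")
  expect_identical(term_signature(red$terms[["nhr-40"]]), "act(N)")
  expect_identical(term_signature(red$terms[["sult-1"]]), "act(N)*act(S)")
  # a pure term in the knocked-out protein collapses to no regulated production
  fam1 <- build_family()
  m <- model_from_index(fam1, index_of_model(fam1, local({
    new <- grnsets:::new_grn_model(list(
      `eud-1` = grn_term("E", "activation"),
      `nhr-40` = grn_term("E", "activation", exponent = 2L),
      `sult-1` = grn_term("S", "activation")
    ), NULL, grn_regulators())
    new
  })))
  red2 <- reduce_for_knockout(m, "eud-1")
  expect_identical(term_signature(red2$terms[["nhr-40"]]), "0")
  expect_true(is.na(red2$model_index))
  # knocking out twice errors
  expect_error(reduce_for_knockout(red2, "eud-1"), "not in the model")
})

test_that("named structures match their printed equations and round-trip", {
  nm <- named_models()
  m <- nm$model_11574
  expect_identical(term_signature(m$terms[["eud-1"]]), "act(N)*act(S)")
  expect_identical(term_signature(m$terms[["nhr-40"]]), "act(N)")
  expect_identical(term_signature(m$terms[["sult-1"]]), "act(E)^2")
  u <- nm$unified
  expect_identical(term_signature(u$terms[["eud-1"]]), "act(E)*act(N)")
  expect_identical(term_signature(u$terms[["nhr-40"]]), "act(E)*act(N)")
  expect_identical(term_signature(u$terms[["sult-1"]]), "act(N)*act(S)")
  fam <- build_family()
  for (model in nm) {
    expect_equal(index_of_model(fam, model_from_index(fam, model$model_index)),
                 model$model_index)
  }
})

test_that("model JSON serialization round-trips", {
  m <- named_models()$unified
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, path)
  m2 <- model_from_json(path)
  expect_identical(
    vapply(m2$terms, term_signature, character(1)),
    vapply(m$terms, term_signature, character(1))
  )
  red <- reduce_for_knockout(m, "sult-1")
  m3 <- model_from_json(model_to_json(red))
  expect_identical(m3$knockout, "sult-1")
})
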