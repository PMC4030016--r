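# Integrator correctness against closed forms, conservation, determinism,
# node scaling and serialization.

test_that("integrator matches the linear synthesis-degradation closed form", {
  m <- linearModel(syn = 2, deg = 0.1)
  for (dur in c(100, 5000, 50000)) {
    tr <- integrateNetwork(m, duration = dur)
    expect_equal(tr$times[1], 0)
    expect_equal(tr$times[length(tr$times)], dur)
    expected <- (2 / 0.1) * (1 - exp(-0.1 * tr$times))
    expect_lt(max(abs(tr$amounts[, "S"] - expected) / pmax(expected, 1e-12)),
              1e-6)
  }
})

test_that("all-zero rates leave the state unchanged", {
  m <- networkModel(data.frame(id = c("A", "B"), initial_amount = c(3, 7),
                               synthesis_rate = 0, degradation_rate = 0),
                    list(networkReaction("r", reactants = c(A = 1),
                                         products = c(B = 1), k = 0)))
  tr <- integrateNetwork(m, duration = 1000)
  expect_equal(unname(tr$amounts[nrow(tr$amounts), ]), c(3, 7))
})

test_that("mass-action binding conserves stoichiometric totals", {
  m <- bindingModel(k = 0.01, a0 = 5, b0 = 3)
  # the depleted partner may undershoot within -atol; that is clipped with
  # a logged warning
  expect_warning(tr <- integrateNetwork(m, duration = 100000),
                 "clipping")
  expect_true(all(tr$amounts >= 0))
  totalA <- tr$amounts[, "A"] + tr$amounts[, "C"]
  totalB <- tr$amounts[, "B"] + tr$amounts[, "C"]
  expect_lt(max(abs(totalA - 5)) / 5, 1e-8)
  expect_lt(max(abs(totalB - 3)) / 3, 1e-8)
  # binding actually proceeded
  expect_gt(tr$amounts[nrow(tr$amounts), "C"], 2.9)
})

test_that("repeated integration is bitwise deterministic", {
  m <- cascadeModel()
  tr1 <- integrateNetwork(m, duration = 20000)
  tr2 <- integrateNetwork(m, duration = 20000)
  expect_identical(tr1$amounts, tr2$amounts)
})

test_that("integration rejects invalid input", {
  m <- linearModel()
  expect_error(integrateNetwork(m, state = c(S = NaN), duration = 10),
               "non-finite")
  expect_error(integrateNetwork(m, state = c(X = 1), duration = 10),
               "cover all species")
})

test_that("steady state of the linear model is syn/deg", {
  ss <- findSteadyState(linearModel(syn = 2, deg = 0.1), max_time = 50000)
  expect_true(ss$converged)
  expect_equal(unname(ss$state[["S"]]), 20, tolerance = 1e-5)
  expect_lt(ss$residual, 1e-6)
})

test_that("a model already at its fixed point converges at time zero", {
  ss <- findSteadyState(linearModel(syn = 2, deg = 0.1, init = 20))
  expect_true(ss$converged)
  expect_equal(ss$reached_at, 0)
})

test_that("unbounded growth reports non-convergence without error", {
  ss <- findSteadyState(linearModel(syn = 2, deg = 0), max_time = 50000)
  expect_false(ss$converged)
  expect_gt(ss$residual, 1e-6)
})

test_that("scaleReactionNodes is multiplicative with value semantics", {
  m <- cascadeModel()
  m1 <- scaleReactionNodes(m, c(act_R = 1))
  expect_equal(modelReactions(m1)$act_R$rate_scale, 1)
  tr0 <- integrateNetwork(m, duration = 5000)
  tr1 <- integrateNetwork(m1, duration = 5000)
  expect_identical(tr0$amounts, tr1$amounts)

  m2 <- scaleReactionNodes(scaleReactionNodes(m, c(act_R = 0.5)),
                           c(act_R = 0.5))
  expect_equal(modelReactions(m2)$act_R$rate_scale, 0.25)
  # the input model is untouched
  expect_equal(modelReactions(m)$act_R$rate_scale, 1)
  expect_error(scaleReactionNodes(m, c(nope = 2)), "nope")
})

test_that("zeroing a species' only synthesis empties it at steady state", {
  m <- linearModel(syn = 0.5, deg = 0.05, init = 10)
  m <- networkModel(
    data.frame(id = "S", initial_amount = 10, synthesis_rate = 0,
               degradation_rate = 0.05),
    list(networkReaction("syn_S", products = c(S = 1), k = 0.5)))
  off <- scaleReactionNodes(m, c(syn_S = 0))
  ss <- suppressWarnings(findSteadyState(off, max_time = 50000))
  expect_true(ss$converged)
  expect_lt(ss$state[["S"]], 1e-3)
})

test_that("network JSON round trip preserves structure and dynamics", {
  m <- refNet()
  path <- withr::local_tempfile(fileext = ".json")
  writeNetworkJSON(m, path)
  m2 <- readNetworkJSON(path)
  expect_equal(modelSpecies(m2), modelSpecies(m))
  expect_equal(length(modelReactions(m2)), length(modelReactions(m)))
  expect_equal(modelReactions(m2)$act_MEK, modelReactions(m)$act_MEK)
  tr <- integrateNetwork(m, duration = 2000, n_out = 11)
  tr2 <- integrateNetwork(m2, duration = 2000, n_out = 11)
  expect_identical(tr$amounts, tr2$amounts)
})

test_that("SBML export is well-formed and complete", {
  m <- cascadeModel()
  path <- withr::local_tempfile(fileext = ".xml")
  exportSBML(m, path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "sbml")
  ns <- xml2::xml_ns(doc)
  species <- xml2::xml_find_all(doc, ".//d1:species", ns)
  expect_equal(length(species), nrow(modelSpecies(m)))
  laws <- xml2::xml_find_all(doc, ".//d1:kineticLaw", ns)
  expect_gte(length(laws), length(modelReactions(m)))
})
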