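# The three-state protocol and dose-response generation.

test_that("phase end times honor the protocol durations", {
  net <- refNet()
  r <- runThreeState(net, cellLineProfile("empty"), NULL, 0,
                     control_state = refControl())
  expect_equal(unname(r$phase_ends), c(50000, 175000, 375000))
  p <- simulationProtocol(control_duration = 1000, disease_duration = 2000,
                          treatment_duration = 3000)
  r2 <- runThreeState(net, cellLineProfile("empty"), NULL, 0, p,
                      control_state = refControl())
  expect_equal(unname(r2$phase_ends), c(1000, 3000, 6000))
  expect_error(simulationProtocol(control_duration = -1))
})

test_that("a null drug changes nothing and is called resistant", {
  net <- refNet()
  prof <- cellLineProfile("avatar", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3))
  r <- runThreeState(net, prof, NULL, 0, control_state = refControl())
  expect_lt(abs(r$change), 0.5)
  expect_equal(r$call, "resistant")
})

test_that("an empty profile reproduces the control network's drug response", {
  net <- refNet()
  ctrl <- refControl()
  drug <- getDrug("lapatinib")
  r_empty <- runThreeState(net, cellLineProfile("none"), drug, 1,
                           control_state = ctrl)
  # disease state of the empty avatar is the control steady state
  expect_equal(max(abs(r_empty$disease_state - ctrl) /
                     pmax(ctrl, 1e-6)), 0, tolerance = 1e-4)
  treated <- applyDrug(net, drug, 1)
  tr <- integrateNetwork(treated, state = ctrl, duration = 200000)
  direct <- setNames(tr$amounts[nrow(tr$amounts), ], colnames(tr$amounts))
  expect_equal(unname(r_empty$treated_state), unname(direct),
               tolerance = 1e-6)
})

test_that("an EGFR-driven avatar is sensitive to saturating erlotinib", {
  net <- refNet()
  prof <- cellLineProfile("EGFR-dependent", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3))
  r <- runThreeState(net, prof, getDrug("erlotinib"), 1000,
                     control_state = refControl())
  expect_lt(r$change, -20)
  expect_equal(r$call, "sensitive")
})

test_that("reusing the disease state matches recomputation exactly", {
  net <- refNet()
  prof <- cellLineProfile("A", data.frame(
    gene = "CDKN2A", kind = "loss_of_function", magnitude = 5))
  drug <- getDrug("PD0332991")
  r1 <- runThreeState(net, prof, drug, 1, control_state = refControl())
  r2 <- runThreeState(net, prof, drug, 1,
                      disease_state = r1$disease_state)
  expect_lt(abs(r1$change - r2$change), 1e-9)
  expect_equal(r1$treated_state, r2$treated_state, tolerance = 1e-12)
})

test_that("doubling the treatment duration barely moves the endpoint", {
  net <- refNet()
  prof <- cellLineProfile("A", data.frame(
    gene = "ERBB2", kind = "overexpression", magnitude = 3))
  drug <- getDrug("lapatinib")
  r1 <- runThreeState(net, prof, drug, 1, control_state = refControl())
  p2 <- simulationProtocol(treatment_duration = 400000)
  r2 <- runThreeState(net, prof, drug, 1, p2,
                      disease_state = r1$disease_state)
  expect_lt(abs(r1$change - r2$change), 1)
})

test_that("dose-response is computed per dose with shared disease state", {
  net <- refNet()
  prof <- cellLineProfile("EGFR-dependent", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3))
  dr <- doseResponse(net, prof, getDrug("erlotinib"),
                     doses = 10^seq(-2, 3, length.out = 8),
                     control_state = refControl())
  expect_length(dr$responses, 8)
  expect_true(all(diff(dr$responses) <= 1e-6))
  expect_error(doseResponse(net, prof, getDrug("erlotinib"),
                            doses = c(1, 2, 3)), "4")
  expect_error(doseResponse(net, prof, getDrug("erlotinib"),
                            doses = c(1, 1, 2, 3)), "increasing")
})

test_that("IC50 interpolation brackets the -50% crossing", {
  doses <- 10^seq(-2, 2, length.out = 9)
  # synthetic response crossing -50% between two grid points
  resp <- -100 * doses / (doses + 0.7)
  ic50 <- virtumor:::.interpolateIC50(doses, resp)
  i <- max(which(resp > -50))
  expect_gt(ic50, doses[i])
  expect_lt(ic50, doses[i + 1])
  expect_equal(ic50, 0.7, tolerance = 0.25)
  # undefined when never crossed
  expect_true(is.na(virtumor:::.interpolateIC50(doses, resp / 4)))
})

test_that("a flat zero response stays at zero with no IC50", {
  net <- refNet()
  prof <- cellLineProfile("A", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3))
  null_drug <- NULL
  r <- vapply(1:4, function(i)
    runThreeState(net, prof, NULL, 0, control_state = refControl())$change,
    numeric(1))
  expect_true(all(abs(r) < 1e-9))
})
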