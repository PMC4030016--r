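# Association testing and agreement statistics.

test_that("agreement arithmetic is exact", {
  recs <- function(n, k) data.frame(
    predicted_call = rep("sensitive", n),
    observed_call = rep(c("sensitive", "resistant"), c(k, n - k)))
  expect_equal(agreementStats(recs(80, 61))$percent_agreement, 76.25)
  expect_equal(agreementStats(recs(25, 22))$percent_agreement, 88)
  expect_equal(agreementStats(recs(10, 0))$percent_agreement, 0)
  expect_error(agreementStats(recs(0, 0)), "no prediction")
  # permutation invariance
  r <- recs(40, 13)
  set.seed(5)
  expect_equal(agreementStats(r[sample(40), ])$percent_agreement,
               agreementStats(r)$percent_agreement)
})

test_that("a pathway-matched aberration reproduces as a positive control", {
  net <- refNet()
  rec <- associationRecord("EGFR", "overexpression", "erlotinib",
                           "sensitizing", c("POS1", "POS2"))
  profiles <- list(
    POS1 = cellLineProfile("POS1", data.frame(
      gene = "EGFR", kind = "overexpression", magnitude = 3)),
    POS2 = cellLineProfile("POS2", data.frame(
      gene = c("EGFR", "IL6"), kind = c("overexpression", "overexpression"),
      magnitude = c(3, 2))))
  out <- testAssociation(net, rec, profiles, control_state = refControl())
  expect_true(out$reproduced)
  expect_true(all(out$per_line$line_reproduced))
})

test_that("a pathway-disjoint aberration does not reproduce", {
  net <- refNet()
  # IL6 drives JAK/STAT, untouched by the MEK inhibitor
  rec <- associationRecord("IL6", "overexpression", "AZD6244",
                           "sensitizing", "NEG1")
  profiles <- list(NEG1 = cellLineProfile("NEG1", data.frame(
    gene = "IL6", kind = "overexpression", magnitude = 3)))
  out <- testAssociation(net, rec, profiles, control_state = refControl())
  expect_false(out$reproduced)
  expect_lt(abs(out$per_line$parent_change - out$per_line$variant_change), 3)
})

test_that("identical parent and variant never count as reproduced", {
  # with the aberration mapped to nothing dynamical the margin rule must
  # reject; emulate by epsilon exceeding any numerical difference
  net <- refNet()
  rec <- associationRecord("IL6", "overexpression", "erlotinib",
                           "sensitizing", "N1")
  profiles <- list(N1 = cellLineProfile("N1", data.frame(
    gene = "IL6", kind = "overexpression", magnitude = 1.0001)))
  out <- testAssociation(net, rec, profiles, epsilon = 1,
                         control_state = refControl())
  expect_false(out$reproduced)
})

test_that("association preconditions are enforced", {
  net <- refNet()
  rec <- associationRecord("BRAF", "activating_mutation", "AZD6244",
                           "sensitizing", "X1")
  profiles <- list(X1 = cellLineProfile("X1", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3)))
  expect_error(testAssociation(net, rec, profiles,
                               control_state = refControl()),
               "lacks the aberration")
  bad <- associationRecord("BRAF", "activating_mutation", "unobtainium",
                           "sensitizing", "X1")
  expect_error(runRetrospectivePanel(net, list(bad), profiles),
               "unknown drug")
})

test_that("associations CSV round trips through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(
    "gene,kind,drug,direction,cell_lines",
    "BRAF,activating_mutation,AZD6244,sensitizing,COLO205;HT29",
    sep = "\n"), path)
  recs <- readAssociationsCSV(path)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$cell_lines, c("COLO205", "HT29"))
})

test_that("the prospective panel covers the grid and flags gaps", {
  net <- refNet()
  avatars <- list(
    cellLineProfile("AV1", data.frame(gene = "EGFR",
                                      kind = "overexpression",
                                      magnitude = 4), locked = TRUE),
    cellLineProfile("AV2", data.frame(gene = "CDKN2A",
                                      kind = "knockdown",
                                      magnitude = 5), locked = TRUE))
  drugs <- c("erlotinib", "bortezomib")
  grid <- expand.grid(cell_line = c("AV1", "AV2"), drug = drugs,
                      stringsAsFactors = FALSE)
  # observed = predicted by construction -> 100% agreement
  pre <- runProspectivePanel(net, avatars, drugs,
                             cbind(grid, observed_call = "sensitive"))
  obs <- pre$records[, c("cell_line", "drug")]
  obs$observed_call <- pre$records$predicted_call
  pan <- runProspectivePanel(net, avatars, drugs, obs)
  expect_equal(nrow(pan$records), 4)
  expect_equal(pan$stats$percent_agreement, 100)
  expect_equal(nrow(pan$per_drug), 2)
  # missing cell in the observed table errors by name
  expect_error(runProspectivePanel(net, avatars, drugs, obs[-2, ]),
               "no entry")
  # unlocked avatars warn
  unlocked <- list(cellLineProfile("AV1", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 4)))
  expect_warning(
    runProspectivePanel(net, unlocked, "erlotinib",
                        obs[obs$cell_line == "AV1" &
                              obs$drug == "erlotinib", ]),
    "unlocked")
})
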