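# Avatar calibration against alignment-drug observations.

alignmentObs <- function(cell_line, drugs, calls, pct = NA_real_) {
  data.frame(cell_line = cell_line, drug = drugs, observed_call = calls,
             observed_pct_change = pct, stringsAsFactors = FALSE)
}

# Observations simulated from a ground-truth avatar.
simulateObs <- function(net, profile, drugs, dose = 1) {
  ctrl <- refControl()
  r1 <- runThreeState(net, profile, getDrug(drugs[1]), dose,
                      control_state = ctrl)
  out <- list(data.frame(cell_line = profile@id, drug = drugs[1],
                         observed_call = r1$call,
                         observed_pct_change = r1$change))
  for (d in drugs[-1]) {
    r <- runThreeState(net, profile, getDrug(d), dose,
                       disease_state = r1$disease_state)
    out[[d]] <- data.frame(cell_line = profile@id, drug = d,
                           observed_call = r$call,
                           observed_pct_change = r$change)
  }
  do.call(rbind, out)
}

test_that("alignment recovers a synthetic avatar at call level", {
  net <- refNet()
  truth <- cellLineProfile("SYN", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 6))
  obs <- simulateObs(net, truth, c("erlotinib", "sorafenib", "dasatinib"))
  # the truth avatar is erlotinib-sensitive; the default magnitude is not
  start <- cellLineProfile("SYN", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3))
  r_def <- runThreeState(net, start, getDrug("erlotinib"), 1,
                         control_state = refControl())
  expect_false(identical(r_def$call, obs$observed_call[1]) &&
                 abs(r_def$change - obs$observed_pct_change[1]) < 0.5)
  fit <- alignAvatar(net, start, obs)
  expect_equal(fit$n_mismatch, 0)
  expect_true(all(fit$matched))
  expect_true(isLocked(fit$profile))
  # only magnitudes moved, never the gene set
  expect_equal(perturbations(fit$profile)$gene, perturbations(start)$gene)
  expect_equal(perturbations(fit$profile)$kind, perturbations(start)$kind)
})

test_that("a dataset consistent with the defaults is a fixed point", {
  net <- refNet()
  prof <- cellLineProfile("CONS", data.frame(
    gene = "CDKN2A", kind = "loss_of_function", magnitude = 5))
  obs <- simulateObs(net, prof, c("erlotinib", "dasatinib"))
  fit <- alignAvatar(net, prof, obs)
  expect_equal(unname(fit$multipliers), rep(1, 1))
  expect_equal(fit$n_mismatch, 0)
  # re-running on an unlocked copy of the fit changes nothing further
  again <- cellLineProfile(prof@id, perturbations(fit$profile))
  fit2 <- alignAvatar(net, again, obs)
  expect_equal(unname(fit2$multipliers), rep(1, nrow(perturbations(again))))
})

test_that("pathway-disjoint demands surface as reported mismatches", {
  net <- refNet()
  prof <- cellLineProfile("DISJ", data.frame(
    gene = "CDH1", kind = "loss_of_function", magnitude = 5))
  obs <- alignmentObs("DISJ", "sorafenib", "sensitive")
  fit <- alignAvatar(net, prof, obs)
  expect_gte(fit$n_mismatch, 1)
  expect_equal(fit$mismatches$drug, "sorafenib")
  expect_match(fit$mismatches$probes_block, "ras_mapk")
})

test_that("locked profiles and contradictory observations are rejected", {
  net <- refNet()
  locked <- cellLineProfile("L", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3), locked = TRUE)
  expect_error(alignAvatar(net, locked,
                           alignmentObs("L", "erlotinib", "sensitive")),
               "locked")
  prof <- cellLineProfile("C", data.frame(
    gene = "EGFR", kind = "overexpression", magnitude = 3))
  contradictory <- rbind(alignmentObs("C", "erlotinib", "sensitive"),
                         alignmentObs("C", "erlotinib", "resistant"))
  expect_error(alignAvatar(net, prof, contradictory), "contradictory")
  expect_error(alignAvatar(net, prof,
                           alignmentObs("OTHER", "erlotinib", "sensitive")),
               "no alignment observations")
})

test_that("alignment TSV reader validates its vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("cell_line\tdrug\tobserved_call\tobserved_pct_change",
                   "GBM8\terlotinib\tsensitive\t-34", sep = "\n"), path)
  tab <- readAlignmentTSV(path)
  expect_equal(tab$observed_call, "sensitive")
  writeLines(paste("cell_line\tdrug\tobserved_call",
                   "GBM8\terlotinib\tmaybe", sep = "\n"), path)
  expect_error(readAlignmentTSV(path), "sensitive/resistant")
})
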