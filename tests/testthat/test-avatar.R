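# Gene perturbations -> reaction edits -> avatars and variants.

test_that("perturbation kinds map to the documented reaction edits", {
  net <- refNet()
  e <- perturbationEdits(list(gene = "EGFR", kind = "overexpression",
                              magnitude = 3), net)
  expect_equal(e, c(syn_EGFR = 3))
  e <- perturbationEdits(list(gene = "RB1", kind = "deletion",
                              magnitude = NA_real_), net)
  expect_equal(e, c(syn_RB1 = 0.01))
  e <- perturbationEdits(list(gene = "BRAF", kind = "activating_mutation",
                              magnitude = NA_real_), net)
  expect_equal(e, c(act_BRAF = 5))  # default magnitude
  e <- perturbationEdits(list(gene = "CDKN2A", kind = "knockdown",
                              magnitude = 4), net)
  expect_equal(e, c(syn_CDKN2A = 0.25))
  expect_error(perturbationEdits(list(gene = "EGFR", kind = "overexpression",
                                      magnitude = -1), net), "magnitude")
  expect_error(perturbationEdits(list(gene = "NOSUCHGENE",
                                      kind = "overexpression",
                                      magnitude = 2), net), "NOSUCHGENE")
})

test_that("declared-unmapped genes give empty edits plus a notice", {
  net <- refNet()
  expect_message(
    e <- perturbationEdits(list(gene = "RUNX3", kind = "knockdown",
                                magnitude = 5), net),
    "unmapped")
  expect_length(e, 0)
})

test_that("an empty profile leaves the dynamics unchanged", {
  net <- refNet()
  av <- createAvatar(net, cellLineProfile("empty"))
  expect_equal(modelMetadata(av)$profile_id, "empty")
  tr0 <- integrateNetwork(net, duration = 2000, n_out = 5)
  tr1 <- integrateNetwork(av, duration = 2000, n_out = 5)
  expect_identical(tr0$amounts, tr1$amounts)
})

test_that("the SK987-like avatar shifts AKT and CDKN2A the narrated way", {
  net <- refNet()
  av <- suppressMessages(createAvatar(net, studyFixture("sk987_profile")))
  ctrl <- refControl()
  dis <- integrateNetwork(av, state = ctrl, duration = 125000)
  dstate <- setNames(dis$amounts[nrow(dis$amounts), ],
                     colnames(dis$amounts))
  expect_gt(dstate[["AKT1_act"]], ctrl[["AKT1_act"]])
  expect_lt(dstate[["CDKN2A_act"]], ctrl[["CDKN2A_act"]])
})

test_that("avatar creation commutes across perturbations", {
  net <- refNet()
  p <- data.frame(gene = c("EGFR", "CDKN2A"),
                  kind = c("overexpression", "loss_of_function"),
                  magnitude = c(3, 5))
  a1 <- createAvatar(net, cellLineProfile("fwd", p))
  a2 <- createAvatar(net, cellLineProfile("rev", p[2:1, ]))
  r1 <- modelReactions(a1); r2 <- modelReactions(a2)
  expect_equal(vapply(r1, `[[`, numeric(1), "rate_scale"),
               vapply(r2, `[[`, numeric(1), "rate_scale"))
})

test_that("variants add and remove perturbations with id suffixes", {
  du145 <- cellLineProfile("DU145", data.frame(
    gene = c("RB1", "TP53"), kind = c("deletion", "loss_of_function"),
    magnitude = c(NA, 5)))
  wt <- makeVariant(du145, remove = c("RB1", "deletion"))
  expect_equal(profileId(wt), "DU145_WT_RB1")
  expect_equal(nrow(perturbations(wt)), 1)
  expect_equal(perturbations(wt)$gene, "TP53")

  back <- makeVariant(wt, add = data.frame(gene = "RB1", kind = "deletion",
                                           magnitude = NA_real_))
  expect_setequal(paste(perturbations(back)$gene, perturbations(back)$kind),
                  paste(perturbations(du145)$gene, perturbations(du145)$kind))
  expect_error(makeVariant(du145, remove = c("KRAS", "activating_mutation")),
               "KRAS")
  locked <- cellLineProfile("L", locked = TRUE)
  expect_error(makeVariant(locked, add = data.frame(
    gene = "EGFR", kind = "copy_gain", magnitude = 2)), "locked")
})

test_that("RB1 deletion derepresses E2F and raises proliferation", {
  net <- refNet()
  ctrl <- refControl()
  rb <- cellLineProfile("RB1null", data.frame(gene = "RB1",
                                              kind = "deletion",
                                              magnitude = NA_real_))
  r <- runThreeState(net, rb, NULL, 0, control_state = ctrl)
  expect_gt(r$disease_state[["E2F"]], ctrl[["E2F"]] * 1.5)
  expect_gt(r$disease_indices$proliferation,
            computeIndices(ctrl)$proliferation)
})

test_that("variant round trip preserves drug response", {
  net <- refNet()
  ctrl <- refControl()
  prof <- cellLineProfile("X", data.frame(
    gene = c("EGFR", "CDKN2A"), kind = c("overexpression", "knockdown"),
    magnitude = c(3, 5)))
  back <- makeVariant(makeVariant(prof, remove = c("CDKN2A", "knockdown")),
                      add = data.frame(gene = "CDKN2A", kind = "knockdown",
                                       magnitude = 5))
  drug <- getDrug("erlotinib")
  r1 <- runThreeState(net, prof, drug, 1, control_state = ctrl)
  r2 <- runThreeState(net, back, drug, 1, control_state = ctrl)
  expect_lt(abs(r1$change - r2$change), 1e-9)
})

test_that("profile TSV reading and writing round trips", {
  profs <- studyFixture("garnett_line_profiles")[1:4]
  path <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTSV(profs, path)
  back <- readProfileTSV(path)
  expect_setequal(names(back), names(profs))
  expect_equal(perturbations(back$HT29), perturbations(profs$HT29))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cell_line\tgene\tkind\tmagnitude\nA\tEGFR\tsuperduper\t2", bad)
  expect_error(readProfileTSV(bad), "superduper")
})

test_that("the shipped profile tables load and validate", {
  p <- readProfileTSV(system.file("extdata",
                                  "garnett_line_profiles_synthetic.tsv",
                                  package = "virtumor"))
  expect_gte(length(p), 16)
  sk <- readProfileTSV(system.file("extdata", "sk987_profile.tsv",
                                   package = "virtumor"))
  expect_equal(names(sk), "SK987")
})
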