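# Phenotype index arithmetic, classification boundary, weight optimization.

# A state with every biomarker set to one value (plus extras ignored).
uniformState <- function(v = 1) setNames(rep(v, length(unlist(indexBiomarkers()))),
                                         unlist(indexBiomarkers()))

biomarkerState <- function(proliferation = 1, survival = 1, apoptosis = 1) {
  b <- indexBiomarkers()
  c(setNames(rep(proliferation, 4), b$proliferation),
    setNames(rep(survival, 6), b$survival),
    setNames(rep(apoptosis, 4), b$apoptosis))
}

test_that("uniform biomarkers give unit indices", {
  idx <- computeIndices(uniformState(1))
  expect_equal(idx$proliferation, 1)
  expect_equal(idx$survival, 1)
  expect_equal(idx$apoptosis, 1)
  expect_equal(idx$viability, 1)
  expect_equal(idx$relative_growth, 1)
})

test_that("viability is survival/apoptosis and growth their mean", {
  idx <- computeIndices(biomarkerState(survival = 2, apoptosis = 1,
                                       proliferation = 1))
  expect_equal(idx$viability, 2)
  expect_equal(idx$relative_growth, 1.5)
})

test_that("missing or degenerate biomarkers error informatively", {
  s <- uniformState(1)
  expect_error(computeIndices(s[setdiff(names(s), "BAX")]), "BAX")
  expect_error(computeIndices(biomarkerState(apoptosis = 0)), "apoptosis")
})

test_that("indices are homogeneous and viability scale-invariant", {
  set.seed(7)
  for (i in 1:5) {
    s <- setNames(runif(length(unlist(indexBiomarkers())), 0.1, 5),
                  unlist(indexBiomarkers()))
    c0 <- computeIndices(s)
    for (cc in c(0.5, 3)) {
      c1 <- computeIndices(s * cc)
      expect_equal(c1$proliferation, cc * c0$proliferation)
      expect_equal(c1$survival, cc * c0$survival)
      expect_equal(c1$apoptosis, cc * c0$apoptosis)
      expect_equal(c1$viability, c0$viability)
    }
  }
})

test_that("percent change is exact signed arithmetic", {
  expect_equal(percentChange(1.0, 0.75), -25)
  expect_equal(percentChange(1.0, 1.0), 0)
  expect_equal(percentChange(0.8, 1.0), 25)
  expect_error(percentChange(0, 1), "baseline")
})

test_that("classification boundary is exact at -threshold", {
  expect_equal(classifyResponse(-25), "sensitive")
  expect_equal(classifyResponse(-15), "resistant")
  expect_equal(classifyResponse(-20), "resistant")
  expect_equal(classifyResponse(-20 - 1e-9), "sensitive")
  # monotone in percent change
  pc <- seq(-60, 20, by = 2.5)
  calls <- classifyResponse(pc)
  expect_true(all(diff(calls == "sensitive") <= 0))
  # configurable threshold
  expect_equal(classifyResponse(-16, threshold = 15), "sensitive")
})

test_that("custom weights validate onto the simplex", {
  b <- indexBiomarkers()
  w <- indexWeights(proliferation = setNames(c(0.4, 0.3, 0.2, 0.1),
                                             names(b$proliferation)))
  expect_equal(sum(w$proliferation), 1)
  expect_error(indexWeights(proliferation = setNames(rep(0.5, 4),
                                                     names(b$proliferation))),
               "sum to 1")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(unclass(w), as.list), path)
  w2 <- readIndexWeights(path)
  expect_equal(w2$proliferation, w$proliferation)
})

# Brute-force oracle over the same 0.1 grid, written independently.
oracleWeights <- function(X, trend, step = 0.1) {
  d <- ncol(X); steps <- round(1 / step)
  best <- NULL; best_cor <- -Inf
  grid <- expand.grid(rep(list(0:steps), d - 1))
  for (i in seq_len(nrow(grid))) {
    w <- as.numeric(grid[i, ])
    if (sum(w) > steps) next
    wfull <- c(w, steps - sum(w)) / steps
    # expand.grid varies the first column fastest; re-order to match
    # lexicographic enumeration on (w1, w2, ...)
    v <- as.numeric(X %*% wfull)
    if (length(unique(v)) < 2) next
    rho <- suppressWarnings(cor(v, trend, method = "spearman"))
    if (!is.na(rho) && rho > best_cor + 1e-12) {
      best_cor <- rho; best <- wfull
    }
  }
  list(weights = best, correlation = best_cor)
}

test_that("weight optimization recovers a planted weight vector", {
  b <- indexBiomarkers()$proliferation
  set.seed(11)
  X <- matrix(runif(8 * 4, 0.5, 4), nrow = 8,
              dimnames = list(NULL, unname(b)))
  planted <- c(0.3, 0.2, 0.4, 0.1)
  trend <- rank(X %*% planted)
  states <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  fit <- optimizeWeights(states, trend, index = "proliferation")
  expect_equal(fit$correlation, 1)
  # the oracle agrees a perfect correlation is attainable on the grid
  orc <- oracleWeights(X, trend)
  expect_equal(orc$correlation, 1)
})

test_that("a single informative biomarker takes all the weight", {
  b <- indexBiomarkers()$proliferation
  set.seed(13)
  # large-amplitude uninformative biomarkers: any admixture breaks the ranks
  X <- matrix(runif(8 * 4, 0, 100), nrow = 8,
              dimnames = list(NULL, unname(b)))
  X[, 2] <- seq_len(8)          # the informative biomarker
  trend <- seq_len(8)
  states <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  fit <- optimizeWeights(states, trend, index = "proliferation")
  expect_equal(fit$correlation, 1)
  expect_gte(fit$weights[[names(b)[2]]], 0.9)
})

test_that("degenerate inputs are rejected or reported as undefined", {
  states <- replicate(4, uniformState(1), simplify = FALSE)
  fit <- optimizeWeights(states, 1:4, index = "survival")
  expect_true(is.na(fit$correlation))
  expect_error(optimizeWeights(states[1:2], 1:2), "3 conditions")
})
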