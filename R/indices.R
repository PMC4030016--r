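# The five phenotype indices scored from a network state.
#
# Proliferation = weighted mean of the active CDK-cyclin complexes
#   (CDK4-CCND1, CDK2-CCNE, CDK2-CCNA, CDK1-CCNB1);
# Survival = weighted mean of AKT1 (active form), BCL2, MCL1, BIRC5, BIRC2,
#   XIAP;
# Apoptosis = weighted mean of BAX, CASP3 (active), NOXA, CASP8 (active);
# Viability = Survival / Apoptosis;
# Relative growth = (Survival + Proliferation) / 2
#   (the proxy for metabolic-activity viability assays).
#
# Biomarker tokens map to network species; AKT1/CASP3/CASP8 contribute via
# their active (phosphorylated/cleaved) forms since the signaling readout is
# activity, not total protein.

.BIOMARKERS <- list(
  proliferation = c("CDK4-CCND1" = "CDK4_CCND1", "CDK2-CCNE" = "CDK2_CCNE",
                    "CDK2-CCNA" = "CDK2_CCNA", "CDK1-CCNB1" = "CDK1_CCNB1"),
  survival = c(AKT1 = "AKT1_act", BCL2 = "BCL2", MCL1 = "MCL1",
               BIRC5 = "BIRC5", BIRC2 = "BIRC2", XIAP = "XIAP"),
  apoptosis = c(BAX = "BAX", CASP3 = "CASP3_act", NOXA = "NOXA",
                CASP8 = "CASP8_act"))

#' Biomarker -> species mapping used by the indices
#' @return named list of named character vectors (token -> species id).
#' @export
indexBiomarkers <- function() .BIOMARKERS

#' Index weight sets
#'
#' Three named nonnegative weight vectors (one per sub-index), each summing
#' to 1 over its biomarker tokens. Defaults are uniform within each index.
#'
#' @param proliferation,survival,apoptosis named weight vectors over the
#'   biomarker tokens of [indexBiomarkers()].
#' @return an `IndexWeights` list.
#' @export
indexWeights <- function(proliferation = NULL, survival = NULL,
                         apoptosis = NULL) {
  build <- function(w, tokens, label) {
    if (is.null(w)) w <- setNames(rep(1 / length(tokens), length(tokens)),
                                  tokens)
    if (!setequal(names(w), tokens))
      stop(label, " weights must be named over: ",
           paste(tokens, collapse = ", "))
    w <- w[tokens]
    if (any(w < 0)) stop(label, " weights must be >= 0")
    if (abs(sum(w) - 1) > 1e-6)
      stop(label, " weights must sum to 1 (got ", sum(w), ")")
    w / sum(w)
  }
  structure(list(
    proliferation = build(proliferation, names(.BIOMARKERS$proliferation),
                          "proliferation"),
    survival = build(survival, names(.BIOMARKERS$survival), "survival"),
    apoptosis = build(apoptosis, names(.BIOMARKERS$apoptosis), "apoptosis")),
    class = "IndexWeights")
}

#' @rdname indexWeights
#' @export
defaultIndexWeights <- function() indexWeights()

#' Read index weights from YAML or JSON
#'
#' Expects three top-level maps `proliferation`, `survival`, `apoptosis`
#' keyed by biomarker token; validated onto the simplex.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `IndexWeights` list.
#' @export
readIndexWeights <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  indexWeights(proliferation = unlist(x$proliferation),
               survival = unlist(x$survival),
               apoptosis = unlist(x$apoptosis))
}

#' Compute the five phenotype indices from a state
#'
#' @param state named vector of species amounts (a.u.).
#' @param weights an [indexWeights()] set.
#' @return list of class `PhenotypeIndices` with `proliferation`,
#'   `survival`, `apoptosis`, `viability`, `relative_growth`.
#' @export
computeIndices <- function(state, weights = defaultIndexWeights()) {
  vals <- lapply(names(.BIOMARKERS), function(ix) {
    sp <- .BIOMARKERS[[ix]]
    missing <- setdiff(unname(sp), names(state))
    if (length(missing))
      stop("missing biomarker species: ", paste(missing, collapse = ", "))
    amounts <- state[unname(sp)]
    if (any(amounts < 0)) stop("negative biomarker amounts")
    sum(weights[[ix]] * amounts)
  })
  names(vals) <- names(.BIOMARKERS)
  if (vals$apoptosis <= 0)
    stop("apoptosis index is 0; viability (survival/apoptosis) undefined")
  structure(list(proliferation = vals$proliferation,
                 survival = vals$survival,
                 apoptosis = vals$apoptosis,
                 viability = vals$survival / vals$apoptosis,
                 relative_growth = (vals$survival + vals$proliferation) / 2),
            class = "PhenotypeIndices")
}

#' Percent change of an index between two states
#'
#' @param baseline pre-treatment index value (> 0).
#' @param treated post-treatment index value.
#' @return signed percent: `100 * (treated - baseline) / baseline`.
#' @export
percentChange <- function(baseline, treated) {
  if (any(baseline <= 0)) stop("baseline index must be > 0")
  100 * (treated - baseline) / baseline
}

#' Classify a percent change as sensitive or resistant
#'
#' Sensitive means a strict decrease of more than `threshold` percent; a
#' change of exactly `-threshold` is resistant (the resistant rule reads
#' "decreases by less than threshold", taken inclusive of equality).
#'
#' @param percent_change signed percent change(s).
#' @param threshold positive percent (default 20).
#' @return character vector of `"sensitive"`/`"resistant"`.
#' @export
classifyResponse <- function(percent_change, threshold = 20) {
  stopifnot(threshold > 0)
  ifelse(percent_change < -threshold, "sensitive", "resistant")
}

#' Optimize index weights against an experimental trend
#'
#' Deterministic brute-force search over the probability simplex (grid step
#' 0.1) for the weight vector whose index values across the given states
#' have maximum Spearman rank correlation with the experimentally reported
#' trend; ties are broken lexicographically in grid enumeration order.
#'
#' @param states list of named amount vectors (>= 3 conditions).
#' @param trend numeric trend ranks, one per state (a total order).
#' @param index which sub-index to optimize
#'   (`"proliferation"`/`"survival"`/`"apoptosis"`).
#' @param step grid step on the simplex (default 0.1).
#' @return list with `weights` (named, summing to 1), `correlation`
#'   (achieved Spearman rho, NA if undefined) and `index`.
#' @export
optimizeWeights <- function(states, trend,
                            index = c("proliferation", "survival",
                                      "apoptosis"),
                            step = 0.1) {
  index <- match.arg(index)
  if (length(states) < 3 || length(trend) != length(states))
    stop("need >= 3 conditions with one trend rank per state")
  tokens <- names(.BIOMARKERS[[index]])
  sp <- unname(.BIOMARKERS[[index]])
  X <- do.call(rbind, lapply(states, function(s) {
    missing <- setdiff(sp, names(s))
    if (length(missing))
      stop("missing biomarker species: ", paste(missing, collapse = ", "))
    s[sp]
  }))
  grid <- .simplexGrid(length(tokens), round(1 / step))
  best <- NULL; best_cor <- -Inf
  for (i in seq_len(nrow(grid))) {
    v <- as.numeric(X %*% grid[i, ])
    if (length(unique(v)) < 2) next
    rho <- suppressWarnings(cor(v, trend, method = "spearman"))
    if (is.na(rho)) next
    if (rho > best_cor + 1e-12) { best_cor <- rho; best <- grid[i, ] }
  }
  if (is.null(best))
    return(list(weights = setNames(rep(NA_real_, length(tokens)), tokens),
                correlation = NA_real_, index = index))
  list(weights = setNames(best, tokens), correlation = best_cor,
       index = index)
}

# All compositions of `steps` grid units into d nonnegative parts, in
# lexicographic order; rows sum to 1.
.simplexGrid <- function(d, steps) {
  if (d == 1) return(matrix(1, 1, 1))
  rows <- list()
  recurse <- function(prefix, remaining, left) {
    if (left == 1) {
      rows[[length(rows) + 1L]] <<- c(prefix, remaining)
      return()
    }
    for (v in 0:remaining) recurse(c(prefix, v), remaining - v, left - 1)
  }
  recurse(integer(0), steps, d)
  do.call(rbind, rows) / steps
}
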