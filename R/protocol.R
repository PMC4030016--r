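# The three-state simulation protocol: control (untriggered, 50,000 s),
# disease (perturbations overlaid, further 125,000 s), drug treatment
# (further 200,000 s at constant drug level). Percent change is scored
# treated-phase-end against disease-phase-end, i.e. the drug effect on the
# diseased system, and classified with the >20% rule.

#' Simulation protocol settings
#'
#' @param control_duration,disease_duration,treatment_duration phase lengths
#'   in simulated seconds (defaults 50,000 / 125,000 / 200,000).
#' @param index_used index the sensitivity call is made on
#'   (`"relative_growth"` default; `"viability"` or `"proliferation"`
#'   selectable since dose-response figures are drawn on viability).
#' @param threshold percent-decrease threshold for the sensitive call.
#' @return a `SimulationProtocol` list.
#' @export
simulationProtocol <- function(control_duration = 50000,
                               disease_duration = 125000,
                               treatment_duration = 200000,
                               index_used = c("relative_growth", "viability",
                                              "proliferation"),
                               threshold = 20) {
  stopifnot(control_duration > 0, disease_duration > 0,
            treatment_duration > 0, threshold > 0)
  structure(list(control_duration = control_duration,
                 disease_duration = disease_duration,
                 treatment_duration = treatment_duration,
                 index_used = match.arg(index_used),
                 threshold = threshold),
            class = "SimulationProtocol")
}

#' Run the three-state protocol
#'
#' Control phase: the untriggered reference network is integrated to its
#' steady state (error if it does not converge). Disease phase: the
#' profile's perturbations are applied and the system re-equilibrates.
#' Treatment phase: the drug is applied at the given constant dose. Indices
#' are computed at each phase end; the percent change of the configured
#' index (treated vs disease baseline) yields the sensitive/resistant call.
#'
#' @param network the reference [NetworkModel-class].
#' @param profile a [CellLineProfile-class].
#' @param drug a [DrugDefinition-class], or NULL for an untreated run.
#' @param dose post-ADME dose (a.u.).
#' @param protocol a [simulationProtocol()].
#' @param weights an [indexWeights()] set.
#' @param control_state optional precomputed control steady state (named
#'   amounts); callers running many avatars reuse it.
#' @param disease_state optional precomputed disease state for this profile
#'   (as from a previous run's `$disease_state`); skips phases 1-2.
#' @return list of class `ProtocolResult`: phase-end states, indices,
#'   `percent_change` (all five indices), `call`, phase end times.
#' @export
runThreeState <- function(network, profile, drug, dose,
                          protocol = simulationProtocol(),
                          weights = defaultIndexWeights(),
                          control_state = NULL, disease_state = NULL) {
  stopifnot(is(network, "NetworkModel"), is(profile, "CellLineProfile"))
  avatar <- createAvatar(network, profile)
  if (is.null(disease_state)) {
    if (is.null(control_state)) {
      ss <- untriggeredBaseline(network, max_time = protocol$control_duration)
      control_state <- ss$state
    }
    traj <- integrateNetwork(avatar, state = control_state,
                             duration = protocol$disease_duration)
    disease_state <- setNames(traj$amounts[nrow(traj$amounts), ],
                              colnames(traj$amounts))
  }
  treated_model <- applyDrug(avatar, drug, dose)
  traj3 <- integrateNetwork(treated_model, state = disease_state,
                            duration = protocol$treatment_duration)
  treated_state <- setNames(traj3$amounts[nrow(traj3$amounts), ],
                            colnames(traj3$amounts))
  disease_idx <- computeIndices(disease_state, weights)
  treated_idx <- computeIndices(treated_state, weights)
  pc <- setNames(vapply(.INDEX_NAMES, function(ix)
    percentChange(disease_idx[[ix]], treated_idx[[ix]]), numeric(1)),
    .INDEX_NAMES)
  change <- pc[[protocol$index_used]]
  structure(list(
    cell_line = profile@id,
    drug = if (is.null(drug)) "none" else drug@name,
    dose = dose,
    control_state = control_state,
    disease_state = disease_state,
    treated_state = treated_state,
    control_indices = if (!is.null(control_state))
      computeIndices(control_state, weights) else NULL,
    disease_indices = disease_idx,
    treated_indices = treated_idx,
    percent_change = pc,
    index_used = protocol$index_used,
    change = change,
    call = classifyResponse(change, protocol$threshold),
    phase_ends = cumsum(c(control = protocol$control_duration,
                          disease = protocol$disease_duration,
                          treated = protocol$treatment_duration))),
    class = "ProtocolResult")
}

#' Dose-response curve with IC50
#'
#' Runs the treatment phase once per dose against a single shared disease
#' state (computing it once and branching is numerically identical to
#' recomputing, the phases being deterministic). The IC50 is the log-linear
#' interpolation of the first crossing of the -50% level; it is undefined
#' (NA) if the curve never crosses.
#'
#' @inheritParams runThreeState
#' @param doses increasing vector of >= 4 doses.
#' @return list of class `DoseResponse`: `doses`, `responses` (percent
#'   change of the configured index per dose), `calls`, `ic50`.
#' @export
doseResponse <- function(network, profile, drug, doses,
                         protocol = simulationProtocol(),
                         weights = defaultIndexWeights(),
                         control_state = NULL) {
  if (length(doses) < 4 || is.unsorted(doses, strictly = TRUE))
    stop("need >= 4 strictly increasing doses")
  first <- runThreeState(network, profile, drug, doses[1], protocol, weights,
                         control_state = control_state)
  disease_state <- first$disease_state
  responses <- numeric(length(doses))
  responses[1] <- first$change
  for (i in seq_along(doses)[-1]) {
    r <- runThreeState(network, profile, drug, doses[i], protocol, weights,
                       disease_state = disease_state)
    responses[i] <- r$change
  }
  structure(list(cell_line = profile@id,
                 drug = if (is.null(drug)) "none" else drug@name,
                 doses = doses, responses = responses,
                 calls = classifyResponse(responses, protocol$threshold),
                 index_used = protocol$index_used,
                 ic50 = .interpolateIC50(doses, responses)),
            class = "DoseResponse")
}

# First crossing of the -50% level, interpolated linearly in log10(dose).
.interpolateIC50 <- function(doses, responses, level = -50) {
  for (i in seq_len(length(doses) - 1)) {
    r1 <- responses[i]; r2 <- responses[i + 1]
    if (r1 > level && r2 <= level) {
      if (doses[i] <= 0) {  # cannot place a log interpolant at dose 0
        return(doses[i + 1])
      }
      f <- (level - r1) / (r2 - r1)
      return(10^(log10(doses[i]) +
                   f * (log10(doses[i + 1]) - log10(doses[i]))))
    }
  }
  NA_real_
}
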