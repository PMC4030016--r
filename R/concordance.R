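# Mutation-drug association testing (parent vs wild-type-variant pairs) and
# predicted-vs-observed agreement statistics.

#' Association record
#'
#' @param gene gene symbol carrying the aberration.
#' @param kind perturbation kind (vocabulary of [cellLineProfile()]).
#' @param drug drug name (must be in the library).
#' @param direction `"sensitizing"` or `"resistance_conferring"`.
#' @param cell_lines character vector of profile ids to test (>= 1).
#' @param note source note.
#' @return an `AssociationRecord` list.
#' @export
associationRecord <- function(gene, kind, drug, direction, cell_lines,
                              note = "") {
  stopifnot(length(cell_lines) >= 1, direction %in% .DIRECTIONS,
            kind %in% .PERTURBATION_KINDS)
  structure(list(gene = gene, kind = kind, drug = drug,
                 direction = direction, cell_lines = cell_lines,
                 note = note), class = "AssociationRecord")
}

#' Read an associations CSV
#'
#' Columns: `gene, kind, drug, direction, cell_lines` (semicolon-separated
#' profile ids).
#'
#' @param path file path.
#' @return list of `AssociationRecord`.
#' @export
readAssociationsCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    associationRecord(tab$gene[i], tab$kind[i], tab$drug[i],
                      tab$direction[i],
                      strsplit(tab$cell_lines[i], ";")[[1]]))
}

#' Test one mutation-drug association
#'
#' For each named cell line the three-state protocol is run on the parent
#' profile and on its wild-type variant (the aberration removed, everything
#' else retained). A sensitizing association is reproduced in a line when
#' the parent's percent change is more negative than the variant's by at
#' least `epsilon` percentage points (the margin separating directionality
#' from integrator noise); resistance-conferring is the reverse. The
#' association is reproduced when all tested lines agree in direction
#' (`strictness = "unanimity"`), or most of them (`"majority"`).
#'
#' @param network the reference network.
#' @param record an [associationRecord()].
#' @param profiles named list of [CellLineProfile-class] covering the
#'   record's cell lines; each must carry the aberration.
#' @param dose reference dose.
#' @param protocol,weights as in [runThreeState()].
#' @param epsilon direction margin in percentage points.
#' @param strictness `"unanimity"` (default) or `"majority"`.
#' @param control_state optional precomputed control steady state.
#' @return list of class `AssociationOutcome`: per-line data.frame
#'   (`parent_change`, `variant_change`, `line_reproduced`) and
#'   `reproduced`.
#' @export
testAssociation <- function(network, record, profiles, dose = 1,
                            protocol = simulationProtocol(),
                            weights = defaultIndexWeights(),
                            epsilon = 1,
                            strictness = c("unanimity", "majority"),
                            control_state = NULL) {
  strictness <- match.arg(strictness)
  drug <- getDrug(record$drug)
  if (is.null(control_state))
    control_state <- untriggeredBaseline(
      network, max_time = protocol$control_duration)$state
  rows <- lapply(record$cell_lines, function(cl) {
    prof <- profiles[[cl]]
    if (is.null(prof)) stop("no profile for cell line '", cl, "'")
    has <- any(prof@perturbations$gene == record$gene &
                 prof@perturbations$kind == record$kind)
    if (!has)
      stop("profile '", cl, "' lacks the aberration (", record$gene, ", ",
           record$kind, ")")
    variant <- makeVariant(prof, remove = c(record$gene, record$kind))
    rp <- runThreeState(network, prof, drug, dose, protocol, weights,
                        control_state = control_state)
    rv <- runThreeState(network, variant, drug, dose, protocol, weights,
                        control_state = control_state)
    rep_line <- if (record$direction == "sensitizing")
      rp$change < rv$change - epsilon
    else rp$change > rv$change + epsilon
    data.frame(cell_line = cl, parent_change = rp$change,
               variant_change = rv$change, parent_call = rp$call,
               variant_call = rv$call, line_reproduced = rep_line,
               stringsAsFactors = FALSE)
  })
  per_line <- do.call(rbind, rows)
  reproduced <- if (strictness == "unanimity") all(per_line$line_reproduced)
  else mean(per_line$line_reproduced) > 0.5
  structure(list(gene = record$gene, kind = record$kind, drug = record$drug,
                 direction = record$direction, per_line = per_line,
                 reproduced = reproduced, strictness = strictness,
                 epsilon = epsilon),
            class = "AssociationOutcome")
}

#' Agreement statistics over prediction records
#'
#' Exact integer tally; the percentage is an exact ratio, rounded only at
#' presentation (2 decimals in the `print` method).
#'
#' @param records data.frame with columns `predicted_call` and
#'   `observed_call` (non-empty).
#' @return list of class `AgreementStats`: `n_total`, `n_match`,
#'   `percent_agreement`.
#' @export
agreementStats <- function(records) {
  if (is.null(records) || !nrow(records)) stop("no prediction records")
  if (any(is.na(records$observed_call)))
    stop("every record needs an observed_call")
  n_total <- nrow(records)
  n_match <- sum(records$predicted_call == records$observed_call)
  structure(list(n_total = n_total, n_match = n_match,
                 percent_agreement = 100 * n_match / n_total),
            class = "AgreementStats")
}

#' @export
print.AgreementStats <- function(x, ...) {
  cat(sprintf("AgreementStats: %d/%d matched (%.2f%%)\n", x$n_match,
              x$n_total, x$percent_agreement))
  invisible(x)
}

#' Run a panel of retrospective association tests
#'
#' Maps [testAssociation()] over the records (sharing one control steady
#' state) and tallies reproduced directions.
#'
#' @inheritParams testAssociation
#' @param records list of [associationRecord()].
#' @return list of class `RetrospectivePanel`: `outcomes`, `summary`
#'   data.frame, `stats` ([agreementStats()] over reproduced flags).
#' @export
runRetrospectivePanel <- function(network, records, profiles, dose = 1,
                                  protocol = simulationProtocol(),
                                  weights = defaultIndexWeights(),
                                  epsilon = 1,
                                  strictness = c("unanimity", "majority")) {
  strictness <- match.arg(strictness)
  for (rec in records) getDrug(rec$drug)  # fail fast on unknown drugs
  control <- untriggeredBaseline(network,
                                 max_time = protocol$control_duration)$state
  outcomes <- lapply(records, testAssociation, network = network,
                     profiles = profiles, dose = dose, protocol = protocol,
                     weights = weights, epsilon = epsilon,
                     strictness = strictness, control_state = control)
  summary <- do.call(rbind, lapply(outcomes, function(o)
    data.frame(gene = o$gene, kind = o$kind, drug = o$drug,
               direction = o$direction,
               n_lines = nrow(o$per_line),
               n_lines_reproduced = sum(o$per_line$line_reproduced),
               reproduced = o$reproduced, stringsAsFactors = FALSE)))
  stats <- agreementStats(data.frame(
    predicted_call = ifelse(summary$reproduced, "match", "mismatch"),
    observed_call = "match", stringsAsFactors = FALSE))
  list(outcomes = outcomes, summary = summary, stats = stats)
}

#' Run a prospective prediction panel
#'
#' One three-state prediction per (cell line, drug) cell -- the disease
#' state of each avatar is computed once and shared across drugs -- compared
#' against the observed-response table.
#'
#' @param network the reference network.
#' @param avatars list of locked [CellLineProfile-class] (a warning is
#'   issued for unlocked avatars unless `allow_unlocked`).
#' @param drugs character vector of drug names.
#' @param observed data.frame with columns `cell_line, drug, observed_call`
#'   covering the full grid.
#' @param dose reference dose.
#' @param protocol,weights as in [runThreeState()].
#' @param allow_unlocked suppress the unlocked-avatar warning.
#' @return list of class `ProspectivePanel`: `records` (one row per cell),
#'   `stats`, `per_drug` breakdown.
#' @export
runProspectivePanel <- function(network, avatars, drugs, observed, dose = 1,
                                protocol = simulationProtocol(),
                                weights = defaultIndexWeights(),
                                allow_unlocked = FALSE) {
  unlocked <- vapply(avatars, function(a) !a@locked, logical(1))
  if (any(unlocked) && !allow_unlocked)
    warning("unlocked avatar(s): ",
            paste(vapply(avatars[unlocked], profileId, character(1)),
                  collapse = ", "),
            " (the workflow locks avatars by alignment first)")
  drug_objs <- lapply(drugs, getDrug)
  control <- untriggeredBaseline(network,
                                 max_time = protocol$control_duration)$state
  obs_key <- paste(observed$cell_line, observed$drug)
  rows <- list()
  for (av in avatars) {
    r1 <- runThreeState(network, av, drug_objs[[1]], dose, protocol, weights,
                        control_state = control)
    ds <- r1$disease_state
    for (j in seq_along(drugs)) {
      r <- if (j == 1) r1 else
        runThreeState(network, av, drug_objs[[j]], dose, protocol, weights,
                      disease_state = ds)
      key <- paste(av@id, drugs[j])
      hit <- match(key, obs_key)
      if (is.na(hit))
        stop("observed table has no entry for (", av@id, ", ", drugs[j], ")")
      rows[[key]] <- data.frame(
        cell_line = av@id, drug = drugs[j], percent_change = r$change,
        predicted_call = r$call,
        observed_call = observed$observed_call[hit],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  per_drug <- do.call(rbind, lapply(split(records, records$drug), function(d) {
    s <- agreementStats(d)
    data.frame(drug = d$drug[1], n_total = s$n_total, n_match = s$n_match,
               percent_agreement = s$percent_agreement,
               stringsAsFactors = FALSE)
  }))
  rownames(per_drug) <- NULL
  list(records = records, stats = agreementStats(records),
       per_drug = per_drug)
}
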