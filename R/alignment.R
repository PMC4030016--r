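# Avatar calibration ("alignment") against observed responses to the
# alignment drugs -- erlotinib probes EGFR-pathway dominance, sorafenib
# MEK/ERK activation, dasatinib SRC signaling. Only the magnitudes of the
# profile's existing perturbations move (never the set of perturbed genes);
# the fitted profile is locked.

.ALIGNMENT_BLOCK <- c(erlotinib = "rtk (EGFR)", sorafenib = "ras_mapk (MEK/ERK)",
                      dasatinib = "src (SRC)")

#' Read an alignment observation table
#'
#' Tab-separated columns: `cell_line, drug, observed_call,
#' observed_pct_change` (the percent change may be empty).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readAlignmentTSV <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "observed_call")
  if (!all(need %in% names(tab)))
    stop("alignment TSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(tab$observed_pct_change))
    tab$observed_pct_change <- NA_real_
  bad <- setdiff(tab$observed_call, .CALLS)
  if (length(bad)) stop("observed_call must be sensitive/resistant")
  tab
}

#' Align an avatar's perturbation magnitudes to observed drug responses
#'
#' Deterministic coordinate descent: for each perturbation (fixed order by
#' gene symbol) a per-perturbation magnitude multiplier is scanned over a
#' 9-point log grid spanning [1/10, 10]; up to `max_sweeps` sweeps. The
#' objective is lexicographic -- first maximize the number of matched
#' sensitive/resistant calls on the alignment drugs, then minimize the
#' squared error against any observed percent changes, then stay closest to
#' the unadjusted magnitudes. Mismatches that persist at the optimum are
#' reported (with the pathway block each drug probes), never hidden. The
#' returned profile has the fitted magnitudes and is locked.
#'
#' @param network the reference [NetworkModel-class].
#' @param profile an unlocked [CellLineProfile-class].
#' @param observations data.frame as from [readAlignmentTSV()]; rows for
#'   other cell lines are ignored.
#' @param drugs drug library subset to align against (default: the three
#'   alignment drugs present in the observations).
#' @param dose reference dose for all alignment runs.
#' @param protocol,weights as in [runThreeState()].
#' @param grid_points,max_sweeps search resolution.
#' @return list of class `AlignmentResult`: `profile` (locked), `matched`
#'   (named logical per drug), `n_mismatch`, `mismatches` (data.frame with
#'   the probed pathway block), `multipliers`, `trace`.
#' @export
alignAvatar <- function(network, profile, observations,
                        drugs = NULL, dose = 1,
                        protocol = simulationProtocol(),
                        weights = defaultIndexWeights(),
                        grid_points = 9, max_sweeps = 3) {
  if (profile@locked) stop("profile '", profile@id, "' is locked")
  obs <- observations[observations$cell_line == profile@id, , drop = FALSE]
  if (!nrow(obs)) stop("no alignment observations for '", profile@id, "'")
  if (anyDuplicated(obs$drug)) {
    dup <- obs$drug[duplicated(obs$drug)]
    contradictory <- vapply(dup, function(d) {
      length(unique(obs$observed_call[obs$drug == d])) > 1
    }, logical(1))
    if (any(contradictory))
      stop("contradictory duplicate observations for drug(s): ",
           paste(dup[contradictory], collapse = ", "))
    obs <- obs[!duplicated(obs$drug), , drop = FALSE]
  }
  lib <- drugLibrary()
  drug_objs <- lapply(obs$drug, getDrug, library = lib)
  names(drug_objs) <- obs$drug
  control <- untriggeredBaseline(network,
                                 max_time = protocol$control_duration)$state
  p <- profile@perturbations
  coord_order <- order(p$gene, p$kind)
  tunable <- coord_order[p$kind[coord_order] != "deletion"]
  grid <- 10^seq(-1, 1, length.out = grid_points)
  mult <- rep(1, nrow(p))
  evals <- 0L

  objective <- function(m) {
    q <- p
    nd <- q$kind != "deletion"
    q$magnitude[nd] <- q$magnitude[nd] * m[nd]
    prof <- cellLineProfile(profile@id, q)
    sim_calls <- character(nrow(obs)); sim_pc <- numeric(nrow(obs))
    r1 <- runThreeState(network, prof, drug_objs[[1]], dose, protocol,
                        weights, control_state = control)
    sim_calls[1] <- r1$call; sim_pc[1] <- r1$change
    if (nrow(obs) > 1) for (i in 2:nrow(obs)) {
      ri <- runThreeState(network, prof, drug_objs[[i]], dose, protocol,
                          weights, disease_state = r1$disease_state)
      sim_calls[i] <- ri$call; sim_pc[i] <- ri$change
    }
    evals <<- evals + 1L
    have_pc <- !is.na(obs$observed_pct_change)
    sse <- if (any(have_pc))
      sum((sim_pc[have_pc] - obs$observed_pct_change[have_pc])^2) else 0
    list(n_match = sum(sim_calls == obs$observed_call), sse = sse,
         calls = sim_calls, pc = sim_pc)
  }

  better <- function(a, dist_a, b, dist_b) {
    if (a$n_match != b$n_match) return(a$n_match > b$n_match)
    if (abs(a$sse - b$sse) > 1e-9) return(a$sse < b$sse)
    dist_a < dist_b - 1e-12
  }
  dist <- function(m) sum(abs(log10(m)))
  cur <- objective(mult)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (ci in tunable) {
      best_m <- mult[ci]; best <- cur
      for (g in grid) {
        if (abs(g - mult[ci]) < 1e-12) next
        cand <- mult; cand[ci] <- g
        res <- objective(cand)
        if (better(res, dist(cand), best,
                   dist(`[<-`(mult, ci, best_m)))) {
          best <- res; best_m <- g
        }
      }
      if (abs(best_m - mult[ci]) > 1e-12) {
        mult[ci] <- best_m; cur <- best; changed <- TRUE
      }
    }
    if (!changed) break
  }
  q <- p
  nd <- q$kind != "deletion"
  q$magnitude[nd] <- q$magnitude[nd] * mult[nd]
  fitted <- cellLineProfile(profile@id, q, provenance = profile@provenance,
                            locked = TRUE)
  matched <- setNames(cur$calls == obs$observed_call, obs$drug)
  mism <- data.frame(cell_line = rep(profile@id, sum(!matched)),
                     drug = obs$drug[!matched],
                     observed = obs$observed_call[!matched],
                     predicted = cur$calls[!matched],
                     probes_block = unname(
                       .ALIGNMENT_BLOCK[obs$drug[!matched]]),
                     stringsAsFactors = FALSE)
  structure(list(profile = fitted, matched = matched,
                 n_mismatch = sum(!matched), mismatches = mism,
                 multipliers = setNames(mult, paste(p$gene, p$kind)),
                 trace = list(evaluations = evals, sweeps = sweep,
                              final_calls = setNames(cur$calls, obs$drug),
                              final_pct_change = setNames(cur$pc, obs$drug))),
            class = "AlignmentResult")
}
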