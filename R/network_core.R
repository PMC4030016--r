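# Deterministic ODE integration of a NetworkModel with steady-state
# detection. Amount units are dimensionless a.u.; time is the simulated
# second. Integration uses the stiff-capable lsoda solver (deSolve) with a
# compiled right-hand side.

.LAW_CODE <- c(mass_action = 1L, michaelis_menten = 2L, hill = 3L)

# Flatten a model into the vectors the compiled RHS consumes.
.compileModel <- function(model) {
  sp <- model@species
  idx <- setNames(seq_len(nrow(sp)) - 1L, sp$id)  # 0-based
  rx <- model@reactions
  m <- length(rx)
  law <- integer(m); k <- Km <- hn <- scale <- numeric(m)
  ra_ptr <- pr_ptr <- mo_ptr <- integer(m + 1L)
  ra_idx <- pr_idx <- mo_idx <- mo_role <- integer(0)
  ra_st <- pr_st <- mo_str <- numeric(0)
  for (i in seq_len(m)) {
    r <- rx[[i]]
    law[i] <- .LAW_CODE[[r$law$form]]
    p <- r$law$parameters
    k[i] <- p$k
    Km[i] <- if (is.null(p$Km)) 1 else p$Km
    hn[i] <- if (is.null(p$hill_n)) 1 else p$hill_n
    scale[i] <- r$rate_scale
    ra_ptr[i + 1L] <- ra_ptr[i] + nrow(r$reactants)
    pr_ptr[i + 1L] <- pr_ptr[i] + nrow(r$products)
    mo_ptr[i + 1L] <- mo_ptr[i] + nrow(r$modifiers)
    ra_idx <- c(ra_idx, unname(idx[r$reactants$species]))
    ra_st <- c(ra_st, r$reactants$stoich)
    pr_idx <- c(pr_idx, unname(idx[r$products$species]))
    pr_st <- c(pr_st, r$products$stoich)
    mo_idx <- c(mo_idx, unname(idx[r$modifiers$species]))
    mo_role <- c(mo_role, ifelse(r$modifiers$role == "activator", 1L, -1L))
    mo_str <- c(mo_str, r$modifiers$strength)
  }
  list(ids = sp$id, law = law, k = k, Km = Km, hn = hn, scale = scale,
       ra_ptr = ra_ptr, ra_idx = as.integer(ra_idx), ra_st = ra_st,
       pr_ptr = pr_ptr, pr_idx = as.integer(pr_idx), pr_st = pr_st,
       mo_ptr = mo_ptr, mo_idx = as.integer(mo_idx),
       mo_role = as.integer(mo_role), mo_str = mo_str,
       syn = sp$synthesis_rate, deg = sp$degradation_rate)
}

.rhs <- function(cm, y) {
  .network_rhs_cpp(y, cm$law, cm$k, cm$Km, cm$hn, cm$scale,
                   cm$ra_ptr, cm$ra_idx, cm$ra_st,
                   cm$pr_ptr, cm$pr_idx, cm$pr_st,
                   cm$mo_ptr, cm$mo_idx, cm$mo_role, cm$mo_str,
                   cm$syn, cm$deg)
}

.stateVector <- function(model, state) {
  ids <- model@species$id
  if (is.null(state)) return(setNames(model@species$initial_amount, ids))
  missing <- setdiff(ids, names(state))
  if (length(missing))
    stop("state does not cover all species: ", paste(missing, collapse = ", "))
  s <- state[ids]
  if (any(!is.finite(s))) stop("non-finite state amounts for: ",
                               paste(ids[!is.finite(s)], collapse = ", "))
  s
}

#' Integrate a network model over time
#'
#' Deterministic integration with lsoda. The returned trajectory holds the
#' sampled times (seconds, starting at `start`) and a matrix of species
#' amounts; amounts are guaranteed non-negative (undershoots within
#' `[-atol, 0)` are clipped to zero with a warning, anything below `-atol`
#' aborts).
#'
#' @param model a [NetworkModel-class].
#' @param state named vector of starting amounts covering all species, or
#'   NULL for the species table's `initial_amount`.
#' @param duration simulated seconds (> 0).
#' @param start time of the first sample (for bookkeeping across protocol
#'   phases).
#' @param n_out number of output samples (>= 2; endpoint always included).
#' @param rtol,atol relative/absolute integrator tolerances.
#' @return list of class `Trajectory` with elements `times` (length `n_out`)
#'   and `amounts` (`n_out` x species matrix).
#' @export
integrateNetwork <- function(model, state = NULL, duration, start = 0,
                             n_out = 101, rtol = 1e-6, atol = 1e-9) {
  stopifnot(is(model, "NetworkModel"), duration > 0, n_out >= 2)
  y0 <- .stateVector(model, state)
  cm <- .compileModel(model)
  times <- seq(0, duration, length.out = n_out)
  func <- function(t, y, parms) list(.rhs(cm, y))
  out <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 100000)
  istate <- attr(out, "istate")
  if (nrow(out) < length(times) || (!is.null(istate) && istate[1] < 0)) {
    last <- out[nrow(out), -1]
    resid <- abs(.rhs(cm, last))
    stop("integrator failure (step-size collapse); largest residual at species '",
         cm$ids[which.max(resid)], "'")
  }
  amounts <- unname(out[, -1, drop = FALSE])
  colnames(amounts) <- cm$ids
  low <- amounts < 0
  if (any(low)) {
    if (min(amounts) < -atol)
      stop("negative amounts below -atol for species: ",
           paste(unique(colnames(amounts)[which(low, arr.ind = TRUE)[, 2]]),
                 collapse = ", "))
    warning("clipping small negative undershoot (within -atol) to 0")
    amounts[low] <- 0
  }
  structure(list(times = times + start, amounts = amounts),
            class = "Trajectory")
}

#' Find a steady state of a network model
#'
#' Integrates up to `max_time`, checking the relative rate residual
#' `max_s |ds/dt| / max(|s|, 1e-6)` at every `check_every` simulated seconds;
#' the first checkpoint under `tol` is reported. Never raises on
#' non-convergence: the caller inspects `converged`.
#'
#' @param model a [NetworkModel-class].
#' @param state starting amounts (NULL for initial amounts).
#' @param max_time horizon in seconds.
#' @param tol relative rate tolerance (> 0).
#' @param check_every residual check interval in seconds.
#' @return list of class `SteadyStateResult`: `state` (named amounts),
#'   `residual`, `converged`, `reached_at`.
#' @export
findSteadyState <- function(model, state = NULL, max_time = 50000,
                            tol = 1e-6, check_every = 1000) {
  stopifnot(tol > 0, max_time > 0)
  y0 <- .stateVector(model, state)
  cm <- .compileModel(model)
  resid0 <- .residual(cm, y0)
  if (resid0 < tol)
    return(structure(list(state = y0, residual = resid0, converged = TRUE,
                          reached_at = 0), class = "SteadyStateResult"))
  n_out <- max(101, ceiling(max_time / check_every) + 1)
  traj <- integrateNetwork(model, state = state, duration = max_time,
                           n_out = n_out)
  for (i in seq_along(traj$times)[-1]) {
    y <- setNames(traj$amounts[i, ], colnames(traj$amounts))
    resid <- .residual(cm, y)
    if (resid < tol)
      return(structure(list(state = y, residual = resid, converged = TRUE,
                            reached_at = traj$times[i] - traj$times[1]),
                       class = "SteadyStateResult"))
  }
  y <- setNames(traj$amounts[nrow(traj$amounts), ], colnames(traj$amounts))
  structure(list(state = y, residual = .residual(cm, y), converged = FALSE,
                 reached_at = max_time), class = "SteadyStateResult")
}

.residual <- function(cm, y) {
  dy <- .rhs(cm, y)
  max(abs(dy) / pmax(abs(y), 1e-6))
}

#' Rate residual of a state
#'
#' Convenience wrapper exposing the steady-state residual measure.
#' @inheritParams integrateNetwork
#' @return max relative |ds/dt| over species.
#' @export
networkResidual <- function(model, state = NULL) {
  .residual(.compileModel(model), .stateVector(model, state))
}

#' Scale reaction nodes of a model
#'
#' Returns a new model with `rate_scale` of the named reactions multiplied by
#' the given factors (value semantics: the input model is unmodified).
#' Repeated edits on one reaction compose multiplicatively.
#'
#' @param model a [NetworkModel-class].
#' @param edits named numeric vector (names = reaction ids, values = factors
#'   >= 0) or data.frame with columns `reaction`, `factor`.
#' @return the edited model.
#' @export
scaleReactionNodes <- function(model, edits) {
  if (is.data.frame(edits)) edits <- setNames(edits$factor, edits$reaction)
  if (!length(edits)) return(model)
  if (any(!is.finite(edits)) || any(edits < 0))
    stop("scale factors must be finite and >= 0")
  unknown <- setdiff(names(edits), names(model@reactions))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  for (i in seq_along(edits)) {
    id <- names(edits)[i]
    model@reactions[[id]]$rate_scale <-
      model@reactions[[id]]$rate_scale * edits[[i]]
  }
  model
}

# ---- JSON round-trip --------------------------------------------------------

#' Read / write the network JSON format
#'
#' The on-disk schema is a top-level object `{species: [...], reactions:
#' [...], metadata: {...}}` where species carry `id/name/kind/
#' initial_amount/synthesis_rate/degradation_rate` and reactions carry
#' `id/reactants/products/modifiers/law/rate_scale`. Writing then reading
#' reproduces the model exactly (lossless round trip).
#'
#' @param path file path.
#' @return `readNetworkJSON` returns a [NetworkModel-class];
#'   `writeNetworkJSON` invisibly returns `path`.
#' @export
readNetworkJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- do.call(rbind, lapply(j$species, function(s)
    data.frame(id = s$id, name = s$name, kind = s$kind,
               initial_amount = s$initial_amount,
               synthesis_rate = s$synthesis_rate,
               degradation_rate = s$degradation_rate,
               stringsAsFactors = FALSE)))
  rx <- lapply(j$reactions, function(r) {
    side <- function(x) {
      if (!length(x)) return(NULL)
      setNames(vapply(x, function(e) e$stoich, numeric(1)),
               vapply(x, function(e) e$species, character(1)))
    }
    mods <- if (length(r$modifiers)) data.frame(
      species = vapply(r$modifiers, `[[`, character(1), "species"),
      role = vapply(r$modifiers, `[[`, character(1), "role"),
      strength = vapply(r$modifiers, `[[`, numeric(1), "strength"),
      stringsAsFactors = FALSE) else NULL
    networkReaction(r$id, reactants = side(r$reactants),
                    products = side(r$products), modifiers = mods,
                    law = r$law$form, k = r$law$parameters$k,
                    Km = r$law$parameters$Km,
                    hill_n = r$law$parameters$hill_n,
                    rate_scale = r$rate_scale)
  })
  networkModel(sp, rx, metadata = if (is.null(j$metadata)) list() else j$metadata)
}

#' @rdname readNetworkJSON
#' @param model a [NetworkModel-class].
#' @export
writeNetworkJSON <- function(model, path) {
  sp <- model@species
  species <- lapply(seq_len(nrow(sp)), function(i) as.list(sp[i, ]))
  reactions <- lapply(model@reactions, function(r) {
    side <- function(tab) lapply(seq_len(nrow(tab)), function(i)
      list(species = tab$species[i], stoich = tab$stoich[i]))
    list(id = r$id, reactants = side(r$reactants),
         products = side(r$products),
         modifiers = lapply(seq_len(nrow(r$modifiers)), function(i)
           list(species = r$modifiers$species[i],
                role = r$modifiers$role[i],
                strength = r$modifiers$strength[i])),
         law = r$law, rate_scale = r$rate_scale)
  })
  jsonlite::write_json(list(species = species,
                            reactions = unname(reactions),
                            metadata = model@metadata),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# ---- SBML export ------------------------------------------------------------

.mmlCn <- function(x) sprintf("<cn>%.17g</cn>", x)
.mmlCi <- function(x) sprintf("<ci>%s</ci>", x)
.mmlApply <- function(op, ...) paste0("<apply><", op, "/>",
                                      paste0(..., collapse = ""), "</apply>")

.reactionMathML <- function(r) {
  p <- r$law$parameters
  terms <- c(.mmlCn(p$k * r$rate_scale))
  ra <- r$reactants
  if (r$law$form == "mass_action") {
    for (i in seq_len(nrow(ra))) {
      t <- .mmlCi(ra$species[i])
      if (ra$stoich[i] != 1)
        t <- .mmlApply("power", t, .mmlCn(ra$stoich[i]))
      terms <- c(terms, t)
    }
  } else if (nrow(ra)) {
    s <- .mmlCi(ra$species[1])
    hn <- if (is.null(p$hill_n)) 1 else p$hill_n
    num <- if (r$law$form == "hill") .mmlApply("power", s, .mmlCn(hn)) else s
    den_s <- if (r$law$form == "hill")
      .mmlApply("plus", .mmlApply("power", .mmlCn(p$Km), .mmlCn(hn)),
                .mmlApply("power", s, .mmlCn(hn)))
    else .mmlApply("plus", .mmlCn(p$Km), s)
    terms <- c(terms, .mmlApply("divide", num, den_s))
    if (nrow(ra) > 1)
      for (i in 2:nrow(ra)) terms <- c(terms, .mmlCi(ra$species[i]))
  }
  mo <- r$modifiers
  hn <- if (is.null(p$hill_n)) 1 else p$hill_n
  KmV <- if (is.null(p$Km)) 1 else p$Km
  for (i in seq_len(nrow(mo))) {
    a <- .mmlCi(mo$species[i])
    an <- .mmlApply("power", a, .mmlCn(hn))
    if (mo$role[i] == "activator") {
      terms <- c(terms, .mmlApply("divide",
                                  .mmlApply("times", .mmlCn(mo$strength[i]), an),
                                  .mmlApply("plus",
                                            .mmlApply("power", .mmlCn(KmV),
                                                      .mmlCn(hn)), an)))
    } else {
      t <- .mmlApply("power",
                     .mmlApply("times", .mmlCn(mo$strength[i] / KmV), a),
                     .mmlCn(hn))
      terms <- c(terms, .mmlApply("divide", .mmlCn(1),
                                  .mmlApply("plus", .mmlCn(1), t)))
    }
  }
  if (length(terms) == 1) terms else .mmlApply("times", terms)
}

#' Export a model as SBML Level 3
#'
#' Writes species, reactions and kinetic laws (as MathML) in SBML Level 3
#' Version 2 core. Export only; synthesis/degradation species fields are
#' emitted as per-species rate annotations on dedicated reactions.
#'
#' @param model a [NetworkModel-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
exportSBML <- function(model, path) {
  sp <- model@species
  spNodes <- paste0(sprintf(
    '      <species id="%s" name="%s" compartment="cell" initialAmount="%.17g" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
    sp$id, sp$name, sp$initial_amount), collapse = "\n")
  synRx <- character(0)
  for (i in seq_len(nrow(sp))) {
    if (sp$synthesis_rate[i] > 0)
      synRx <- c(synRx, .sbmlReaction(
        id = paste0("synfield_", sp$id[i]), reactants = NULL,
        products = data.frame(species = sp$id[i], stoich = 1),
        math = .mmlCn(sp$synthesis_rate[i])))
    if (sp$degradation_rate[i] > 0)
      synRx <- c(synRx, .sbmlReaction(
        id = paste0("degfield_", sp$id[i]),
        reactants = data.frame(species = sp$id[i], stoich = 1),
        products = NULL,
        math = .mmlApply("times", .mmlCn(sp$degradation_rate[i]),
                         .mmlCi(sp$id[i]))))
  }
  rxNodes <- vapply(model@reactions, function(r)
    .sbmlReaction(r$id, r$reactants, r$products, .reactionMathML(r),
                  modifiers = r$modifiers$species), character(1))
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '  <model id="virtumor_network">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="cell" spatialDimensions="3" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', spNodes, '\n    </listOfSpecies>\n',
    '    <listOfReactions>\n',
    paste(c(unname(rxNodes), synRx), collapse = "\n"),
    '\n    </listOfReactions>\n',
    '  </model>\n</sbml>\n')
  xml2::write_xml(xml2::read_xml(doc), path)
  invisible(path)
}

.sbmlReaction <- function(id, reactants, products, math,
                          modifiers = character(0)) {
  refs <- function(tab, tag) {
    if (is.null(tab) || !nrow(tab)) return("")
    paste0("        <listOf", tag, "s>\n",
           paste0(sprintf(
             '          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
             tab$species, tab$stoich), collapse = "\n"),
           "\n        </listOf", tag, "s>\n")
  }
  mods <- if (length(modifiers))
    paste0("        <listOfModifiers>\n",
           paste0(sprintf('          <modifierSpeciesReference species="%s"/>',
                          modifiers), collapse = "\n"),
           "\n        </listOfModifiers>\n") else ""
  paste0('      <reaction id="', id, '" reversible="false">\n',
         refs(reactants, "Reactant"), refs(products, "Product"), mods,
         '        <kineticLaw>\n',
         '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
         math, '</math>\n',
         '        </kineticLaw>\n      </reaction>')
}
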