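# Tiny fixture networks built in code (no files).

# One species with zero-order synthesis and first-order decay:
# closed form s(t) = (syn/deg) * (1 - exp(-deg * t)) from s(0) = 0.
linearModel <- function(syn = 2, deg = 0.1, init = 0) {
  networkModel(data.frame(id = "S", kind = "protein", initial_amount = init,
                          synthesis_rate = syn, degradation_rate = deg))
}

# Pure irreversible binding A + B -> C; stoichiometric totals A+C and B+C
# are conserved exactly along trajectories.
bindingModel <- function(k = 0.01, a0 = 5, b0 = 3) {
  networkModel(
    data.frame(id = c("A", "B", "C"), kind = "protein",
               initial_amount = c(a0, b0, 0), synthesis_rate = 0,
               degradation_rate = 0),
    list(networkReaction("bind", reactants = c(A = 1, B = 1),
                         products = c(C = 1), k = k)))
}

# Acyclic activation cascade R -> X -> Y: the receptor activation reaction
# act_R is the drug target; Y_act is the downstream readout.
cascadeModel <- function() {
  sp <- data.frame(
    id = c("R", "R_act", "X", "X_act", "Y", "Y_act"),
    kind = c("protein", "active_form", "protein", "active_form",
             "protein", "active_form"),
    initial_amount = c(10, 0.1, 10, 0.1, 10, 0.1),
    synthesis_rate = c(0.1, 0, 0.1, 0, 0.1, 0),
    degradation_rate = c(0.01, 0.002, 0.01, 0.002, 0.01, 0.002))
  act <- function(id, from, to, k, mod = NULL) {
    networkReaction(id, reactants = setNames(1, from),
                    products = setNames(1, to), modifiers = mod, k = k)
  }
  mods <- function(sp) data.frame(species = sp, role = "activator",
                                  strength = 2)
  networkModel(sp, list(
    act("act_R", "R", "R_act", 0.01),
    act("deact_R", "R_act", "R", 0.25),
    act("act_X", "X", "X_act", 0.05, mods("R_act")),
    act("deact_X", "X_act", "X", 0.25),
    act("act_Y", "Y", "Y_act", 0.05, mods("X_act")),
    act("deact_Y", "Y_act", "Y", 0.25)),
    metadata = list(act_map = list(R = "act_R")))
}

cascadeDrug <- function(emax = 1) {
  drugDefinition("R-inhibitor",
                 data.frame(node = "act_R", action = "inhibit", potency = 1,
                            emax = emax, hill_n = 1))
}

# Shared reference network + control state (built once per test run).
refNet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildReferenceNetwork()
    cache
  }
})

refControl <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- untriggeredBaseline(refNet())$state
    cache
  }
})
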