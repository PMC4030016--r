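# The reduced reference cancer network: named pathway blocks wired together.
#
# Topology and kinetics are a documented desk-scale reconstruction (the
# full-scale commercial network this emulates is proprietary). Conventions:
# every mapped signaling gene G is a synthesized/degraded pool species `G`
# plus an active form `G_act` produced by one or more activation reactions
# (`act_G[_input]`) and recycled by a first-order deactivation. Activation
# reactions carry the upstream couplings as activator/inhibitor modifiers;
# drugs and genetic perturbations act multiplicatively on the `rate_scale`
# of synthesis ("syn_*") or activation ("act_*") reactions through the
# registries stored in the model metadata.
#
# Two response-curve regimes are used deliberately:
#  * trunk couplings (RTK -> RAS/PI3K -> effectors) run with a half-effect
#    constant far above the operating level (Km = 20 a.u. vs active forms of
#    ~0.2-1), i.e. near-linear: a fractional flux cut at a drug's target
#    propagates undamped, so the share a pathway holds of an index's drive
#    decides how consequential its inhibition is;
#  * the BRAF -> MEK step is saturable (Km = 1.0, Hill 2): a constitutively
#    active (5x) BRAF sits on the flat shoulder, decoupling MEK output from
#    upstream RTK input (lapatinib resistance of BRAF mutants) while a MEK
#    inhibitor still cuts the step proportionally.
# CDKN2A/CDKN2B act INK4-style, blocking CDK4-cyclin D1 association: their
# loss multiplies the CDK4-CCND1 complex and with it the share of the
# proliferation index that CCND1-directed drugs can reach. CDK subunit
# pools are degradation-dominated so complex abundance tracks cyclin
# abundance linearly (no free-kinase competition artifacts).

.BLOCK_NAMES <- c("rtk", "adherens", "src", "ras_mapk", "pi3k_akt_mtor",
                  "jak_stat", "nfkb_proteasome", "cell_cycle", "p53",
                  "apoptosis", "cox2", "mevalonate")

# Index biomarkers each block contributes (by gene symbol; used to guard
# against configs that would make the phenotype indices uncomputable).
.BLOCK_BIOMARKERS <- list(
  cell_cycle = c("CDK4-CCND1", "CDK2-CCNE", "CDK2-CCNA", "CDK1-CCNB1"),
  pi3k_akt_mtor = c("AKT1"),
  apoptosis = c("BAX", "CASP3", "NOXA", "CASP8", "BCL2", "MCL1", "BIRC5",
                "BIRC2", "XIAP"))

#' Network build configuration
#'
#' @param enabled_blocks block names to assemble (default: all).
#' @param overrides named list: reaction id -> list of kinetic parameter
#'   edits (`k`, `Km`, `hill_n`, `rate_scale`).
#' @param version version tag recorded in metadata.
#' @return a `NetworkBuildConfig` list.
#' @export
networkBuildConfig <- function(enabled_blocks = .BLOCK_NAMES,
                               overrides = list(), version = "reduced-1") {
  unknown <- setdiff(enabled_blocks, .BLOCK_NAMES)
  if (length(unknown))
    stop("unknown pathway block(s): ", paste(unknown, collapse = ", "))
  structure(list(enabled_blocks = enabled_blocks, overrides = overrides,
                 version = version), class = "NetworkBuildConfig")
}

# ---- builder helpers --------------------------------------------------------

.newBuilder <- function() {
  b <- new.env(parent = emptyenv())
  b$species <- list(); b$reactions <- list(); b$block_of_sp <- character(0)
  b$block_of_rx <- character(0); b$gene_map <- list()
  b$syn_map <- list(); b$act_map <- list(); b$unmapped <- character(0)
  b
}

.addSp <- function(b, block, id, kind = "protein", init = 0, syn = 0,
                   deg = 0, name = id) {
  b$species[[id]] <- data.frame(id = id, name = name, kind = kind,
                                initial_amount = init, synthesis_rate = syn,
                                degradation_rate = deg,
                                stringsAsFactors = FALSE)
  b$block_of_sp[id] <- block
  invisible(id)
}

.mods <- function(species, role = "activator", strength = 1) {
  data.frame(species = species, role = role, strength = strength,
             stringsAsFactors = FALSE)
}

.addRx <- function(b, block, id, reactants = NULL, products = NULL,
                   modifiers = NULL, law = "mass_action", k = 1, Km = 1,
                   hill_n = 1) {
  b$reactions[[id]] <- networkReaction(id, reactants, products, modifiers,
                                       law, k, Km, hill_n)
  b$block_of_rx[id] <- block
  invisible(id)
}

.register <- function(b, species, syn = character(0), act = character(0)) {
  b$syn_map[[species]] <- c(b$syn_map[[species]], syn)
  b$act_map[[species]] <- c(b$act_map[[species]], act)
}

# Pool + active-form pattern for a signaling protein.
.addProtein <- function(b, block, id, pool_syn = 0.1, pool_deg = 0.01,
                        act_k = NULL, act_modifiers = NULL, deact = 0.25,
                        act_deg = 0.002, Km = 1, hill_n = 1,
                        pool_init = NULL, act_init = 0.1) {
  if (is.null(pool_init)) pool_init <- pool_syn / max(pool_deg, 1e-6)
  .addSp(b, block, id, "protein", init = pool_init, deg = pool_deg)
  syn_id <- paste0("syn_", id)
  .addRx(b, block, syn_id, products = setNames(1, id), k = pool_syn)
  .register(b, id, syn = syn_id)
  if (!is.null(act_k)) {
    act_sp <- paste0(id, "_act")
    .addSp(b, block, act_sp, "active_form", init = act_init, deg = act_deg)
    act_id <- paste0("act_", id)
    .addRx(b, block, act_id, reactants = setNames(1, id),
           products = setNames(1, act_sp), modifiers = act_modifiers,
           k = act_k, Km = Km, hill_n = hill_n)
    .addRx(b, block, paste0("deact_", id), reactants = setNames(1, act_sp),
           products = setNames(1, id), k = deact)
    .register(b, id, act = act_id)
  }
  invisible(id)
}

# Extra activation route for an already-declared protein.
.addActivation <- function(b, block, id, tag, k, modifiers, Km = 1,
                           hill_n = 1) {
  act_id <- paste0("act_", id, "_", tag)
  .addRx(b, block, act_id, reactants = setNames(1, id),
         products = setNames(1, paste0(id, "_act")), modifiers = modifiers,
         k = k, Km = Km, hill_n = hill_n)
  .register(b, id, act = act_id)
  invisible(act_id)
}

# Synthesized effector protein (no active form; level is the signal).
.addEffector <- function(b, block, id, deg = 0.02, init = 1) {
  .addSp(b, block, id, "protein", init = init, deg = deg)
}

.addSynRoute <- function(b, block, id, tag, k, modifiers = NULL, Km = 1,
                         hill_n = 1) {
  syn_id <- if (is.null(tag)) paste0("syn_", id) else
    paste0("syn_", id, "_", tag)
  .addRx(b, block, syn_id, products = setNames(1, id),
         modifiers = modifiers, k = k, Km = Km, hill_n = hill_n)
  .register(b, id, syn = syn_id)
  invisible(syn_id)
}

# Linear-regime half-effect constant for trunk couplings (a.u.).
.KLIN <- 20

# ---- the reference build ----------------------------------------------------

#' Build the reduced reference cancer network
#'
#' Assembles the control (non-transformed epithelial) signaling network from
#' named pathway blocks: receptor tyrosine kinases (EGFR, ERBB2, MET, PDGFR,
#' VEGFR, KIT, IGF1R), ABL/SRC, RAS-BRAF-MEK-ERK, PI3K-AKT-mTOR,
#' IL6-JAK-STAT, the cyclin/CDK cell-cycle machinery with CDKN2A/CDKN2B and
#' RB1-E2F, p53-NOXA-BAX, the apoptosis/survival proteins, NF-kB with
#' proteasome-mediated IkB turnover, COX2-PGE2, the mevalonate/HMGCR to
#' RAS-prenylation axis, and CDH1 adherens restraint of ERBB2 signaling.
#' Assembly is deterministic: the same config always yields an identical
#' model. The model metadata carries the gene map, the synthesis/activity
#' reaction registries, the pathway block catalogue and the list of declared
#' unmapped genes (RUNX3).
#'
#' @param config a [networkBuildConfig()].
#' @return a [NetworkModel-class]; the block catalogue is available through
#'   [pathwayBlocks()].
#' @export
buildReferenceNetwork <- function(config = networkBuildConfig()) {
  stopifnot(inherits(config, "NetworkBuildConfig"))
  disabled <- setdiff(.BLOCK_NAMES, config$enabled_blocks)
  missing_bm <- unlist(.BLOCK_BIOMARKERS[disabled], use.names = FALSE)
  if (length(missing_bm))
    stop("config omits blocks carrying index biomarkers: ",
         paste(missing_bm, collapse = ", "))
  b <- .newBuilder()

  ## -- rtk: receptor tyrosine kinases (basal ligand drive folded into act_k)
  .addProtein(b, "rtk", "EGFR", act_k = 0.012)
  .addProtein(b, "rtk", "ERBB2", act_k = 0.008,
              act_modifiers = .mods("CDH1_act", "inhibitor", 12.0))
  .addProtein(b, "rtk", "MET", act_k = 0.008)
  .addProtein(b, "rtk", "PDGFR", act_k = 0.006)
  .addProtein(b, "rtk", "VEGFR", act_k = 0.006)
  .addProtein(b, "rtk", "KIT", act_k = 0.006)
  .addProtein(b, "rtk", "IGF1R", act_k = 0.006)
  # MET cross-activates ERBB2 (receptor heterodimerization), also gated by
  # CDH1 sequestration -- the lever behind the MET/lapatinib association.
  # inhibitor strength rides on the reaction Km, so the CDH1 restraint is
  # strength 12 in Km = 1 units -> 240 on this Km = 20 reaction
  .addActivation(b, "rtk", "ERBB2", "met", k = 0.15,
                 modifiers = rbind(.mods("MET_act", "activator", 16),
                                   .mods("CDH1_act", "inhibitor", 240)),
                 Km = .KLIN)

  ## -- adherens: CDH1 restrains ERBB2 signaling
  .addProtein(b, "adherens", "CDH1", act_k = 0.010)

  ## -- src: SRC and ABL non-receptor kinases
  .addProtein(b, "src", "SRC", act_k = 0.004)
  .addActivation(b, "src", "SRC", "egfr", k = 0.02,
                 modifiers = .mods("EGFR_act", "activator", 20), Km = .KLIN)
  .addProtein(b, "src", "ABL", act_k = 0.006)

  ## -- mevalonate: HMGCR -> mevalonate-derived prenylation of RAS
  .addSp(b, "mevalonate", "HMGCR", "protein", init = 10, syn = 0.1,
         deg = 0.01)
  .addSp(b, "mevalonate", "MEV", "metabolite", init = 1.5, deg = 0)
  .addRx(b, "mevalonate", "syn_MEV", products = c(MEV = 1),
         modifiers = .mods("HMGCR", "activator", 1), k = 0.25)
  .addRx(b, "mevalonate", "deg_MEV", reactants = c(MEV = 1), k = 0.15)
  .register(b, "HMGCR", act = "syn_MEV")

  ## -- ras_mapk: RAS with additive prenylation-gated inputs
  .addProtein(b, "ras_mapk", "RAS", act_k = NULL)
  .addSp(b, "ras_mapk", "RAS_act", "active_form", init = 0.3, deg = 0.002)
  .addRx(b, "ras_mapk", "deact_RAS", reactants = c(RAS_act = 1),
         products = c(RAS = 1), k = 0.25)
  ras_in <- list(egfr = c("EGFR_act", 0.016), erbb2 = c("ERBB2_act", 0.003),
                 met = c("MET_act", 0.001), pdgfr = c("PDGFR_act", 0.004),
                 vegfr = c("VEGFR_act", 0.0025), kit = c("KIT_act", 0.004),
                 igf1r = c("IGF1R_act", 0.0025), src = c("SRC_act", 0.007),
                 abl = c("ABL_act", 0.0045))
  for (tag in names(ras_in)) {
    act_id <- paste0("act_RAS_", tag)
    .addRx(b, "ras_mapk", act_id, reactants = c(RAS = 1),
           products = c(RAS_act = 1),
           modifiers = rbind(.mods(ras_in[[tag]][1], "activator", 20),
                             .mods("MEV", "activator", 8)),
           k = as.numeric(ras_in[[tag]][2]), Km = .KLIN)
    .register(b, "RAS", act = act_id)
  }
  .addProtein(b, "ras_mapk", "BRAF", act_k = 0.04,
              act_modifiers = .mods("RAS_act", "activator", 12),
              Km = .KLIN)
  # saturable step: constitutive BRAF decouples MEK from upstream input
  .addProtein(b, "ras_mapk", "MEK", act_k = 0.055,
              act_modifiers = .mods("BRAF_act", "activator", 2.0),
              Km = 1.0, hill_n = 2)
  .addProtein(b, "ras_mapk", "ERK", act_k = 0.030,
              act_modifiers = .mods("MEK_act", "activator", 20),
              Km = .KLIN)

  ## -- pi3k_akt_mtor
  .addProtein(b, "pi3k_akt_mtor", "PI3K", act_k = NULL)
  .addSp(b, "pi3k_akt_mtor", "PI3K_act", "active_form", init = 0.3,
         deg = 0.002)
  .addRx(b, "pi3k_akt_mtor", "deact_PI3K", reactants = c(PI3K_act = 1),
         products = c(PI3K = 1), k = 0.25)
  pi3k_in <- list(egfr = c("EGFR_act", 0.0075), erbb2 = c("ERBB2_act", 0.016),
                  met = c("MET_act", 0.002), igf1r = c("IGF1R_act", 0.004),
                  src = c("SRC_act", 0.007), pge2 = c("PGE2", 0.006))
  for (tag in names(pi3k_in)) {
    act_id <- paste0("act_PI3K_", tag)
    .addRx(b, "pi3k_akt_mtor", act_id, reactants = c(PI3K = 1),
           products = c(PI3K_act = 1),
           modifiers = .mods(pi3k_in[[tag]][1], "activator", 20),
           k = as.numeric(pi3k_in[[tag]][2]), Km = .KLIN)
    .register(b, "PI3K", act = act_id)
  }
  .addProtein(b, "pi3k_akt_mtor", "AKT1", act_k = 0.020,
              act_modifiers = .mods("PI3K_act", "activator", 20),
              Km = .KLIN)
  .addProtein(b, "pi3k_akt_mtor", "MTOR", act_k = 0.020,
              act_modifiers = .mods("AKT1_act", "activator", 20),
              Km = .KLIN)

  ## -- jak_stat: IL6-driven STAT3
  .addEffector(b, "jak_stat", "IL6", deg = 0.05, init = 1)
  .addSynRoute(b, "jak_stat", "IL6", NULL, k = 0.05)
  .addProtein(b, "jak_stat", "JAK", act_k = 0.030,
              act_modifiers = .mods("IL6", "activator", 8), Km = .KLIN)
  .addProtein(b, "jak_stat", "STAT3", act_k = 0.040,
              act_modifiers = .mods("JAK_act", "activator", 20), Km = .KLIN)

  ## -- nfkb_proteasome: NF-kB held down by IkB; proteasome degrades IkB.
  # PSM is the proteasome node; its "activity" is the set of
  # proteasome-mediated degradation reactions (the bortezomib handle).
  .addSp(b, "nfkb_proteasome", "PSM", "protein", init = 1, syn = 0.02,
         deg = 0.02)
  .addProtein(b, "nfkb_proteasome", "NFKB", act_k = 0.045,
              act_modifiers = .mods("IKB", "inhibitor", 2.0), hill_n = 2)
  .addSp(b, "nfkb_proteasome", "IKB", "protein", init = 1, deg = 0)
  .addRx(b, "nfkb_proteasome", "syn_IKB", products = c(IKB = 1), k = 0.1)
  .addRx(b, "nfkb_proteasome", "deg_IKB", reactants = c(IKB = 1), k = 0.1)
  .register(b, "IKB", syn = "syn_IKB")
  .register(b, "PSM", act = "deg_IKB")

  ## -- p53 -> NOXA / BAX
  .addSp(b, "p53", "P53", "protein", init = 1, deg = 0)
  .addRx(b, "p53", "syn_P53", products = c(P53 = 1), k = 0.05)
  .addRx(b, "p53", "deg_P53", reactants = c(P53 = 1), k = 0.05)
  .register(b, "P53", syn = "syn_P53")
  .register(b, "PSM", act = "deg_P53")

  ## -- apoptosis: effectors and survival proteins
  .addSp(b, "apoptosis", "NOXA", "protein", init = 0.3, deg = 0)
  .addSynRoute(b, "apoptosis", "NOXA", NULL, k = 0.004)
  .addSynRoute(b, "apoptosis", "NOXA", "p53", k = 0.020,
               modifiers = .mods("P53", "activator", 1))
  .addRx(b, "apoptosis", "deg_NOXA", reactants = c(NOXA = 1), k = 0.05)
  .register(b, "PSM", act = "deg_NOXA")
  .addEffector(b, "apoptosis", "BAX", deg = 0.02, init = 1)
  .addSynRoute(b, "apoptosis", "BAX", NULL, k = 0.010)
  .addSynRoute(b, "apoptosis", "BAX", "p53", k = 0.020,
               modifiers = .mods("P53", "activator", 1))
  .addProtein(b, "apoptosis", "CASP8", pool_syn = 0.05, act_k = 0.008)
  .addProtein(b, "apoptosis", "CASP3", pool_syn = 0.05, act_k = 0.030,
              act_modifiers = rbind(.mods("BAX", "activator", 1),
                                    .mods("CASP8_act", "activator", 2.0),
                                    .mods("XIAP", "inhibitor", 0.5),
                                    .mods("BCL2", "inhibitor", 0.3)))
  surv <- list(
    BCL2 = list(nfkb = c("NFKB_act", 0.020), stat3 = c("STAT3_act", 0.040)),
    MCL1 = list(stat3 = c("STAT3_act", 0.030), mtor = c("MTOR_act", 0.050)),
    XIAP = list(nfkb = c("NFKB_act", 0.015), akt = c("AKT1_act", 0.070)),
    BIRC2 = list(nfkb = c("NFKB_act", 0.045)),
    BIRC5 = list(nfkb = c("NFKB_act", 0.015), mtor = c("MTOR_act", 0.055)))
  for (sname in names(surv)) {
    .addEffector(b, "apoptosis", sname, deg = 0.02, init = 1)
    for (tag in names(surv[[sname]]))
      .addSynRoute(b, "apoptosis", sname, tag,
                   k = as.numeric(surv[[sname]][[tag]][2]),
                   modifiers = .mods(surv[[sname]][[tag]][1], "activator", 16),
                   Km = .KLIN)
  }

  ## -- cox2: NF-kB-induced COX2 -> PGE2 -> (weak) PI3K input
  .addSp(b, "cox2", "COX2", "protein", init = 0.6, deg = 0.02)
  .addSynRoute(b, "cox2", "COX2", "nfkb", k = 0.030,
               modifiers = .mods("NFKB_act", "activator", 1))
  .addSp(b, "cox2", "COX2_act", "active_form", init = 0.2, deg = 0.002)
  .addRx(b, "cox2", "act_COX2", reactants = c(COX2 = 1),
         products = c(COX2_act = 1), k = 0.2)
  .addRx(b, "cox2", "deact_COX2", reactants = c(COX2_act = 1),
         products = c(COX2 = 1), k = 0.25)
  .register(b, "COX2", act = "act_COX2")
  .addSp(b, "cox2", "PGE2", "metabolite", init = 0.3, deg = 0.05)
  .addRx(b, "cox2", "syn_PGE2", products = c(PGE2 = 1),
         modifiers = .mods("COX2_act", "activator", 1), k = 0.05)

  ## -- cell_cycle
  # CCND1 integrates ERK (dominant), NF-kB and mTOR drive.
  .addSp(b, "cell_cycle", "CCND1", "protein", init = 0.8, deg = 0.04)
  .addRx(b, "cell_cycle", "deg_CCND1_gsk3", reactants = c(CCND1 = 1),
         modifiers = .mods("AKT1_act", "inhibitor", 9.0), k = 0.44)
  .addSynRoute(b, "cell_cycle", "CCND1", "erk", k = 0.60,
               modifiers = .mods("ERK_act", "activator", 4.3), Km = 4)
  .addSynRoute(b, "cell_cycle", "CCND1", "nfkb", k = 2.00,
               modifiers = .mods("NFKB_act", "activator", 1), hill_n = 2)
  .addSynRoute(b, "cell_cycle", "CCND1", "mtor", k = 0.80,
               modifiers = .mods("MTOR_act", "activator", 1))
  # CDK subunit pools are degradation-dominated (buffered): complex levels
  # track cyclin abundance instead of competing for a scarce kinase pool.
  .addSp(b, "cell_cycle", "CDK4", "protein", init = 3, deg = 0.9)
  .addSynRoute(b, "cell_cycle", "CDK4", NULL, k = 2.70)
  .addSp(b, "cell_cycle", "CDK4_CCND1", "complex", init = 0.4, deg = 0.05)
  # CDKN2A/CDKN2B act INK4-style: they block CDK4-cyclin D1 association
  .addRx(b, "cell_cycle", "bind_CDK4_CCND1",
         reactants = c(CDK4 = 1, CCND1 = 1), products = c(CDK4_CCND1 = 1),
         modifiers = rbind(.mods("CDKN2A_act", "inhibitor", 45),
                           .mods("CDKN2B_act", "inhibitor", 10),
                           .mods("CDKN1B", "inhibitor", 2.0)),
         k = 0.085)
  .register(b, "CDK4_CCND1", act = "bind_CDK4_CCND1")
  .addProtein(b, "cell_cycle", "CDKN2A", pool_syn = 0.06, act_k = 0.010)
  .addProtein(b, "cell_cycle", "CDKN2B", pool_syn = 0.06, act_k = 0.005)
  # RB1-gated E2F: active E2F accumulates in proportion to CDK4-CCND1 (and
  # CDK2-CCNE) kinase activity and is restrained by the RB1 pool; RB1 loss
  # lifts the restraint (E2F derepression).
  .addSp(b, "cell_cycle", "RB1", "protein", init = 5, deg = 0.01)
  .addSynRoute(b, "cell_cycle", "RB1", NULL, k = 0.05)
  .addSp(b, "cell_cycle", "E2F", "protein", init = 0.3, deg = 0.05)
  .addRx(b, "cell_cycle", "syn_E2F", products = c(E2F = 1),
         modifiers = .mods("RB1", "inhibitor", 0.6), k = 0.03)
  .register(b, "E2F", syn = "syn_E2F")
  .addSynRoute(b, "cell_cycle", "E2F", "ccnd", k = 0.06,
               modifiers = rbind(.mods("CDK4_CCND1", "activator", 12),
                                 .mods("RB1", "inhibitor", 12)),
               Km = .KLIN)
  .addSynRoute(b, "cell_cycle", "E2F", "ccne", k = 0.02,
               modifiers = rbind(.mods("CDK2_CCNE", "activator", 12),
                                 .mods("RB1", "inhibitor", 12)),
               Km = .KLIN)
  # p27 (CDKN1B) restrains the CDK2/CDK1 complexes and is turned over by
  # the proteasome -- the cell-cycle arm of proteasome inhibition
  .addSp(b, "cell_cycle", "CDKN1B", "protein", init = 0.4, deg = 0)
  .addRx(b, "cell_cycle", "syn_CDKN1B", products = c(CDKN1B = 1), k = 0.02)
  .addRx(b, "cell_cycle", "deg_CDKN1B", reactants = c(CDKN1B = 1), k = 0.05)
  .register(b, "CDKN1B", syn = "syn_CDKN1B")
  .register(b, "PSM", act = "deg_CDKN1B")
  # E2F-driven cyclins E/A; CCNB1 follows CDK2-CCNA
  .addSp(b, "cell_cycle", "CDK2", "protein", init = 2, deg = 0.3)
  .addSynRoute(b, "cell_cycle", "CDK2", NULL, k = 0.60)
  .addSp(b, "cell_cycle", "CCNE", "protein", init = 0.5, deg = 0.03)
  .addSynRoute(b, "cell_cycle", "CCNE", "e2f", k = 0.15,
               modifiers = .mods("E2F", "activator", 12), Km = .KLIN)
  .addSp(b, "cell_cycle", "CDK2_CCNE", "complex", init = 0.5, deg = 0.05)
  .addRx(b, "cell_cycle", "bind_CDK2_CCNE",
         reactants = c(CDK2 = 1, CCNE = 1), products = c(CDK2_CCNE = 1),
         modifiers = .mods("CDKN1B", "inhibitor", 2.0), k = 0.02)
  .register(b, "CDK2_CCNE", act = "bind_CDK2_CCNE")
  .addSp(b, "cell_cycle", "CCNA", "protein", init = 0.5, deg = 0.03)
  .addSynRoute(b, "cell_cycle", "CCNA", "e2f", k = 0.12,
               modifiers = .mods("E2F", "activator", 12), Km = .KLIN)
  .addSp(b, "cell_cycle", "CDK2_CCNA", "complex", init = 0.5, deg = 0.05)
  .addRx(b, "cell_cycle", "bind_CDK2_CCNA",
         reactants = c(CDK2 = 1, CCNA = 1), products = c(CDK2_CCNA = 1),
         modifiers = .mods("CDKN1B", "inhibitor", 2.0), k = 0.02)
  .register(b, "CDK2_CCNA", act = "bind_CDK2_CCNA")
  .addSp(b, "cell_cycle", "CDK1", "protein", init = 2, deg = 0.3)
  .addSynRoute(b, "cell_cycle", "CDK1", NULL, k = 0.60)
  .addSp(b, "cell_cycle", "CCNB1", "protein", init = 0.5, deg = 0.03)
  .addSynRoute(b, "cell_cycle", "CCNB1", "ccna", k = 0.10,
               modifiers = .mods("CDK2_CCNA", "activator", 12), Km = .KLIN)
  .addSp(b, "cell_cycle", "CDK1_CCNB1", "complex", init = 0.5, deg = 0.05)
  .addRx(b, "cell_cycle", "bind_CDK1_CCNB1",
         reactants = c(CDK1 = 1, CCNB1 = 1), products = c(CDK1_CCNB1 = 1),
         modifiers = .mods("CDKN1B", "inhibitor", 2.0), k = 0.02)
  .register(b, "CDK1_CCNB1", act = "bind_CDK1_CCNB1")

  # ---- apply parameter overrides, prune disabled blocks, assemble ----------
  for (rid in names(config$overrides)) {
    if (!rid %in% names(b$reactions))
      stop("override names unknown reaction: ", rid)
    ov <- config$overrides[[rid]]
    for (pn in intersect(names(ov), c("k", "Km", "hill_n")))
      b$reactions[[rid]]$law$parameters[[pn]] <- ov[[pn]]
    if (!is.null(ov$rate_scale)) b$reactions[[rid]]$rate_scale <- ov$rate_scale
  }
  keep_sp <- names(b$species)[b$block_of_sp[names(b$species)] %in%
                                config$enabled_blocks]
  keep_rx <- names(b$reactions)[b$block_of_rx[names(b$reactions)] %in%
                                  config$enabled_blocks]
  rx <- list()
  for (rid in keep_rx) {
    r <- b$reactions[[rid]]
    if (!all(c(r$reactants$species, r$products$species) %in% keep_sp)) next
    drop_mod <- !r$modifiers$species %in% keep_sp
    if (any(drop_mod)) r$modifiers <- r$modifiers[!drop_mod, , drop = FALSE]
    rx[[rid]] <- r
  }
  sp <- do.call(rbind, b$species[keep_sp])
  rownames(sp) <- NULL
  blocks <- lapply(intersect(.BLOCK_NAMES, config$enabled_blocks), function(bn)
    list(name = bn,
         species_ids = names(b$block_of_sp)[b$block_of_sp == bn],
         reaction_ids = intersect(names(rx),
                                  names(b$block_of_rx)[b$block_of_rx == bn])))
  names(blocks) <- vapply(blocks, `[[`, character(1), "name")
  gene_map <- .defaultGeneMap()
  gene_map <- gene_map[vapply(gene_map, function(g) g %in% keep_sp,
                              logical(1))]
  meta <- list(
    version = config$version,
    provenance = paste("Reduced reference cancer network; topology and all",
                       "kinetic parameters are a documented reconstruction,",
                       "not literature-fitted values."),
    blocks = blocks,
    gene_map = gene_map,
    unmapped_genes = "RUNX3",
    syn_map = b$syn_map[intersect(names(b$syn_map), keep_sp)],
    act_map = b$act_map[intersect(names(b$act_map), keep_sp)],
    log = character(0))
  networkModel(sp, rx, metadata = meta)
}

# Gene symbol -> network species. Aliases for symbols the input tables use.
.defaultGeneMap <- function() {
  list(EGFR = "EGFR", ERBB2 = "ERBB2", HER2 = "ERBB2", MET = "MET",
       PDGFR = "PDGFR", PDGFRA = "PDGFR", PDGFRB = "PDGFR",
       VEGFR = "VEGFR", KDR = "VEGFR", KIT = "KIT", IGF1R = "IGF1R",
       ABL = "ABL", ABL1 = "ABL", SRC = "SRC", CDH1 = "CDH1",
       BRAF = "BRAF", RAS = "RAS", KRAS = "RAS", NRAS = "RAS", HRAS = "RAS",
       MEK = "MEK", MAP2K1 = "MEK", ERK = "ERK", MAPK1 = "ERK",
       PI3K = "PI3K", PIK3CA = "PI3K", AKT1 = "AKT1", MTOR = "MTOR",
       IL6 = "IL6", JAK = "JAK", JAK2 = "JAK", STAT3 = "STAT3",
       NFKB = "NFKB", NFKB1 = "NFKB", CCND1 = "CCND1", CDK4 = "CDK4",
       CDK6 = "CDK4", CDK2 = "CDK2", CDK1 = "CDK1", CCNE = "CCNE",
       CCNE1 = "CCNE", CCNA = "CCNA", CCNA2 = "CCNA", CCNB1 = "CCNB1",
       CDKN2A = "CDKN2A", CDKN2B = "CDKN2B", RB1 = "RB1", E2F = "E2F",
       E2F1 = "E2F", TP53 = "P53", P53 = "P53", BAX = "BAX", BCL2 = "BCL2",
       MCL1 = "MCL1", XIAP = "XIAP", BIRC2 = "BIRC2", BIRC5 = "BIRC5",
       NOXA = "NOXA", PMAIP1 = "NOXA", CASP3 = "CASP3", CASP8 = "CASP8",
       COX2 = "COX2", PTGS2 = "COX2", HMGCR = "HMGCR", IKB = "IKB", CDKN1B = "CDKN1B",
       NFKBIA = "IKB", PSM = "PSM", PSMB5 = "PSM")
}

#' Pathway block catalogue of a built model
#'
#' @param model a model from [buildReferenceNetwork()].
#' @return named list of blocks (`name`, `species_ids`, `reaction_ids`).
#' @export
pathwayBlocks <- function(model) {
  stopifnot(is(model, "NetworkModel"))
  blocks <- model@metadata$blocks
  if (is.null(blocks)) stop("model carries no block catalogue")
  blocks
}

#' Untriggered (control) baseline of the reference network
#'
#' Simulates the control network to its steady state -- the non-transformed
#' epithelial baseline of the three-state protocol. Errors on
#' non-convergence, naming the species with the largest residual.
#'
#' @param model a model from [buildReferenceNetwork()].
#' @param max_time horizon (default 50,000 s, the control-phase duration).
#' @param tol steady-state tolerance.
#' @return a `SteadyStateResult` (see [findSteadyState()]).
#' @export
untriggeredBaseline <- function(model, max_time = 50000, tol = 1e-6) {
  ss <- findSteadyState(model, max_time = max_time, tol = tol)
  if (!ss$converged) {
    cm <- .compileModel(model)
    dy <- abs(.rhs(cm, ss$state)) / pmax(abs(ss$state), 1e-6)
    stop(sprintf(
      "control network did not reach steady state within %g s; largest residual at species '%s' (%.3g)",
      max_time, cm$ids[which.max(dy)], max(dy)))
  }
  ss
}
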