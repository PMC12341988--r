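#' Configuration for the mini methanotroph model
#'
#' The generator emulates the metabolic architecture of a
#' verrucomicrobial methanotroph: a menaquinone-based electron transport
#' chain with a reversible complex I, a periplasmic methane
#' monooxygenase drawing electrons from the menaquinol pool, a
#' lanthanide-type methanol dehydrogenase feeding a cytochrome branch
#' (which can also oxidize formaldehyde directly), a THF-dependent
#' formaldehyde oxidation route yielding NADPH and ATP, formate
#' dehydrogenase, a lumped CBB carbon-fixation route (the only carbon
#' assimilation path), periplasmic (quinone-coupled) and cytosolic
#' (NAD-coupled) hydrogenases, the propane -> isopropanol -> acetone ->
#' acetol -> methylglyoxal -> pyruvate chain, lumped pyruvate oxidation
#' (TCA), five lumped biomass precursor pools, and maintenance
#' reactions.
#'
#' @param po_ratio ATP per O assumed for the respiratory chain (default
#'   2.5); sets the ATP synthase proton stoichiometry.
#' @param aciii_protons protons translocated per menaquinol by the
#'   alternative complex III surrogate (default 2).
#' @param gam,ngam maintenance defaults (10.86 mmol ATP/gDW and
#'   3.5 mmol ATP/gDW/h).
#' @param include_c3_pathway,include_hydrogenases logicals switching the
#'   heterotrophic and autotrophic modules on or off.
#' @param reversible_complex_i if `TRUE` complex I is reversible in the
#'   base model (conditions can also override this per scenario).
#' @param seed integer; only used when `bound_jitter > 0`.
#' @param bound_jitter relative jitter applied to internal upper bounds
#'   for test variants (default 0 = fully deterministic).
#' @return list of class `minimodel_config`.
#' @export
minimodel_config <- function(po_ratio = 2.5, aciii_protons = 2,
                             gam = 10.86, ngam = 3.5,
                             include_c3_pathway = TRUE,
                             include_hydrogenases = TRUE,
                             reversible_complex_i = FALSE,
                             seed = 1L, bound_jitter = 0) {
  stopifnot(po_ratio > 0, aciii_protons >= 0,
            aciii_protons == round(aciii_protons), gam >= 0, ngam >= 0)
  structure(list(po_ratio = po_ratio, aciii_protons = aciii_protons,
                 gam = gam, ngam = ngam,
                 include_c3_pathway = include_c3_pathway,
                 include_hydrogenases = include_hydrogenases,
                 reversible_complex_i = reversible_complex_i,
                 seed = as.integer(seed), bound_jitter = bound_jitter),
            class = "minimodel_config")
}

## metabolite table for the mini-model (formulas in flat convention;
## the ferri/ferro cytochrome pair shares a formula and differs in
## charge only, so electron transfers balance with explicit protons)
.mini_mets <- function() {
  m <- function(id, name, comp, formula, charge)
    data.frame(id = id, name = name, compartment = comp, formula = formula,
               charge = charge, stringsAsFactors = FALSE)
  rbind(
    m("ch4_e", "methane", "e", "CH4", 0), m("ch4_p", "methane", "p", "CH4", 0),
    m("o2_e", "oxygen", "e", "O2", 0), m("o2_p", "oxygen", "p", "O2", 0),
    m("co2_c", "carbon dioxide", "c", "CO2", 0),
    m("co2_e", "carbon dioxide", "e", "CO2", 0),
    m("h2o_c", "water", "c", "H2O", 0), m("h2o_p", "water", "p", "H2O", 0),
    m("h2o_e", "water", "e", "H2O", 0),
    m("h_c", "proton", "c", "H", 1), m("h_p", "proton", "p", "H", 1),
    m("h_e", "proton", "e", "H", 1),
    m("nh4_e", "ammonium", "e", "H4N", 1), m("nh4_c", "ammonium", "c", "H4N", 1),
    m("h2_e", "hydrogen", "e", "H2", 0), m("h2_p", "hydrogen", "p", "H2", 0),
    m("h2_c", "hydrogen", "c", "H2", 0),
    m("meoh_p", "methanol", "p", "CH4O", 0),
    m("fald_p", "formaldehyde", "p", "CH2O", 0),
    m("fald_c", "formaldehyde", "c", "CH2O", 0),
    m("for_p", "formate", "p", "CHO2", -1), m("for_c", "formate", "c", "CHO2", -1),
    m("ppa_e", "propane", "e", "C3H8", 0), m("ppa_p", "propane", "p", "C3H8", 0),
    m("ppoh_e", "isopropanol", "e", "C3H8O", 0),
    m("ppoh_p", "isopropanol", "p", "C3H8O", 0),
    m("actn_e", "acetone", "e", "C3H6O", 0), m("actn_p", "acetone", "p", "C3H6O", 0),
    m("actl_p", "acetol", "p", "C3H6O2", 0),
    m("mgx_p", "methylglyoxal", "p", "C3H4O2", 0),
    m("mgx_c", "methylglyoxal", "c", "C3H4O2", 0),
    m("pyr_c", "pyruvate", "c", "C3H3O3", -1),
    m("mqn8_c", "menaquinone 8", "c", "C51H72O2", 0),
    m("mql8_c", "menaquinol 8", "c", "C51H74O2", 0),
    m("ficytC_p", "ferricytochrome c", "p", "C42H44FeN8O8S2", 3),
    m("focytC_p", "ferrocytochrome c", "p", "C42H44FeN8O8S2", 2),
    m("nad_c", "NAD+", "c", "C21H26N7O14P2", -1),
    m("nadh_c", "NADH", "c", "C21H27N7O14P2", -2),
    m("nadp_c", "NADP+", "c", "C21H25N7O17P3", -3),
    m("nadph_c", "NADPH", "c", "C21H26N7O17P3", -4),
    m("atp_c", "ATP", "c", "C10H12N5O13P3", -4),
    m("adp_c", "ADP", "c", "C10H12N5O10P2", -3),
    m("pi_c", "phosphate", "c", "HO4P", -2),
    m("skel_c", "carbon skeleton pool", "c", "", 0),
    m("aa_c", "amino acid pool", "c", "", 0),
    m("nucl_c", "nucleotide pool", "c", "", 0),
    m("lipid_c", "lipid pool", "c", "", 0),
    m("cofac_c", "cofactor pool", "c", "", 0),
    m("biomass_c", "biomass", "c", "", 0)
  )
}

#' Build the mini methanotroph model
#'
#' Deterministic for a fixed configuration. Every internal reaction is
#' elementally balanced by construction: the five biomass precursor
#' pools receive the exact residual formula of their synthesis
#' reactions, and the biomass pseudo-metabolite the residual of the
#' (normalized) biomass reaction. The returned model is normalized to a
#' biomass weight of 1 g/mmol and carries the configured GAM and NGAM.
#'
#' @param config a [minimodel_config()].
#' @return a `metabolic_model` with roughly 50 reactions, 45 metabolites
#'   and 3 compartments.
#' @export
build_minimodel <- function(config = minimodel_config()) {
  mets <- .mini_mets()
  formulas <- stats::setNames(mets$formula, mets$id)
  BIG <- 1000
  rxns <- list()
  add <- function(id, st, lb, ub, gene = "", sub) {
    rxns[[id]] <<- list(id = id, stoichiometry = st, lb = lb, ub = ub,
                        gene_rule = gene, subsystem = sub)
  }
  sv <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }

  ## --- exchanges (closed by default except water/protons) ---------------
  ex <- function(met, lb = 0) add(paste0("EX_", met), sv(stats::setNames(-1, met)),
                                  lb, BIG, sub = "Exchange")
  ex("ch4_e"); ex("o2_e"); ex("co2_e"); ex("nh4_e")
  ex("h2o_e", -BIG); ex("h_e", -BIG)
  if (config$include_hydrogenases) ex("h2_e")
  if (config$include_c3_pathway) { ex("ppa_e"); ex("ppoh_e"); ex("actn_e") }
  add("DM_biomass_c", sv(biomass_c = -1), 0, BIG, sub = "Exchange")

  ## --- transport (diffusion, reversible) --------------------------------
  tr <- function(id, from, to) add(id, sv(stats::setNames(c(-1, 1), c(from, to))),
                                   -BIG, BIG, sub = "Transport")
  tr("CH4tpp", "ch4_e", "ch4_p"); tr("O2tpp", "o2_e", "o2_p")
  tr("CO2tex", "co2_c", "co2_e"); tr("H2Otex", "h2o_c", "h2o_e")
  tr("H2Otpp", "h2o_p", "h2o_c"); tr("Htex", "h_p", "h_e")
  tr("NH4tex", "nh4_e", "nh4_c")
  tr("FALDtpp", "fald_p", "fald_c"); tr("FORtpp", "for_p", "for_c")
  if (config$include_hydrogenases) {
    tr("H2tpp", "h2_e", "h2_p"); tr("H2tcp", "h2_p", "h2_c")
  }
  if (config$include_c3_pathway) {
    tr("PPAtpp", "ppa_e", "ppa_p"); tr("PPOHtpp", "ppoh_e", "ppoh_p")
    tr("ACTNtpp", "actn_e", "actn_p"); tr("MGXtpp", "mgx_p", "mgx_c")
  }

  ## --- methane oxidation (periplasm) ------------------------------------
  add("PMMOipp",
      sv(ch4_p = -1, o2_p = -1, mql8_c = -1, meoh_p = 1, h2o_p = 1, mqn8_c = 1),
      0, BIG, "(pmoC1 and pmoA1 and pmoB1) or (pmoC2 and pmoA2 and pmoB2)",
      "Methane oxidation")
  add("XOXFpp",
      sv(meoh_p = -1, ficytC_p = -2, fald_p = 1, focytC_p = 2, h_p = 2),
      0, BIG, "xoxF and xoxG and xoxJ", "Methane oxidation")
  add("FALDHpp",
      sv(fald_p = -1, h2o_p = -1, ficytC_p = -2, for_p = 1, focytC_p = 2, h_p = 3),
      0, BIG, "xoxF", "Methane oxidation")

  ## --- cytosolic C1 ------------------------------------------------------
  ## THF route lumped: methylene-THF -> formyl-THF -> formate, with the
  ## formate-THF-ligase ATP and FolD-derived NADPH captured in one step
  add("FALDTHF",
      sv(fald_c = -1, nadp_c = -1, adp_c = -1, pi_c = -1,
         for_c = 1, nadph_c = 1, atp_c = 1, h_c = 1),
      0, BIG, "folD and fhs", "Formaldehyde oxidation (THF)")
  add("FDH", sv(for_c = -1, nad_c = -1, co2_c = 1, nadh_c = 1),
      0, BIG, "fdhA", "Formate metabolism")
  add("CBB",
      sv(co2_c = -3, nadph_c = -5, atp_c = -7, h2o_c = -4,
         pyr_c = 1, nadp_c = 5, adp_c = 7, pi_c = 7, h_c = 3),
      0, BIG, "cbbL and cbbS and prk", "CBB cycle")
  add("PYRTCA",
      sv(pyr_c = -1, h2o_c = -2, nad_c = -4, mqn8_c = -1, adp_c = -1, pi_c = -1,
         co2_c = 3, nadh_c = 4, mql8_c = 1, atp_c = 1, h_c = 2),
      0, BIG, "pdhA and gltA and sdhA", "TCA cycle")

  ## --- C3 oxidation chain (periplasm) ------------------------------------
  if (config$include_c3_pathway) {
    add("PMMO3ppa",
        sv(ppa_p = -1, o2_p = -1, mql8_c = -1, ppoh_p = 1, h2o_p = 1, mqn8_c = 1),
        0, BIG, "pmoC3 and pmoA3 and pmoB3", "C3 substrate oxidation")
    add("GMCppi",
        sv(ppoh_p = -1, ficytC_p = -2, actn_p = 1, focytC_p = 2, h_p = 2),
        0, BIG, "gmcO", "C3 substrate oxidation")
    add("PMMO3actn",
        sv(actn_p = -1, o2_p = -1, mql8_c = -1, actl_p = 1, h2o_p = 1, mqn8_c = 1),
        0, BIG, "pmoC3 and pmoA3 and pmoB3 and pmoD", "C3 substrate oxidation")
    add("GMCppa",
        sv(actl_p = -1, ficytC_p = -2, mgx_p = 1, focytC_p = 2, h_p = 2),
        0, BIG, "gmcO", "C3 substrate oxidation")
    ## stands in for the three-step methylglyoxal -> pyruvate pathway
    add("MGXPYR", sv(mgx_c = -1, h2o_c = -1, nad_c = -1,
                     pyr_c = 1, nadh_c = 1, h_c = 2),
        0, BIG, "mgsA", "C3 assimilation")
  }

  ## --- hydrogenases -------------------------------------------------------
  if (config$include_hydrogenases) {
    add("HYD4pp", sv(h2_p = -1, mqn8_c = -1, mql8_c = 1),
        0, BIG, "hyd1d", "Hydrogen oxidation")
    add("NAD_H2", sv(h2_c = -1, nad_c = -1, nadh_c = 1, h_c = 1),
        0, BIG, "hyd3b", "Hydrogen oxidation")
  }

  ## --- electron transport chain ------------------------------------------
  ## complex I: 4 protons translocated per NADH -> menaquinol
  add("NADH16pp",
      sv(nadh_c = -1, mqn8_c = -1, h_c = -5, nad_c = 1, mql8_c = 1, h_p = 4),
      if (config$reversible_complex_i) -BIG else 0, BIG,
      "nuoA and nuoB and nuoC", "Electron transport chain")
  ## alternative complex III surrogate: menaquinol -> 2 cytochrome c,
  ## 2 chemical + config$aciii_protons pumped protons appear outside
  np <- config$aciii_protons
  add("CYO1_KT",
      sv(mql8_c = -1, ficytC_p = -2, h_c = -np,
         mqn8_c = 1, focytC_p = 2, h_p = 2 + np),
      0, BIG, "actA and actB", "Electron transport chain")
  ## cbb3-type cytochrome oxidase, per 2 electrons
  add("CYTCBB3pp1",
      sv(focytC_p = -2, o2_p = -0.5, h_c = -4, ficytC_p = 2, h2o_c = 1, h_p = 2),
      0, BIG, "ccoN and ccoO", "Electron transport chain")
  ## ATP synthase: proton cost tied to the configured P/O ratio; with the
  ## default chain (4 + 2 + aciii + 2 protons per NADH -> 1/2 O2) this is
  ## (8 + aciii)/po protons per ATP
  nh <- (8 + config$aciii_protons) / config$po_ratio
  add("ATPS4rpp",
      sv(adp_c = -1, pi_c = -1, h_p = -nh, atp_c = 1, h2o_c = 1, h_c = nh - 1),
      -BIG, BIG, "atpA and atpB and atpC", "Electron transport chain")
  ## proton-translocating transhydrogenase (NADPH supply at pmf cost)
  add("THD2pp",
      sv(nadh_c = -1, nadp_c = -1, h_p = -2, nad_c = 1, nadph_c = 1, h_c = 2),
      0, BIG, "pntA and pntB", "Electron transport chain")

  ## --- biomass precursor pools -------------------------------------------
  pool <- function(id, pool_met, st, gene = "") {
    st[pool_met] <- 1
    add(id, st, 0, BIG, gene, "Biomass precursor synthesis")
    ## derive the pool formula as the exact residual of the synthesis step
    counts <- numeric(0)
    for (mid in setdiff(names(st), pool_met)) {
      fc <- parse_formula(formulas[[mid]])
      v <- fc * (-st[[mid]])
      for (el in names(v)) counts[el] <- (if (el %in% names(counts)) counts[el] else 0) + v[[el]]
    }
    formulas[[pool_met]] <<- format_formula(counts)
  }
  pool("POOLC", "skel_c",
       sv(pyr_c = -2, nadph_c = -2, atp_c = -2, h_c = -2,
          nadp_c = 2, adp_c = 2, pi_c = 2))
  pool("POOLAA", "aa_c",
       sv(pyr_c = -2, nh4_c = -2, nadph_c = -2, atp_c = -4,
          nadp_c = 2, adp_c = 4, pi_c = 4))
  pool("POOLNUC", "nucl_c",
       sv(pyr_c = -2, nh4_c = -2, h2o_c = -2, nadph_c = -2, atp_c = -6,
          nadp_c = 2, adp_c = 6, pi_c = 6))
  pool("POOLLIP", "lipid_c",
       sv(pyr_c = -3, nadph_c = -6, atp_c = -3, h_c = -6,
          nadp_c = 6, adp_c = 3, pi_c = 3))
  pool("POOLCOF", "cofac_c",
       sv(pyr_c = -1, nh4_c = -1, h2o_c = -1, nadph_c = -1, atp_c = -2,
          nadp_c = 1, adp_c = 2, pi_c = 2))

  add("BIOMASS",
      sv(skel_c = -1.0, aa_c = -3.0, nucl_c = -0.5, lipid_c = -0.7,
         cofac_c = -0.3, biomass_c = 1),
      0, BIG, "", "Biomass and maintenance")
  add("ATPM", sv(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      0, BIG, "", "Biomass and maintenance")

  mets$formula <- formulas[mets$id]
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- mets[mets$id %in% used, , drop = FALSE]
  model <- metabolic_model(id = "mini_methanotroph", metabolites = mets,
                           reactions = rxns, objective_id = "BIOMASS")
  model <- normalize_biomass(model)
  model <- set_maintenance(model, maintenance_spec(gam = config$gam,
                                                   ngam = config$ngam,
                                                   po_ratio = config$po_ratio))
  if (config$bound_jitter > 0) {
    set.seed(config$seed)
    for (rid in names(model$reactions)[!is_exchange(model)]) {
      j <- stats::runif(1, -config$bound_jitter, config$bound_jitter)
      model$reactions[[rid]]$ub <- model$reactions[[rid]]$ub * (1 + j)
    }
  }
  model$extras$minimodel_config <- unclass(config)
  model
}

#' Standard condition fixtures for the mini-model
#'
#' Five named scenarios covering the standard growth regimes: methanotrophic
#' growth at 3.5 C-mmol/gDW/h, autotrophic growth on H2+CO2 at
#' 13.2 mmol H2/gDW/h (periplasmic share 0.76, complex I reversible),
#' and heterotrophic growth on propane, isopropanol and acetone at the
#' same carbon uptake. Each fixture carries its expected qualitative
#' outcome.
#'
#' @param model optional model used to derive ratio denominators.
#' @param carbon_uptake carbon uptake rate (default 3.5 C-mmol/gDW/h).
#' @param h2_uptake autotrophic H2 uptake (default 13.2 mmol/gDW/h).
#' @return list of fixtures: each has `name`, `condition`,
#'   `expect_growth`, `complex_i_sign` (`"forward"`, `"reverse"` or `NA`).
#' @export
default_fixtures <- function(model = NULL, carbon_uptake = 3.5,
                             h2_uptake = 13.2) {
  fixture <- function(substrate, sign) {
    list(name = substrate,
         condition = build_condition(substrate, carbon_uptake = carbon_uptake,
                                     model = model, h2_uptake = h2_uptake),
         expect_growth = TRUE, complex_i_sign = sign)
  }
  list(fixture("ch4", "forward"),
       fixture("h2_co2", NA_character_),
       fixture("propane", "forward"),
       fixture("isopropanol", "forward"),
       fixture("acetone", "forward"))
}
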