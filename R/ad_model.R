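#' The eight Alzheimer's disease category nodes
#'
#' Category node names (as used in the network) mapped to the headings of
#' the revised NINCDS-ADRDA research-criteria classification.
#'
#' @return a named character vector: names are node names, values are the
#'   display labels.
#' @export
ad_categories <- function() {
  c(ProdromalAD             = "Prodromal AD",
    ADdementia              = "AD dementia",
    TypicalAD               = "Typical AD",
    AtypicalAD              = "Atypical AD",
    MixedAD                 = "Mixed AD",
    PreclinicalAD           = "Preclinical states of AD",
    ADPathology             = "Alzheimer's Pathology",
    MildCognitiveImpairment = "Mild Cognitive Impairment")
}

#' Default wiring of the ambiguous mitochondrial/oxidative sub-nodes
#'
#' The published model couples mitochondrial dynamics (Mito) and the
#' oxidative-stress / inflammation / isoprostane axis to the GTPase branch
#' and metal-ion exposure, but spreads each concept over numbered sub-nodes
#' (`Mito1..3`, `OxidStress1/2`, ...) whose exact parent partition over
#' \{MetalIons, OPA1, MFN1, DVLP, FIS1\} is not fully determined; the
#' arities are fixed by the shapes of the parameter tables.  This default
#' assigns `Mito1 <- (OPA1, MFN1)`, `Mito2 <- (DVLP, FIS1)`,
#' `Mito3 <- MetalIons`, and routes each paired sub-node through
#' `(Mito1, MetalIons)` / `(Mito2, MetalIons)`; the amyloid-coupled lesions
#' read `(Ab12, AbAPP)`.  In every bundled case study these tables are
#' deterministic-false, so all category probabilities are invariant to the
#' choice (a tested property); [build_ad_network()] accepts any rewiring
#' with the same arities.
#'
#' @return named list of parent vectors.
#' @export
ad_default_wiring <- function() {
  list(
    Mito1         = c("OPA1", "MFN1"),
    Mito2         = c("DVLP", "FIS1"),
    Mito3         = "MetalIons",
    OxidStress1   = c("Mito1", "MetalIons"),
    OxidStress2   = c("Mito2", "MetalIons"),
    Inflamation1  = c("Mito1", "MetalIons"),
    Inflamation2  = c("Mito2", "MetalIons"),
    Isoprostanes1 = c("Mito1", "MetalIons"),
    Isoprostanes2 = c("Mito2", "MetalIons"),
    SenilePlaques = c("Ab12", "AbAPP"),
    Unbalance_Ca  = c("Ab12", "AbAPP"),
    Vascular      = c("Ab12", "AbAPP")
  )
}

# wiring slots and their required arities (set by the parameter-table shapes)
ad_wiring_arity <- c(
  Mito1 = 2L, Mito2 = 2L, Mito3 = 1L,
  OxidStress1 = 2L, OxidStress2 = 2L,
  Inflamation1 = 2L, Inflamation2 = 2L,
  Isoprostanes1 = 2L, Isoprostanes2 = 2L,
  SenilePlaques = 2L, Unbalance_Ca = 2L, Vascular = 2L
)

# (node, parameter slot, parents) of every stochastic node
ad_stochastic_table <- function(wiring) {
  tab <- list(
    # roots: the "parent knots" of the acyclic graph
    list("Age_Inheritance", "Age_Inheritance", character()),
    list("MetalIons",       "MetalIons",       character()),
    list("p53",             "p53",             character()),
    list("Cytokines",       "Cytokines",       character()),
    list("APP",             "APP",             character()),
    list("DailyActivities", "DailyActivities", character()),
    # age/heredity-driven biomarkers
    list("APOE4",      "APOE4",      "Age_Inheritance"),
    list("PS1_2",      "PS1_2",      "Age_Inheritance"),
    list("LewyBodies", "LewyBodies", "Age_Inheritance"),
    list("miRNAs",     "miRNAs",     "Age_Inheritance"),
    # lifestyle factors, also age-conditioned
    list("Hypertension",     "Hypertension",     "Age_Inheritance"),
    list("Depression",       "Depression",       "Age_Inheritance"),
    list("Smoking",          "Smoking",          "Age_Inheritance"),
    list("Diabetes",         "Diabetes",         "Age_Inheritance"),
    list("Obesity",          "Obesity",          "Age_Inheritance"),
    list("PhysicalActivity", "PhysicalActivity", "Age_Inheritance"),
    # molecular cascade
    list("GTP",         "GTP",         "p53"),
    list("Tau_Phospho", "Tau_Phospho", "Cytokines"),
    list("Ab12",        "Ab",          c("APOE4", "PS1_2")),
    list("AbAPP",       "Ab_APP",      "APP"),
    list("MFN1", "MFN1", "GTP"),
    list("OPA1", "OPA1", "GTP"),
    list("DVLP", "DVLP", "GTP"),
    list("FIS1", "FIS1", "GTP"),
    list("Mito1", "Mito1", wiring$Mito1),
    list("Mito2", "Mito2", wiring$Mito2),
    list("Mito3", "Mito3", wiring$Mito3),
    list("OxidStress1",   "OxidStress1",   wiring$OxidStress1),
    list("OxidStress2",   "OxidStress2",   wiring$OxidStress2),
    list("Inflamation1",  "Inflamation1",  wiring$Inflamation1),
    list("Inflamation2",  "Inflamation2",  wiring$Inflamation2),
    list("Isoprostanes1", "Isoprostanes1", wiring$Isoprostanes1),
    list("Isoprostanes2", "Isoprostanes2", wiring$Isoprostanes2),
    # lesions and clinical signs
    list("SenilePlaques", "SenilePlaques", wiring$SenilePlaques),
    list("Unbalance_Ca",  "Unbalance_Ca",  wiring$Unbalance_Ca),
    list("Vascular",      "Vascular",      wiring$Vascular),
    list("LogopenicAphasiaCortexAtrophy", "LogopenicAphasiaCortexAtrophy",
         "Tau_Phospho"),
    list("MemoryHippocampalLoss",  "MemoryHippocampalLoss",  "Tau_Phospho"),
    list("ExecLangPrax",           "ExecLangPrax",           "Tau_Phospho"),
    list("VisualNeuropsychiatric", "VisualNeuropsychiatric", "Tau_Phospho"),
    list("MCI", "MCI_due_to_DayLiving", "DailyActivities")
  )
  names(tab) <- vapply(tab, `[[`, character(1L), 1L)
  tab
}

# deterministic max aggregators, including the eight category read-outs
ad_deterministic_table <- function() {
  list(
    Ab           = c("Ab12", "AbAPP"),
    Mito         = c("Mito1", "Mito2", "Mito3"),
    OxidStress   = c("OxidStress1", "OxidStress2"),
    Inflamation  = c("Inflamation1", "Inflamation2"),
    Isoprostanes = c("Isoprostanes1", "Isoprostanes2"),
    Lifestyle    = c("Hypertension", "Depression", "Smoking", "Diabetes",
                     "Obesity", "PhysicalActivity"),
    max1         = c("Ab", "LewyBodies", "Mito", "OxidStress",
                     "MemoryHippocampalLoss", "SenilePlaques",
                     "Unbalance_Ca", "Lifestyle", "Inflamation",
                     "Isoprostanes"),
    ProdromalAD  = c("max1", "OxidStress"),
    ADdementia   = c("Ab", "Vascular"),
    max2         = c("Ab", "Tau_Phospho", "Vascular", "ExecLangPrax"),
    TypicalAD    = c("max2", "VisualNeuropsychiatric"),
    AtypicalAD   = c("LogopenicAphasiaCortexAtrophy",
                     "MemoryHippocampalLoss"),
    MixedAD      = c("Vascular", "ProdromalAD"),
    PreclinicalAD = c("Ab", "Tau_Phospho"),
    ADPathology  = "miRNAs",
    MildCognitiveImpairment = "MCI"
  )
}

check_ad_wiring <- function(wiring) {
  extra <- setdiff(names(wiring), names(ad_wiring_arity))
  if (length(extra)) {
    stop("unknown wiring slot(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  w <- utils::modifyList(ad_default_wiring(), wiring)
  for (nm in names(ad_wiring_arity)) {
    if (length(w[[nm]]) != ad_wiring_arity[[nm]]) {
      stop("wiring slot '", nm, "' needs ", ad_wiring_arity[[nm]],
           " parent(s) to match its parameter-table shape, got ",
           length(w[[nm]]), call. = FALSE)
    }
  }
  w
}

#' Structural template of the Alzheimer's disease network
#'
#' The full node/edge structure with no CPTs attached; used by
#' [bind_parameters()] to match a data list before [build_ad_network()]
#' assembles the runnable network.
#'
#' @param wiring parent assignment for the ambiguous sub-nodes, see
#'   [ad_default_wiring()].
#' @return a [bn_network()] whose stochastic nodes carry `NULL` CPTs.
#' @export
ad_network_template <- function(wiring = ad_default_wiring()) {
  wiring <- check_ad_wiring(wiring)
  stoch <- lapply(ad_stochastic_table(wiring), function(row) {
    bn_stochastic(row[[1L]], cpt = NULL, parents = row[[3L]],
                  param = row[[2L]])
  })
  det <- ad_deterministic_table()
  det_nodes <- lapply(names(det), function(nm) bn_max(nm, det[[nm]]))
  bn_network(c(stoch, det_nodes))
}

#' Assemble the Alzheimer's disease network from parameter tables
#'
#' Builds the full biomarker network: 41 stochastic `dcat` nodes (each
#' bound to one `p.*` parameter table of the data-list format) and 16
#' deterministic max aggregators including the eight diagnostic category
#' read-outs (`ProdromalAD`, `ADdementia`, `TypicalAD`, `AtypicalAD`,
#' `MixedAD`, `PreclinicalAD`, `ADPathology`, `MildCognitiveImpairment`).
#' The `max1` risk pool feeding Prodromal AD aggregates the amyloid, Lewy
#' body, mitochondrial, oxidative, lesion and *lifestyle* branches, where
#' lifestyle is the OR of all six modifiable factors (hypertension,
#' depression, smoking, diabetes, obesity, physical inactivity).
#'
#' @param params named list of CPTs (or values coercible by [cpt()]) keyed
#'   by parameter slot name (`Age_Inheritance`, `Ab`, `Ab_APP`, ...,
#'   `MCI_due_to_DayLiving`), e.g. the `params` element of
#'   [bind_parameters()].
#' @param wiring see [ad_default_wiring()].
#' @return a validated [bn_network()].
#' @export
build_ad_network <- function(params, wiring = ad_default_wiring()) {
  wiring <- check_ad_wiring(wiring)
  names(params) <- gsub("-", "_", names(params), fixed = TRUE)
  tab <- ad_stochastic_table(wiring)
  slots <- vapply(tab, `[[`, character(1L), 2L)
  missing <- setdiff(slots, names(params))
  if (length(missing)) {
    stop("missing parameter table(s): ",
         paste(paste0("p.", missing), collapse = ", "), call. = FALSE)
  }
  stoch <- lapply(tab, function(row) {
    bn_stochastic(row[[1L]],
                  cpt = as_cpt(params[[row[[2L]]]],
                               n_parents = length(row[[3L]])),
                  parents = row[[3L]], param = row[[2L]])
  })
  det <- ad_deterministic_table()
  det_nodes <- lapply(names(det), function(nm) bn_max(nm, det[[nm]]))
  net <- bn_network(c(stoch, det_nodes))
  stop_on_diagnostics(net)
  net
}

#' Load one of the four bundled case studies
#'
#' Each case study ships as the WinBUGS data list printed with the original
#' report, parsed and bound to the network at load time, together with the
#' expected category report transcribed from the published results tables
#' (the 10,000-iteration columns).
#'
#' Two of the printed data lists contradict their own results tables, and
#' the results tables are taken as authoritative: case 3 prints
#' `p.miRNAs` rows (0,1) (which would force Alzheimer's Pathology to 1.0)
#' while its table reports 0.0; case 4 additionally prints `p.Vascular`
#' rows (0,1) while its table reports AD dementia, Typical AD and Mixed AD
#' as 0.0/0.0/0.464.  With `corrected = TRUE` (default) those tables are
#' replaced by deterministic-false rows; each substitution is announced
#' with a message and recorded in the `corrections` field.  With
#' `corrected = FALSE` the fixture is built exactly as printed.
#'
#' @param id case study number, 1 to 4.
#' @param corrected apply the documented corrections (default `TRUE`).
#' @param wiring see [ad_default_wiring()].
#' @param quiet suppress the correction messages.
#' @return an object of class `ad_example`: a list with `id`, `network`,
#'   `evidence`, `params`, `doc` (the parsed data list), `expected` (data
#'   frame transcribed from the published tables: `category`, `label`,
#'   `probability`, `mean`, `sd`, `mc_error`), `corrections`, `corrected`.
#' @export
load_example <- function(id, corrected = TRUE, wiring = ad_default_wiring(),
                         quiet = FALSE) {
  if (!id %in% 1:4) stop("id must be 1, 2, 3 or 4", call. = FALSE)
  path <- system.file("extdata", sprintf("example%d.txt", id),
                      package = "adbn", mustWork = TRUE)
  doc <- read_data_list(path)
  bound <- bind_parameters(doc, ad_network_template(wiring))
  params <- bound$params
  corrections <- ad_example_corrections(id)
  if (corrected) {
    for (corr in corrections) {
      if (!quiet) {
        message("case study ", id, ": replacing p.", corr$param,
                " as printed with deterministic-false rows (", corr$reason,
                ")")
      }
      params[[corr$param]] <- cpt(datalist_array(corr$replacement))
    }
  }
  structure(
    list(id = id,
         network = build_ad_network(params, wiring = wiring),
         evidence = bound$evidence,
         params = params,
         doc = doc,
         expected = ad_example_expected(id),
         corrections = corrections,
         corrected = corrected),
    class = "ad_example"
  )
}

#' @export
print.ad_example <- function(x, ...) {
  cat("<ad_example> case study ", x$id, ": ", length(x$evidence),
      " clamped node(s), ", length(x$params), " parameter tables",
      if (x$corrected && length(x$corrections)) {
        paste0(", ", length(x$corrections), " correction(s) applied")
      } else "",
      "\n", sep = "")
  invisible(x)
}

det_false <- function(k) {
  # deterministic-false parameter table, row-major data-list form
  list(data = rep(c(1, 0), 2L^k), dim = rep(2L, k + 1L))
}

ad_example_corrections <- function(id) {
  reason_mirna <- paste0("the published table reports Alzheimer's ",
                         "Pathology 0.0, but the printed rows (0,1) force 1.0")
  reason_vasc <- paste0("the published table reports AD dementia and ",
                        "Typical AD 0.0 and Mixed AD 0.464, but the ",
                        "printed rows (0,1) force all three to 1.0")
  switch(as.character(id),
    "3" = list(list(param = "miRNAs", reason = reason_mirna,
                    replacement = det_false(1L))),
    "4" = list(list(param = "miRNAs", reason = reason_mirna,
                    replacement = det_false(1L)),
               list(param = "Vascular", reason = reason_vasc,
                    replacement = det_false(2L))),
    list()
  )
}

# expected category reports transcribed from the published results tables
# (10,000-iteration columns)
ad_example_expected <- function(id) {
  cats <- ad_categories()
  vals <- switch(as.character(id),
    "1" = list(p  = c(0.562, 0.502, 0.502, 0, 0.562, 0.502, 0, 0.999),
               sd = c(0.4961, 0.5, 0.5, 0, 0.4961, 0.5, 0, 0.03603),
               mc = c(0.00473, 0.00458, 0.00458, 1e-12, 0.00473, 0.00458,
                      1e-12, 3.667e-4)),
    "2" = list(p  = c(0.562, 1, 1, 0, 1, 0.502, 1, 0),
               sd = c(0.4961, 0, 0, 0, 0, 0.5, 0, 0),
               mc = c(0.00473, 1e-12, 1e-12, 1e-12, 1e-12, 0.00458, 1e-12,
                      1e-12)),
    "3" = list(p  = c(1, 1, 1, 0, 1, 1, 0, 0),
               sd = rep(0, 8L),
               mc = rep(1e-12, 8L)),
    "4" = list(p  = c(0.464, 0, 0, 0, 0.464, 0, 0, 0),
               sd = c(0.4987, 0, 0, 0, 0.4987, 0, 0, 0),
               mc = c(0.004383, 1e-12, 1e-12, 1e-12, 0.004383, 1e-12,
                      1e-12, 1e-12))
  )
  data.frame(category = names(cats), label = unname(cats),
             probability = vals$p, mean = vals$p + 1, sd = vals$sd,
             mc_error = vals$mc, stringsAsFactors = FALSE)
}

#' Registry of published biomarker risk rates
#'
#' The relative probabilities of Alzheimer's disease progression attributed
#' to each biomarker in the source literature, as fractions.  Rows reported
#' as ranges carry `low`/`high` bounds; `point` is the value actually used
#' in the bundled case studies where that is determinable (e.g. APOE4 uses
#' 0.70), otherwise the midpoint; rows published only as prose (senile
#' plaques, amyloid beta, hippocampal loss) carry a `note` and a chosen
#' point value.
#'
#' @return a data frame with columns `biomarker`, `low`, `high`, `point`,
#'   `note`.
#' @export
prior_registry <- function() {
  r <- function(biomarker, point, low = point, high = point, note = NA_character_) {
    data.frame(biomarker = biomarker, low = low, high = high, point = point,
               note = note, stringsAsFactors = FALSE)
  }
  out <- rbind(
    r("Age (>85)", 0.38),
    r("Age (75-84)", 0.43),
    r("Age (65-74)", 0.15),
    r("Age (<65)", 0.04),
    r("Lewy Body disease", 0.116, 0.10, 0.20,
      "conclusive diagnosis only post mortem; case studies use 0.116"),
    r("APP", 0.10, 0.10, 0.50,
      "published as 10%, 15% or 50% depending on scenario"),
    r("Hypertension", 0.20),
    r("GTPases", 0.01, 0, 0.01, "published as <1%; stored as upper bound"),
    r("Depression", 0.132),
    r("Smoking", 0.274),
    r("Diabetes", 0.064),
    r("Obesity", 0.034),
    r("Physical Activity", 0.177),
    r("APOE4", 0.70, 0.30, 0.70,
      "range 30-70%; case study 3 uses 0.70"),
    r("PS 1,2", 0.05),
    r("Amyloid Angiopathy", 0.80),
    r("Oxidative Stress", 0.275, 0.25, 0.30, "midpoint of 25-30%"),
    r("Inflammation", 0.35, 0.30, 0.40, "midpoint of 30-40%"),
    r("Isoprostanes", 0.50),
    r("P53", 0.75),
    r("Cytokines", 0.50),
    r("miRNAs", 0.60),
    r("DVLP", 0.743),
    r("OPA1", 0.614),
    r("MFN1", 0.278),
    r("MFN2", 0.336),
    r("FIS1", 0.60),
    r("Visual, neuropsychiatric disorders", 0.05),
    r("Executive, language, praxis disorders", 0.40),
    r("DayLiving disorders", 0.15, 0.10, 0.20, "midpoint of 10-20%"),
    r("Metal Ions", 0.24),
    r("Unbalance Ca", 0.05),
    r("Senile plaques", 0.60, 0.60, 1.00,
      "published as over 60% by age 80, increasing linearly with age"),
    r("Amyloid Beta", 0.50, 0.50, 1.00, "published as over 50% at ages >85"),
    r("Hippocampal volume loss/Memory Impairment", 0.10, 0.10, 0.10,
      "about 10% of elders over 70 have significant memory loss")
  )
  rownames(out) <- NULL
  out
}

#' Look up a biomarker's point risk rate
#'
#' @param biomarker row name in [prior_registry()].
#' @return the point value as a fraction.
#' @export
prior_probability <- function(biomarker) {
  reg <- prior_registry()
  i <- match(biomarker, reg$biomarker)
  if (is.na(i)) {
    stop("unknown biomarker: '", biomarker, "'; see prior_registry()",
         call. = FALSE)
  }
  reg$point[i]
}
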