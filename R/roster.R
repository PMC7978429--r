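#' Roster of major archosaurian hindlimb muscle-tendon units
#'
#' The 35+ major hindlimb muscles of Archosauria with the homologous names in
#' Crocodylia and in Aves (Phasianidae), their suspected main actions, and
#' their reconstruction status across the bird-line: a few muscles were lost
#' (FTI2 within Dinosauromorpha; FTI1 and PIFE3 between Avialae and Aves),
#' the ITC evolved within Dinosauromorpha (its Crocodylia-grade precursor is
#' the IF), and some states are too ambiguous in fossils to reconstruct.
#' Only rows with `modeled == TRUE` carry moment-arm traits.
#'
#' @return A tibble with columns `abbrev`, `crocodylia`, `aves`,
#'   `main_action`, `modeled`, `lost_at`, `evolved_at`, and logical joint
#'   membership columns `hip`, `knee`, `ankle`.
#' @export
muscle_roster <- function() {
  r <- tibble::tribble(
    ~abbrev, ~crocodylia, ~aves, ~main_action, ~modeled, ~lost_at, ~evolved_at, ~hip, ~knee, ~ankle,
    "CFL",   "M. caudofemoralis longus", "M. caudofemoralis pars caudalis", "hip extensor", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "CFB",   "M. caudofemoralis brevis", "M. caudofemoralis pars pelvica", "hip extensor", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "ILFB",  "M. iliofibularis", "M. iliofibularis", "hip extensor/knee flexor", TRUE, NA, NA, TRUE, TRUE, FALSE,
    "ADD1",  "M. adductor femoris 1", "M. puboischiofemoralis medialis", "hip adductor/hip extensor", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "ADD2",  "M. adductor femoris 2", "M. puboischiofemoralis lateralis", "hip adductor/hip extensor", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "FTI1",  "M. flexor tibialis internus 1", NA, "hip extensor/knee flexor", TRUE, "Avialae-Aves", NA, TRUE, TRUE, FALSE,
    "FTI2",  "M. flexor tibialis internus 2", NA, "hip extensor/knee flexor", FALSE, "Dinosauromorpha", NA, TRUE, TRUE, FALSE,
    "FTI3",  "M. flexor tibialis internus 3", "M. flexor cruris medialis", "hip extensor/knee flexor", TRUE, NA, NA, TRUE, TRUE, FALSE,
    "FTI4",  "M. flexor tibialis internus 4", NA, "hip extensor/knee flexor", FALSE, NA, NA, TRUE, TRUE, FALSE,
    "FTE",   "M. flexor tibialis externus", "M. flexor cruris lateralis pars pelvica", "hip extensor/knee flexor", TRUE, NA, NA, TRUE, TRUE, FALSE,
    "ISTR",  "M. ischiotrochantericus", "M. ischiofemoralis", "hip extensor/hip lateral rotator", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "AMB",   "M. ambiens 1", "M. ambiens", "hip flexor/knee extensor", TRUE, NA, NA, TRUE, TRUE, TRUE,
    "AMB2",  "M. ambiens 2", NA, "hip flexor/knee extensor", FALSE, NA, NA, TRUE, TRUE, FALSE,
    "IT1",   "M. iliotibialis 1", "M. iliotibialis cranialis", "hip flexor/knee extensor", TRUE, NA, NA, TRUE, TRUE, FALSE,
    "IT2",   "M. iliotibialis 2", "M. iliotibialis lateralis pars preacetabularis", "hip flexor/knee extensor", TRUE, NA, NA, TRUE, TRUE, FALSE,
    "IT3",   "M. iliotibialis 3", "M. iliotibialis lateralis pars postacetabularis", "hip extensor/knee extensor", TRUE, NA, NA, TRUE, TRUE, FALSE,
    "PIFE1", "M. puboischiofemoralis externus 1", "M. obturatorius lateralis", "hip flexor/hip lateral rotator", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "PIFE2", "M. puboischiofemoralis externus 2", "M. obturatorius medialis", "hip flexor/hip lateral rotator", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "PIFE3", "M. puboischiofemoralis externus 3", NA, "hip flexor/hip lateral rotator", TRUE, "Avialae-Aves", NA, TRUE, FALSE, FALSE,
    "PIFI1", "M. puboischiofemoralis internus 1", "M. iliofemoralis internus", "hip flexor/hip medial rotator", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "PIFI2", "M. puboischiofemoralis internus 2", "M. iliotrochantericus cranialis", "hip flexor/hip medial rotator", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "IFE",   "M. iliofemoralis", "M. iliofemoralis externus", "hip abductor", TRUE, NA, NA, TRUE, FALSE, FALSE,
    "ITC",   NA, "M. iliotrochantericus caudalis", "hip abductor/hip medial rotator", TRUE, NA, "Dinosauromorpha", TRUE, FALSE, FALSE,
    "FMTE",  "M. femorotibialis externus", "M. femorotibialis lateralis", "knee extensor", TRUE, NA, NA, FALSE, TRUE, FALSE,
    "FMTI",  "M. femorotibialis internus", "M. femorotibialis medialis", "knee extensor", TRUE, NA, NA, FALSE, TRUE, FALSE,
    "GL",    "M. gastrocnemius lateralis", "M. gastrocnemius pars lateralis", "knee flexor/ankle plantarflexor", TRUE, NA, NA, FALSE, TRUE, TRUE,
    "GM",    "M. gastrocnemius medialis", "M. gastrocnemius pars medialis", "ankle plantarflexor", TRUE, NA, NA, FALSE, FALSE, TRUE,
    "EDL",   "M. extensor digitorum longus", "M. tibialis cranialis caput femorale", "ankle dorsiflexor/knee extensor", TRUE, NA, NA, FALSE, TRUE, TRUE,
    "EHL",   "M. extensor hallucis longus", "M. extensor hallucis longus", "ankle dorsiflexor", TRUE, NA, NA, FALSE, FALSE, TRUE,
    "TA",    "M. tibialis anterior", "M. tibialis cranialis caput tibiale", "ankle dorsiflexor", TRUE, NA, NA, FALSE, TRUE, TRUE,
    "FDL",   "M. flexor digitorum longus", "M. flexor digitorum longus", "ankle plantarflexor/knee flexor", TRUE, NA, NA, FALSE, TRUE, TRUE,
    "FHL",   "M. flexor hallucis longus", "M. flexor hallucis longus", "ankle plantarflexor/knee flexor", TRUE, NA, NA, FALSE, TRUE, TRUE,
    "FL",    "M. fibularis longus", "M. fibularis longus", "ankle plantarflexor", TRUE, NA, NA, FALSE, FALSE, TRUE,
    "FLT",   "M. fibularis longus (secondary tendon)", "M. fibularis longus (secondary tendon)", "ankle plantarflexor", TRUE, NA, NA, FALSE, FALSE, TRUE,
    "FB",    "M. fibularis brevis", "M. fibularis brevis", "ankle dorsiflexor", TRUE, NA, NA, FALSE, FALSE, TRUE,
    "EDB",   "M. extensor digitorum brevis", NA, "toe extensor", FALSE, NA, NA, FALSE, FALSE, FALSE,
    "FDB",   "M. flexor digitorum brevis", NA, "toe flexor", FALSE, NA, NA, FALSE, FALSE, FALSE,
    "PP",    "M. pronator profundus", NA, "tibiofibular rotator", FALSE, "Dinosauromorpha", NA, FALSE, FALSE, FALSE,
    "IC",    "M. interosseus cruris", NA, "tibiofibular rotator", FALSE, "Neotheropoda", NA, FALSE, FALSE, FALSE
  )
  r
}

#' Reference per-muscle mean normalized moment-arm estimates
#'
#' The published summary of mean (across ancestral nodes) normalized
#' moment-arm ancestral estimates for each muscle and degree of freedom in
#' the 13-taxon bird-line study configuration, signed according to
#' [action_sign_convention()]. These are node-averaged summary values, not
#' node-wise series; they serve as a compact empirical anchor for the trend
#' machinery and for the worked examples.
#'
#' @return A tibble with columns `joint`, `dof`, `mtu`, `mean_ace`.
#' @export
reference_mean_ace <- function() {
  path <- system.file("extdata", "birdline_mean_ace_reference.csv",
                      package = "archolimb")
  readr::read_csv(path, show_col_types = FALSE)
}
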