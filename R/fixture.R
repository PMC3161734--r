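#' The packaged nitrogen-metabolism core model
#'
#' A reduced, carbon-balanced reconstruction of night-time nitrogen
#' metabolism in *Chlamydomonas reinhardtii*: glycolysis/gluconeogenesis,
#' the oxidative and non-oxidative pentose phosphate pathway, acetate
#' uptake, the citrate cycle with the glyoxylate shunt, a lumped electron
#' transport chain and transhydrogenase, nitrate/nitrite/ammonium
#' assimilation (GS/GOGAT and GDH), and the biosynthesis routes of the five
#' target amino acids glycine, alanine, asparagine, lysine and arginine.
#' Carbon sources are G6P (from starch breakdown) and acetate; nitrogen
#' sources are nitrate, nitrite and ammonium; energy and redox carriers are
#' internal. The circadian (CHLAMY1-) regulated reactions shipped with the
#' model are glucose-6-phosphate isomerase, the NADP-dependent isocitrate
#' dehydrogenase, nitrite reductase and argininosuccinate lyase.
#'
#' This is a synthetic stand-in at reduced scale, assembled from textbook
#' pathway structure, not a transcription of a published genome-scale or
#' supplementary model; it preserves the topology that drives the circadian
#' analysis (G6PI gating glycolysis so that its loss forces G6P through the
#' CO2-releasing oxidative PPP; NiR being essential for nitrate/nitrite use;
#' ASL being essential for arginine) at a size where complete elementary
#' flux mode enumeration is fast.
#'
#' @return A [metabolic_network()] with its model configuration attached.
#' @export
chlamy_core_network <- function() {
  dir <- system.file("extdata", "chlamy_core_synthetic", package = "circaflux",
                     mustWork = TRUE)
  parse_reaction_table(file.path(dir, "reactions.tsv"),
                       file.path(dir, "metabolites.tsv"),
                       file.path(dir, "config.yaml"),
                       name = "chlamy_nitrogen_core_synthetic")
}

#' Named analysis scenarios on the core model
#'
#' Three scenario configurations for [run_scenario()]:
#' \describe{
#'   \item{`full`}{the complete core model, G6P + acetate as carbon sources,
#'     all shipped regulated reactions.}
#'   \item{`gap_variant`}{glycolysis and the pentose phosphate pathway
#'     removed and glyceraldehyde-3-phosphate (GAP) + acetate fed instead of
#'     G6P; used to show that the drop in maximum yield under regulation
#'     depends on the carbon source, while the distribution shift does not.}
#'   \item{`asl_nir_only`}{regulation restricted to the two enzymes with
#'     experimentally confirmed CHLAMY1 binding, argininosuccinate lyase and
#'     nitrite reductase.}
#' }
#'
#' @param name Scenario name.
#' @param w_affected Weight for the weighted scheme.
#' @param out_dir Optional output directory, passed through.
#' @return A configuration list for [run_scenario()].
#' @export
chlamy_core_scenario <- function(name = c("full", "gap_variant", "asl_nir_only"),
                                 w_affected = 0.1, out_dir = NULL) {
  name <- match.arg(name)
  net <- chlamy_core_network()
  if (name == "gap_variant") {
    ext <- union(setdiff(net$config$external, "G6P"), "GAP")
    net <- subnetwork(net,
                      drop_reactions = c("R_PGI", "R_PFKALD", "R_PPPOX", "R_PPPNOX"),
                      externals_override = ext)
    net$name <- "chlamy_nitrogen_core_synthetic_gap"
    net$config$carbon_sources <- c("GAP", "ACE")
  }
  regulated <- if (name == "asl_nir_only") c("R_NIR", "R_ASL")
               else net$config$regulated_reactions
  list(network = net, regulated = regulated, w_affected = w_affected,
       out_dir = out_dir, scenario = name)
}
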