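#' Published best/worst AUC reference table
#'
#' The bundled table of published benchmark AUC values for the three model
#' families evaluated over the beta grid on the PhysioNet/CinC 2016
#' heart-sound subsets ("a"-"f", pooled combinations) and the Michigan set:
#' per model and subset, the AUC at the best- and worst-performing beta and
#' those beta values.  Feeding it through [delta_from_auc_table()] yields
#' the beta-sensitivity ratios without any training.
#'
#' @return Data frame with columns `model`, `subset`, `best_auc`,
#'   `best_beta`, `worst_auc`, `worst_beta`.
#' @export
reference_auc_table <- function() {
  utils::read.csv(system.file("extdata", "reference_auc.csv",
                              package = "pcgdense"),
                  stringsAsFactors = FALSE)
}
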