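#' Reference sequences of the four core histones
#'
#' Full-length human reference sequences used to assign histone roles to
#' chains of a predicted complex and to map acidic-patch residues by
#' alignment. Positions are counted from the initiator methionine, so the
#' acidic-patch residues of the H2A reference are E57, E62, E65, D91, E92
#' and E93.
#'
#' The shipped entries are the isoforms used to build nucleosome prediction
#' jobs: H2A type 2-C, H2B type 1-K, H3.2 and H4. Predicted constructs are
#' typically tailless truncations of these (H2A 12-119, H2B 32-125,
#' H3 39-134, H4 21-103); role assignment aligns chains to the full
#' references, so truncation does not matter.
#'
#' @return Named character vector with elements `H2A`, `H2B`, `H3`, `H4`.
#' @export
#' @examples
#' nchar(histone_references())
histone_references <- function() {
  c(
    H2A = "MSGRGKQGGKARAKAKSRSSRAGLQFPVGRVHRLLRKGNYAERVGAGAPVYLAAVLEYLTAEILELAGNAARDNKKTRIIPRHLQLAIRNDEELNKLLGGVTIAQGGVLPNIQAVLLPKKTESSKSKSK",
    H2B = "MPEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSRKESYSIYVYKVLKQVHPDTGISSKAMGIMNSFVNDIFERIAGEASRLAHYNKRSTITSREIQTAVRLLLPGELAKHAVSEGTKAVTKYTSAK",
    H3  = "MARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGTVALREIRRYQKSTELLIRKLPFQRLVREIAQDFKTDLRFQSSAVMALQEASEAYLVGLFEDTNLCAIHAKRVTIMPKDIQLARRIRGERA",
    H4  = "MSGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLKVFLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG"
  )
}

#' Acidic-patch residue definition
#'
#' The nucleosome acidic patch is the negatively charged H2A/H2B surface
#' cluster that most nucleosome binders dock onto, usually via an arginine
#' or lysine "anchor". On human H2A type 2-C it comprises E57, E62, E65,
#' D91, E92 and E93 (positions on the full reference, Met = 1). Two
#' sub-pockets are distinguished: AP1 (E62, D91, E93), the classical
#' arginine-anchor pocket, and AP2 (E62, D91, E65).
#'
#' Positions refer to the shipped H2A reference sequence; on an actual
#' chain they are located by pairwise alignment (see
#' [locate_patch_residues()]), so truncated or renumbered constructs are
#' handled transparently.
#'
#' @return An object of class `acidic_patch`: a list with integer vectors
#'   `ap` (all six positions), `ap1`, `ap2`, and the `reference` H2A
#'   sequence.
#' @export
#' @examples
#' defn <- acidic_patch_definition()
#' defn$ap1
acidic_patch_definition <- function() {
  ref <- histone_references()[["H2A"]]
  ap  <- c(E57 = 57L, E62 = 62L, E65 = 65L, D91 = 91L, E92 = 92L, E93 = 93L)
  defn <- list(
    ap  = ap,
    ap1 = ap[c("E62", "D91", "E93")],
    ap2 = ap[c("E62", "D91", "E65")],
    reference = ref
  )
  # sanity: the reference must carry acidic residues at the stated positions
  stopifnot(all(substring(ref, ap, ap) %in% c("E", "D")))
  class(defn) <- "acidic_patch"
  defn
}

#' @export
print.acidic_patch <- function(x, ...) {
  cat("Acidic patch definition (H2A reference numbering, Met = 1)\n")
  cat("  AP : ", paste(names(x$ap), collapse = " "), "\n")
  cat("  AP1: ", paste(names(x$ap1), collapse = " "), "\n")
  cat("  AP2: ", paste(names(x$ap2), collapse = " "), "\n")
  invisible(x)
}

#' Prediction-workflow bookkeeping
#'
#' Recomputes the sizes of a whole-proteome nucleosome-prediction campaign
#' from its stated inputs: starting from `n_nuclear` candidate proteins,
#' those longer than `max_len` residues are dropped, proteins above the
#' predictor's single-job limit are split into two segments, and every
#' prediction job yields `models_per_prediction` structural models.
#'
#' @param n_nuclear number of candidate nuclear proteins entering the screen.
#' @param n_over_max proteins exceeding `max_len`, excluded outright.
#' @param n_split proteins over the predictor length limit, each split into
#'   two segments predicted separately.
#' @param models_per_prediction models generated per prediction job.
#' @param max_len hard length cap (residues) above which proteins are dropped.
#' @return List with `n_processed`, `n_split_predictions`,
#'   `n_single_predictions` and `n_total_predictions`.
#' @export
#' @examples
#' screen_bookkeeping()$n_total_predictions
screen_bookkeeping <- function(n_nuclear = 7655L, n_over_max = 2L,
                               n_split = 25L, models_per_prediction = 5L,
                               max_len = 8000L) {
  n_processed <- n_nuclear - n_over_max
  n_split_predictions <- n_split * 2L * models_per_prediction
  n_single <- (n_processed - n_split) * models_per_prediction
  list(
    n_processed = n_processed,
    n_split_predictions = n_split_predictions,
    n_single_predictions = n_single,
    n_total_predictions = n_split_predictions + n_single
  )
}
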