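# Strength-factor (SF) scoring of predicted binder-nucleosome models.
#
# Each contacting residue pair k gets a weight combining two confidence
# indices: p_a,k, the transformed predicted aligned error (pae_max - rawPAE,
# with pae_max = 31.75, the server's maximum raw PAE), and p_l,k, the raw
# pLDDT. Their product, averaged over the two directions of the PAE matrix,
# is the pair weight; the sum over pairs is the unnormalized SF, and
# dividing by B (the unnormalized SF of a designated reference complex,
# canonically BARD1-nucleosome) gives the normalized SF.

#' Scoring parameters
#'
#' @param contact_cutoff contact distance cutoff in Angstroms.
#' @param pae_max maximum raw PAE of the predictor output; the PAE
#'   transform is `pae_max - rawPAE`.
#' @param clamp_negative clamp negative transformed-PAE values (rawPAE above
#'   `pae_max`) to zero, so low-confidence contacts never subtract signal.
#' @param weight_mode `"directional_mean"` (default) averages the two
#'   directional products `(pae_max - pae(a,b)) * plddt(a)`;
#'   `"component_mean"` averages the transformed PAE and pLDDT separately
#'   and multiplies the means. The two readings differ only in cross terms.
#' @param clash_dist,clash_tolerance forwarded to [detect_clashes()].
#' @return An object of class `scoring_params`.
#' @export
#' @examples
#' scoring_params()
scoring_params <- function(contact_cutoff = 5.0, pae_max = 31.75,
                           clamp_negative = TRUE,
                           weight_mode = c("directional_mean",
                                           "component_mean"),
                           clash_dist = 1.2, clash_tolerance = 0L) {
  stopifnot(contact_cutoff > 0, pae_max > 0, clash_dist > 0,
            clash_tolerance >= 0)
  structure(list(contact_cutoff = contact_cutoff, pae_max = pae_max,
                 clamp_negative = isTRUE(clamp_negative),
                 weight_mode = match.arg(weight_mode),
                 clash_dist = clash_dist,
                 clash_tolerance = as.integer(clash_tolerance)),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("SF scoring parameters:\n")
  cat("  contact cutoff :", x$contact_cutoff, "A\n")
  cat("  PAE transform  :", x$pae_max, "- rawPAE",
      if (x$clamp_negative) "(clamped at 0)" else "", "\n")
  cat("  weight mode    :", x$weight_mode, "\n")
  cat("  clash          : <", x$clash_dist, "A, tolerance",
      x$clash_tolerance, "\n")
  invisible(x)
}

#' Confidence weights of contacting residue pairs
#'
#' For each residue pair the transformed PAE is read in both matrix
#' directions and combined with the per-residue pLDDT per the chosen
#' `weight_mode`. The returned `p_a` and `p_l` columns are always the
#' direction-averaged components; `weight` follows the mode.
#'
#' @param contacts a `contact_set`.
#' @param confidence a `confidence_bundle` for the same model.
#' @param params a `scoring_params`.
#' @return data.frame: the contact pairs plus `p_a`, `p_l`, `weight`.
#' @export
pair_weights <- function(contacts, confidence, params = scoring_params()) {
  stopifnot(inherits(contacts, "contact_set"),
            inherits(confidence, "confidence_bundle"),
            inherits(params, "scoring_params"))
  pairs <- contacts$pairs
  if (nrow(pairs) == 0L)
    return(cbind(pairs, p_a = numeric(0), p_l = numeric(0),
                 weight = numeric(0)))
  tm <- confidence$token_map
  ti <- .token_lookup(tm, pairs$binder_chain, pairs$binder_resno)
  tj <- .token_lookup(tm, pairs$histone_chain, pairs$histone_resno)
  clamp <- function(v) if (params$clamp_negative) pmax(v, 0) else v
  t_ij <- clamp(params$pae_max - confidence$pae[cbind(ti, tj)])
  t_ji <- clamp(params$pae_max - confidence$pae[cbind(tj, ti)])
  pl_i <- confidence$plddt_by_token[ti]
  pl_j <- confidence$plddt_by_token[tj]
  p_a <- (t_ij + t_ji) / 2
  p_l <- (pl_i + pl_j) / 2
  weight <- switch(params$weight_mode,
                   directional_mean = (t_ij * pl_i + t_ji * pl_j) / 2,
                   component_mean = p_a * p_l)
  cbind(pairs, p_a = p_a, p_l = p_l, weight = weight)
}

#' Score one model end to end
#'
#' Runs the full per-model scoring path: clash exclusion, contact
#' detection at the cutoff, residue-pair deduplication, confidence
#' weighting, and summation to the unnormalized strength factor. Excluded
#' models (predictor clash flag, or geometric binder-histone/DNA clashes)
#' carry `sf_raw = 0` and the exclusion flag. If `ref` is supplied the
#' normalized SF is filled in as well.
#'
#' @param model a classified `predicted_model`.
#' @param confidence its `confidence_bundle`.
#' @param params a `scoring_params`.
#' @param ref optional `sf_reference` for normalization.
#' @return An `sf_result`: list with `model_id`, `weights` (data.frame),
#'   `n_contacts`, `sf_raw`, `sf` (NA until normalized), `excluded_by_clash`.
#' @export
score_model <- function(model, confidence, params = scoring_params(),
                        ref = NULL) {
  clash <- detect_clashes(model, confidence, clash_dist = params$clash_dist,
                          tolerance = params$clash_tolerance)
  if (clash$excluded) {
    res <- structure(list(model_id = model$model_id,
                          weights = NULL, n_contacts = 0L,
                          sf_raw = 0, sf = NA_real_,
                          excluded_by_clash = TRUE),
                     class = "sf_result")
  } else {
    ac <- find_atom_contacts(model, cutoff = params$contact_cutoff)
    cs <- dedupe_to_residue_pairs(ac, model_id = model$model_id)
    w <- pair_weights(cs, confidence, params)
    res <- structure(list(model_id = model$model_id, weights = w,
                          n_contacts = nrow(w),
                          sf_raw = if (nrow(w)) sum(w$weight) else 0,
                          sf = NA_real_, excluded_by_clash = FALSE),
                     class = "sf_result")
  }
  if (!is.null(ref)) res <- normalize_sf(res, ref)
  res
}

#' Unnormalized SF of a contact set
#'
#' Sum of confidence weights over contacting residue pairs; the empty set
#' scores zero.
#'
#' @inheritParams pair_weights
#' @return Numeric scalar.
#' @export
sf_raw <- function(contacts, confidence, params = scoring_params()) {
  w <- pair_weights(contacts, confidence, params)
  if (nrow(w) == 0L) 0 else sum(w$weight)
}

#' Build a normalization reference
#'
#' Scores a designated reference complex (canonically the BARD1-nucleosome
#' complex) with the same parameters and stores its unnormalized SF as the
#' scaling factor B.
#'
#' @param model classified reference `predicted_model`.
#' @param confidence its `confidence_bundle`.
#' @param params a `scoring_params`.
#' @param source free-text description of the reference.
#' @return An `sf_reference`: list with `B` and `source`.
#' @export
sf_reference <- function(model, confidence, params = scoring_params(),
                         source = model$model_id) {
  res <- score_model(model, confidence, params)
  if (res$excluded_by_clash)
    stop("reference model is excluded by clash filtering", call. = FALSE)
  if (res$sf_raw <= 0)
    stop("reference model has non-positive unnormalized SF (",
         res$sf_raw, "); cannot normalize", call. = FALSE)
  structure(list(B = res$sf_raw, source = source), class = "sf_reference")
}

#' Normalize an SF result against a reference
#'
#' @param result an `sf_result`.
#' @param ref an `sf_reference` (or list with positive element `B`).
#' @return The result with `sf = sf_raw / B` filled in (0 for excluded
#'   models).
#' @export
normalize_sf <- function(result, ref) {
  stopifnot(inherits(result, "sf_result"))
  if (is.null(ref$B) || !is.finite(ref$B) || ref$B <= 0)
    stop("normalization reference B must be a positive number",
         call. = FALSE)
  result$sf <- if (result$excluded_by_clash) 0 else result$sf_raw / ref$B
  result
}

#' @export
print.sf_result <- function(x, ...) {
  cat("SF result for model '", x$model_id, "'\n", sep = "")
  if (x$excluded_by_clash) {
    cat("  excluded by clash filtering; sf = 0\n")
  } else {
    cat("  contacts:", x$n_contacts, " sf_raw:", format(x$sf_raw),
        " sf:", if (is.na(x$sf)) "(unnormalized)" else format(x$sf), "\n")
  }
  invisible(x)
}

#' Best-of-models score for one protein
#'
#' Each protein is predicted several times (typically five models); its
#' score is the highest normalized SF across models. Excluded models
#' participate with SF 0; ties keep the first model in input order.
#'
#' @param results list of normalized `sf_result` objects for one protein.
#' @param protein_id identifier for the rank entry.
#' @return One-row data.frame: `protein_id`, `sf_best`, `model_of_best`,
#'   `n_models`, `n_excluded`.
#' @export
best_of_models <- function(results, protein_id) {
  if (length(results) == 0L) stop("no models supplied", call. = FALSE)
  sfs <- vapply(results, function(r) {
    if (r$excluded_by_clash) 0
    else if (is.na(r$sf)) stop("results must be normalized first",
                               call. = FALSE)
    else r$sf
  }, numeric(1))
  best <- which.max(sfs)  # first maximum on ties
  data.frame(protein_id = protein_id, sf_best = sfs[best],
             model_of_best = results[[best]]$model_id,
             n_models = length(results),
             n_excluded = sum(vapply(results, `[[`, logical(1),
                                     "excluded_by_clash")),
             stringsAsFactors = FALSE)
}

#' Rank proteins by best SF
#'
#' Stable descending sort on `sf_best`; rows tied on the score keep their
#' input order, so ranks are reproducible when inputs are pre-sorted by
#' protein id.
#'
#' @param entries data.frame of rank entries from [best_of_models()].
#' @return An `sf_ranking` data.frame with a `rank` column (1 = best).
#' @export
rank_proteins <- function(entries) {
  ord <- order(-entries$sf_best)  # stable radix sort
  out <- entries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("sf_ranking", "data.frame")
  out
}

#' @export
print.sf_ranking <- function(x, ...) {
  cat("SF ranking of", nrow(x), "proteins\n")
  print.data.frame(utils::head(x, 15L))
  if (nrow(x) > 15L) cat("  ...", nrow(x) - 15L, "more\n")
  knee <- attr(x, "knee")
  if (!is.null(knee) && !is.na(knee))
    cat("Kneedle cut after rank", knee, "\n")
  invisible(x)
}

#' Plot an SF ranking curve
#'
#' Rank on the x axis, best normalized SF on the y axis, with the Kneedle
#' knee marked when detectable.
#'
#' @param x an `sf_ranking`.
#' @param ... forwarded to [graphics::plot()].
#' @method plot sf_ranking
#' @export
plot.sf_ranking <- function(x, ...) {
  graphics::plot(x$rank, x$sf_best, type = "l", xlab = "rank",
                 ylab = "normalized SF", ...)
  knee <- kneedle_top(x$sf_best)
  if (!is.na(knee)) {
    graphics::abline(v = knee, lty = 2)
    graphics::points(knee, x$sf_best[knee], pch = 19)
  }
  invisible(x)
}

#' Knee detection on a ranked score curve
#'
#' Classic Kneedle for a non-increasing score list: x and y are min-max
#' normalized to the unit square (so the endpoint chord always runs from
#' (0,1) to (1,0)), and the knee is the point of maximal perpendicular
#' distance from that chord, computed through the difference curve
#' `|1 - x - y| / sqrt(2)`. Sensitivity is fixed at 1 and no smoothing is
#' applied. Top hits are the entries up to and including the knee.
#'
#' @param sorted_scores non-increasing numeric vector, length >= 3.
#' @param tol distances below `tol` count as "on the chord"; a curve whose
#'   maximal chord distance is below `tol` (e.g. a straight line or a
#'   constant list) has no knee.
#' @return Integer index (1-based) of the knee, or `NA` when no knee
#'   exists.
#' @export
#' @examples
#' kneedle_top(c(10, 9.5, 9, 1, 0.9, 0.8))
kneedle_top <- function(sorted_scores, tol = 1e-9) {
  n <- length(sorted_scores)
  if (n < 3L) stop("need at least 3 scores", call. = FALSE)
  if (any(diff(sorted_scores) > 1e-12))
    stop("scores must be sorted in non-increasing order", call. = FALSE)
  rng <- sorted_scores[1L] - sorted_scores[n]
  if (rng <= 0) return(NA_integer_)  # constant list: no knee
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (sorted_scores - sorted_scores[n]) / rng
  d <- abs(1 - x - y) / sqrt(2)
  if (max(d) < tol) return(NA_integer_)
  which.max(d)
}
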