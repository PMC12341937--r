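# Batch workflow: score -> rank -> knee; consistency; benchmark.
#
# All batch interfaces are manifest-driven (explicit pairing of model and
# confidence files per protein) rather than directory-globbing, and every
# run is deterministic: proteins are processed in lexicographic id order
# and all sorts are stable.

.read_manifest <- function(manifest, required) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(required %in% names(manifest)))
    stop("manifest must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  manifest
}

.load_classified <- function(path, references = histone_references()) {
  classify_chains(read_structure(path), references = references)
}

#' Run the screening workflow over a manifest
#'
#' For each protein: load its models (typically five), apply clash
#' filtering, detect contacts, compute the normalized SF per model, and
#' keep the best model's score. Proteins are then ranked by best SF and
#' the Kneedle knee of the ranked curve is located. Per-protein failures
#' (unreadable files, classification errors) are collected in a failures
#' table and do not stop the run.
#'
#' @param manifest data.frame (or TSV path) with columns `protein_id`,
#'   `model_path`, `confidence_path`; one row per model.
#' @param reference_model,reference_confidence paths (or loaded objects)
#'   for the normalization reference complex.
#' @param params a [scoring_params()].
#' @param references histone reference sequences for chain classification.
#' @return A `screen_result`: list with `scores` (per-model table),
#'   `ranking` (an `sf_ranking` with the knee index in attribute
#'   `"knee"`), `failures`, `reference_B`, `params`.
#' @export
run_screen <- function(manifest, reference_model, reference_confidence,
                       params = scoring_params(),
                       references = histone_references()) {
  manifest <- .read_manifest(manifest, c("protein_id", "model_path",
                                         "confidence_path"))
  ref_m <- if (inherits(reference_model, "predicted_model"))
    reference_model else .load_classified(reference_model, references)
  ref_c <- if (inherits(reference_confidence, "confidence_bundle"))
    reference_confidence else read_confidence(reference_confidence, ref_m)
  ref <- sf_reference(ref_m, ref_c, params)

  empty_scores <- data.frame(protein_id = character(0),
                             model_id = character(0),
                             n_contacts = integer(0), sf_raw = numeric(0),
                             sf = numeric(0), excluded = logical(0))
  empty_fail <- data.frame(protein_id = character(0),
                           model_path = character(0), error = character(0))
  if (nrow(manifest) == 0L) {
    warning("empty manifest: nothing to score")
    ranking <- rank_proteins(data.frame(protein_id = character(0),
                                        sf_best = numeric(0),
                                        model_of_best = character(0),
                                        n_models = integer(0),
                                        n_excluded = integer(0)))
    return(structure(list(scores = empty_scores, ranking = ranking,
                          failures = empty_fail, reference_B = ref$B,
                          params = params), class = "screen_result"))
  }

  scores <- empty_scores; failures <- empty_fail
  entries <- NULL
  for (pid in sort(unique(manifest$protein_id))) {
    rows <- manifest[manifest$protein_id == pid, , drop = FALSE]
    results <- list()
    for (r in seq_len(nrow(rows))) {
      res <- tryCatch({
        m <- .load_classified(rows$model_path[r], references)
        conf <- read_confidence(rows$confidence_path[r], m)
        score_model(m, conf, params, ref = ref)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures, data.frame(
          protein_id = pid, model_path = rows$model_path[r],
          error = conditionMessage(res)))
      } else {
        results <- c(results, list(res))
        scores <- rbind(scores, data.frame(
          protein_id = pid, model_id = res$model_id,
          n_contacts = res$n_contacts, sf_raw = res$sf_raw, sf = res$sf,
          excluded = res$excluded_by_clash))
      }
    }
    if (length(results) > 0L)
      entries <- rbind(entries, best_of_models(results, pid))
  }
  if (is.null(entries))
    entries <- data.frame(protein_id = character(0), sf_best = numeric(0),
                          model_of_best = character(0),
                          n_models = integer(0), n_excluded = integer(0))
  ranking <- rank_proteins(entries)
  attr(ranking, "knee") <- if (nrow(ranking) >= 3L)
    kneedle_top(ranking$sf_best) else NA_integer_
  structure(list(scores = scores, ranking = ranking, failures = failures,
                 reference_B = ref$B, params = params),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Nucleosome-binder screen:", nrow(x$ranking), "proteins scored,",
      nrow(x$failures), "failures; B =", format(x$reference_B), "\n")
  print(x$ranking)
  invisible(x)
}

#' Run the acidic-patch consistency workflow
#'
#' For each protein, loads its models, extracts patch-contacting binder
#' residues on the occupied face, computes all pairwise inter-model RMSDs
#' at the patch, and estimates the per-protein mode RMSD. The consistency
#' score normalizes each mode against the cohort maximum (computed over
#' this run). Proteins whose consistency is undefined (no patch contacts
#' shared between any model pair) are flagged, not dropped.
#'
#' @param manifest data.frame (or TSV path) with columns `protein_id`,
#'   `model_path`; one row per model.
#' @param defn an [acidic_patch_definition()].
#' @param cutoff centroid distance cutoff (Angstroms).
#' @param references histone reference sequences for classification.
#' @return List with `table` (protein_id, n_pairs_defined, mode_rmsd,
#'   score, undefined, note) and `details` (the `consistency_result`s).
#' @export
run_consistency <- function(manifest, defn = acidic_patch_definition(),
                            cutoff = 5.0,
                            references = histone_references()) {
  manifest <- .read_manifest(manifest, c("protein_id", "model_path"))
  pids <- sort(unique(manifest$protein_id))
  details <- list()
  tab <- data.frame(protein_id = character(0), n_pairs_defined = integer(0),
                    mode_rmsd = numeric(0), score = numeric(0),
                    undefined = logical(0), note = character(0))
  for (pid in pids) {
    rows <- manifest[manifest$protein_id == pid, , drop = FALSE]
    out <- tryCatch({
      models <- lapply(rows$model_path, .load_classified,
                       references = references)
      pcs <- lapply(models, binder_patch_residues, defn = defn,
                    cutoff = cutoff)
      cr <- patch_rmsd_matrix(models, pcs, protein_id = pid)
      if (!cr$undefined) cr$mode_rmsd <- mode_rmsd(cr$rmsd_pairs)
      cr
    }, error = function(e) e)
    if (inherits(out, "error")) {
      tab <- rbind(tab, data.frame(protein_id = pid, n_pairs_defined = 0L,
                                   mode_rmsd = NA_real_, score = NA_real_,
                                   undefined = TRUE,
                                   note = conditionMessage(out)))
    } else {
      details[[pid]] <- out
      tab <- rbind(tab, data.frame(
        protein_id = pid, n_pairs_defined = sum(!is.na(out$rmsd_pairs)),
        mode_rmsd = out$mode_rmsd, score = NA_real_,
        undefined = out$undefined, note = ""))
    }
  }
  defined <- !is.na(tab$mode_rmsd)
  if (any(defined)) {
    cohort_max <- max(tab$mode_rmsd[defined])
    if (cohort_max > 0) {
      tab$score[defined] <- consistency_score(tab$mode_rmsd[defined],
                                              cohort_max)
    } else {
      tab$score[defined] <- 1  # every protein perfectly consistent
    }
    for (pid in names(details)) {
      i <- match(pid, tab$protein_id)
      details[[pid]]$mode_rmsd <- tab$mode_rmsd[i]
      details[[pid]]$score <- tab$score[i]
    }
  }
  rownames(tab) <- NULL
  list(table = tab, details = details)
}

#' Run the benchmark workflow
#'
#' Compares predicted against experimentally solved complexes of the same
#' binders: for each pair, the (binder residue, acidic-patch residue)
#' interaction pairs are extracted from both structures and the
#' prediction is called positive when their Jaccard overlap reaches the
#' threshold.
#'
#' @param pairs data.frame (or TSV path) with columns `protein_id`,
#'   `predicted_path`, `reference_path`.
#' @param defn an [acidic_patch_definition()].
#' @param cutoff atomic contact cutoff (Angstroms).
#' @param threshold minimum Jaccard overlap for a positive call.
#' @param references histone reference sequences for classification.
#' @return List with `calls` (per-pair table), `n_positive`, `n_total`.
#' @export
run_benchmark <- function(pairs, defn = acidic_patch_definition(),
                          cutoff = 5.0, threshold = 0.3,
                          references = histone_references()) {
  pairs <- .read_manifest(pairs, c("protein_id", "predicted_path",
                                   "reference_path"))
  if (any(is.na(pairs$predicted_path) | is.na(pairs$reference_path) |
            pairs$predicted_path == "" | pairs$reference_path == ""))
    stop("every benchmark entry needs both a predicted and a reference",
         " structure", call. = FALSE)
  calls <- data.frame(protein_id = character(0), jaccard = numeric(0),
                      positive = logical(0), undefined = logical(0),
                      n_predicted = integer(0), n_reference = integer(0))
  for (r in seq_len(nrow(pairs))) {
    pm <- .load_classified(pairs$predicted_path[r], references)
    rm <- .load_classified(pairs$reference_path[r], references)
    call <- benchmark_hit(patch_contact_pairs(pm, defn, cutoff),
                          patch_contact_pairs(rm, defn, cutoff),
                          threshold = threshold)
    calls <- rbind(calls, data.frame(
      protein_id = pairs$protein_id[r], jaccard = call$jaccard,
      positive = call$positive, undefined = call$undefined,
      n_predicted = call$n_predicted, n_reference = call$n_reference))
  }
  list(calls = calls, n_positive = sum(calls$positive),
       n_total = nrow(calls))
}
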