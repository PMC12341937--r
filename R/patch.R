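# Acidic-patch analyses: locating patch residues on H2A chains by
# alignment, patch-proximal binder extraction, inter-model consistency via
# mode pairwise RMSD, anchor motif windows, and benchmark hit-calling.

# map reference positions to sequence indices through an ends-free global
# alignment; returns data.frame(ref_pos, seq_index) for aligned, non-gap
# column pairs
.align_map <- function(ref, seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(seq),
    type = "overlap", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  rp <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L
  ref_pos <- integer(0); seq_index <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") rp <- rp + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-" && s[k] != "-") {
      ref_pos <- c(ref_pos, rp)
      seq_index <- c(seq_index, si)
    }
  }
  data.frame(ref_pos = ref_pos, seq_index = seq_index)
}

#' Locate acidic-patch residues on an H2A chain
#'
#' Maps reference positions of the patch definition onto the author
#' numbering of a (possibly truncated or renumbered) H2A chain by pairwise
#' alignment to the reference sequence.
#'
#' @param model a classified `predicted_model`.
#' @param chain_id an H2A chain of the model.
#' @param defn an [acidic_patch_definition()].
#' @param positions reference positions to map; defaults to all six patch
#'   residues.
#' @return data.frame with `ref_pos`, `resno`, `aa` for every mapped
#'   position (unmapped positions are absent).
#' @export
locate_patch_residues <- function(model, chain_id,
                                  defn = acidic_patch_definition(),
                                  positions = defn$ap) {
  seq <- chain_sequence(model, chain_id)
  map <- .align_map(defn$reference, seq)
  sel <- model$residues$chain_id == chain_id
  resnos <- model$residues$resno[sel]
  aas <- model$residues$aa[sel]
  hit <- map[map$ref_pos %in% positions, , drop = FALSE]
  data.frame(ref_pos = hit$ref_pos, resno = resnos[hit$seq_index],
             aa = aas[hit$seq_index], stringsAsFactors = FALSE)
}

#' Centroid of the acidic-patch pocket on one face
#'
#' Unweighted mean of the heavy-atom coordinates of the AP1 and AP2
#' residues (their union) on the given H2A chain.
#'
#' @inheritParams locate_patch_residues
#' @param face chain id of the H2A copy defining the face.
#' @return Numeric 3-vector (Angstroms).
#' @export
patch_centroid <- function(model, defn = acidic_patch_definition(),
                           face) {
  need <- sort(unique(c(defn$ap1, defn$ap2)))
  loc <- locate_patch_residues(model, face, defn, positions = need)
  missing <- setdiff(need, loc$ref_pos)
  if (length(missing) > 0L)
    stop("acidic-patch residues missing on chain ", face, ": reference ",
         paste(missing, collapse = ", "), call. = FALSE)
  sel <- model$atoms$chain_id == face & model$atoms$resno %in% loc$resno
  colMeans(as.matrix(model$atoms[sel, c("x", "y", "z")]))
}

#' Binder residues at the acidic patch
#'
#' Finds binder residues with at least one heavy atom within `cutoff` of
#' the acidic-patch centroid. Both H2A faces of the nucleosome are
#' evaluated and the face with more qualifying residues is reported (tie:
#' the first H2A chain in chain order). Residues are partitioned into
#' maximal runs of consecutive sequence numbers (`segments`).
#'
#' @inheritParams patch_centroid
#' @param cutoff distance from the centroid (Angstroms).
#' @return A `patch_contacts` object: list with `model_id`, `face`,
#'   `centroid`, `residues` (sorted binder seq ids) and `segments` (list of
#'   integer vectors).
#' @export
binder_patch_residues <- function(model, defn = acidic_patch_definition(),
                                  cutoff = 5.0) {
  faces <- .chains_with_role(model, "H2A")
  if (length(faces) == 0L) stop("model has no H2A chain", call. = FALSE)
  binder <- .chains_with_role(model, "BINDER")
  ab <- .atoms_of_chains(model, binder)
  per_face <- lapply(faces, function(f) {
    cen <- tryCatch(patch_centroid(model, defn, f), error = function(e) NULL)
    if (is.null(cen)) return(NULL)
    d <- sqrt((ab$x - cen[1])^2 + (ab$y - cen[2])^2 + (ab$z - cen[3])^2)
    list(face = f, centroid = cen,
         residues = sort(unique(ab$resno[d <= cutoff])))
  })
  per_face <- Filter(Negate(is.null), per_face)
  if (length(per_face) == 0L)
    stop("no H2A face carries the complete acidic-patch definition",
         call. = FALSE)
  counts <- vapply(per_face, function(p) length(p$residues), integer(1))
  best <- per_face[[which.max(counts)]]  # first face wins ties
  segs <- if (length(best$residues) == 0L) list()
          else unname(split(best$residues,
                            cumsum(c(1L, diff(best$residues) != 1L))))
  structure(list(model_id = model$model_id, face = best$face,
                 centroid = best$centroid, residues = best$residues,
                 segments = segs),
            class = "patch_contacts")
}

#' @export
print.patch_contacts <- function(x, ...) {
  cat("Acidic-patch binder residues for model '", x$model_id,
      "' (face ", x$face, ")\n", sep = "")
  cat("  residues:", if (length(x$residues)) paste(x$residues,
                                                   collapse = " ")
                     else "(none)", "\n")
  cat("  segments:", length(x$segments), "\n")
  invisible(x)
}

#' Representative patch-binding segment
#'
#' When a binder touches the acidic patch through several sequence
#' segments, the longest is the representative; length ties are resolved
#' by a uniform draw under an explicit, recorded seed so the choice is
#' reproducible.
#'
#' @param pcs a `patch_contacts` object with at least one segment.
#' @param seed integer seed for the tie-break draw.
#' @return Integer vector of binder seq ids (the chosen segment), with the
#'   seed recorded in attribute `"seed"`.
#' @export
select_representative_segment <- function(pcs, seed = 985866441L) {
  stopifnot(inherits(pcs, "patch_contacts"))
  if (length(pcs$segments) == 0L)
    stop("no patch-binding segments to select from", call. = FALSE)
  lens <- lengths(pcs$segments)
  cand <- which(lens == max(lens))
  pick <- if (length(cand) == 1L) cand else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    cand[sample.int(length(cand), 1L)]
  }
  structure(pcs$segments[[pick]], seed = seed)
}

#' Superpose one model onto another over the histone core
#'
#' Least-squares rigid (Kabsch) superposition of model `b` onto model `a`
#' using shared histone C-alpha atoms, matched by chain id and author
#' residue number. Predicted models come in arbitrary frames, so all
#' inter-model comparisons go through this common histone frame.
#'
#' @param model_a,model_b classified `predicted_model`s sharing at least 3
#'   histone C-alpha atoms.
#' @return A `superposition`: list with `rotation` (3x3), `translation`
#'   (3-vector; apply as `x %*% t(rotation) + translation`), `rmsd` over
#'   the fitted atoms, and `n_atoms`.
#' @export
superpose_on_histones <- function(model_a, model_b) {
  hist_roles <- c("H2A", "H2B", "H3", "H4")
  ca_of <- function(m) {
    a <- m$atoms[m$atoms$chain_id %in% .chains_with_role(m, hist_roles) &
                   m$atoms$elety == "CA", , drop = FALSE]
    a$key <- paste(a$chain_id, a$resno)
    a
  }
  aa <- ca_of(model_a); bb <- ca_of(model_b)
  common <- intersect(aa$key, bb$key)
  if (length(common) < 3L)
    stop("fewer than 3 shared histone C-alpha atoms (", length(common),
         ")", call. = FALSE)
  A <- as.matrix(aa[match(common, aa$key), c("x", "y", "z")])
  B <- as.matrix(bb[match(common, bb$key), c("x", "y", "z")])
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(crossprod(Bc, Ac))          # H = B^T A
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ca - as.numeric(R %*% cb)
  Bfit <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - Bfit)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_atoms = length(common)),
            class = "superposition")
}

#' Apply a superposition to a model
#'
#' @param model a `predicted_model`.
#' @param sp a `superposition` from [superpose_on_histones()].
#' @return The model with all atom coordinates transformed.
#' @export
apply_superposition <- function(model, sp) {
  stopifnot(inherits(sp, "superposition"))
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(sp$rotation)
  xyz <- sweep(xyz, 2, sp$translation, "+")
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' Pairwise inter-model RMSD at the acidic patch
#'
#' For every pair among a protein's models (10 pairs for the usual five),
#' the models are superposed over their shared histone core and the RMSD
#' is computed over C-alpha atoms of the intersection of their
#' patch-contacting binder residues. Pairs with an empty intersection are
#' reported as `NA` and flagged; if all pairs are empty the protein's
#' consistency is undefined.
#'
#' @param models list of classified `predicted_model`s for one protein.
#' @param pcs_list list of `patch_contacts`, parallel to `models`.
#' @param protein_id identifier for the result.
#' @return A `consistency_result`: list with `protein_id`, `rmsd_pairs`
#'   (named numeric, `NA` for undefined pairs), `mode_rmsd` and `score`
#'   (both `NA` until filled by [mode_rmsd()] / [consistency_score()]),
#'   and `undefined` flag.
#' @export
patch_rmsd_matrix <- function(models, pcs_list,
                              protein_id = "protein") {
  stopifnot(length(models) >= 2L, length(models) == length(pcs_list))
  n <- length(models)
  combs <- utils::combn(n, 2)
  vals <- rep(NA_real_, ncol(combs))
  names(vals) <- apply(combs, 2, paste, collapse = "-")
  binder_ca <- function(m, resnos) {
    b <- .chains_with_role(m, "BINDER")
    a <- m$atoms[m$atoms$chain_id %in% b & m$atoms$elety == "CA" &
                   m$atoms$resno %in% resnos, , drop = FALSE]
    a[order(a$resno), c("resno", "x", "y", "z"), drop = FALSE]
  }
  for (k in seq_len(ncol(combs))) {
    i <- combs[1L, k]; j <- combs[2L, k]
    common <- intersect(pcs_list[[i]]$residues, pcs_list[[j]]$residues)
    if (length(common) == 0L) next
    sp <- superpose_on_histones(models[[i]], models[[j]])
    mj <- apply_superposition(models[[j]], sp)
    A <- binder_ca(models[[i]], common)
    B <- binder_ca(mj, common)
    shared <- intersect(A$resno, B$resno)
    if (length(shared) == 0L) next
    A <- A[match(shared, A$resno), ]; B <- B[match(shared, B$resno), ]
    vals[k] <- sqrt(mean((A$x - B$x)^2 + (A$y - B$y)^2 + (A$z - B$z)^2))
  }
  structure(list(protein_id = protein_id, rmsd_pairs = vals,
                 mode_rmsd = NA_real_, score = NA_real_,
                 undefined = all(is.na(vals))),
            class = "consistency_result")
}

#' Mode of a set of RMSD values
#'
#' The mode of the continuous RMSD distribution is estimated by histogram
#' binning: values are binned at `bin_width` (bins anchored at zero) and
#' the center of the most populated bin is returned; ties go to the
#' lowest-RMSD bin. `NA` values are ignored.
#'
#' @param values numeric RMSDs (Angstroms).
#' @param bin_width histogram bin width (Angstroms).
#' @return Numeric scalar (Angstroms). When the values of the winning bin
#'   are all identical (notably a run of exact zeros from identical
#'   models) that exact value is returned instead of the bin center, so
#'   perfectly consistent model sets keep mode 0.
#' @export
#' @examples
#' mode_rmsd(c(0.51, 0.52, 0.55, 2.0, 3.1))  # 0.55
mode_rmsd <- function(values, bin_width = 0.1) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no RMSD values", call. = FALSE)
  stopifnot(bin_width > 0, all(values >= 0))
  idx <- floor(values / bin_width + 1e-9)
  counts <- table(idx)
  top <- max(counts)
  win <- min(as.integer(names(counts)[counts == top]))  # lowest bin on tie
  inwin <- values[idx == win]
  if (max(inwin) - min(inwin) < 1e-12) return(unname(inwin[1L]))
  (win + 0.5) * bin_width
}

#' Prediction-consistency score
#'
#' One minus the ratio of a protein's mode patch RMSD to the maximum mode
#' RMSD in the cohort, clipped to [0, 1]: 1 means the five models agree
#' perfectly at the patch, 0 means the protein is the least consistent in
#' the cohort.
#'
#' @param mode the protein's mode RMSD (Angstroms).
#' @param cohort_max maximum mode RMSD over all proteins in the cohort
#'   (must be positive).
#' @return Numeric in [0, 1].
#' @export
consistency_score <- function(mode, cohort_max) {
  if (!is.finite(cohort_max) || cohort_max <= 0)
    stop("cohort_max must be a positive number", call. = FALSE)
  pmin(pmax(1 - mode / cohort_max, 0), 1)
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("Patch consistency for '", x$protein_id, "'\n", sep = "")
  cat("  pairwise RMSDs:",
      paste(format(round(x$rmsd_pairs, 3)), collapse = " "), "\n")
  cat("  mode:", format(x$mode_rmsd), " score:", format(x$score),
      if (x$undefined) " (undefined)" else "", "\n")
  invisible(x)
}

#' Motif window around one anchor residue
#'
#' Extracts the 21-residue window (center plus 10 residues either side) of
#' a binder sequence, padded with `"-"` at the termini so all windows stay
#' column-registered for logo building.
#'
#' @param binder_seq binder chain sequence (one-letter codes).
#' @param center_pos 1-based position of the anchor in `binder_seq`.
#' @return Character scalar of length 21.
#' @export
motif_window <- function(binder_seq, center_pos) {
  n <- nchar(binder_seq)
  stopifnot(center_pos >= 1L, center_pos <= n)
  idx <- (center_pos - 10L):(center_pos + 10L)
  chars <- ifelse(idx < 1L | idx > n, "-",
                  substring(binder_seq, idx, idx))
  paste(chars, collapse = "")
}

#' Anchor motif windows of a binder
#'
#' Finds every arginine or lysine on the binder that contacts an AP1 or
#' AP2 residue (atomic contact at `cutoff` to a residue mapping to the
#' sub-pocket positions on either H2A face) and extracts its 21-residue
#' window.
#'
#' @param model a classified `predicted_model`.
#' @param defn an [acidic_patch_definition()].
#' @param cutoff contact cutoff (Angstroms).
#' @return data.frame with `center_resno`, `center_aa`, `window`; zero rows
#'   when no anchor contacts the pocket.
#' @export
motif_windows <- function(model, defn = acidic_patch_definition(),
                          cutoff = 5.0) {
  pocket <- sort(unique(c(defn$ap1, defn$ap2)))
  pairs <- patch_contact_pairs(model, defn, cutoff = cutoff,
                               positions = pocket)
  empty <- data.frame(center_resno = integer(0), center_aa = character(0),
                      window = character(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  binder <- .chains_with_role(model, "BINDER")
  sel <- model$residues$chain_id == binder
  resnos <- model$residues$resno[sel]
  seq <- paste(model$residues$aa[sel], collapse = "")
  centers <- sort(unique(pairs$binder_resno))
  aa <- model$residues$aa[sel][match(centers, resnos)]
  keep <- aa %in% c("R", "K")
  centers <- centers[keep]; aa <- aa[keep]
  if (length(centers) == 0L) return(empty)
  windows <- vapply(centers, function(r)
    motif_window(seq, match(r, resnos)), character(1))
  data.frame(center_resno = centers, center_aa = aa, window = windows,
             stringsAsFactors = FALSE)
}

#' Write motif windows as aligned FASTA
#'
#' @param windows data.frame from [motif_windows()] (optionally with a
#'   `protein_id` column used in headers).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_motifs_fasta <- function(windows, path) {
  ids <- if ("protein_id" %in% names(windows))
    paste0(windows$protein_id, "_", windows$center_resno)
  else paste0("anchor_", windows$center_resno)
  lines <- as.vector(rbind(paste0(">", ids), windows$window))
  writeLines(lines, path)
  invisible(path)
}

#' Binder-patch residue pairs of a model
#'
#' Residue pairs (binder seq id, acidic-patch reference position) formed
#' by atomic contacts between the binder and acidic-patch residues on
#' either H2A face. Histone residues are mapped into reference numbering
#' by alignment, so predicted and experimental structures with different
#' constructs share a common frame.
#'
#' @param model a classified `predicted_model`.
#' @param defn an [acidic_patch_definition()].
#' @param cutoff atomic contact cutoff (Angstroms).
#' @param positions patch positions to restrict to (default: all six).
#' @return data.frame with `binder_resno`, `ap_pos` (unique rows).
#' @export
patch_contact_pairs <- function(model, defn = acidic_patch_definition(),
                                cutoff = 5.0, positions = defn$ap) {
  cs <- dedupe_to_residue_pairs(find_atom_contacts(model, cutoff),
                                model_id = model$model_id)
  pairs <- cs$pairs[cs$pairs$histone_type == "H2A", , drop = FALSE]
  out <- data.frame(binder_resno = integer(0), ap_pos = integer(0))
  for (f in unique(pairs$histone_chain)) {
    loc <- locate_patch_residues(model, f, defn, positions = positions)
    sub <- pairs[pairs$histone_chain == f &
                   pairs$histone_resno %in% loc$resno, , drop = FALSE]
    if (nrow(sub) == 0L) next
    out <- rbind(out, data.frame(
      binder_resno = sub$binder_resno,
      ap_pos = loc$ref_pos[match(sub$histone_resno, loc$resno)]))
  }
  unique(out)
}

#' Benchmark a predicted patch interaction against a reference
#'
#' Compares the (binder residue, acidic-patch residue) pair sets of a
#' predicted and an experimentally solved complex by Jaccard overlap; the
#' prediction is a positive hit when the overlap reaches `threshold`. The
#' comparison is symmetric in its two arguments. When both sets are empty
#' the overlap is undefined and the call is negative with a flag.
#'
#' @param predicted,reference data.frames from [patch_contact_pairs()].
#' @param threshold minimum Jaccard index for a positive call.
#' @return A `benchmark_call`: list with `jaccard`, `positive`,
#'   `undefined`, `n_predicted`, `n_reference`, `threshold`.
#' @export
benchmark_hit <- function(predicted, reference, threshold = 0.3) {
  kp <- unique(paste(predicted$binder_resno, predicted$ap_pos))
  kr <- unique(paste(reference$binder_resno, reference$ap_pos))
  if (length(kp) == 0L && length(kr) == 0L) {
    return(structure(list(jaccard = NA_real_, positive = FALSE,
                          undefined = TRUE, n_predicted = 0L,
                          n_reference = 0L, threshold = threshold),
                     class = "benchmark_call"))
  }
  jac <- length(intersect(kp, kr)) / length(union(kp, kr))
  structure(list(jaccard = jac, positive = jac >= threshold,
                 undefined = FALSE, n_predicted = length(kp),
                 n_reference = length(kr), threshold = threshold),
            class = "benchmark_call")
}

#' @export
print.benchmark_call <- function(x, ...) {
  cat("Benchmark call: jaccard =", format(x$jaccard),
      if (x$undefined) "(undefined)" else "",
      "-> ", if (x$positive) "POSITIVE" else "negative",
      " (threshold ", x$threshold, ")\n", sep = " ")
  invisible(x)
}
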