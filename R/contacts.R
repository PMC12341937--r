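# Binder-histone contact detection at a distance cutoff.
#
# Neighbor search uses a uniform grid (cell lists): atoms are binned into
# cubic cells of edge `cutoff`, and candidate partners for an atom are
# drawn from its 27 surrounding cells. The result contract is exactly the
# brute-force all-pairs search; the grid only prunes the candidate set.

# integer cell key for 3D binning; cells indexed relative to the bounding
# box so keys stay well inside 32-bit range for any realistic model
.cell_keys <- function(xyz, cutoff) {
  cx <- floor(xyz[, 1] / cutoff)
  cy <- floor(xyz[, 2] / cutoff)
  cz <- floor(xyz[, 3] / cutoff)
  list(cx = cx - min(cx), cy = cy - min(cy), cz = cz - min(cz))
}

# all pairs (i from set A, j from set B) with euclidean distance <= cutoff;
# returns data.frame(i, j, dist) with i, j row indices into A and B
.grid_pairs <- function(xyz_a, xyz_b, cutoff) {
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (nrow(xyz_a) == 0L || nrow(xyz_b) == 0L) return(empty)
  # common binning frame
  mins <- pmin(apply(xyz_a, 2, min), apply(xyz_b, 2, min))
  ka <- floor(sweep(xyz_a, 2, mins) / cutoff)
  kb <- floor(sweep(xyz_b, 2, mins) / cutoff)
  dims <- pmax(apply(ka, 2, max), apply(kb, 2, max)) + 1
  enc <- function(k) k[, 1] + dims[1] * (k[, 2] + dims[2] * k[, 3])
  key_b <- enc(kb)
  b_by_cell <- split(seq_len(nrow(xyz_b)), key_b)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- vector("list", 0L); out_j <- vector("list", 0L)
  out_d <- vector("list", 0L)
  key_a <- enc(ka)
  for (cell in unique(key_a)) {
    ia <- which(key_a == cell)
    k0 <- ka[ia[1L], ]
    neigh <- sweep(offs, 2, as.numeric(k0), "+")
    ok <- neigh[, 1] >= 0 & neigh[, 2] >= 0 & neigh[, 3] >= 0 &
      neigh[, 1] < dims[1] & neigh[, 2] < dims[2] & neigh[, 3] < dims[3]
    nkeys <- as.character(neigh[ok, 1] + dims[1] *
                            (neigh[ok, 2] + dims[2] * neigh[ok, 3]))
    jb <- unlist(b_by_cell[nkeys], use.names = FALSE)
    if (length(jb) == 0L) next
    d2 <- outer(rowSums(xyz_a[ia, , drop = FALSE]^2),
                rowSums(xyz_b[jb, , drop = FALSE]^2), "+") -
      2 * xyz_a[ia, , drop = FALSE] %*% t(xyz_b[jb, , drop = FALSE])
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    out_i <- c(out_i, list(ia[hit[, 1]]))
    out_j <- c(out_j, list(jb[hit[, 2]]))
    out_d <- c(out_d, list(sqrt(pmax(d2[hit], 0))))
  }
  if (length(out_i) == 0L) return(empty)
  res <- data.frame(i = unlist(out_i), j = unlist(out_j),
                    dist = unlist(out_d))
  res[res$dist <= cutoff, , drop = FALSE]
}

#' Find binder-histone atomic contacts
#'
#' Returns every heavy-atom pair (one atom from the binder chain, one from
#' a histone chain) whose distance is at or below `cutoff` (default 5
#' Angstroms). DNA chains are not partners for contact scoring (they do
#' participate in clash detection, see [detect_clashes()]).
#'
#' @param model a classified `predicted_model`.
#' @param cutoff contact distance cutoff in Angstroms.
#' @return data.frame with one row per atom pair: binder chain/residue/atom,
#'   histone chain/residue/atom, `histone_type`, `dist`.
#' @export
find_atom_contacts <- function(model, cutoff = 5.0) {
  stopifnot(cutoff > 0)
  binder <- .chains_with_role(model, "BINDER")
  histones <- model$chains$chain_id[
    model$chains$role %in% c("H2A", "H2B", "H3", "H4")]
  if (length(binder) == 0L || length(histones) == 0L)
    stop("model must have a BINDER chain and at least one histone chain",
         call. = FALSE)
  ab <- .atoms_of_chains(model, binder)
  ah <- .atoms_of_chains(model, histones)
  hits <- .grid_pairs(as.matrix(ab[, c("x", "y", "z")]),
                      as.matrix(ah[, c("x", "y", "z")]), cutoff)
  role_of <- stats::setNames(model$chains$role, model$chains$chain_id)
  out <- data.frame(
    binder_chain = ab$chain_id[hits$i],
    binder_resno = ab$resno[hits$i],
    binder_elety = ab$elety[hits$i],
    histone_chain = ah$chain_id[hits$j],
    histone_resno = ah$resno[hits$j],
    histone_elety = ah$elety[hits$j],
    histone_type = unname(role_of[ah$chain_id[hits$j]]),
    dist = hits$dist,
    stringsAsFactors = FALSE
  )
  out[order(out$binder_chain, out$binder_resno, out$histone_chain,
            out$histone_resno, out$dist), , drop = FALSE]
}

#' Collapse atom contacts to residue pairs
#'
#' Confidence weighting operates on amino-acid contacting pairs, so atomic
#' contacts are deduplicated to one entry per distinct (binder residue,
#' histone residue) with the minimum atom-atom distance retained.
#'
#' @param atom_contacts output of [find_atom_contacts()].
#' @param model_id identifier stored on the resulting set.
#' @return A `contact_set`: list with `model_id` and `pairs`, a data.frame
#'   with columns `binder_chain`, `binder_resno`, `histone_chain`,
#'   `histone_resno`, `histone_type`, `min_dist`.
#' @export
dedupe_to_residue_pairs <- function(atom_contacts, model_id = "") {
  if (nrow(atom_contacts) == 0L) {
    pairs <- data.frame(binder_chain = character(0),
                        binder_resno = integer(0),
                        histone_chain = character(0),
                        histone_resno = integer(0),
                        histone_type = character(0),
                        min_dist = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(model_id = model_id, pairs = pairs),
                     class = "contact_set"))
  }
  key <- paste(atom_contacts$binder_chain, atom_contacts$binder_resno,
               atom_contacts$histone_chain, atom_contacts$histone_resno,
               sep = "\r")
  first <- !duplicated(key)
  pairs <- atom_contacts[first, c("binder_chain", "binder_resno",
                                  "histone_chain", "histone_resno",
                                  "histone_type"), drop = FALSE]
  pairs$min_dist <- as.numeric(
    tapply(atom_contacts$dist, key, min)[key[first]])
  pairs <- pairs[order(pairs$binder_chain, pairs$binder_resno,
                       pairs$histone_chain, pairs$histone_resno), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(model_id = model_id, pairs = pairs), class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("Contact set for model '", x$model_id, "': ", nrow(x$pairs),
      " residue pairs\n", sep = "")
  if (nrow(x$pairs) > 0L) print(utils::head(x$pairs, 10L))
  invisible(x)
}

#' Detect steric clashes involving the binder
#'
#' A model is excluded from scoring when the predictor's own clash flag is
#' set, or when the number of binder heavy atoms closer than `clash_dist`
#' to any histone or DNA heavy atom exceeds `tolerance`. The default 1.2
#' Angstroms is an uncontroversial hard-sphere violation for heavy atoms.
#'
#' @param model a classified `predicted_model`.
#' @param confidence optional `confidence_bundle` carrying the predictor
#'   clash flag.
#' @param clash_dist distance (Angstroms) below which an atom pair counts
#'   as clashing.
#' @param tolerance number of clashing atom pairs tolerated before the
#'   model is excluded.
#' @return A `clash_report`: list with `has_confidence_clash`,
#'   `n_histone_clash_atom_pairs`, `excluded`.
#' @export
detect_clashes <- function(model, confidence = NULL, clash_dist = 1.2,
                           tolerance = 0L) {
  binder <- .chains_with_role(model, "BINDER")
  partners <- model$chains$chain_id[
    model$chains$role %in% c("H2A", "H2B", "H3", "H4", "DNA")]
  ab <- .atoms_of_chains(model, binder)
  ah <- .atoms_of_chains(model, partners)
  hits <- .grid_pairs(as.matrix(ab[, c("x", "y", "z")]),
                      as.matrix(ah[, c("x", "y", "z")]), clash_dist)
  n_clash <- sum(hits$dist < clash_dist)  # strictly-below per the contract
  flag <- !is.null(confidence) && isTRUE(confidence$has_clash)
  structure(list(has_confidence_clash = flag,
                 n_histone_clash_atom_pairs = n_clash,
                 excluded = flag || n_clash > tolerance),
            class = "clash_report")
}

#' @export
print.clash_report <- function(x, ...) {
  cat("Clash report: predictor flag =", x$has_confidence_clash,
      "; geometric clash pairs =", x$n_histone_clash_atom_pairs,
      "; excluded =", x$excluded, "\n")
  invisible(x)
}

#' Histone-combination category of a contact set
#'
#' Which of the four core histone types the binder touches. The 15
#' non-empty subsets of \{H2A, H2B, H3, H4\} are the theoretical binding
#' categories; an empty result means "no histone contact" and is reported
#' outside the 15 categories.
#'
#' @param contacts a `contact_set`.
#' @return Sorted character vector, a subset of `c("H2A","H2B","H3","H4")`
#'   (possibly empty).
#' @export
histone_combination <- function(contacts) {
  stopifnot(inherits(contacts, "contact_set"))
  sort(unique(contacts$pairs$histone_type))
}

#' All theoretical histone-combination categories
#'
#' @return Character vector of the 15 non-empty subsets of the four core
#'   histones, each encoded as `"+"`-joined sorted type names.
#' @export
histone_combination_levels <- function() {
  types <- c("H2A", "H2B", "H3", "H4")
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(types, k, paste, collapse = "+", simplify = FALSE)))
  as.character(combos)
}

#' Export a contact set as a tab-separated table
#'
#' @param contacts a `contact_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(contacts, path) {
  stopifnot(inherits(contacts, "contact_set"))
  df <- cbind(model_id = contacts$model_id, contacts$pairs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
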