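# Uniform in-memory representation of one predicted complex model.
#
# A `predicted_model` is a list of three aligned data.frames:
#   atoms    - one row per heavy atom (chain_id, resno, resid, aa, elety,
#              elesy, x, y, z, o, b)
#   residues - one row per polymer residue (chain_id, resno, aa, nucleic,
#              plddt), in file order; this order defines the confidence
#              token order
#   chains   - one row per chain (chain_id, role, nucleic, n_res)
# Author residue numbering (resno) is the coordinate convention throughout;
# mmCIF label_seq is ignored.

.nucleic_resids <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI",
                     "N", "DN")

.res_one_letter <- function(resid, nucleic) {
  out <- character(length(resid))
  if (any(nucleic)) out[nucleic] <- substring(resid[nucleic],
                                              nchar(resid[nucleic]))
  if (any(!nucleic)) out[!nucleic] <- bio3d::aa321(resid[!nucleic])
  out[is.na(out) | out == ""] <- "X"
  out
}

.model_from_bio3d <- function(pdb, model_id, source_path) {
  at <- pdb$atom
  keep <- !(at$elesy %in% c("H", "D")) & at$type %in% c("ATOM", "HETATM")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: ", source_path, call. = FALSE)
  at$b[is.na(at$b)] <- 0
  at$o[is.na(at$o)] <- 1
  nucleic <- at$resid %in% .nucleic_resids
  atoms <- data.frame(
    chain_id = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    aa = .res_one_letter(as.character(at$resid), nucleic),
    elety = as.character(at$elety),
    elesy = as.character(at$elesy),
    x = at$x, y = at$y, z = at$z,
    o = at$o, b = at$b,
    stringsAsFactors = FALSE
  )
  .model_from_atoms(atoms, model_id, source_path)
}

# build a predicted_model from an atom table (see header for columns)
.model_from_atoms <- function(atoms, model_id, source_path = "") {
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", source_path, call. = FALSE)
  nucleic <- atoms$resid %in% .nucleic_resids
  key <- !duplicated(paste(atoms$chain_id, atoms$resno))
  residues <- data.frame(
    chain_id = atoms$chain_id[key],
    resno = atoms$resno[key],
    aa = atoms$aa[key],
    nucleic = nucleic[key],
    stringsAsFactors = FALSE
  )
  # per-residue pLDDT: B-factor of the representative atom (CA, or C1' for
  # nucleotides), mean atom B-factor when absent
  rk <- paste(atoms$chain_id, atoms$resno)
  rep_atom <- ifelse(residues$nucleic, "C1'", "CA")
  plddt <- vapply(seq_len(nrow(residues)), function(i) {
    sel <- rk == paste(residues$chain_id[i], residues$resno[i])
    hit <- sel & atoms$elety == rep_atom[i]
    if (any(hit)) atoms$b[which(hit)[1L]] else mean(atoms$b[sel])
  }, numeric(1))
  residues$plddt <- pmin(pmax(plddt, 0), 100)

  ck <- !duplicated(residues$chain_id)
  chains <- data.frame(
    chain_id = residues$chain_id[ck],
    role = "UNKNOWN",
    nucleic = tapply(residues$nucleic, residues$chain_id, all)[
      residues$chain_id[ck]],
    n_res = as.integer(table(residues$chain_id)[residues$chain_id[ck]]),
    stringsAsFactors = FALSE
  )
  rownames(chains) <- NULL
  structure(list(model_id = model_id, source_path = source_path,
                 atoms = atoms, residues = residues, chains = chains,
                 classified = FALSE),
            class = "predicted_model")
}

#' Read a predicted complex structure
#'
#' Loads a PDB or mmCIF file into a `predicted_model`: all chains, residues
#' and heavy atoms (hydrogens are dropped), with per-residue pLDDT taken
#' from the B-factor column of the representative atom (C-alpha, or C1' for
#' nucleotides). Chain roles are `UNKNOWN` until [classify_chains()] is run.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (decide from the extension).
#' @param model_id identifier carried through all downstream results;
#'   defaults to the file name without extension.
#' @return A `predicted_model`.
#' @seealso [classify_chains()], [read_confidence()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path))
    else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse ", format, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  .model_from_bio3d(pdb, model_id = model_id, source_path = path)
}

#' Residue token map of a model
#'
#' Confidence data (PAE matrix, pLDDT vector) are indexed by token, one
#' token per polymer residue in file order. Returns the mapping between
#' (chain, author residue number) and token index.
#'
#' @param model a `predicted_model`.
#' @return data.frame with columns `chain_id`, `resno`, `token` (1-based).
#' @export
token_map <- function(model) {
  stopifnot(inherits(model, "predicted_model"))
  data.frame(chain_id = model$residues$chain_id,
             resno = model$residues$resno,
             token = seq_len(nrow(model$residues)),
             stringsAsFactors = FALSE)
}

.token_lookup <- function(tm, chain_id, resno) {
  idx <- match(paste(chain_id, resno), paste(tm$chain_id, tm$resno))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("residue ", chain_id[bad], ":", resno[bad],
         " is missing from the confidence token map", call. = FALSE)
  }
  tm$token[idx]
}

#' Read an AlphaFold-style confidence file for a model
#'
#' Parses a JSON confidence object holding the token-level predicted
#' aligned error (PAE) matrix and the predictor's clash flag. Two dialects
#' are accepted: the server style (`pae` square array plus `has_clash`) and
#' the flat fixture dialect written by [write_fixture_files()] (identical
#' fields, optional `plddt` vector). When `plddt` is absent the per-residue
#' pLDDT stored in the model's B-factors is used.
#'
#' @param path path to the JSON confidence file.
#' @param model the `predicted_model` the confidences belong to; its residue
#'   count must equal the PAE matrix dimension.
#' @return A `confidence_bundle`: list with `pae` (n x n matrix, Angstrom-like
#'   units), `token_map`, `has_clash`, `plddt_by_token`.
#' @export
read_confidence <- function(path, model) {
  stopifnot(inherits(model, "predicted_model"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$pae))
    stop("confidence file ", path, " has no 'pae' field", call. = FALSE)
  pae <- as.matrix(obj$pae)
  if (nrow(pae) != ncol(pae))
    stop("PAE matrix is not square: ", nrow(pae), " x ", ncol(pae),
         call. = FALSE)
  n <- nrow(model$residues)
  if (nrow(pae) != n)
    stop("confidence token count (", nrow(pae),
         ") does not match model residue count (", n, ")", call. = FALSE)
  if (any(pae < 0)) stop("negative PAE values in ", path, call. = FALSE)
  plddt <- if (!is.null(obj$plddt)) as.numeric(obj$plddt)
           else model$residues$plddt
  if (length(plddt) != n)
    stop("pLDDT vector length (", length(plddt),
         ") does not match model residue count (", n, ")", call. = FALSE)
  if (any(plddt < 0 | plddt > 100))
    stop("pLDDT values outside [0, 100] in ", path, call. = FALSE)
  structure(list(pae = unname(pae), token_map = token_map(model),
                 has_clash = isTRUE(as.logical(obj$has_clash)),
                 plddt_by_token = plddt),
            class = "confidence_bundle")
}

#' Write a confidence bundle to JSON
#'
#' Serializes a PAE matrix, clash flag and pLDDT vector in the flat dialect
#' read back by [read_confidence()].
#'
#' @param pae square numeric matrix.
#' @param path output path.
#' @param has_clash predictor clash flag.
#' @param plddt optional per-token pLDDT vector.
#' @return `path`, invisibly.
#' @export
write_confidence <- function(pae, path, has_clash = FALSE, plddt = NULL) {
  stopifnot(is.matrix(pae), nrow(pae) == ncol(pae))
  obj <- list(pae = pae, has_clash = has_clash)
  if (!is.null(plddt)) obj$plddt <- plddt
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# identity of a chain sequence against a reference: matching columns of an
# ends-free global alignment, as a percentage of the shorter sequence.
# Normalizing by the shorter length keeps short spurious overlaps from
# scoring high while full-length truncated constructs still reach 100%.
.seq_identity <- function(seq, ref) {
  if (nchar(seq) == 0L) return(0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(seq),
    type = "overlap", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4)
  100 * Biostrings::nmatch(aln) / min(nchar(seq), nchar(ref))
}

#' One-letter sequence of a chain
#'
#' @param model a `predicted_model`.
#' @param chain_id chain identifier.
#' @return Character scalar.
#' @export
chain_sequence <- function(model, chain_id) {
  sel <- model$residues$chain_id == chain_id
  if (!any(sel)) stop("no chain '", chain_id, "' in model", call. = FALSE)
  paste(model$residues$aa[sel], collapse = "")
}

#' Assign biological roles to the chains of a model
#'
#' Every nucleotide chain becomes `DNA`. Each protein chain is aligned
#' against the four shipped histone references; a chain reaching at least
#' `min_identity` percent sequence identity is assigned that histone role
#' (ties broken by highest identity), and any chain below the threshold for
#' all four references is the candidate `BINDER`. Exactly one binder chain
#' must remain, otherwise an error lists the assigned roles. The operation
#' is idempotent.
#'
#' @param model a `predicted_model`.
#' @param references named character vector of histone reference sequences
#'   (`H2A`, `H2B`, `H3`, `H4`); defaults to [histone_references()].
#' @param min_identity identity threshold (percent) for histone assignment.
#' @return The model with `chains$role` filled in and `classified = TRUE`.
#' @export
classify_chains <- function(model, references = histone_references(),
                            min_identity = 80) {
  stopifnot(inherits(model, "predicted_model"))
  stopifnot(all(c("H2A", "H2B", "H3", "H4") %in% names(references)))
  roles <- character(nrow(model$chains))
  for (i in seq_len(nrow(model$chains))) {
    if (isTRUE(model$chains$nucleic[i])) { roles[i] <- "DNA"; next }
    seq <- chain_sequence(model, model$chains$chain_id[i])
    ident <- vapply(references, .seq_identity, numeric(1), seq = seq)
    best <- which.max(ident)
    roles[i] <- if (ident[best] >= min_identity) names(references)[best]
                else "BINDER"
  }
  n_binder <- sum(roles == "BINDER")
  if (n_binder != 1L)
    stop("expected exactly one BINDER chain after classification, found ",
         n_binder, " (roles: ",
         paste(model$chains$chain_id, roles, sep = "=", collapse = ", "),
         ")", call. = FALSE)
  model$chains$role <- roles
  model$classified <- TRUE
  model
}

#' @export
print.predicted_model <- function(x, ...) {
  cat("Predicted complex model '", x$model_id, "'\n", sep = "")
  cat("  ", nrow(x$chains), " chains, ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms\n", sep = "")
  role <- if (x$classified) x$chains$role else rep("?", nrow(x$chains))
  cat("  chains:", paste(x$chains$chain_id, role, sep = ":", collapse = " "),
      "\n")
  invisible(x)
}

# chain ids holding a given role (model must be classified)
.chains_with_role <- function(model, role) {
  if (!isTRUE(model$classified))
    stop("model is not classified; run classify_chains() first",
         call. = FALSE)
  model$chains$chain_id[model$chains$role %in% role]
}

# atom-table subset for a set of chains; columns plus global atom index
.atoms_of_chains <- function(model, chain_ids) {
  idx <- which(model$atoms$chain_id %in% chain_ids)
  cbind(model$atoms[idx, , drop = FALSE], atom_idx = idx)
}
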