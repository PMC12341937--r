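# Fully synthetic mini-nucleosome fixtures.
#
# The screening method depends only on inter-atomic distances and
# confidence values, so fixtures are built from ideal C-alpha traces (one
# heavy atom per residue, 3.8 A spacing) on well-separated parallel lanes,
# with no attempt at physical realism. Every planted quantity -- contact
# distances, clashes, PAE entries, pLDDT values -- is known exactly and is
# recoverable by the corresponding analysis operation.

.FIX_SPACING <- 3.8   # A between consecutive residues along a lane
.FIX_LANE <- 24       # A between chain lanes

#' Specify a synthetic mini-nucleosome fixture
#'
#' The fixture holds eight short histone chains (two copies each of H2A,
#' H2B, H3 and H4, embedding exact subsequences of the shipped reference
#' sequences so [classify_chains()] exercises its real alignment path; the
#' H2A window always ends at reference position 93, so the full acidic
#' patch is present whenever `n_histone_res >= 37`), two short DNA
#' strands, and one binder chain.
#'
#' @param seed integer seed; fixture generation is a pure function of seed
#'   plus spec (identical bytes on re-run).
#' @param n_histone_res residues per histone chain (max 83, so every
#'   window fits inside the reference tailless constructs).
#' @param n_dna nucleotides per DNA strand.
#' @param binder_length binder residues (ignored when `binder_sequence` is
#'   given).
#' @param binder_sequence optional explicit binder sequence (one-letter).
#' @param planted_contacts data.frame(`binder_resno`, `histone_chain`,
#'   `histone_resno`, `dist`): each row is realized as the minimum
#'   heavy-atom distance between the two residues.
#' @param clash_pairs same columns; distances below the clash threshold.
#' @param planted_pae data.frame(`chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `value`); entries are planted in both matrix directions
#'   unless a logical `symmetric` column says otherwise. All other entries
#'   hold `pae_default`.
#' @param planted_plddt data.frame(`chain_id`, `resno`, `value`); all other
#'   residues hold `plddt_default`.
#' @param has_clash predictor clash flag to store in the confidence file.
#' @param pae_default,plddt_default background confidence values. The PAE
#'   default of 31.75 makes every non-planted contact weigh exactly zero.
#' @param contact_cutoff,margin placement validation: no unplanned
#'   binder-nucleosome residue pair may fall below `contact_cutoff +
#'   margin` (clash-planted binder residues exempt).
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_histone_res = 40L, n_dna = 10L,
                         binder_length = 30L, binder_sequence = NULL,
                         planted_contacts = NULL, clash_pairs = NULL,
                         planted_pae = NULL, planted_plddt = NULL,
                         has_clash = FALSE, pae_default = 31.75,
                         plddt_default = 50, contact_cutoff = 5.0,
                         margin = 0.5) {
  stopifnot(n_histone_res >= 2L, n_histone_res <= 83L, n_dna >= 1L,
            binder_length >= 1L, pae_default >= 0,
            plddt_default >= 0, plddt_default <= 100)
  structure(list(seed = as.integer(seed), n_histone_res = n_histone_res,
                 n_dna = n_dna, binder_length = binder_length,
                 binder_sequence = binder_sequence,
                 planted_contacts = planted_contacts,
                 clash_pairs = clash_pairs, planted_pae = planted_pae,
                 planted_plddt = planted_plddt,
                 has_clash = isTRUE(has_clash),
                 pae_default = pae_default, plddt_default = plddt_default,
                 contact_cutoff = contact_cutoff, margin = margin),
            class = "fixture_spec")
}

# chain roster: id, histone type (or DNA/BINDER), reference start position
.fixture_roster <- function(spec) {
  n <- spec$n_histone_res
  starts <- c(H3 = 39L, H4 = 21L, H2A = max(12L, 94L - n), H2B = 32L)
  data.frame(
    chain_id = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"),
    kind = c("H3", "H4", "H2A", "H2B", "H3", "H4", "H2A", "H2B",
             "DNA", "DNA", "BINDER"),
    start = c(starts, starts, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

.random_protein_seq <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

#' Build the mini-nucleosome model of a fixture
#'
#' Lays out the 11 chains of the fixture on parallel lanes (one C-alpha or
#' C1' atom per residue at 3.8 A spacing; lanes 24 A apart; the binder
#' lane 48 A away from the nucleosome lanes, to be repositioned by
#' [place_binder()]). Histone chains carry author numbering equal to their
#' reference positions; planted pLDDT values are written into the atom
#' B-factors so the model and its confidence file agree.
#'
#' @param spec a `fixture_spec`.
#' @return An unclassified `predicted_model`.
#' @export
make_mini_nucleosome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  refs <- histone_references()
  roster <- .fixture_roster(spec)
  dna_codes <- strsplit(paste(rep("ACGT", ceiling(spec$n_dna / 4)),
                              collapse = ""), "")[[1L]][seq_len(spec$n_dna)]
  binder_seq <- spec$binder_sequence
  if (is.null(binder_seq))
    binder_seq <- .random_protein_seq(spec$binder_length, spec$seed)
  rows <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    kind <- roster$kind[i]
    if (kind %in% c("H2A", "H2B", "H3", "H4")) {
      start <- roster$start[i]
      aa <- strsplit(substring(refs[[kind]], start,
                               start + spec$n_histone_res - 1L), "")[[1L]]
      resno <- seq(start, length.out = length(aa))
      resid <- bio3d::aa123(aa)
      elety <- "CA"; elesy <- "C"
    } else if (kind == "DNA") {
      aa <- dna_codes
      resno <- seq_along(aa)
      resid <- paste0("D", aa)
      elety <- "C1'"; elesy <- "C"
    } else {
      aa <- strsplit(binder_seq, "")[[1L]]
      resno <- seq_along(aa)
      resid <- bio3d::aa123(aa)
      elety <- "CA"; elesy <- "C"
    }
    lane_y <- if (kind == "BINDER") -2 * .FIX_LANE
              else (i - 1) * .FIX_LANE
    rows[[i]] <- data.frame(
      chain_id = roster$chain_id[i], resno = as.integer(resno),
      resid = resid, aa = aa, elety = elety, elesy = elesy,
      x = (seq_along(aa) - 1) * .FIX_SPACING, y = lane_y, z = 0,
      o = 1, b = spec$plddt_default, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(spec$planted_plddt)) {
    pp <- spec$planted_plddt
    idx <- match(paste(pp$chain_id, pp$resno),
                 paste(atoms$chain_id, atoms$resno))
    if (anyNA(idx))
      stop("planted pLDDT references an unknown residue", call. = FALSE)
    atoms$b[idx] <- pp$value
  }
  .model_from_atoms(atoms, model_id = paste0("fixture_seed", spec$seed))
}

#' Place the binder to realize planted contacts and clashes
#'
#' Moves each planted binder residue so that its minimum heavy-atom
#' distance to the planted histone (or DNA) residue equals the planted
#' value exactly; unplanted binder residues stay on the distant binder
#' lane. Placement is then validated by brute force: every planted
#' distance must reproduce, and no unplanned binder-nucleosome residue
#' pair may fall below `contact_cutoff + margin` (binder residues planted
#' as clashes are exempt, since a sub-clash placement necessarily drags
#' them near neighbouring residues).
#'
#' @param model model from [make_mini_nucleosome()].
#' @param spec the same `fixture_spec`.
#' @return The model with the binder repositioned.
#' @export
place_binder <- function(model, spec) {
  plants <- rbind(
    if (!is.null(spec$planted_contacts)) spec$planted_contacts,
    if (!is.null(spec$clash_pairs)) spec$clash_pairs)
  if (is.null(plants) || nrow(plants) == 0L) return(model)
  if (anyDuplicated(plants$binder_resno))
    stop("infeasible geometry: a binder residue has more than one planted",
         " partner", call. = FALSE)
  clash_res <- if (is.null(spec$clash_pairs)) integer(0)
               else spec$clash_pairs$binder_resno
  for (k in seq_len(nrow(plants))) {
    bi <- which(model$atoms$chain_id == "K" &
                  model$atoms$resno == plants$binder_resno[k])
    hi <- which(model$atoms$chain_id == plants$histone_chain[k] &
                  model$atoms$resno == plants$histone_resno[k])
    if (length(bi) == 0L || length(hi) == 0L)
      stop("planted contact references an unknown residue (binder ",
           plants$binder_resno[k], " / ", plants$histone_chain[k], ":",
           plants$histone_resno[k], ")", call. = FALSE)
    model$atoms$x[bi] <- model$atoms$x[hi]
    model$atoms$y[bi] <- model$atoms$y[hi]
    model$atoms$z[bi] <- model$atoms$z[hi] + plants$dist[k]
  }
  # brute-force validation of every planted and unplanned pair
  ab <- model$atoms[model$atoms$chain_id == "K", , drop = FALSE]
  ah <- model$atoms[model$atoms$chain_id != "K", , drop = FALSE]
  d <- sqrt(outer(ab$x, ah$x, "-")^2 + outer(ab$y, ah$y, "-")^2 +
              outer(ab$z, ah$z, "-")^2)
  planted_key <- paste(plants$binder_resno, plants$histone_chain,
                       plants$histone_resno)
  pair_key <- outer(ab$resno, paste(ah$chain_id, ah$resno), paste)
  is_planted <- matrix(pair_key %in% planted_key, nrow = nrow(ab))
  want <- plants$dist[match(pair_key[is_planted], planted_key)]
  if (any(abs(d[is_planted] - want) > 1e-9))
    stop("infeasible geometry: a planted distance did not reproduce",
         call. = FALSE)
  floor_d <- spec$contact_cutoff + spec$margin
  exempt <- ab$resno %in% clash_res
  viol <- !is_planted & d < floor_d & !matrix(exempt, nrow(ab), ncol(d))
  if (any(viol))
    stop("infeasible geometry: unplanned pair within ", floor_d,
         " A of the binder", call. = FALSE)
  model
}

#' Synthesize the confidence bundle of a fixture
#'
#' Square PAE matrix holding `pae_default` (31.75 by default, so every
#' non-planted contact transforms to weight zero) except at planted
#' entries; pLDDT `plddt_default` except planted values; the clash flag as
#' specified; token map consistent with the model.
#'
#' @param model the fixture model (from [place_binder()]).
#' @param spec the same `fixture_spec`.
#' @return A `confidence_bundle`.
#' @export
synth_confidence <- function(model, spec) {
  tm <- token_map(model)
  n <- nrow(tm)
  pae <- matrix(spec$pae_default, n, n)
  if (!is.null(spec$planted_pae)) {
    pp <- spec$planted_pae
    a <- .token_lookup(tm, pp$chain_a, pp$resno_a)
    b <- .token_lookup(tm, pp$chain_b, pp$resno_b)
    sym <- if ("symmetric" %in% names(pp)) pp$symmetric else
      rep(TRUE, nrow(pp))
    pae[cbind(a, b)] <- pp$value
    if (any(sym)) pae[cbind(b[sym], a[sym])] <- pp$value[sym]
  }
  plddt <- rep(spec$plddt_default, n)
  if (!is.null(spec$planted_plddt)) {
    idx <- .token_lookup(tm, spec$planted_plddt$chain_id,
                         spec$planted_plddt$resno)
    plddt[idx] <- spec$planted_plddt$value
  }
  structure(list(pae = pae, token_map = tm, has_clash = spec$has_clash,
                 plddt_by_token = plddt),
            class = "confidence_bundle")
}

# minimal mmCIF writer for fixture models (atom_site loop with auth fields)
.write_mmcif <- function(model, path) {
  a <- model$atoms
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  ent <- match(a$chain_id, unique(a$chain_id))
  rec <- sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    seq_len(nrow(a)), a$elesy, a$elety, a$resid, a$chain_id, ent, a$resno,
    a$x, a$y, a$z, a$o, a$b, a$resno, a$resid, a$chain_id, a$elety)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Generate and write a complete fixture to disk
#'
#' Builds the mini-nucleosome, places the binder, synthesizes the
#' confidence data, and writes three files to `dir`: `<stem>.cif` (the
#' model), `<stem>_confidence.json` (flat confidence dialect) and
#' `<stem>_manifest.tsv` (a table of all planted truths for test
#' assertions). Output is byte-identical across re-runs with the same
#' spec.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return List with `model`, `confidence`, and the three `paths`.
#' @export
write_fixture_files <- function(spec, dir, stem = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- place_binder(make_mini_nucleosome(spec), spec)
  conf <- synth_confidence(model, spec)
  cif <- file.path(dir, paste0(stem, ".cif"))
  json <- file.path(dir, paste0(stem, "_confidence.json"))
  man <- file.path(dir, paste0(stem, "_manifest.tsv"))
  .write_mmcif(model, cif)
  write_confidence(conf$pae, json, has_clash = conf$has_clash,
                   plddt = conf$plddt_by_token)
  truth <- rbind(
    if (!is.null(spec$planted_contacts))
      cbind(kind = "contact", spec$planted_contacts),
    if (!is.null(spec$clash_pairs))
      cbind(kind = "clash", spec$clash_pairs))
  if (is.null(truth))
    truth <- data.frame(kind = character(0), binder_resno = integer(0),
                        histone_chain = character(0),
                        histone_resno = integer(0), dist = numeric(0))
  utils::write.table(truth, man, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(model = model, confidence = conf,
       paths = list(model = cif, confidence = json, manifest = man))
}
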