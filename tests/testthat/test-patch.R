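test_that("patch centroid is the unweighted heavy-atom mean", {
  fx <- fx_model(seed = 41)
  m <- fx$model
  cen <- patch_centroid(m, face = "C")
  # independent averaging over AP1 u AP2 residues of chain C
  defn <- acidic_patch_definition()
  pocket <- sort(unique(c(defn$ap1, defn$ap2)))
  sel <- m$atoms$chain_id == "C" & m$atoms$resno %in% pocket
  expect_equal(unname(cen),
               unname(colMeans(as.matrix(m$atoms[sel, c("x", "y", "z")]))),
               tolerance = 1e-12)

  # single-atom and midpoint degenerate cases on a hand-built pocket
  h2a <- histone_references()[["H2A"]]
  hseq <- strsplit(substr(h2a, 54, 93), "")[[1]]
  mkrow <- function(resno, aa, x, y = 0, z = 0)
    data.frame(chain_id = "C", resno = resno, resid = bio3d::aa123(aa),
               aa = aa, elety = "CA", elesy = "C", x = x, y = y, z = z,
               o = 1, b = 50, stringsAsFactors = FALSE)
  atoms <- do.call(rbind, lapply(seq_along(hseq), function(i)
    mkrow(53 + i, hseq[i], (i - 1) * 3.8)))
  # collapse the pocket to two points at (0,0,0) and (2,0,0)
  atoms$x[atoms$resno %in% c(62, 65)] <- 0
  atoms$y[atoms$resno %in% c(62, 65)] <- 0
  atoms$x[atoms$resno %in% c(91, 93)] <- 2
  atoms$y[atoms$resno %in% c(91, 93)] <- 0
  binder <- do.call(rbind, lapply(1:5, function(i)
    mkrow(i, "W", 200 + (i - 1) * 3.8)))
  binder$chain_id <- "K"
  m2 <- classify_chains(nucscreen:::.model_from_atoms(rbind(atoms, binder),
                                                      "mid"))
  expect_equal(unname(patch_centroid(m2, face = "C")), c(1, 0, 0))
  # a missing pocket residue is reported by reference position
  atoms2 <- atoms[atoms$resno != 91, ]
  m3 <- classify_chains(nucscreen:::.model_from_atoms(
    rbind(atoms2, binder), "gap"))
  expect_error(patch_centroid(m3, face = "C"), "missing on chain C")
})

test_that("patch-proximal binder residues split into consecutive segments", {
  fx <- fx_model(seed = 42)
  m <- fx$model
  cen <- patch_centroid(m, face = "C")
  for (r in 10:14) m <- move_binder_residue(m, r, cen + c((r - 12), 0, 3))
  m <- move_binder_residue(m, 30, cen + c(0, 4, 0))
  pcs <- binder_patch_residues(m)
  expect_equal(pcs$face, "C")
  expect_equal(pcs$residues, c(10:14, 30))
  expect_equal(pcs$segments, list(10:14, 30L))
  # brute-force distance check: all residues really are within 5 A
  ab <- m$atoms[m$atoms$chain_id == "K", ]
  d <- sqrt((ab$x - cen[1])^2 + (ab$y - cen[2])^2 + (ab$z - cen[3])^2)
  expect_equal(sort(unique(ab$resno[d <= 5])), pcs$residues)

  # boundary: 4.9 A in, beyond 5 A out
  m4 <- move_binder_residue(fx$model, 5, cen + c(0, 0, 4.9))
  expect_true(5 %in% binder_patch_residues(m4)$residues)
  m5 <- move_binder_residue(fx$model, 5, cen + c(0, 0, 5.2))
  expect_equal(length(binder_patch_residues(m5)$residues), 0L)
})

test_that("representative segment is longest, with seeded tie-breaks", {
  mkpcs <- function(segs) structure(
    list(model_id = "m", face = "C", centroid = c(0, 0, 0),
         residues = sort(unlist(segs)), segments = segs),
    class = "patch_contacts")
  expect_equal(select_representative_segment(mkpcs(list(1:5, 20:30))),
               20:30, ignore_attr = TRUE)
  expect_equal(select_representative_segment(mkpcs(list(7:9))), 7:9,
               ignore_attr = TRUE)
  tie <- mkpcs(list(1:5, 11:15))
  picks <- replicate(5, select_representative_segment(tie, seed = 123),
                     simplify = FALSE)
  expect_true(all(vapply(picks, identical, logical(1), picks[[1]])))
  expect_error(select_representative_segment(mkpcs(list())), "no patch")
})

test_that("histone superposition recovers rigid motion exactly", {
  fx <- fx_model(seed = 43)
  sp0 <- superpose_on_histones(fx$model, fx$model)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-10)

  moved <- rotate_model(fx$model, theta = 1.2, shift = c(-4, 8, 15))
  sp <- superpose_on_histones(fx$model, moved)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)

  # one displaced histone C-alpha: rmsd equals the quaternion oracle
  bumped <- fx$model
  i <- which(bumped$atoms$chain_id == "A" & bumped$atoms$resno == 50)
  bumped$atoms$z[i] <- bumped$atoms$z[i] + 1
  sp2 <- superpose_on_histones(fx$model, rotate_model(bumped))
  hist_chains <- c("A", "B", "C", "D", "E", "F", "G", "H")
  A <- as.matrix(fx$model$atoms[fx$model$atoms$chain_id %in% hist_chains,
                                c("x", "y", "z")])
  B0 <- rotate_model(bumped)
  B <- as.matrix(B0$atoms[B0$atoms$chain_id %in% hist_chains,
                          c("x", "y", "z")])
  expect_equal(sp2$rmsd, horn_rmsd(A, B), tolerance = 1e-9)
})

test_that("patch RMSD matrix yields all pairs and survives permutation", {
  fx <- fx_model(seed = 44)
  base <- fx$model
  cen <- patch_centroid(base, face = "C")
  for (r in 8:12) base <- move_binder_residue(base, r,
                                              cen + c(r - 10, 0, 2))
  shifts <- c(0, 0.4, 0.5, 0.45, 2.0)
  models <- lapply(shifts, function(s) {
    m <- base
    for (r in 8:12) {
      i <- m$atoms$chain_id == "K" & m$atoms$resno == r
      m$atoms$z[i] <- m$atoms$z[i] + s
    }
    m
  })
  pcs <- lapply(models, binder_patch_residues)
  cr <- patch_rmsd_matrix(models, pcs, "perturbed")
  expect_equal(length(cr$rmsd_pairs), 10L)
  expect_false(cr$undefined)
  # oracle: identical equal displacement on every atom -> rmsd = |ds|
  want <- apply(utils::combn(5, 2), 2,
                function(p) abs(shifts[p[1]] - shifts[p[2]]))
  expect_equal(unname(cr$rmsd_pairs), want, tolerance = 1e-9)

  # identical models give ten zeros and a perfect score
  same <- lapply(1:5, function(i) base)
  pcs0 <- lapply(same, binder_patch_residues)
  cr0 <- patch_rmsd_matrix(same, pcs0, "identical")
  expect_equal(unname(cr0$rmsd_pairs), rep(0, 10), tolerance = 1e-10)

  # permutation leaves the multiset of pairwise values unchanged
  perm <- c(3, 1, 5, 2, 4)
  crp <- patch_rmsd_matrix(models[perm], pcs[perm], "perm")
  expect_equal(sort(round(unname(crp$rmsd_pairs), 9)),
               sort(round(unname(cr$rmsd_pairs), 9)))
})

test_that("mode RMSD is the center of the most populated bin", {
  expect_equal(mode_rmsd(c(0.51, 0.52, 0.55, 2.0, 3.1)), 0.55)
  expect_equal(mode_rmsd(rep(1.23, 6)), 1.23)  # degenerate bin snaps
  expect_equal(mode_rmsd(rep(0, 10)), 0)       # identical models
  expect_equal(mode_rmsd(0.31), 0.31)
  # tie goes to the lowest bin
  expect_equal(mode_rmsd(c(0.11, 0.12, 0.81, 0.82)), 0.15)
  expect_error(mode_rmsd(numeric(0)), "no RMSD")
})

test_that("consistency scores live in [0,1] with the stated endpoints", {
  expect_equal(consistency_score(0, 4.8), 1.0)
  expect_equal(consistency_score(4.8, 4.8), 0.0)
  expect_equal(consistency_score(1.2, 4.8), 0.75)
  expect_error(consistency_score(1, 0), "positive")
  set.seed(7)
  modes <- runif(50, 0, 6)
  sc <- consistency_score(modes, max(modes))
  expect_true(all(sc >= 0 & sc <= 1))
  # monotone decreasing in the mode within a fixed cohort
  expect_true(all(diff(sc[order(modes)]) <= 0))
})

test_that("motif windows are 21 long, centered on R/K, gap-padded", {
  seqchars <- rep("A", 40); seqchars[15] <- "R"; seqchars[1] <- "K"
  bseq <- paste(seqchars, collapse = "")
  w15 <- motif_window(bseq, 15)
  expect_equal(nchar(w15), 21L)
  expect_equal(substr(w15, 11, 11), "R")
  expect_equal(w15, paste(seqchars[5:25], collapse = ""))
  w1 <- motif_window(bseq, 1)
  expect_equal(substr(w1, 1, 10), "----------")
  expect_equal(substr(w1, 11, 11), "K")

  # end-to-end: an arginine anchored at AP1 yields one window
  bs <- paste(c(rep("A", 9), "R", rep("G", 20)), collapse = "")
  fx <- fx_model(seed = 45, binder_sequence = bs, planted = data.frame(
    binder_resno = 10, histone_chain = "C", histone_resno = 62,
    dist = 4.0))
  mw <- motif_windows(fx$model)
  expect_equal(nrow(mw), 1L)
  expect_equal(mw$center_resno, 10)
  expect_equal(substr(mw$window, 11, 11), "R")
  expect_equal(nchar(mw$window), 21L)

  # no Arg/Lys at the pocket -> no windows
  bs2 <- paste(rep("A", 30), collapse = "")
  fx2 <- fx_model(seed = 46, binder_sequence = bs2, planted = data.frame(
    binder_resno = 10, histone_chain = "C", histone_resno = 62,
    dist = 4.0))
  expect_equal(nrow(motif_windows(fx2$model)), 0L)
})

test_that("benchmark calls use symmetric Jaccard overlap", {
  a <- data.frame(binder_resno = c(10, 11), ap_pos = c(62, 91))
  b <- data.frame(binder_resno = c(10, 12), ap_pos = c(62, 93))
  expect_equal(benchmark_hit(a, a)$jaccard, 1.0)
  expect_true(benchmark_hit(a, a)$positive)
  disj <- data.frame(binder_resno = 20, ap_pos = 65)
  expect_equal(benchmark_hit(a, disj)$jaccard, 0)
  expect_false(benchmark_hit(a, disj)$positive)
  # 1 shared of 3 total
  expect_equal(benchmark_hit(a, b)$jaccard, 1 / 3)
  expect_true(benchmark_hit(a, b)$positive)  # >= 0.3
  expect_equal(benchmark_hit(a, b)$jaccard, benchmark_hit(b, a)$jaccard)
  none <- benchmark_hit(a[0, ], b[0, ])
  expect_true(none$undefined)
  expect_false(none$positive)
})

test_that("patch contact pairs live in the reference numbering frame", {
  fx <- fx_model(seed = 47, planted = data.frame(
    binder_resno = c(5, 9), histone_chain = c("C", "C"),
    histone_resno = c(62, 91), dist = 4.0))
  pp <- patch_contact_pairs(fx$model)
  expect_equal(pp[order(pp$binder_resno), ]$ap_pos, c(62, 91))
  # contacts outside the patch are not patch pairs
  fx2 <- fx_model(seed = 48, planted = data.frame(
    binder_resno = 5, histone_chain = "C", histone_resno = 75, dist = 4.0))
  expect_equal(nrow(patch_contact_pairs(fx2$model)), 0L)
})
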