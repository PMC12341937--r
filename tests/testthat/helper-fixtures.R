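# Shared fixture builders and independent oracles.
# Oracles deliberately use different algorithms from the implementation:
# contacts by full O(n^2) distance enumeration (vs grid cell lists),
# superposition by Horn's quaternion method (vs Kabsch/SVD), knee by
# geometric point-to-chord distance (vs the difference-curve form).

# a classified fixture model plus confidence bundle with planted contacts
fx_model <- function(seed = 1, planted = NULL, pae = NULL, plddt = NULL,
                     clash = NULL, has_clash = FALSE, ...) {
  spec <- fixture_spec(seed = seed, planted_contacts = planted,
                       planted_pae = pae, planted_plddt = plddt,
                       clash_pairs = clash, has_clash = has_clash, ...)
  m <- classify_chains(place_binder(make_mini_nucleosome(spec), spec))
  list(model = m, confidence = synth_confidence(m, spec), spec = spec)
}

# random planted-contact table: n contacts on distinct binder/histone
# residues at distances in [dmin, dmax]
random_plants <- function(n, seed, dmin = 4.0, dmax = 4.9,
                          chains = c("A", "B", "C", "D"),
                          n_histone_res = 40) {
  set.seed(seed)
  starts <- c(A = 39, B = 21, C = max(12, 94 - n_histone_res), D = 32)
  ch <- sample(chains, n, replace = TRUE)
  data.frame(
    binder_resno = sample(30, n),
    histone_chain = ch,
    histone_resno = starts[ch] + sample(n_histone_res, n,
                                        replace = TRUE) - 1,
    dist = round(runif(n, dmin, dmax), 3))
}

# brute-force all-pairs binder-histone contact search
bf_contacts <- function(model, cutoff = 5.0) {
  hist_chains <- model$chains$chain_id[
    model$chains$role %in% c("H2A", "H2B", "H3", "H4")]
  ab <- model$atoms[model$atoms$chain_id %in% "K", , drop = FALSE]
  bc <- model$chains$chain_id[model$chains$role == "BINDER"]
  ab <- model$atoms[model$atoms$chain_id %in% bc, , drop = FALSE]
  ah <- model$atoms[model$atoms$chain_id %in% hist_chains, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(ab))) {
    d <- sqrt((ab$x[i] - ah$x)^2 + (ab$y[i] - ah$y)^2 +
                (ab$z[i] - ah$z)^2)
    hit <- which(d <= cutoff)
    if (length(hit))
      out <- rbind(out, data.frame(
        binder_chain = ab$chain_id[i], binder_resno = ab$resno[i],
        binder_elety = ab$elety[i], histone_chain = ah$chain_id[hit],
        histone_resno = ah$resno[hit], histone_elety = ah$elety[hit],
        dist = d[hit]))
  }
  if (is.null(out))
    out <- data.frame(binder_chain = character(0),
                      binder_resno = integer(0),
                      binder_elety = character(0),
                      histone_chain = character(0),
                      histone_resno = integer(0),
                      histone_elety = character(0), dist = numeric(0))
  out[order(out$binder_chain, out$binder_resno, out$histone_chain,
            out$histone_resno, out$dist), , drop = FALSE]
}

contact_key <- function(df) {
  sort(paste(df$binder_chain, df$binder_resno, df$binder_elety,
             df$histone_chain, df$histone_resno, df$histone_elety))
}

# Horn quaternion absolute orientation: rotate B onto A, return rmsd over
# the fitted points
horn_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- crossprod(Bc, Ac)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), 1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), 1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
}

# geometric knee oracle: max perpendicular distance of the min-max
# normalized curve from the line through its normalized endpoints
knee_oracle <- function(scores, tol = 1e-9) {
  n <- length(scores)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- scores[1] - scores[n]
  if (rng <= 0) return(NA_integer_)
  y <- (scores - scores[n]) / rng
  p1 <- c(x[1], y[1]); p2 <- c(x[n], y[n])
  v <- p2 - p1
  d <- abs(v[1] * (p1[2] - y) - (p1[1] - x) * v[2]) / sqrt(sum(v^2))
  if (max(d) < tol) return(NA_integer_)
  which.max(d)
}

# random convex decreasing curve: increments are negative and increasing
convex_decreasing <- function(n, seed) {
  set.seed(seed)
  inc <- -sort(runif(n - 1, 0.01, 1), decreasing = TRUE)
  cumsum(c(10, inc))
}

# rigid-body motion applied to a whole model
rotate_model <- function(model, theta = 0.9, shift = c(7, -11, 3)) {
  ct <- cos(theta); st <- sin(theta)
  R <- matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, ct, -st, 0, st, ct), 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model
}

# move all atoms of one binder residue to an absolute position
move_binder_residue <- function(model, resno, pos) {
  i <- model$atoms$chain_id == "K" & model$atoms$resno == resno
  model$atoms$x[i] <- pos[1]; model$atoms$y[i] <- pos[2]
  model$atoms$z[i] <- pos[3]
  model
}
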