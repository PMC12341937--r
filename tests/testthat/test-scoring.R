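test_that("pair weights follow the confidence transform", {
  # pae at the transform maximum zeroes the weight regardless of pLDDT
  atmax <- fx_model(seed = 31, planted = data.frame(
    binder_resno = 3, histone_chain = "C", histone_resno = 62, dist = 4.0),
    plddt = data.frame(chain_id = c("K", "C"), resno = c(3, 62),
                       value = c(100, 100)))
  cs <- dedupe_to_residue_pairs(find_atom_contacts(atmax$model), "atmax")
  w <- pair_weights(cs, atmax$confidence)
  expect_equal(w$weight, 0)

  # pae 0 both ways with pLDDT 100 gives the maximum weight 31.75 * 100
  best <- fx_model(seed = 32, planted = data.frame(
    binder_resno = 3, histone_chain = "C", histone_resno = 62, dist = 4.0),
    pae = data.frame(chain_a = "K", resno_a = 3, chain_b = "C",
                     resno_b = 62, value = 0),
    plddt = data.frame(chain_id = c("K", "C"), resno = c(3, 62),
                       value = c(100, 100)))
  csb <- dedupe_to_residue_pairs(find_atom_contacts(best$model), "best")
  wb <- pair_weights(csb, best$confidence)
  expect_equal(wb$weight, 3175)

  # asymmetric PAE, directional mean:
  # ((31.75-10)*80 + (31.75-20)*60) / 2 = 1222.5
  asym <- fx_model(seed = 33, planted = data.frame(
    binder_resno = 3, histone_chain = "C", histone_resno = 62, dist = 4.0),
    pae = data.frame(chain_a = c("K", "C"), resno_a = c(3, 62),
                     chain_b = c("C", "K"), resno_b = c(62, 3),
                     value = c(10, 20), symmetric = c(FALSE, FALSE)),
    plddt = data.frame(chain_id = c("K", "C"), resno = c(3, 62),
                       value = c(80, 60)))
  csa <- dedupe_to_residue_pairs(find_atom_contacts(asym$model), "asym")
  wa <- pair_weights(csa, asym$confidence)
  expect_equal(wa$weight, 1222.5)
  expect_equal(wa$p_a, (21.75 + 11.75) / 2)
  expect_equal(wa$p_l, 70)
  # component-mean reading differs only in cross terms
  wc <- pair_weights(csa, asym$confidence,
                     scoring_params(weight_mode = "component_mean"))
  expect_equal(wc$weight, ((21.75 + 11.75) / 2) * 70)
})

test_that("sf_raw is additive over pairs and zero on empty sets", {
  plants <- data.frame(binder_resno = c(2, 6, 9, 13, 17),
                       histone_chain = c("A", "B", "C", "D", "G"),
                       histone_resno = c(45, 30, 62, 50, 91),
                       dist = c(4.0, 4.2, 4.4, 4.6, 4.8))
  paes <- c(3, 8, 12, 20, 25)
  plddts <- data.frame(
    chain_id = c("K", "K", "K", "K", "K", "A", "B", "C", "D", "G"),
    resno = c(plants$binder_resno, plants$histone_resno),
    value = c(90, 85, 80, 75, 70, 60, 55, 50, 45, 40))
  fx <- fx_model(seed = 34, planted = plants,
                 pae = data.frame(chain_a = "K",
                                  resno_a = plants$binder_resno,
                                  chain_b = plants$histone_chain,
                                  resno_b = plants$histone_resno,
                                  value = paes),
                 plddt = plddts)
  cs <- dedupe_to_residue_pairs(find_atom_contacts(fx$model), "five")
  # independent hand summation of the five planted weights
  t_ <- 31.75 - paes
  pl_b <- c(90, 85, 80, 75, 70); pl_h <- c(60, 55, 50, 45, 40)
  hand <- sum((t_ * pl_b + t_ * pl_h) / 2)
  expect_equal(sf_raw(cs, fx$confidence), hand, tolerance = 1e-12)

  empty <- dedupe_to_residue_pairs(
    find_atom_contacts(fx$model)[0, ], "empty")
  expect_equal(sf_raw(empty, fx$confidence), 0)
})

test_that("normalization is exact self-unity and linear", {
  fx <- fx_model(seed = 35, planted = data.frame(
    binder_resno = 3, histone_chain = "C", histone_resno = 62, dist = 4.0),
    pae = data.frame(chain_a = "K", resno_a = 3, chain_b = "C",
                     resno_b = 62, value = 5))
  ref <- sf_reference(fx$model, fx$confidence)
  self <- score_model(fx$model, fx$confidence, ref = ref)
  expect_identical(self$sf, 1.0)

  res <- self; res$sf_raw <- 2 * ref$B
  expect_equal(normalize_sf(res, ref)$sf, 2.0)
  res$sf_raw <- 0
  expect_equal(normalize_sf(res, ref)$sf, 0)
  expect_error(normalize_sf(res, list(B = 0)), "positive")
})

test_that("excluded models score zero and carry the exclusion flag", {
  fx <- fx_model(seed = 36,
                 planted = data.frame(binder_resno = 3,
                                      histone_chain = "C",
                                      histone_resno = 62, dist = 4.0),
                 has_clash = TRUE)
  ref <- list(B = 100)
  res <- normalize_sf(score_model(fx$model, fx$confidence), ref)
  expect_true(res$excluded_by_clash)
  expect_equal(res$sf_raw, 0)
  expect_equal(res$sf, 0)
})

test_that("SF responds monotonically to cutoff, PAE and pLDDT", {
  plants <- random_plants(6, seed = 370, dmin = 4.0, dmax = 4.4)
  pae <- data.frame(chain_a = "K", resno_a = plants$binder_resno,
                    chain_b = plants$histone_chain,
                    resno_b = plants$histone_resno, value = 10)
  fx <- fx_model(seed = 37, planted = plants, pae = pae)
  p5 <- scoring_params(contact_cutoff = 5.0)
  p6 <- scoring_params(contact_cutoff = 6.5)
  sf5 <- score_model(fx$model, fx$confidence, p5)$sf_raw
  sf6 <- score_model(fx$model, fx$confidence, p6)$sf_raw
  expect_gte(sf6, sf5)

  # uniform PAE inflation lowers (or preserves, clamped) the score
  inflated <- fx$confidence
  inflated$pae <- pmin(inflated$pae + 5, 31.75)
  expect_lte(score_model(fx$model, inflated, p5)$sf_raw, sf5)

  # raising every pLDDT raises the score
  lifted <- fx$confidence
  lifted$plddt_by_token <- pmin(lifted$plddt_by_token + 20, 100)
  expect_gte(score_model(fx$model, lifted, p5)$sf_raw, sf5)

  # rigid-body motion leaves the score unchanged
  moved <- rotate_model(fx$model)
  expect_equal(score_model(moved, fx$confidence, p5)$sf_raw, sf5,
               tolerance = 1e-9)
})

test_that("best-of-models takes the max with first-model tie-breaks", {
  mk <- function(id, sf, excl = FALSE)
    structure(list(model_id = id, weights = NULL, n_contacts = 0L,
                   sf_raw = sf * 10, sf = if (excl) 0 else sf,
                   excluded_by_clash = excl), class = "sf_result")
  e <- best_of_models(list(mk("m1", 0.2), mk("m2", 0.9), mk("m3", 0.4),
                           mk("m4", 0.4), mk("m5", 0.1)), "p")
  expect_equal(e$sf_best, 0.9)
  expect_equal(e$model_of_best, "m2")

  allx <- best_of_models(list(mk("m1", 0, TRUE), mk("m2", 0, TRUE)), "p")
  expect_equal(allx$sf_best, 0)

  tie <- best_of_models(list(mk("a", 0.7), mk("b", 0.7)), "p")
  expect_equal(tie$model_of_best, "a")
  expect_error(best_of_models(list(), "p"), "no models")
})

test_that("ranking is a stable descending sort", {
  one <- data.frame(protein_id = "p", sf_best = 1, model_of_best = "m",
                    n_models = 5L, n_excluded = 0L)
  expect_equal(rank_proteins(one)$rank, 1L)

  asc <- data.frame(protein_id = letters[1:5], sf_best = 1:5,
                    model_of_best = "m", n_models = 5L, n_excluded = 0L)
  expect_equal(rank_proteins(asc)$protein_id, rev(letters[1:5]))

  set.seed(99)
  big <- data.frame(protein_id = sprintf("p%03d", 1:100),
                    sf_best = round(runif(100), 2), model_of_best = "m",
                    n_models = 5L, n_excluded = 0L)
  rk <- rank_proteins(big)
  # comparison-sort oracle: stable sort by decreasing score
  oracle <- big[order(big$sf_best, decreasing = TRUE, method = "radix"), ]
  expect_equal(rk$protein_id, oracle$protein_id)
  expect_true(all(diff(rk$sf_best) <= 0))
  expect_equal(sort(rk$rank), 1:100)
})

test_that("kneedle matches the geometric chord-distance oracle", {
  # a straight line has no knee
  expect_true(is.na(kneedle_top(seq(5, 1, length.out = 10))))
  expect_true(is.na(kneedle_top(rep(2, 5))))

  cliff <- c(1.0, 0.95, 0.9, 0.1, 0.09, 0.08)
  expect_equal(kneedle_top(cliff), knee_oracle(cliff))
  expect_equal(kneedle_top(cliff), 4L)  # frozen from the oracle

  hyper <- 1 / (1 + (0:20))
  expect_equal(kneedle_top(hyper), knee_oracle(hyper))

  for (s in 1:25) {
    y <- convex_decreasing(30, seed = 400 + s)
    expect_equal(kneedle_top(y), knee_oracle(y))
  }
  expect_error(kneedle_top(c(2, 1)), "at least 3")
  expect_error(kneedle_top(c(1, 2, 3)), "non-increasing")
})
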