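test_that("ums_profile matches a brute-force residual recomputation", {
  set.seed(31)
  kset <- random_karplus_set("VAL")
  res <- generate_residue(kset, "staggered", populations = c(0.3, 0.3, 0.4),
                          sigma = 0.3, seed = 7)
  prof <- ums_profile(res, kset, step = 5)
  for (i in seq_len(nrow(prof))) {
    jc <- evaluate_at_chi1(kset, prof$chi1[i], names(res$measurements))
    expect_equal(prof$rmsd[i],
                 sqrt(mean((res$measurements - jc)^2)), tolerance = 1e-12)
  }
  expect_error(ums_profile(res, kset, step = 0), "step")
})

test_that("noise-free UMS recovers the generating chi1", {
  set.seed(32)
  kset <- random_karplus_set("ILE")
  res <- generate_residue(kset, "pure", chi1 = -65)
  fit <- fit_ums(res, kset, step = 0.1)
  expect_equal(fit$chi1, -65, tolerance = 0.1)
  expect_lt(fit$rmsd, 1e-9)
  # symmetric single coupling (no sine terms, delta 0) -> profile even in chi1
  ksym <- karplus_set("VAL", list("N-CG1" = karplus_coefficients(4, -1, 2)))
  rsym <- suppressWarnings(residue_couplings("sym", "VAL", c("N-CG1" = 3)))
  psym <- ums_profile(rsym, ksym, step = 1)
  v <- setNames(psym$rmsd, psym$chi1)
  for (chi in seq(1, 179)) {
    expect_equal(unname(v[as.character(chi)]), unname(v[as.character(-chi)]),
                 tolerance = 1e-12)
  }
})

test_that("single-coupling profiles show the ~180-degree degeneracy", {
  # a cos2-dominated Karplus curve is nearly 180-periodic, so every solution
  # chi has a degenerate twin near chi + 180 (the paper-level ambiguity);
  # depending on the J value there may additionally be mirror solutions
  set.seed(33)
  worst <- replicate(50, {
    k <- karplus_coefficients(runif(1, 2, 8), runif(1, -2, -0.5),
                              runif(1, 1, 4))
    kset <- karplus_set("VAL", list("HA-HB" = k))
    chi_true <- runif(1, -180, 180)
    res <- suppressWarnings(generate_residue(kset, "pure", chi1 = chi_true))
    fit <- fit_ums(res, kset, step = 0.5, force_global = TRUE)
    expect_gte(nrow(fit$minima), 2L)
    m <- fit$minima$chi1
    max(vapply(seq_along(m), function(j) {
      min(circ_distance(wrap_angle(m[j] + 180), m[-j]))
    }, numeric(1)))
  })
  expect_true(all(worst < 90))
  expect_lt(median(worst), 30)
})

test_that("ums_minima selection prefers staggered minima (second-minimum rule)", {
  # constructed profile: global minimum at -100 (non-staggered), second
  # minimum at 170 within 30 degrees of 180
  chi <- seq(-179.9, 180, by = 0.1)
  bump <- function(center, depth, kappa = 8) {
    depth * exp(kappa * (cos((chi - center) * pi / 180) - 1))
  }
  v <- 2 - bump(-100, 1.7) - bump(170, 1.5)
  prof <- structure(data.frame(chi1 = chi, rmsd = v),
                    step = 0.1, class = c("ums_profile", "data.frame"))
  fit <- ums_minima(prof)
  expect_equal(fit$chi1, 170, tolerance = 0.2)
  expect_equal(fit$selected_rank, 2L)
  expect_equal(fit$minima$chi1[1], -100, tolerance = 0.2)
  # the flag restores the global minimum
  fitg <- ums_minima(prof, force_global = TRUE)
  expect_equal(fitg$chi1, -100, tolerance = 0.2)
  expect_equal(fitg$selected_rank, 1L)
  # flat profile errors
  flat <- structure(data.frame(chi1 = chi, rmsd = rep(1, length(chi))),
                    step = 0.1, class = c("ums_profile", "data.frame"))
  expect_error(ums_minima(flat), "flat")
})

test_that("uncertainty extents trace the rmsd_min + window region", {
  # V-shaped periodic curve around 0 with slope 0.01 Hz/deg: the 0.2 Hz
  # window spans 20 degrees on each side
  chi <- seq(-179.9, 180, by = 0.1)
  v <- 0.01 * circ_distance(chi, 0)
  prof <- structure(data.frame(chi1 = chi, rmsd = v),
                    step = 0.1, class = c("ums_profile", "data.frame"))
  fit <- ums_minima(prof, window = 0.2)
  expect_equal(unname(fit$uncertainty["minus"]), 20, tolerance = 0.2)
  expect_equal(unname(fit$uncertainty["plus"]), 20, tolerance = 0.2)
  # asymmetric curve: steeper on the right
  v2 <- ifelse(wrap_angle(chi) >= 0, 0.02, 0.01) * circ_distance(chi, 0)
  prof2 <- structure(data.frame(chi1 = chi, rmsd = v2),
                     step = 0.1, class = c("ums_profile", "data.frame"))
  fit2 <- ums_minima(prof2, window = 0.2)
  expect_equal(unname(fit2$uncertainty["minus"]), 20, tolerance = 0.2)
  expect_equal(unname(fit2$uncertainty["plus"]), 10, tolerance = 0.2)
})

test_that("TMSS recovers exact mixtures and vertex solutions", {
  set.seed(34)
  kset <- random_karplus_set("VAL")
  res <- generate_residue(kset, "staggered", populations = c(0.2, 0.5, 0.3))
  fit <- tmss_populations(res, kset)
  expect_equal(unname(fit$populations), c(0.2, 0.5, 0.3), tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$chi1, 180)

  pure <- generate_residue(kset, "pure", chi1 = 180)
  fitp <- tmss_populations(pure, kset)
  expect_equal(unname(fitp$populations), c(0, 1, 0), tolerance = 1e-8)
  expect_equal(sum(fit$populations), 1, tolerance = 1e-9)
  expect_true(all(fit$populations >= 0))
})

test_that("TMSS matches the dense simplex grid oracle", {
  set.seed(35)
  for (i in 1:10) {
    kset <- random_karplus_set("VAL")
    res <- generate_residue(kset, "staggered",
                            populations = c(0.2, 0.5, 0.3),
                            sigma = runif(1, 0.2, 1.5), seed = 100 + i)
    fit <- tmss_populations(res, kset)
    A <- t(sapply(c(60, 180, -60), function(a) {
      evaluate_at_chi1(kset, a, names(res$measurements))
    }))
    grid_rmsd <- tmss_grid_oracle(t(A), res$measurements, res$n)
    expect_lte(fit$rmsd, grid_rmsd + 1e-9)  # exact solver never loses
    expect_lt(grid_rmsd - fit$rmsd, 1e-3)   # and the grid is close behind
  }
})

test_that("TMST recovers pure conformers and nests below TMSS and UMS", {
  set.seed(36)
  kset <- random_karplus_set("ILE")
  pure <- generate_residue(kset, "pure", chi1 = -65)
  fit <- tmst_fit(pure, kset, step = 0.1)
  expect_equal(fit$chi1, -65, tolerance = 0.1)
  expect_equal(max(fit$conformers$population), 1, tolerance = 1e-6)
  expect_lt(fit$rmsd, 1e-6)

  for (i in 1:5) {
    res <- generate_residue(kset, "staggered",
                            populations = c(0.2, 0.5, 0.3),
                            sigma = 0.5, seed = 200 + i)
    ums <- fit_ums(res, kset, step = 0.5)
    tmss <- tmss_populations(res, kset)
    tmst <- tmst_fit(res, kset, step = 0.5)
    expect_lte(tmst$rmsd, tmss$rmsd + 1e-9)
    expect_lte(tmst$rmsd, ums$rmsd + 1e-9)
    expect_equal(sum(tmst$conformers$population), 1, tolerance = 1e-9)
    expect_true(all(tmst$conformers$population >= 0))
  }
})

test_that("TMST objective is invariant under 120-degree label rotation", {
  set.seed(37)
  kset <- random_karplus_set("VAL")
  res <- generate_residue(kset, "trigonal", chi1 = -50,
                          populations = c(0.6, 0.25, 0.15), sigma = 0.3,
                          seed = 9)
  fit <- tmst_fit(res, kset, step = 0.5)
  obj <- function(chi0, p) {
    pred <- p[1] * evaluate_at_chi1(kset, chi0, names(res$measurements)) +
      p[2] * evaluate_at_chi1(kset, chi0 + 120, names(res$measurements)) +
      p[3] * evaluate_at_chi1(kset, chi0 - 120, names(res$measurements))
    sqrt(mean((res$measurements - pred)^2))
  }
  offs <- round((fit$conformers$chi1 - fit$chi1) %% 360) %% 360
  p <- fit$conformers$population[match(c(0, 120, 240), offs)]
  base <- obj(fit$chi1, p)
  expect_equal(obj(fit$chi1 + 120, p[c(2, 3, 1)]), base, tolerance = 1e-9)
  expect_equal(obj(fit$chi1 - 120, p[c(3, 1, 2)]), base, tolerance = 1e-9)
  expect_equal(base, fit$rmsd, tolerance = 1e-9)
})

test_that("classification reproduces the published reference residues", {
  # Val7: UMS chi1 -177.6, TMST populations (0, 0.86, 0.14) -> unimodal, 180
  c1 <- classify_residue(-177.6, c(0, 0.86, 0.14))
  expect_equal(c1$label, "unimodal")
  expect_equal(c1$dominant_bin, 180)
  # Val88: chi1 164.6 is staggered-compatible but populations peak at 0.47
  c2 <- classify_residue(164.6, c(0.13, 0.47, 0.40))
  expect_equal(c2$label, "trimodal")
  expect_true(c2$criteria$staggered$pass)
  expect_false(c2$criteria$population$pass)
  # Leu78: chi1 100.2 fails both criteria
  c3 <- classify_residue(100.2, c(0.26, 0.31, 0.43))
  expect_equal(c3$label, "trimodal")
  expect_false(c3$criteria$staggered$pass)
  # boundary conventions: 30-degree deviation kept, population 0.60 fails
  expect_equal(classify_residue(90, c(0.7, 0.2, 0.1))$label, "unimodal")
  expect_equal(classify_residue(90.1, c(0.7, 0.2, 0.1))$label, "trimodal")
  expect_equal(classify_residue(180, c(0.2, 0.60, 0.2))$label, "trimodal")
  # TMSS-based criterion is available behind the config option
  ts <- structure(list(populations = c(p60 = 0.1, p180 = 0.8, pm60 = 0.1)),
                  class = "tmss_result")
  c4 <- classify_residue(-177.6, c(0.4, 0.35, 0.25), tmss = ts,
                         population_from = "tmss")
  expect_equal(c4$label, "unimodal")
})

test_that("predict_couplings respects model structure and linearity", {
  set.seed(38)
  kset <- random_karplus_set("VAL")
  res <- generate_residue(kset, "pure", chi1 = 55)
  ums <- fit_ums(res, kset, step = 0.1)
  expect_equal(predict_couplings(ums, kset, names(res$measurements)),
               res$measurements, tolerance = 1e-3)
  tmss_unit <- structure(list(populations = c(p60 = 1, p180 = 0, pm60 = 0)),
                         class = "tmss_result")
  expect_equal(predict_couplings(tmss_unit, kset),
               evaluate_at_chi1(kset, 60), tolerance = 1e-12)
  # mixture prediction equals evaluation of the mixed coefficient curve
  p <- c(0.25, 0.45, 0.30)
  tmst <- structure(list(conformers = data.frame(
    chi1 = c(50, 170, -70), population = p)), class = "tmst_result")
  pred <- predict_couplings(tmst, kset)
  mixed <- p[1] * evaluate_at_chi1(kset, 50) +
    p[2] * evaluate_at_chi1(kset, 170) + p[3] * evaluate_at_chi1(kset, -70)
  expect_equal(pred, mixed, tolerance = 1e-12)
  expect_error(predict_couplings(list(), kset), "ums_result")
})

test_that("rmsd_j_total pools couplings across residues", {
  set.seed(39)
  kset <- random_karplus_set("VAL")
  r1 <- generate_residue(kset, "pure", chi1 = 60, residue_id = "a")
  r2 <- generate_residue(kset, "pure", chi1 = 180, residue_id = "b")
  f1 <- fit_ums(r1, kset, step = 0.1); f2 <- fit_ums(r2, kset, step = 0.1)
  out <- rmsd_j_total(list(r1, r2), list(f1, f2), kset)
  expect_equal(out$m, 18L)
  expect_lt(out$rmsd, 1e-3)

  # hand arithmetic: one coupling off by 1 Hz among m = 4
  ksmall <- karplus_set("VAL", list(
    "HA-HB" = karplus_coefficients(c0 = 5),
    "N-CG1" = karplus_coefficients(c0 = 2),
    "C-CG1" = karplus_coefficients(c0 = 3),
    "N-HB" = karplus_coefficients(c0 = 1)))
  meas <- c("HA-HB" = 6, "N-CG1" = 2, "C-CG1" = 3, "N-HB" = 1)
  r <- residue_couplings("x", "VAL", meas)
  u <- structure(list(chi1 = 0), class = "ums_result")
  out <- rmsd_j_total(list(r), list(u), ksmall)
  expect_equal(out$rmsd, 0.5)
  expect_equal(out$m, 4L)
  expect_error(rmsd_j_total(list(), list(), kset), "empty")
})

test_that("sparse coupling sets warn about under-determined populations", {
  kset <- demo_karplus_set("VAL")
  expect_warning(
    residue_couplings("v", "VAL", c("HA-HB" = 7, "N-HB" = -1)),
    "under-determined")
  # a five-proton-coupling mask (as for residues with only 1H data) still runs
  keep <- c("HA-HB", "HA-CG1", "HA-CG2", "N-HB", "C-HB")
  res <- generate_residue(kset, "pure", chi1 = 170,
                          mask = setdiff(names(kset$entries), keep))
  expect_equal(res$n, 5L)
  fit <- tmss_populations(res, kset)
  expect_equal(sum(fit$populations), 1, tolerance = 1e-9)
  expect_error(generate_residue(kset, "pure", chi1 = 0,
                                mask = names(kset$entries)), "mask")
})
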