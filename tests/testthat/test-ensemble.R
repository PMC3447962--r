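toy_curves <- function() {
  # three clearly distinct conformer profiles of a 3-domain toy
  base <- toy_multidomain(3, atoms_per_domain = 80, linker_length = 12,
                          seed = 1)
  fam <- conformer_family(base, 20, mode = "hinge", seed = 2,
                          max_angle = pi * 0.8)
  profile_set(subset_conformations(fam, c(1, 10, 20)))
}

test_that("chi-square definition, scale fit, and error contracts", {
  q <- c(0.1, 0.2, 0.3)
  e <- saxs_curve(q, c(2, 4, 6), sigma = c(1, 1, 1))
  t1 <- saxs_curve(q, c(1, 3, 5))
  expect_equal(chi_square(e, t1, fit_scale = FALSE)$chi2, 1.0)
  # proportional curves: fitted scale 0.5, chi2 exactly 0
  t2 <- saxs_curve(q, 2 * c(2, 4, 6))
  sc <- chi_square(e, t2, fit_scale = TRUE)
  expect_equal(sc$scale, 0.5)
  expect_equal(sc$chi2, 0)
  # identical curves
  expect_equal(chi_square(e, saxs_curve(q, c(2, 4, 6)))$chi2, 0)
  # grid mismatch and missing errors
  expect_error(chi_square(e, saxs_curve(q + 0.01, c(1, 3, 5))), "grid")
  expect_error(chi_square(saxs_curve(q, c(2, 4, 6)), t1), "sigma")
})

test_that("scale-fitted chi-square is invariant to theoretical rescaling", {
  set.seed(40)
  q <- default_qgrid(40)
  e <- saxs_curve(q, exp(-q^2 * 300) * 1e4, sigma = exp(-q^2 * 300) * 100)
  t0 <- saxs_curve(q, exp(-q^2 * 280) * 3e3)
  ref <- chi_square(e, t0)$chi2
  for (k in c(1e-6, 0.37, 42, 1e8)) {
    tk <- saxs_curve(q, k * t0$I)
    expect_equal(chi_square(e, tk)$chi2, ref, tolerance = 1e-9)
  }
})

test_that("filter_lowest keeps the lowest-chi2 fraction with tie rules", {
  fake_cset <- function(chi2) {
    n <- length(chi2)
    template <- place_atoms(matrix(seq_len(3 * 5), 5, 3), resid = 1:5)
    cs <- conformation_set(template, replicate(n, template$xyz,
                                               simplify = FALSE))
    structure(list(conformations = cs, curves = vector("list", n),
                   rg = rep(10, n), frame_index = seq_len(n),
                   chi2 = chi2, scale = rep(1, n), exp_curve = NULL),
              class = "candidate_set")
  }
  set.seed(41)
  chi2 <- sample(100)
  kept <- filter_lowest(fake_cset(chi2), 0.05)
  expect_equal(length(kept), 5)
  expect_setequal(kept$chi2, sort(chi2)[1:5])
  # 40000 candidates at 5% keep 2000
  big <- fake_cset(runif(40000))
  expect_equal(length(filter_lowest(big, 0.05)), 2000)
  # all-equal chi2: the earliest frames win
  tied <- fake_cset(rep(1, 100))
  expect_equal(filter_lowest(tied, 0.05)$frame_index, 1:5)
  # nested subsets across 2.5/5/7.5%
  cs <- fake_cset(runif(400))
  k1 <- filter_lowest(cs, 0.025)$frame_index
  k2 <- filter_lowest(cs, 0.05)$frame_index
  k3 <- filter_lowest(cs, 0.075)$frame_index
  expect_true(all(k1 %in% k2) && all(k2 %in% k3))
  expect_error(filter_lowest(fake_cset(1:10), 0.05), "zero")
  expect_error(filter_lowest(fake_cset(1:10), 1.5), "fraction")
})

test_that("P(Rg) histogram normalizes and finds constructed peaks", {
  # degenerate: all Rg identical
  h1 <- prg_histogram(rep(35, 50))
  expect_equal(sum(h1$prob), 1)
  expect_equal(nrow(h1$peaks), 1)
  expect_equal(h1$prob[h1$peaks$bin[1]], 1)
  # trimodal sample: three peaks within 0.5 A of the component means
  set.seed(42)
  rg <- c(rnorm(1000, 34, 0.4), rnorm(1000, 37.5, 0.4),
          rnorm(1000, 41, 0.4))
  h3 <- prg_histogram(rg, bin_width = 0.25)
  expect_equal(nrow(h3$peaks), 3)
  expect_equal(sort(h3$peaks$location), c(34, 37.5, 41), tolerance = 0.5 / 34)
  # normalization on arbitrary input
  for (k in 1:5) {
    h <- prg_histogram(runif(200, 10, 50), bin_width = 0.8)
    expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  }
})

test_that("representative selection is greedy in chi2 with RMSD exclusion", {
  # candidate set with controlled geometry: frames are translated copies
  # (RMSD 0 after superposition) or genuinely deformed ones
  set.seed(43)
  base <- matrix(rnorm(60), 20, 3) * 5
  deform <- function(scale) base + matrix(rnorm(60, 0, scale), 20, 3)
  frames <- list(deform(3), base, sweep(base, 2, c(50, 0, 0), "+"),
                 deform(3.2), deform(3.4), deform(3.6))
  template <- place_atoms(base, resid = rep(1:4, each = 5))
  cs <- conformation_set(template, frames)
  cset <- structure(list(conformations = cs, curves = vector("list", 6),
                         rg = rep(12, 6), frame_index = 1:6,
                         chi2 = c(5, 1, 2, 3, 4, 6),
                         scale = rep(1, 6), exp_curve = NULL),
                    class = "candidate_set")
  hist <- prg_histogram(cset$rg, bin_width = 0.5)
  reps <- select_representatives(cset, hist, n_peaks = 1, k_per_peak = 4,
                                 min_rmsd = 2)
  sel <- reps$groups[[1]]
  # frame 2 (chi2 = 1) first; frame 3 is its rigid copy -> skipped;
  # then chi2 order 4, 5, 1
  expect_equal(sel[1], 2)
  expect_false(3 %in% sel)
  expect_equal(sel, c(2, 4, 5, 1))
  # requesting more than admissible warns and returns fewer
  expect_warning(
    r2 <- select_representatives(cset, hist, n_peaks = 1, k_per_peak = 6,
                                 min_rmsd = 2),
    "admissible")
  expect_lt(length(r2$groups[[1]]), 6)
})

test_that("weight enumeration is exact and complete", {
  w3 <- enumerate_weights(3, 0.1)
  expect_equal(nrow(w3), 66) # C(12, 2) compositions of 10 into 3 parts
  expect_equal(nrow(unique(w3)), 66)
  expect_equal(enumerate_weights(1), matrix(1, 1, 1), ignore_attr = TRUE)
  w2 <- enumerate_weights(2, 0.5)
  expect_equal(w2, rbind(c(0, 1), c(0.5, 0.5), c(1, 0)),
               ignore_attr = TRUE)
  # integer internal representation: counts always sum to the denominator
  for (k in 1:5) {
    w <- enumerate_weights(k, 0.1)
    expect_true(all(rowSums(attr(w, "counts")) ==
                    attr(w, "denominator")))
    expect_equal(rowSums(w), rep(1, nrow(w)), tolerance = 1e-12)
  }
})

test_that("fit_ensemble recovers planted weights and the argmin property", {
  curves <- toy_curves()
  q <- curves[[1]]$q
  # exp built noise-free from member 2 -> weight 1 on it, chi2 = 0
  exp1 <- saxs_curve(q, 3.7 * curves[[2]]$I, sigma = curves[[2]]$I * 0.01)
  fit1 <- fit_ensemble(exp1, curves)
  expect_equal(unname(fit1$weights), c(0, 1, 0))
  expect_equal(fit1$chi2, 0, tolerance = 1e-12)
  expect_equal(fit1$n_evaluated, 66)
  # 0.4/0.3/0.3 mixture at 1% noise: exact grid recovery
  me <- mock_experiment(curves, c(0.4, 0.3, 0.3),
                        noise = noise_model(seed = 5))
  fit2 <- fit_ensemble(me$curve, curves)
  expect_equal(unname(fit2$weights), c(0.4, 0.3, 0.3))
  # argmin property: no enumerated weight vector scores lower
  W <- enumerate_weights(3)
  M <- sapply(curves, `[[`, "I")
  all_chi2 <- apply(W, 1, function(w)
    chi_square(me$curve, saxs_curve(q, as.numeric(M %*% w)))$chi2)
  expect_equal(fit2$chi2, min(all_chi2), tolerance = 1e-12)
  expect_true(all(fit2$chi2 <= all_chi2 + 1e-15))
  # duplicated member curves tie; lexicographically smallest vector wins
  fit3 <- fit_ensemble(exp1, list(curves[[2]], curves[[2]]))
  expect_equal(unname(fit3$weights), c(0, 1))
})

test_that("ensemble fit methods behave like a fitted model object", {
  curves <- toy_curves()
  me <- mock_experiment(curves, c(0.4, 0.3, 0.3),
                        noise = noise_model(seed = 6))
  fit <- fit_ensemble(me$curve, curves)
  expect_s3_class(fit, "saxs_ensemble_fit")
  expect_equal(sum(coef(fit)), 1)
  expect_length(fitted(fit), length(me$curve$q))
  expect_equal(stats::residuals(fit),
               (fitted(fit) - me$curve$I) / me$curve$sigma)
  pr <- predict(fit)
  expect_s3_class(pr, "saxs_curve")
  expect_equal(pr$I, fitted(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_false(identical(sims[[1]]$I, sims[[2]]$I))
  expect_output(print(fit), "chi2")
  expect_output(print(summary(fit)), "weights")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("combination_search enumerates the cross-product and recovers", {
  # pool of a uniformly folding family plus an L-shape family (only the
  # first hinge moves) so the three generators are linearly independent
  # in curve space
  base <- toy_multidomain(3, atoms_per_domain = 80, linker_length = 12,
                          seed = 1)
  fam <- conformer_family(base, 20, mode = "hinge", seed = 2,
                          max_angle = pi * 0.8)
  famL <- conformer_family(base, 20, mode = "hinge", seed = 2,
                           max_angle = pi * 0.8, hinge_scale = c(1, 0))
  pool <- bind_conformations(list(fam, famL))
  pool_curves <- profile_set(pool)
  gens <- c(1, 20, 21) # folded, extended, most-compact L-shape
  me <- mock_experiment(pool_curves[gens], c(0.5, 0.3, 0.2),
                        noise = noise_model(0.002, 3, seed = 7))
  cset <- score_candidates(pool, me$curve, curves = pool_curves)
  # groups of 4 with one generator planted in each
  groups <- list(c(1, 4, 6, 8), c(20, 17, 15, 13), c(21, 24, 26, 28))
  fit <- combination_search(me$curve, groups, cset)
  expect_equal(attr(fit, "n_combinations"), 64)
  expect_setequal(fit$member_ids, gens)
  w <- fit$weights[match(gens, fit$member_ids)]
  expect_equal(unname(w), c(0.5, 0.3, 0.2))
  # single-member groups reduce to one fit_ensemble call
  fit1 <- combination_search(me$curve, list(1, 10, 20), cset)
  expect_equal(attr(fit1, "n_combinations"), 1)
  expect_error(combination_search(me$curve, list(integer(0)), cset),
               "empty")
})

test_that("cross_table shape and diagonal behaviour", {
  curves <- toy_curves()
  mk <- function(w, seed) mock_experiment(curves, w,
                                          noise = noise_model(seed = seed))$curve
  exps <- list(a = mk(c(0.8, 0.1, 0.1), 1), b = mk(c(0.1, 0.1, 0.8), 2))
  fits <- lapply(exps, fit_ensemble, member_curves = curves)
  xt <- cross_table(fits, exps)
  expect_equal(dim(xt), c(2, 2))
  expect_equal(xt[1, 1], fits[[1]]$chi2, tolerance = 1e-9)
  expect_true(all(apply(xt, 1, which.min) == c(1, 2)))
  # single dataset: 1 x 1 matrix equal to the fit chi2
  xt1 <- cross_table(fits[1], exps[1])
  expect_equal(dim(xt1), c(1, 1))
  expect_equal(xt1[1, 1], fits[[1]]$chi2, tolerance = 1e-9)
})
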