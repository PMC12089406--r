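test_that("oh_geometry matches a trigonometric oracle", {
  g <- oh_geometry(c(0, 0, 3), c(0, 0, 1), c(0, 0, 0))
  expect_equal(g$d_OH, 2)
  expect_equal(g$theta_OHC, 180)
  expect_equal(oh_geometry(c(1, 0, 1), c(0, 0, 1), c(0, 0, 0))$theta_OHC, 90)

  set.seed(41)
  for (k in 1:20) {
    O <- rnorm(3, 0, 3); H <- rnorm(3, 0, 3); C <- rnorm(3, 0, 3)
    g <- oh_geometry(O, H, C)
    # law-of-cosines recomputation
    a <- sqrt(sum((O - H)^2)); b <- sqrt(sum((C - H)^2))
    cc <- sqrt(sum((O - C)^2))
    th <- acos(min(1, max(-1, (a^2 + b^2 - cc^2) / (2 * a * b)))) * 180 / pi
    expect_equal(g$d_OH, a, tolerance = 1e-9)
    expect_equal(g$theta_OHC, th, tolerance = 1e-9)
  }
  expect_error(oh_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               class = "nacsel_compute_error")
})

test_that("the NAC criterion is inclusive at its boundaries and capped at 180", {
  crit <- nac_criteria()
  expect_true(is_active(2.8, crit, theta = 170))
  expect_false(is_active(2.81, crit, theta = 170))
  expect_true(is_active(2.0, crit, theta = 155.0))
  expect_false(is_active(2.0, crit, theta = 154.9))
  expect_true(is_active(2.0, crit, theta = 180))   # window capped at 180
  expect_true(is_active(2.0, crit, theta = 185 - 5))
  expect_false(is_active(3.0, crit, theta = 170))
  expect_error(nac_criteria(d_max = -1), class = "nacsel_config_error")
  expect_error(nac_criteria(theta_center = 190), class = "nacsel_config_error")
})

test_that("tally recovers planted counts and silences off-target sites", {
  th <- build_theozyme()
  s <- build_dkp(1)
  gen <- sample_nac_ensemble(th, s, "C-5a", f_active = 0.2, n = 120,
                             seed = 17)
  summ <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index)
  ps <- summ$per_site
  expect_equal(ps$n_active[ps$site == "C-5a"], gen$ledger$planted_count)
  expect_true(all(ps$n_active[ps$site != "C-5a"] == 0L))
  expect_equal(sum(gen$ledger$plan), gen$ledger$planted_count)

  all_on <- sample_nac_ensemble(th, s, "C-7", f_active = 1, n = 25,
                                seed = 2)
  s2 <- tally_ensemble(all_on$ensemble, all_on$sites, all_on$oxo_index)
  expect_equal(s2$per_site$n_active[s2$per_site$site == "C-7"], 25L)

  expect_error(tally_ensemble(gen$ensemble, gen$sites, 1L),
               "not oxygen", class = "nacsel_config_error")
})

test_that("tally equals an independently coded brute-force double loop", {
  th <- build_theozyme()
  subs <- list(build_dkp(1), build_dkp(2), build_dkp(3))
  set.seed(53)
  for (k in 1:8) {
    sub <- subs[[sample(3, 1)]]
    target <- sample(site_labels(sub$sites), 1)
    gen <- sample_nac_ensemble(th, sub, target,
                               f_active = runif(1), n = sample(10:40, 1),
                               seed = sample.int(10000, 1))
    got <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index)
    want <- oracle_tally(gen$ensemble, gen$sites, gen$oxo_index)
    expect_identical(setNames(got$per_site$n_active, got$per_site$site),
                     want[got$per_site$site])
  }
})

test_that("counts are invariant under rigid motion and monotone in criteria", {
  th <- build_theozyme()
  gen <- sample_nac_ensemble(th, build_dkp(2), "C-2'", f_active = 0.4,
                             n = 60, seed = 77)
  base <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index)
  set.seed(78)
  for (k in 1:3) {
    R <- random_rotation(); tr <- rnorm(3, 0, 10)
    moved <- transform_ensemble(gen$ensemble, R, tr)
    got <- tally_ensemble(moved, gen$sites, gen$oxo_index)
    expect_identical(got$per_site$n_active, base$per_site$n_active)
  }
  # monotonicity: enlarging d_max or theta_tol never decreases counts
  for (d in c(2.0, 2.4, 2.8, 3.2, 4.0)) {
    wide <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index,
                           nac_criteria(d_max = d))
    wider <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index,
                            nac_criteria(d_max = d + 0.5))
    expect_true(all(wider$per_site$n_active >= wide$per_site$n_active))
  }
  for (tol in c(5, 15, 25)) {
    a <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index,
                        nac_criteria(theta_tol = tol))
    b <- tally_ensemble(gen$ensemble, gen$sites, gen$oxo_index,
                        nac_criteria(theta_tol = tol + 10))
    expect_true(all(b$per_site$n_active >= a$per_site$n_active))
  }
})

test_that("site ranking orders by count, then distance, then label", {
  mk_summary <- function(df, n) {
    structure(list(n_frames = n, per_site = df, criteria = nac_criteria()),
              class = "NACSummary")
  }
  # dominant-site ordering as seen in engineered-variant ensembles
  df <- data.frame(site = c("C-6", "C-7"), n_active = c(49L, 3L),
                   fraction = c(49, 3) / 5000, mean_d_active = c(2.5, 2.4))
  expect_equal(predict_sites(mk_summary(df, 5000))$site, c("C-6", "C-7"))

  tie <- data.frame(site = c("B", "A"), n_active = c(5L, 5L),
                    fraction = 0.5, mean_d_active = c(2.4, 2.1))
  expect_equal(predict_sites(mk_summary(tie, 10))$site, c("A", "B"))
  tie2 <- data.frame(site = c("B", "A"), n_active = c(5L, 5L),
                     fraction = 0.5, mean_d_active = c(2.2, 2.2))
  expect_equal(predict_sites(mk_summary(tie2, 10))$site, c("A", "B"))

  zeros <- data.frame(site = c("A", "B"), n_active = 0L, fraction = 0,
                      mean_d_active = NA_real_)
  expect_equal(nrow(predict_sites(mk_summary(zeros, 10))), 0L)
})
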