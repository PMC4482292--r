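test_that("relative error E is zero at a perfect fit and one at the mean baseline", {
  d <- toy_dataset()
  perfect <- data.frame(Rab5_hat = d$Rab5, Rab7_hat = d$Rab7)
  expect_equal(error_E(d, perfect), 0)

  baseline <- data.frame(Rab5_hat = rep(mean(d$Rab5), nrow(d)),
                         Rab7_hat = rep(mean(d$Rab7), nrow(d)))
  expect_equal(error_E(d, baseline), 1, tolerance = 1e-14)
})

test_that("E matches the hand-computed three-point example", {
  d <- rab_dataset(0:2, Rab5 = c(1, 2, 3), Rab7 = c(3, 2, 1))
  sim <- data.frame(Rab5_hat = c(1, 2, 5), Rab7_hat = c(3, 2, 1))
  # channel 5: sqrt(4 / 2); channel 7 exact: E = sqrt(2)/2
  expect_equal(error_E(d, sim), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("E is invariant under common rescaling and rejects flat channels", {
  d <- toy_dataset()
  sim <- data.frame(Rab5_hat = d$Rab5 * 1.1, Rab7_hat = d$Rab7 * 0.9)
  e1 <- error_E(d, sim)
  d2 <- rab_dataset(d$t, d$Rab5 * 250, d$Rab7 * 250)
  sim2 <- data.frame(Rab5_hat = sim$Rab5_hat * 250,
                     Rab7_hat = sim$Rab7_hat * 250)
  expect_equal(error_E(d2, sim2), e1, tolerance = 1e-12)

  flat <- rab_dataset(0:2, Rab5 = c(5, 5, 5), Rab7 = c(1, 2, 3))
  expect_error(error_E(flat, sim[1:3, ]), "variance")
  expect_error(error_E(d, sim[1:5, ]), "dataset times")
})

test_that("hidden-state correlation criterion R covers its range and examples", {
  d <- rab_dataset(0:2, Rab5 = c(1, 2, 3), Rab7 = c(3, 2, 1))
  # perfectly positively correlated active states
  expect_equal(corr_R(d, data.frame(R5 = c(2, 4, 6), R7 = c(9, 6, 3))), 0)
  # perfectly anti-correlated: each term clamps at 1
  expect_equal(corr_R(d, data.frame(R5 = c(3, 2, 1), R7 = c(1, 2, 3))), 1)
  # r = 1 and r = 0 mix: R = 1/2
  expect_equal(corr_R(d, data.frame(R5 = c(2, 4, 6), R7 = c(1, 2, 1))), 0.5)
})

test_that("R is invariant under positive affine transforms and handles flat series", {
  d <- toy_dataset()
  tr <- data.frame(R5 = d$Rab5 * 0.3 + 7, R7 = d$Rab7 * 2 - 1)
  expect_equal(corr_R(d, tr), 0)
  # a constant hidden state contributes the full penalty for its channel
  flat5 <- data.frame(R5 = rep(1, nrow(d)), R7 = d$Rab7)
  expect_equal(corr_R(d, flat5), 0.5)
})

test_that("switch detection returns the first persistent dominance change", {
  expect_equal(switch_time(0:2, a = c(3, 2, 1), b = c(1, 2, 3),
                           persistence = 0), 1)
  expect_true(is.na(switch_time(0:2, a = c(3, 2, 3), b = c(1, 1, 1),
                                persistence = 0)))
  # equal channels: dominance from the first time point
  expect_equal(switch_time(0:2, a = c(2, 2, 2), b = c(2, 2, 2),
                           persistence = 0), 0)
  # a transient crossing shorter than the persistence window is skipped
  a <- c(5, 1, 5, 1, 1, 1, 1)
  b <- c(2, 2, 2, 2, 2, 2, 2)
  expect_equal(switch_time(0:6, a, b, persistence = 0), 1)
  expect_equal(switch_time(0:6, a, b, persistence = 2), 3)
})

test_that("switch displacement X normalizes by the observation interval", {
  d <- rab_dataset(seq(0, 100, 10), Rab5 = 100 - seq(0, 100, 10),
                   Rab7 = seq(0, 100, 10), t_s = 40)
  expect_equal(switch_X(d, 40), 0)
  expect_equal(switch_X(d, 55), 0.15)
  expect_equal(switch_X(d, NA), 1)  # no simulated switch: maximum penalty
  d2 <- rab_dataset(seq(0, 100, 10), Rab5 = 100 - seq(0, 100, 10),
                    Rab7 = seq(0, 100, 10), t_s = 0)
  expect_equal(switch_X(d2, 100), 1)
})

test_that("combined criteria reduce to their components at the endpoints", {
  expect_equal(combine_criteria(E = 0.37, R = 0.9, alpha = 1,
                                criterion = "ER"), 0.37)
  expect_equal(combine_criteria(E = 0.37, R = 0.9, alpha = 0,
                                criterion = "ER"), 0.9)
  # worked arithmetic: E = 0.4, R = 0.6, X = 0.2, alpha = 0.5
  expect_equal(combine_criteria(0.4, 0.6, 0.2, alpha = 0.5,
                                criterion = "ER"), 0.5)
  expect_equal(combine_criteria(0.4, 0.6, 0.2, alpha = 0.5,
                                criterion = "EX"), 0.3)
  expect_equal(combine_criteria(0.4, 0.6, 0.2, alpha = 0.5,
                                criterion = "ERX"), 0.4)
  # ERC at alpha = 1 coincides with EC for any beta
  expect_equal(
    combine_criteria(0.4, 0.6, 0.2, C = 0.5, alpha = 1, beta = 0.3,
                     criterion = "ERC"),
    combine_criteria(0.4, 0.6, 0.2, C = 0.5, alpha = 1, beta = 0.3,
                     criterion = "EC"))
  expect_error(combine_criteria(0.4, criterion = "EZ"), "EZ")
  expect_error(criterion_config("EZ"), "EZ")
})

test_that("combined criteria are monotone in each component", {
  base <- combine_criteria(0.4, 0.6, 0.2, C = 0.3, alpha = 0.5, beta = 0.5,
                           criterion = "ERXC")
  for (bump in list(c(E = 0.1), c(R = 0.1), c(X = 0.1), c(C = 0.1))) {
    args <- list(E = 0.4, R = 0.6, X = 0.2, C = 0.3)
    args[[names(bump)]] <- args[[names(bump)]] + bump
    v <- combine_criteria(args$E, args$R, args$X, args$C, alpha = 0.5,
                          beta = 0.5, criterion = "ERXC")
    expect_gte(v, base)
  }
})

test_that("scorecards tabulate all criteria with correct composition", {
  spec <- default_switch_scenario(n = 101, noise_level = 0.05)
  gen <- generate_dataset(spec)
  structures <- list(spec$structure, build_structure(1, 1, 1, 1))
  fits <- fit_all(structures, gen$dataset, criterion_config("E"),
                  cheap_de(), master_seed = 5)
  sc <- score_models(fits, gen$dataset, alpha = 0.5, beta = 0.5)
  expect_equal(nrow(sc), 2)
  expect_true(all(sc$R >= 0 & sc$R <= 1))
  expect_true(all(sc$X >= 0 & sc$X <= 1))
  expect_equal(sc$ERX, 0.5 * sc$E + 0.5 * (sc$R + sc$X) / 2, tolerance = 1e-12)
  expect_equal(sc$RX, (sc$R + sc$X) / 2, tolerance = 1e-12)
  # normalized complexity over the scored set spans [0, 1]
  expect_true(all(sc$C_scaled >= 0 & sc$C_scaled <= 1))
})

test_that("dataset constructor validates shape and detects the switch", {
  d <- rab_dataset(0:2, Rab5 = c(3, 2, 1), Rab7 = c(1, 2, 3), persistence = 0)
  expect_equal(attr(d, "t_s"), 1)
  expect_equal(attr(d, "t0"), 0)
  expect_equal(attr(d, "tmax"), 2)
  expect_error(rab_dataset(c(0, 1, 1), 1:3, 3:1), "increasing")
  expect_error(rab_dataset(0:2, 1:2, 3:1), "length")
})
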