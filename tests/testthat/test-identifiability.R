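# A fabricated bootstrap result for summary-oracle checks.
fake_bootstrap <- function(est, lower = 0, upper = 4) {
  space <- tibble::tibble(name = colnames(est), lower = lower, upper = upper,
                          scale = "linear")
  cm <- suppressWarnings(stats::cor(est))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  out <- structure(
    list(estimates = tibble::as_tibble(est), correlation = cm,
         param_space = space, noise_level = 0.1, n_replicates = nrow(est),
         n_failed = 0L, seed = 1L, criterion = criterion_config("E")),
    class = "rab_bootstrap")
  out$summary <- summarize_identifiability(out)$parameters
  out
}

toy_ridge_dataset <- function(n = 21, noise = 0, seed = 1) {
  t <- seq(0, 10, length.out = n)
  set.seed(seed)
  rab_dataset(t,
              Rab5 = (3 * t + 1) * (1 + stats::rnorm(n, 0, noise)),
              Rab7 = (0.5 * t + 1) * (1 + stats::rnorm(n, 0, noise)))
}

test_that("percentile CIs match a direct quantile computation", {
  est <- cbind(a = c(1, 2, 3), b = c(0.5, 0.5, 0.5), c = c(2, 9, 4))
  fb <- fake_bootstrap(est)
  s <- summarize_identifiability(fb)$parameters
  for (p in colnames(est)) {
    q <- unname(stats::quantile(est[, p], c(0.025, 0.975), type = 7))
    row <- s[s$parameter == p, ]
    expect_equal(c(row$ci_lower, row$ci_upper), q)
    expect_equal(row$ci_length, diff(q))
    expect_gte(row$ci_lower, min(est[, p]))
    expect_lte(row$ci_upper, max(est[, p]))
  }
  # constant column: zero-length interval
  expect_equal(s$ci_length[s$parameter == "b"], 0)
})

test_that("summaries are invariant under replicate permutation", {
  set.seed(66)
  est <- cbind(a = stats::runif(15), b = stats::runif(15, 1, 2))
  s1 <- summarize_identifiability(fake_bootstrap(est))$parameters
  s2 <- summarize_identifiability(fake_bootstrap(est[sample(15), ]))$parameters
  expect_equal(s1, s2)
})

test_that("high-correlation pairs are flagged and sorted by |r|", {
  # identity correlation: nothing flagged
  set.seed(8)
  ind <- cbind(a = stats::rnorm(200), b = stats::rnorm(200))
  expect_equal(nrow(summarize_identifiability(
    fake_bootstrap(ind, lower = -10, upper = 10))$high_correlations), 0)

  x <- stats::rnorm(50)
  est <- cbind(a = x, b = -x + stats::rnorm(50, 0, 0.01),
               c = x + stats::rnorm(50, 0, 0.05))
  pairs <- summarize_identifiability(
    fake_bootstrap(est, lower = -10, upper = 10),
    cor_threshold = 0.9)$high_correlations
  expect_equal(pairs$param_1[1], "a")   # strongest pair first
  expect_equal(pairs$param_2[1], "b")
  expect_true(all(abs(pairs$r) > 0.9))
  expect_true(all(diff(abs(pairs$r)) <= 0))
})

test_that("bound pile-ups are flagged by the stated definition", {
  lower <- 0; upper <- 4
  est <- cbind(at_bound = c(rep(0.01, 6), stats::runif(4, 1, 3)),
               free = stats::runif(10, 1, 3))
  s <- summarize_identifiability(fake_bootstrap(est))$parameters
  expect_true(s$bound_pileup[s$parameter == "at_bound"])   # 60% within 1%
  expect_false(s$bound_pileup[s$parameter == "free"])
})

test_that("zero noise with a fixed refit seed gives identical replicates", {
  toy <- sum_degenerate_toy()
  d <- toy_ridge_dataset()
  bs <- bootstrap_identify(toy, d, noise_level = 0, n_replicates = 3,
                           criterion = criterion_config("E"),
                           de = cheap_de(100), seed = 5,
                           vary_refit_seeds = FALSE)
  expect_true(all(bs$summary$ci_length == 0))
  expect_true(all(bs$summary$sd == 0))
  est <- as.matrix(bs$estimates[, c("a", "b", "c")])
  expect_equal(est[1, ], est[2, ])
})

test_that("the correlation matrix is a valid Pearson matrix", {
  toy <- sum_degenerate_toy()
  d <- toy_ridge_dataset(noise = 0.05)
  bs <- bootstrap_identify(toy, d, noise_level = 0.05, n_replicates = 6,
                           de = cheap_de(150), seed = 9)
  cm <- bs$correlation
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
})

test_that("average CI length grows with the noise level", {
  toy <- sum_degenerate_toy()
  d <- toy_ridge_dataset()
  ci_at <- function(noise) {
    bs <- bootstrap_identify(toy, d, noise_level = noise, n_replicates = 8,
                             de = cheap_de(300), seed = 31)
    mean(bs$summary$ci_length[bs$summary$parameter == "c"])
  }
  expect_lt(ci_at(0.01), ci_at(0.25))
})

test_that("bootstrap outputs are written as parseable tables", {
  toy <- sum_degenerate_toy()
  d <- toy_ridge_dataset(noise = 0.05)
  bs <- bootstrap_identify(toy, d, noise_level = 0.05, n_replicates = 3,
                           de = cheap_de(100), seed = 2)
  dir <- tempfile()
  write_bootstrap(bs, dir)
  sm <- utils::read.csv(file.path(dir, "parameter_summary.csv"))
  expect_equal(sm$parameter, c("a", "b", "c"))
  cm <- utils::read.csv(file.path(dir, "estimate_correlation.csv"),
                        row.names = 1)
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(glance(bs)$n_replicates, 3)
  expect_equal(nrow(tidy(bs)), 3)
})
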