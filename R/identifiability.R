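#' Bootstrap practical-identifiability analysis
#'
#' Repeatedly perturbs every measured value with independent zero-mean
#' Gaussian noise of standard deviation `noise_level * |value|`, refits the
#' model structure on each perturbed dataset, and collects the parameter
#' estimates. The spread of the replicate estimates measures the practical
#' identifiability of each parameter given data of that quality; strong
#' pairwise correlations between estimates expose parameter combinations the
#' data cannot separate.
#'
#' @param model A `rab_structure` (or toy model) to refit.
#' @param dataset The `rab_dataset` to perturb.
#' @param noise_level Proportional noise level (>= 0).
#' @param n_replicates Number of bootstrap replicates (>= 2).
#' @param criterion A [criterion_config()].
#' @param de A [de_config()]; use a reduced `budget_multiplier` for
#'   desk-scale runs.
#' @param seed Master seed; per-replicate noise and refit seeds are derived
#'   from it.
#' @param vary_refit_seeds If `FALSE`, every replicate refit uses the same
#'   optimizer seed, so that at `noise_level = 0` all replicates are
#'   identical (zero-length confidence intervals).
#' @return A `rab_bootstrap`: `estimates` (replicate x parameter tibble),
#'   `correlation` matrix, `summary` tibble (via
#'   [summarize_identifiability()] defaults), and run metadata.
#' @export
bootstrap_identify <- function(model, dataset, noise_level = 0.1,
                               n_replicates = 100,
                               criterion = criterion_config("E"),
                               de = de_config(), seed = 1L,
                               vary_refit_seeds = TRUE) {
  stopifnot(noise_level >= 0, n_replicates >= 2)
  space <- model_param_space(model)
  n <- nrow(dataset)

  reps <- purrr::map(seq_len(n_replicates), function(rep) {
    set.seed(derive_seed(seed, 500000L + rep))
    d_rep <- rab_dataset(
      dataset$t,
      dataset$Rab5 + stats::rnorm(n, 0, noise_level * abs(dataset$Rab5)),
      dataset$Rab7 + stats::rnorm(n, 0, noise_level * abs(dataset$Rab7)),
      t_s = attr(dataset, "t_s")
    )
    refit_seed <- if (vary_refit_seeds) derive_seed(seed, rep)
                  else derive_seed(seed, 1L)
    fit_structure(model, d_rep, criterion, de, seed = refit_seed)
  })

  ok <- vapply(reps, function(f) f$value < 1e6, TRUE)
  if (!any(ok)) {
    stop("all bootstrap replicates failed to fit", call. = FALSE)
  }
  est <- do.call(rbind, lapply(reps[ok], function(f) f$par))
  estimates <- tibble::as_tibble(est)
  estimates <- dplyr::mutate(estimates, replicate = which(ok),
                             value = vapply(reps[ok], `[[`, 0, "value"),
                             .before = 1)

  cm <- suppressWarnings(stats::cor(est))
  cm[is.na(cm)] <- 0  # constant estimates: correlation undefined, report 0
  diag(cm) <- 1

  out <- structure(
    list(estimates = estimates, correlation = cm, param_space = space,
         noise_level = noise_level, n_replicates = n_replicates,
         n_failed = sum(!ok), seed = as.integer(seed),
         criterion = criterion),
    class = "rab_bootstrap"
  )
  out$summary <- summarize_identifiability(out)$parameters
  out
}

#' @export
print.rab_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<rab_bootstrap> %d replicates (%d failed), noise level %.3g, %d parameters\n",
    x$n_replicates, x$n_failed, x$noise_level, nrow(x$param_space)))
  print(x$summary)
  invisible(x)
}

#' Summarize a bootstrap identifiability result
#'
#' Per-parameter distribution statistics (mean, 95% percentile-bootstrap
#' confidence interval, CI-length-to-mean ratio) together with a flag for
#' estimates piling up at the box bounds, plus the pairs of parameters whose
#' estimates are strongly correlated (sorted by decreasing `|r|`).
#'
#' @param result A `rab_bootstrap`.
#' @param cor_threshold Absolute-correlation threshold for flagged pairs.
#' @param bound_tol An estimate is "at a bound" when within this fraction of
#'   the box width of either bound.
#' @param pileup_frac Flag a parameter when at least this fraction of its
#'   estimates are at a bound.
#' @return List with `parameters` (tibble) and `high_correlations` (tibble
#'   with `param_1`, `param_2`, `r`).
#' @export
summarize_identifiability <- function(result, cor_threshold = 0.9,
                                      bound_tol = 0.01, pileup_frac = 0.5) {
  stopifnot(inherits(result, "rab_bootstrap"))
  space <- result$param_space
  est <- as.matrix(result$estimates[, space$name])

  params <- purrr::map_dfr(seq_len(ncol(est)), function(j) {
    x <- est[, j]
    q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    width <- space$upper[j] - space$lower[j]
    at_bound <- mean(x - space$lower[j] <= bound_tol * width |
                       space$upper[j] - x <= bound_tol * width)
    tibble::tibble(
      parameter = space$name[j],
      mean = mean(x), sd = stats::sd(x),
      ci_lower = q[1], ci_upper = q[2],
      ci_length = q[2] - q[1],
      ci_to_mean = (q[2] - q[1]) / abs(mean(x)),
      at_bound_frac = at_bound,
      bound_pileup = at_bound >= pileup_frac
    )
  })

  cm <- result$correlation
  iu <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble::tibble(
    param_1 = rownames(cm)[iu[, 1]],
    param_2 = colnames(cm)[iu[, 2]],
    r = cm[iu]
  )
  pairs <- dplyr::arrange(pairs[abs(pairs$r) > cor_threshold, ],
                          dplyr::desc(abs(.data$r)))
  list(parameters = params, high_correlations = pairs)
}

#' @rdname summarize_identifiability
#' @param x A `rab_bootstrap`.
#' @param ... Unused.
#' @method tidy rab_bootstrap
#' @export
tidy.rab_bootstrap <- function(x, ...) x$summary

#' @method glance rab_bootstrap
#' @export
glance.rab_bootstrap <- function(x, ...) {
  tibble::tibble(
    noise_level = x$noise_level,
    n_replicates = x$n_replicates,
    n_failed = x$n_failed,
    median_ci_to_mean = stats::median(x$summary$ci_to_mean),
    n_bound_pileup = sum(x$summary$bound_pileup)
  )
}

#' Plot bootstrap estimate distributions
#'
#' @param object A `rab_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object (one histogram facet per parameter).
#' @method autoplot rab_bootstrap
#' @export
autoplot.rab_bootstrap <- function(object, ...) {
  long <- tidyr::pivot_longer(object$estimates,
                              dplyr::all_of(object$param_space$name),
                              names_to = "parameter", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "bootstrap estimate", y = "replicates")
}

#' Write bootstrap outputs to disk
#'
#' Writes the per-parameter summary table and the estimate correlation
#' matrix as CSV, and the run metadata as JSON-like plain text.
#'
#' @param result A `rab_bootstrap`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bootstrap <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$summary, file.path(dir, "parameter_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$correlation),
                   file.path(dir, "estimate_correlation.csv"))
  meta <- c(
    sprintf('{"noise_level": %.17g,', result$noise_level),
    sprintf(' "n_replicates": %d,', result$n_replicates),
    sprintf(' "n_failed": %d,', result$n_failed),
    sprintf(' "seed": %d,', result$seed),
    sprintf(' "criterion": "%s"}', result$criterion$criterion)
  )
  writeLines(meta, file.path(dir, "run_metadata.json"))
  invisible(dir)
}

#' A deliberately non-identifiable toy model
#'
#' A closed-form two-channel model in which two parameters enter the output
#' only through their sum: channel 1 is `(a + b) * t + 1`, channel 2 is
#' `c * t + 1`. Fitting it leaves the split between `a` and `b` undetermined
#' (a one-dimensional ridge), so bootstrap replicate estimates of `a` and
#' `b` are strongly anti-correlated — the textbook signature practical
#' identifiability analysis is meant to expose. Fit it with the error-only
#' criterion (it has no hidden active states).
#'
#' @param bounds Box bounds shared by `a`, `b`, `c`.
#' @return A `rab_toy_model` usable with [fit_structure()] and
#'   [bootstrap_identify()].
#' @export
#' @examples
#' toy <- sum_degenerate_toy()
#' toy$predict(list(a = 1, b = 2, c = 0.5), 0:3)
sum_degenerate_toy <- function(bounds = c(0.001, 4)) {
  structure(
    list(
      param_space = tibble::tibble(
        name = c("a", "b", "c"),
        lower = bounds[1], upper = bounds[2], scale = "linear"
      ),
      predict = function(params, times) {
        tibble::tibble(
          Rab5_hat = (params$a + params$b) * times + 1,
          Rab7_hat = params$c * times + 1
        )
      }
    ),
    class = "rab_toy_model"
  )
}
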