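#' Construct a measurement dataset
#'
#' A dataset holds the two observed fluorescence-intensity channels (total
#' Rab5 and total Rab7) on a common, strictly increasing time grid, together
#' with the measured switch time `t_s` — the earliest time from which the
#' Rab7 channel dominates the Rab5 channel persistently. If `t_s` is not
#' supplied it is detected with [switch_time()].
#'
#' @param t Measurement times (s), strictly increasing.
#' @param Rab5,Rab7 Measured channel intensities, same length as `t`.
#' @param t_s Optional externally supplied switch time (s).
#' @param persistence Persistence window (s) for switch detection when `t_s`
#'   is not supplied.
#' @return A `rab_dataset` tibble with columns `t`, `Rab5`, `Rab7` and
#'   attributes `t0`, `tmax`, `t_s`.
#' @export
#' @examples
#' d <- rab_dataset(0:2, Rab5 = c(3, 2, 1), Rab7 = c(1, 2, 3), persistence = 0)
#' attr(d, "t_s")
rab_dataset <- function(t, Rab5, Rab7, t_s = NULL, persistence = 5) {
  if (length(Rab5) != length(t) || length(Rab7) != length(t)) {
    stop("channels must have the same length as the time grid", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  d <- tibble::tibble(t = as.numeric(t), Rab5 = as.numeric(Rab5),
                      Rab7 = as.numeric(Rab7))
  if (is.null(t_s)) t_s <- switch_time(d$t, d$Rab5, d$Rab7, persistence)
  attr(d, "t0") <- d$t[1]
  attr(d, "tmax") <- d$t[length(d$t)]
  attr(d, "t_s") <- t_s
  class(d) <- c("rab_dataset", class(d))
  d
}

#' Relative root-mean-squared model error E
#'
#' The average, over the two observed channels, of the root of the sum of
#' squared residuals normalized by the channel's total sum of squares about
#' its mean. `E = 0` is a perfect fit; `E = 1` is the error of the baseline
#' model that predicts the channel mean at every time point.
#'
#' @param dataset A `rab_dataset` (or data frame with `Rab5`, `Rab7`).
#' @param sim Simulated outputs at the dataset times: a `rab_trajectory` or
#'   data frame with columns `Rab5_hat`, `Rab7_hat`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' d <- rab_dataset(0:2, c(1, 2, 3), c(3, 2, 1))
#' error_E(d, data.frame(Rab5_hat = c(1, 2, 5), Rab7_hat = c(3, 2, 1)))
error_E <- function(dataset, sim) {
  one <- function(y, yhat) {
    if (length(yhat) != length(y)) {
      stop("simulated outputs must be sampled at the dataset times",
           call. = FALSE)
    }
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
      stop("measured channel has zero variance; E is undefined", call. = FALSE)
    }
    sqrt(sum((y - yhat)^2) / sst)
  }
  (one(dataset$Rab5, sim$Rab5_hat) + one(dataset$Rab7, sim$Rab7_hat)) / 2
}

# Pearson correlation with the degenerate (zero-variance) case mapped to 0:
# a flat hidden state cannot explain a switching total.
safe_pearson <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r <- suppressWarnings(stats::cor(x, y))
  if (is.na(r)) 0 else r
}

#' Hidden-state correlation criterion R
#'
#' Measures how well the simulated active-state concentrations track the
#' observed totals: `R = ( min(1 - r(R5_hat, Rab5), 1) +
#' min(1 - r(R7_hat, Rab7), 1) ) / 2` with `r` the Pearson correlation.
#' `R = 0` when both active states are perfectly positively correlated with
#' their totals; anti-correlation is clamped so that `R` stays in `[0, 1]`.
#'
#' @param dataset A `rab_dataset`.
#' @param traj Simulated trajectory (needs columns `R5`, `R7`) sampled at
#'   the dataset times, or a data frame with those columns.
#' @return Scalar in `[0, 1]`.
#' @export
corr_R <- function(dataset, traj) {
  if (length(traj$R5) != nrow(dataset)) {
    stop("trajectory must be sampled at the dataset times", call. = FALSE)
  }
  (min(1 - safe_pearson(traj$R5, dataset$Rab5), 1) +
     min(1 - safe_pearson(traj$R7, dataset$Rab7), 1)) / 2
}

#' Detect the dominance switch time between two channels
#'
#' Returns the earliest time at which channel `b` reaches or exceeds channel
#' `a` and remains so for at least `persistence` seconds (or until the end
#' of the series, whichever comes first). With `persistence = 0` this is the
#' first crossing; if the channels are equal everywhere the first time point
#' is returned.
#'
#' @param times Strictly increasing times.
#' @param a,b Channel values (`a` initially dominant, `b` taking over).
#' @param persistence Persistence window (s).
#' @return The switch time, or `NA_real_` if no persistent switch occurs.
#' @export
#' @examples
#' switch_time(0:2, a = c(3, 2, 1), b = c(1, 2, 3), persistence = 0)  # 1
switch_time <- function(times, a, b, persistence = 5) {
  stopifnot(length(a) == length(b), length(a) == length(times))
  ok <- b >= a
  if (!any(ok)) return(NA_real_)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- length(times)
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    s <- starts[j]; e <- ends[j]
    if (e == n || times[e + 1L] > times[s] + persistence) return(times[s])
  }
  NA_real_
}

#' Switch-time displacement criterion X
#'
#' The absolute difference between the measured and the simulated switch
#' times, normalized by the length of the observation interval:
#' `X = |t_s - t_s_hat| / (tmax - t0)`. A simulation without a switch
#' receives the maximum penalty `X = 1`.
#'
#' @param dataset A `rab_dataset` carrying `t_s`, `t0`, `tmax` attributes.
#' @param t_s_hat Simulated switch time (s), or `NA` for "no switch".
#' @return Scalar in `[0, 1]`.
#' @export
switch_X <- function(dataset, t_s_hat) {
  t0 <- attr(dataset, "t0"); tmax <- attr(dataset, "tmax")
  t_s <- attr(dataset, "t_s")
  if (is.null(t0) || is.null(tmax) || tmax == t0) {
    stop("dataset must span a non-degenerate time interval", call. = FALSE)
  }
  if (is.null(t_s) || is.na(t_s)) {
    stop("dataset has no measured switch time t_s", call. = FALSE)
  }
  if (is.na(t_s_hat)) return(1)
  min(abs(t_s - t_s_hat) / (tmax - t0), 1)
}

criterion_ids <- c("E", "R", "X", "RX", "ER", "EX", "ERX",
                   "EC", "ERC", "EXC", "ERXC")

#' Model-selection criterion configuration
#'
#' @param criterion One of `E`, `R`, `X`, `RX`, `ER`, `EX`, `ERX`, `EC`,
#'   `ERC`, `EXC`, `ERXC`.
#' @param alpha Trade-off in `[0, 1]` between the error `E` (weight `alpha`)
#'   and the domain-specific components `R`/`X`/`RX`.
#' @param beta Trade-off in `[0, 1]` between fit (weight `beta`) and model
#'   complexity for the `*C` criteria.
#' @param complexity_mode `"normalized"` uses `(C - Cmin) / (Cmax - Cmin)`
#'   over the candidate set; `"raw"` uses the process count itself.
#' @param persistence Persistence window (s) for simulated switch detection.
#' @return A `rab_criterion` configuration list.
#' @export
criterion_config <- function(criterion = "ERX", alpha = 0.5, beta = 0.5,
                             complexity_mode = c("normalized", "raw"),
                             persistence = 5) {
  if (!criterion %in% criterion_ids) {
    stop("unknown criterion '", criterion, "'; valid: ",
         paste(criterion_ids, collapse = ", "), call. = FALSE)
  }
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  structure(list(criterion = criterion, alpha = alpha, beta = beta,
                 complexity_mode = match.arg(complexity_mode),
                 persistence = persistence),
            class = "rab_criterion")
}

#' Combine criterion components into a selection-criterion value
#'
#' Implements the combined criteria: `RX = (R + X)/2`;
#' `ER = alpha E + (1-alpha) R`, `EX = alpha E + (1-alpha) X`,
#' `ERX = alpha E + (1-alpha) RX`; and the complexity trade-offs
#' `EC = beta E + (1-beta) C`, `ERC = beta ER + (1-beta) C`,
#' `EXC = beta EX + (1-beta) C`, `ERXC = beta ERX + (1-beta) C`,
#' where `C` is the (raw or normalized) model complexity.
#'
#' @param E,R,X Component values.
#' @param C Complexity value on the configured scale (raw process count or
#'   normalized to `[0, 1]`); only needed for the `*C` criteria.
#' @param alpha,beta Trade-off parameters in `[0, 1]`.
#' @param criterion Criterion id, see [criterion_config()].
#' @return Scalar criterion value.
#' @export
#' @examples
#' combine_criteria(E = 0.4, R = 0.6, X = 0.2, alpha = 0.5, criterion = "ERX")
combine_criteria <- function(E, R = NA_real_, X = NA_real_, C = NA_real_,
                             alpha = 0.5, beta = 0.5, criterion = "ERX") {
  RX <- (R + X) / 2
  ER <- alpha * E + (1 - alpha) * R
  EX <- alpha * E + (1 - alpha) * X
  ERX <- alpha * E + (1 - alpha) * RX
  out <- switch(criterion,
    E = E, R = R, X = X, RX = RX, ER = ER, EX = EX, ERX = ERX,
    EC = beta * E + (1 - beta) * C,
    ERC = beta * ER + (1 - beta) * C,
    EXC = beta * EX + (1 - beta) * C,
    ERXC = beta * ERX + (1 - beta) * C,
    stop("unknown criterion '", criterion, "'", call. = FALSE)
  )
  out
}

# Components (E, R, X and the simulated switch time) of one simulated
# trajectory against a dataset. Internal work-horse shared by the fitting
# objective and the scorecard.
trajectory_components <- function(dataset, traj, persistence = 5) {
  t_s_hat <- switch_time(traj$t, traj$Rab5_hat, traj$Rab7_hat, persistence)
  list(
    E = error_E(dataset, traj),
    R = corr_R(dataset, traj),
    X = switch_X(dataset, t_s_hat),
    t_s_hat = t_s_hat
  )
}

#' Score fitted models under every selection criterion
#'
#' Re-simulates each fitted model at its best parameters and tabulates all
#' criterion values: the error `E`, the hidden-state correlation `R`, the
#' switch displacement `X`, their combinations `RX`, `ER`, `EX`, `ERX`
#' (trade-off `alpha`), and the complexity trade-offs `EC`, `ERC`, `EXC`,
#' `ERXC` (trade-off `beta`). Complexity enters on the configured scale.
#'
#' @param fits Result of [fit_all()] (tibble with a `fit` list-column), or a
#'   list of [fit_structure()] results.
#' @param dataset The `rab_dataset` the models were fitted to.
#' @param alpha,beta Trade-off parameters.
#' @param complexity_mode `"normalized"` (over the scored set) or `"raw"`.
#' @param persistence Persistence window (s) for simulated switch detection.
#' @return A `rab_scorecard` tibble, one row per model, with the slot
#'   choices, `C`, `C_scaled`, and all eleven criterion values.
#' @export
score_models <- function(fits, dataset, alpha = 0.5, beta = 0.5,
                         complexity_mode = c("normalized", "raw"),
                         persistence = 5) {
  complexity_mode <- match.arg(complexity_mode)
  if (is.data.frame(fits)) fits <- fits$fit
  stopifnot(length(fits) > 0)

  rows <- purrr::map(fits, function(f) {
    st <- f$structure
    traj <- simulate_structure(st, f$par, dataset$t)
    if (sim_failed(traj)) {
      comp <- list(E = Inf, R = 1, X = 1, t_s_hat = NA_real_)
    } else {
      comp <- trajectory_components(dataset, traj, persistence)
    }
    tibble::tibble(
      structure_id = st$structure_id,
      gef5 = st$choices[["gef5"]], gap5 = st$choices[["gap5"]],
      gef7 = st$choices[["gef7"]], gap7 = st$choices[["gap7"]],
      C = st$n_processes,
      E = comp$E, R = comp$R, X = comp$X, t_s_hat = comp$t_s_hat
    )
  })
  sc <- dplyr::bind_rows(rows)
  sc$C_scaled <- if (complexity_mode == "normalized") {
    if (max(sc$C) > min(sc$C)) (sc$C - min(sc$C)) / (max(sc$C) - min(sc$C))
    else rep(0, nrow(sc))
  } else {
    as.numeric(sc$C)
  }
  for (id in setdiff(criterion_ids, c("E", "R", "X"))) {
    sc[[id]] <- purrr::pmap_dbl(
      list(sc$E, sc$R, sc$X, sc$C_scaled),
      function(E, R, X, C) combine_criteria(E, R, X, C, alpha, beta, id)
    )
  }
  attr(sc, "alpha") <- alpha
  attr(sc, "beta") <- beta
  attr(sc, "complexity_mode") <- complexity_mode
  class(sc) <- c("rab_scorecard", class(sc))
  sc
}
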