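kind_code <- c(intrinsic = 1, michaelis_menten = 2, sigmoidal = 3,
               exchange_inhibition = 4, linear = 5)
reg_code <- c(none = 0, R5 = 1, R7 = 2)

# Pack named parameters into the fixed 29-double layout consumed by the
# compiled right-hand side (see src/rab_rhs.c).
rhs_parms <- function(structure, params) {
  pv <- numeric(29)
  pv[1:4] <- unlist(params[c("K1", "k1", "K2", "k2")])
  block_of <- function(slot, role) {
    switch(slot, gef5 = 0L, gap5 = 1L,
           gef7 = if (role == "cross") 2L else 3L, gap7 = 4L)
  }
  for (cp in structure$components) {
    off <- 4L + 5L * block_of(cp$slot, cp$role)
    pv[off + 1L] <- kind_code[[cp$kind]]
    pv[off + 2L] <- reg_code[[cp$regulator]]
    vals <- unlist(params[cp$params])
    pv[off + 3L] <- vals[[1]]                      # k or V
    if (length(vals) > 1L) pv[off + 4L] <- vals[[2]]  # Km
    pv[off + 5L] <- structure$hill_exponent
  }
  pv
}

check_params <- function(structure, params) {
  missing <- setdiff(structure$param_space$name, names(params))
  if (length(missing) > 0L) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Simulate a candidate structure over a measurement time grid
#'
#' Numerically integrates the compiled kinetic system from its initial
#' concentrations with a stiff-capable variable-step solver (lsoda) and maps
#' the hidden states to the observed channels. Simulation internal time
#' starts at 0; a measurement time `t` corresponds to internal time
#' `(t - t[1]) + td`, so the free onset offset `td` aligns the unknown start
#' of the kinetics with the first measurement.
#'
#' Integration failures (step-size collapse, non-finite states) are returned
#' as a structured failure object rather than raised, so that parameter
#' estimation can penalize them.
#'
#' @param structure A `rab_structure` from [build_structure()].
#' @param params Named list/vector covering the structure's parameter space
#'   (see [build_structure()]); `td` may be omitted, in which case internal
#'   time equals `times - times[1]`.
#' @param times Strictly increasing measurement times (s).
#' @param rtol,atol Solver tolerances.
#' @param maxsteps Maximum internal solver steps per output interval;
#'   ill-conditioned parameter draws abort (and are penalized) faster with
#'   smaller values.
#' @param engine `"c"` (default) uses the compiled right-hand side; `"r"`
#'   integrates the [compile_rhs()] closure (slow, for cross-checking).
#' @return A `rab_trajectory` tibble with columns `t`, hidden states `r5`,
#'   `R5`, `r7`, `R7`, and observed outputs `Rab5_hat`, `Rab7_hat`; or a
#'   `rab_sim_failure` object. Test with [sim_failed()].
#' @export
#' @examples
#' s <- build_structure(1, 1, 1, 1)
#' p <- c(K1 = 0, k1 = 0.001, K2 = 0, k2 = 0.001,
#'        r5_0 = 1, R5_0 = 0.5, r7_0 = 1, R7_0 = 0.1, K = 1000, td = 5,
#'        gef5_V = 0.5, gef5_Km = 1, gap5_k = 0.1,
#'        gef7_cross_V = 0.5, gef7_cross_Km = 1, gap7_k = 0.1)
#' simulate_structure(s, p, seq(0, 10, by = 1))
simulate_structure <- function(structure, params, times,
                               rtol = 1e-6, atol = 1e-8, maxsteps = 2000,
                               engine = c("c", "r")) {
  stopifnot(inherits(structure, "rab_structure"))
  engine <- match.arg(engine)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  params <- as.list(params)
  td <- if (!is.null(params$td)) params$td else 0
  needed <- setdiff(structure$param_space$name, c("td", "K"))
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0L) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  K <- if (!is.null(params$K)) params$K else 1

  internal <- (times - times[1]) + td
  pad <- internal[1] > 0
  it <- if (pad) c(0, internal) else internal
  y0 <- c(r5 = params$r5_0, R5 = params$R5_0,
          r7 = params$r7_0, R7 = params$R7_0)

  # the solver prints step-size diagnostics on hard failures; keep them out
  # of the console, the failure object carries the condition instead
  sink_file <- file(nullfile(), open = "wt")
  sink(sink_file)
  out <- tryCatch(suppressWarnings({
    if (engine == "c") {
      deSolve::ode(y = unlist(y0), times = it, func = "rab_derivs",
                   parms = rhs_parms(structure, params),
                   dllname = "rabswitch", initfunc = "rab_init",
                   rtol = rtol, atol = atol, maxsteps = maxsteps)
    } else {
      rhs <- compile_rhs(structure)
      pv <- unlist(params[needed])
      deSolve::ode(y = unlist(y0), times = it,
                   func = function(t, y, p) list(rhs(y, pv)),
                   parms = NULL, rtol = rtol, atol = atol,
                   maxsteps = maxsteps)
    }
  }), error = function(e) e, finally = {
    sink()
    close(sink_file)
  })

  if (inherits(out, "error") || nrow(out) < length(it) ||
      !all(is.finite(out[, 2:5]))) {
    msg <- if (inherits(out, "error")) conditionMessage(out)
           else "integration did not reach the end of the time grid"
    return(structure(list(message = msg, structure_id = structure$structure_id),
                     class = "rab_sim_failure"))
  }
  states <- out[if (pad) -1L else TRUE, , drop = FALSE]
  traj <- tibble::tibble(
    t = times,
    r5 = states[, "r5"], R5 = states[, "R5"],
    r7 = states[, "r7"], R7 = states[, "R7"]
  )
  traj <- dplyr::bind_cols(traj, observe(traj, K))
  class(traj) <- c("rab_trajectory", class(traj))
  traj
}

#' Did a simulation fail?
#'
#' @param x Result of [simulate_structure()].
#' @return `TRUE` for a structured integration-failure object.
#' @export
sim_failed <- function(x) inherits(x, "rab_sim_failure")

#' @export
print.rab_sim_failure <- function(x, ...) {
  cat("<rab_sim_failure>", x$message, "\n")
  invisible(x)
}

#' Observation map: scaled total concentrations
#'
#' Only the totals of active- and passive-state concentrations are
#' experimentally observable, up to an intensity scaling factor:
#' `Rab5_hat = K * (r5 + R5)` and `Rab7_hat = K * (r7 + R7)`.
#'
#' @param states A data frame (or `rab_trajectory`) with columns `r5`, `R5`,
#'   `r7`, `R7`.
#' @param K Positive scaling factor (intensity per concentration unit).
#' @return A tibble with columns `Rab5_hat`, `Rab7_hat`.
#' @export
#' @examples
#' observe(data.frame(r5 = 1, R5 = 2, r7 = 3, R7 = 4), K = 1)
observe <- function(states, K) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop("scaling factor K must be a positive number", call. = FALSE)
  }
  tibble::tibble(
    Rab5_hat = K * (states$r5 + states$R5),
    Rab7_hat = K * (states$r7 + states$R7)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Two panels: the observed channels (scaled totals) and the hidden active/
#' passive state concentrations.
#'
#' @param object A `rab_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rab_trajectory
#' @export
autoplot.rab_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "series", values_to = "value")
  long$panel <- ifelse(long$series %in% c("Rab5_hat", "Rab7_hat"),
                       "observed outputs", "hidden states")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
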