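#' Differential Evolution settings
#'
#' Defaults follow the settings found best-suited to this estimation task in
#' earlier work on the endocytosis model: population 81, strategy rand/1/bin,
#' differential weight `F = 0.942`, crossover probability `Cr = 0.915`, and
#' an evaluation budget of 20,000 objective evaluations per free parameter.
#'
#' @param pop_size Population size (>= 4).
#' @param F Differential weight (> 0).
#' @param Cr Crossover probability in `[0, 1]`.
#' @param budget_multiplier Objective-evaluation budget per free parameter.
#' @return A `rab_de_config` list.
#' @export
de_config <- function(pop_size = 81, F = 0.942, Cr = 0.915,
                      budget_multiplier = 20000) {
  stopifnot(pop_size >= 4, F > 0, Cr >= 0, Cr <= 1, budget_multiplier >= 1)
  structure(list(pop_size = as.integer(pop_size), F = F, Cr = Cr,
                 budget_multiplier = budget_multiplier),
            class = "rab_de_config")
}

#' Minimize a box-constrained objective with DE rand/1/bin
#'
#' Plain rand/1/bin Differential Evolution: each generation, every target
#' vector is challenged by a trial built from three distinct random
#' population members (`x_r1 + F * (x_r2 - x_r3)`), binomial crossover with
#' one guaranteed mutant coordinate, clipping to the box, and greedy
#' replacement. Replacement is synchronous (generational): trials compete
#' against the population as it stood at the start of the generation.
#' Budget accounting counts objective evaluations, including the initial
#' population.
#'
#' @param fn Objective `function(theta) -> scalar`; smaller is better.
#' @param lower,upper Box bounds (equal-length numeric vectors).
#' @param budget Total number of objective evaluations allowed; must be at
#'   least the population size.
#' @param config A [de_config()].
#' @param seed Integer seed; runs are bitwise reproducible given the seed.
#' @param scale Optional per-dimension sampling scale for the initial
#'   population: `"linear"` (uniform) or `"log"` (log-uniform).
#' @return List with `par`, `value`, `evaluations`, `history` (best value
#'   after each completed generation).
#' @export
de_optimize <- function(fn, lower, upper, budget, config = de_config(),
                        seed = 1L, scale = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper))
  np <- config$pop_size
  if (budget < np) {
    stop("evaluation budget (", budget, ") is smaller than one generation (",
         np, ")", call. = FALSE)
  }
  if (is.null(scale)) scale <- rep("linear", d)

  set.seed(as.integer(seed))
  pop <- matrix(0, nrow = np, ncol = d)
  for (j in seq_len(d)) {
    pop[, j] <- if (scale[j] == "log") {
      10^stats::runif(np, log10(lower[j]), log10(upper[j]))
    } else {
      stats::runif(np, lower[j], upper[j])
    }
  }
  vals <- apply(pop, 1L, fn)
  evals <- np
  history <- min(vals)

  while (evals < budget) {
    newpop <- pop
    newvals <- vals
    for (i in seq_len(np)) {
      if (evals >= budget) break
      r <- sample(seq_len(np)[-i], 3L)
      mutant <- pop[r[1], ] + config$F * (pop[r[2], ] - pop[r[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- stats::runif(d) < config$Cr
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tv <- fn(trial)
      evals <- evals + 1L
      if (tv <= vals[i]) {
        newpop[i, ] <- trial
        newvals[i] <- tv
      }
    }
    pop <- newpop
    vals <- newvals
    history <- c(history, min(vals))
  }
  best <- which.min(vals)
  list(par = pop[best, ], value = vals[best], evaluations = evals,
       history = history)
}

criterion_needs <- function(criterion) {
  list(
    R = criterion %in% c("R", "RX", "ER", "ERX", "ERC", "ERXC"),
    X = criterion %in% c("X", "RX", "EX", "ERX", "EXC", "ERXC"),
    C = criterion %in% c("EC", "ERC", "EXC", "ERXC")
  )
}

# Parameter space of a fittable model (kinetic structure or toy).
model_param_space <- function(model) {
  if (inherits(model, "rab_structure")) model$param_space
  else if (inherits(model, "rab_toy_model")) model$param_space
  else stop("cannot fit objects of class ", class(model)[1], call. = FALSE)
}

# Simulated response of a fittable model at the dataset times: a data frame
# with Rab5_hat/Rab7_hat (and hidden states for kinetic structures), or a
# rab_sim_failure.
model_response <- function(model, params, times) {
  if (inherits(model, "rab_structure")) {
    simulate_structure(model, params, times)
  } else {
    model$predict(params, times)
  }
}

# Objective closure: criterion value of the simulated candidate, with failed
# integrations penalized.
make_objective <- function(model, dataset, criterion, C_value = 0,
                           failure_penalty = 1e6) {
  space <- model_param_space(model)
  needs <- criterion_needs(criterion$criterion)
  if (needs$R && inherits(model, "rab_toy_model")) {
    stop("criterion ", criterion$criterion,
         " needs hidden active states, which a toy model does not provide",
         call. = FALSE)
  }
  force(C_value)
  function(theta) {
    params <- stats::setNames(as.list(theta), space$name)
    resp <- model_response(model, params, dataset$t)
    if (sim_failed(resp)) return(failure_penalty)
    E <- error_E(dataset, resp)
    R <- if (needs$R) corr_R(dataset, resp) else NA_real_
    X <- if (needs$X) {
      switch_X(dataset, switch_time(dataset$t, resp$Rab5_hat, resp$Rab7_hat,
                                    criterion$persistence))
    } else NA_real_
    v <- combine_criteria(E, R, X, C_value, criterion$alpha, criterion$beta,
                          criterion$criterion)
    if (!is.finite(v)) failure_penalty else v
  }
}

#' Fit one model structure to a dataset by Differential Evolution
#'
#' Minimizes the configured selection criterion of the simulated candidate
#' over the structure's parameter box. Failed integrations contribute the
#' penalty value `1e6`; a candidate whose simulation shows no Rab5-to-Rab7
#' switch is not penalized this way — it receives the maximum switch
#' displacement `X = 1` inside the criterion. The scaling factor `K` is
#' sampled log-uniformly in the initial population (its box spans two
#' decades); all other parameters uniformly.
#'
#' @param model A `rab_structure` (or a toy model, see
#'   [sum_degenerate_toy()]).
#' @param dataset A `rab_dataset`.
#' @param criterion A [criterion_config()]. For the complexity trade-off
#'   criteria the structure's raw process count is used (a per-structure
#'   constant, so it does not move the optimum).
#' @param de A [de_config()].
#' @param seed Integer seed; results are bitwise reproducible given
#'   `(model, seed)`.
#' @return A `rab_fit`: `structure`, best `par` (named), best `value`, the
#'   per-generation best-value `history`, `evaluations`, `n_failures`,
#'   `seed`.
#' @export
fit_structure <- function(model, dataset, criterion = criterion_config("E"),
                          de = de_config(), seed = 1L) {
  space <- model_param_space(model)
  budget <- ceiling(de$budget_multiplier * nrow(space))
  C_value <- if (inherits(model, "rab_structure")) model$n_processes else 0
  n_fail <- 0L
  obj <- make_objective(model, dataset, criterion, C_value)
  counting <- function(theta) {
    v <- obj(theta)
    if (v >= 1e6) n_fail <<- n_fail + 1L
    v
  }
  res <- de_optimize(counting, space$lower, space$upper, budget,
                     config = de, seed = seed, scale = space$scale)
  par <- stats::setNames(res$par, space$name)
  structure(
    list(structure = model, par = par, value = res$value,
         criterion = criterion, evaluations = res$evaluations,
         history = res$history, n_failures = n_fail, seed = as.integer(seed)),
    class = "rab_fit"
  )
}

#' @export
print.rab_fit <- function(x, ...) {
  id <- if (inherits(x$structure, "rab_structure")) x$structure$structure_id
        else "toy"
  cat(sprintf("<rab_fit> structure %s: %s = %.6g after %d evaluations (%d failed)\n",
              id, x$criterion$criterion, x$value, x$evaluations, x$n_failures))
  invisible(x)
}

# Deterministic per-structure seed from (master seed, structure id).
derive_seed <- function(master_seed, structure_id) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 +
                as.numeric(structure_id) * 16807) %% 2147483629 + 1)
}

#' Fit a set of candidate structures
#'
#' Runs [fit_structure()] on every structure, with per-structure seeds
#' derived deterministically from the master seed and the canonical
#' structure id, so results do not depend on evaluation order.
#'
#' @param structures Result of [enumerate_structures()] (or a list of
#'   `rab_structure` objects).
#' @param dataset A `rab_dataset`.
#' @param criterion A [criterion_config()].
#' @param de A [de_config()].
#' @param master_seed Integer master seed.
#' @param progress Print one line per fitted structure.
#' @return A tibble with `structure_id`, slot indices, best `value`,
#'   `evaluations`, `n_failures`, `seed`, and a `fit` list-column.
#' @export
fit_all <- function(structures, dataset, criterion = criterion_config("E"),
                    de = de_config(), master_seed = 1L, progress = FALSE) {
  if (is.data.frame(structures)) structures <- structures$structure
  if (length(structures) == 0L) {
    stop("no structures to fit", call. = FALSE)
  }
  fits <- purrr::map(structures, function(st) {
    f <- fit_structure(st, dataset, criterion, de,
                       seed = derive_seed(master_seed, st$structure_id))
    if (progress) {
      message(sprintf("structure %3d: %s = %.5g",
                      st$structure_id, criterion$criterion, f$value))
    }
    f
  })
  tibble::tibble(
    structure_id = vapply(structures, `[[`, 1L, "structure_id"),
    gef5 = vapply(structures, function(s) s$choices[["gef5"]], 1L),
    gap5 = vapply(structures, function(s) s$choices[["gap5"]], 1L),
    gef7 = vapply(structures, function(s) s$choices[["gef7"]], 1L),
    gap7 = vapply(structures, function(s) s$choices[["gap7"]], 1L),
    value = vapply(fits, `[[`, 0, "value"),
    evaluations = vapply(fits, `[[`, 0L, "evaluations"),
    n_failures = vapply(fits, `[[`, 0L, "n_failures"),
    seed = vapply(fits, `[[`, 0L, "seed"),
    fit = fits
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model: one row per estimated parameter
#'
#' @param x A `rab_fit`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `estimate`, `lower`, `upper`.
#' @method tidy rab_fit
#' @export
tidy.rab_fit <- function(x, ...) {
  space <- model_param_space(x$structure)
  tibble::tibble(parameter = space$name, estimate = unname(x$par),
                 lower = space$lower, upper = space$upper)
}

#' One-row summary of a fitted model
#'
#' @param x A `rab_fit`.
#' @param ... Unused.
#' @return Tibble with the criterion id, best value, evaluations used,
#'   failed-simulation count and seed.
#' @method glance rab_fit
#' @export
glance.rab_fit <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion$criterion,
    value = x$value,
    evaluations = x$evaluations,
    n_failures = x$n_failures,
    seed = x$seed
  )
}
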