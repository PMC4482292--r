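# Shared fixtures: cheap structures, parameter draws and datasets.

# Simplest structure: MM GEF5 auto, intrinsic GAP5, MM GEF7 cross,
# intrinsic GAP7 (8 processes, 16 parameters).
simple_structure <- function() build_structure(1, 1, 1, 1)

# A complete, dynamically tame parameter set for simple_structure().
simple_params <- function(...) {
  p <- c(K1 = 0.1, k1 = 0.05, K2 = 0.08, k2 = 0.02,
         r5_0 = 1, R5_0 = 0.5, r7_0 = 1, R7_0 = 0.2, K = 1e4, td = 20,
         gef5_V = 0.3, gef5_Km = 0.6, gap5_k = 0.1,
         gef7_cross_V = 0.2, gef7_cross_Km = 0.5, gap7_k = 0.05)
  dots <- c(...)
  p[names(dots)] <- dots
  p
}

# Random admissible parameters for an arbitrary structure: kinetic rates and
# initial values drawn small enough that integration over [0, 50] succeeds.
random_params <- function(structure) {
  space <- structure$param_space
  vals <- vapply(seq_len(nrow(space)), function(i) {
    nm <- space$name[i]
    if (nm %in% c("K1", "k1", "K2", "k2")) stats::runif(1, 0.01, 0.5)
    else if (grepl("_0$", nm)) stats::runif(1, 0.1, 2)
    else if (nm == "K") 10^stats::runif(1, 3, 5)
    else if (nm == "td") stats::runif(1, 5, 50)
    else if (grepl("_Km$", nm)) stats::runif(1, 0.2, 2)
    else stats::runif(1, 0.01, 0.5)
  }, 0)
  stats::setNames(vals, space$name)
}

# Small two-channel dataset with a switch at t = 50 (linear crossing).
toy_dataset <- function(n = 21) {
  t <- seq(0, 100, length.out = n)
  rab_dataset(t, Rab5 = 100 - 0.5 * t, Rab7 = 30 + 0.5 * t, persistence = 0)
}

# DE settings small enough for unit tests.
cheap_de <- function(mult = 30) de_config(pop_size = 15, budget_multiplier = mult)
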