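#' The built-in endocytosis kinetic library
#'
#' Loads the declarative library of kinetic functional-form alternatives for
#' the four regulatory slots of the Rab5/Rab7 conversion template: GEF5 and
#' GAP5 (activation/deactivation of Rab5), GEF7 and GAP7 (activation/
#' deactivation of Rab7). Each slot offers mutually exclusive rate-law
#' alternatives (3, 3, 7 and 2 respectively), whose Cartesian product spans
#' the 126 candidate model structures.
#'
#' GEF7 alternatives are composites of a cross-activation component (driven
#' by active Rab5) and an optional auto-activation component (driven by
#' active Rab7).
#'
#' @param path Path to a library configuration document (YAML). Defaults to
#'   the copy shipped with the package.
#' @param hill_exponent Hill exponent used by every sigmoidal rate law
#'   (dimensionless, >= 1). Overrides the value in the document.
#' @param bounds Optional named list overriding box bounds; recognised names
#'   are `kinetic`, `initial`, `scaling`, `onset`, each a length-2 numeric
#'   `c(lower, upper)`.
#' @return An object of class `rab_library`: slots, per-kind parameter
#'   bounds and the Hill exponent.
#' @export
#' @examples
#' lib <- default_library()
#' lengths(lib$slots)
default_library <- function(path = NULL, hill_exponent = NULL, bounds = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "endocytosis_library.yaml",
                        package = "rabswitch", mustWork = TRUE)
  }
  doc <- yaml::read_yaml(path)
  if (!is.null(hill_exponent)) doc$hill_exponent <- hill_exponent
  stopifnot(is.numeric(doc$hill_exponent), doc$hill_exponent >= 1)
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      if (!nm %in% names(doc$bounds)) {
        stop("unknown bounds entry '", nm, "'", call. = FALSE)
      }
      stopifnot(length(bounds[[nm]]) == 2L, bounds[[nm]][1] < bounds[[nm]][2])
      doc$bounds[[nm]] <- as.numeric(bounds[[nm]])
    }
  }
  doc$bounds <- lapply(doc$bounds, as.numeric)
  structure(
    list(slots = doc$slots, bounds = doc$bounds,
         hill_exponent = as.numeric(doc$hill_exponent)),
    class = "rab_library"
  )
}

#' @export
print.rab_library <- function(x, ...) {
  cat("<rab_library> kinetic form alternatives per slot:\n")
  for (s in names(x$slots)) {
    cat(sprintf("  %-5s (%d): %s\n", s, length(x$slots[[s]]),
                paste(vapply(x$slots[[s]], `[[`, "", "name"), collapse = ", ")))
  }
  cat("  Hill exponent:", x$hill_exponent, "\n")
  invisible(x)
}

slot_sizes <- function(library) vapply(library$slots, length, 1L)

# kind -> free-parameter names (the Hill exponent is a fixed library constant)
form_param_names <- function(kind) {
  switch(kind,
    intrinsic = "k",
    linear = "k",
    michaelis_menten = c("V", "Km"),
    sigmoidal = c("V", "Km"),
    exchange_inhibition = c("V", "Km"),
    stop("unknown kinetic form kind '", kind, "'", call. = FALSE)
  )
}

# Evaluate one rate-law component at regulator value x.
eval_form <- function(kind, x, pars, h = 3) {
  switch(kind,
    intrinsic = pars[["k"]],
    linear = pars[["k"]] * x,
    michaelis_menten = pars[["V"]] * x / (pars[["Km"]] + x),
    sigmoidal = {
      xh <- x^h
      pars[["V"]] * xh / (pars[["Km"]]^h + xh)
    },
    exchange_inhibition = pars[["V"]] * pars[["Km"]] / (pars[["Km"]] + x),
    stop("unknown kinetic form kind '", kind, "'", call. = FALSE)
  )
}

#' Build one candidate model structure
#'
#' Assembles a single member of the candidate space from one alternative per
#' regulatory slot. The returned object carries the resolved rate-law
#' components, the process count used as model complexity, and the ordered
#' parameter box (names and bounds) that Differential Evolution searches.
#'
#' The parameter box always contains the GDI association rates/dissociation
#' fluxes `K1, k1, K2, k2`, the four initial concentrations
#' `r5_0, R5_0, r7_0, R7_0`, the observation scaling factor `K` and the
#' onset offset `td`, followed by the kinetic parameters of the chosen
#' forms (prefixed by slot, e.g. `gef5_V`, `gef7_cross_Km`).
#'
#' @param gef5,gap5,gef7,gap7 1-based alternative index for each slot.
#' @param library A `rab_library`, see [default_library()].
#' @return An object of class `rab_structure`.
#' @export
#' @examples
#' s <- build_structure(2, 3, 2, 1)
#' s$n_processes
build_structure <- function(gef5, gap5, gef7, gap7, library = default_library()) {
  sizes <- slot_sizes(library)
  idx <- c(gef5 = gef5, gap5 = gap5, gef7 = gef7, gap7 = gap7)
  for (s in names(idx)) {
    i <- idx[[s]]
    if (length(i) != 1L || is.na(i) || i != as.integer(i) ||
        i < 1L || i > sizes[[s]]) {
      stop("invalid alternative index ", i, " for slot '", s, "' (1..",
           sizes[[s]], ")", call. = FALSE)
    }
  }
  idx <- vapply(idx, as.integer, 1L)

  components <- list()
  for (s in names(idx)) {
    alt <- library$slots[[s]][[idx[[s]]]]
    for (comp in alt$components) {
      prefix <- if (s == "gef7") paste0(s, "_", comp$role) else s
      pnames <- form_param_names(comp$kind)
      components[[length(components) + 1L]] <- list(
        slot = s, role = comp$role, kind = comp$kind,
        regulator = comp$regulator,
        params = stats::setNames(paste0(prefix, "_", pnames), pnames)
      )
    }
  }

  kb <- library$bounds$kinetic
  base <- tibble::tibble(
    name  = c("K1", "k1", "K2", "k2", "r5_0", "R5_0", "r7_0", "R7_0", "K", "td"),
    lower = c(rep(kb[1], 4), rep(library$bounds$initial[1], 4),
              library$bounds$scaling[1], library$bounds$onset[1]),
    upper = c(rep(kb[2], 4), rep(library$bounds$initial[2], 4),
              library$bounds$scaling[2], library$bounds$onset[2]),
    scale = c(rep("linear", 8), "log", "linear")
  )
  kin <- tibble::tibble(
    name  = unlist(lapply(components, function(cp) unname(cp$params))),
    lower = kb[1], upper = kb[2], scale = "linear"
  )
  param_space <- dplyr::bind_rows(base, kin)
  stopifnot(!anyDuplicated(param_space$name))

  form_names <- vapply(names(idx), function(s) {
    library$slots[[s]][[idx[[s]]]]$name
  }, "")

  structure(
    list(
      structure_id = structure_index(idx, sizes),
      choices = idx,
      form_names = form_names,
      components = components,
      n_processes = 4L + length(components),
      param_space = param_space,
      hill_exponent = library$hill_exponent
    ),
    class = "rab_structure"
  )
}

# Canonical 1-based index: lexicographic over (gef5, gap5, gef7, gap7).
structure_index <- function(idx, sizes) {
  as.integer((((idx[["gef5"]] - 1L) * sizes[["gap5"]] + (idx[["gap5"]] - 1L)) *
                sizes[["gef7"]] + (idx[["gef7"]] - 1L)) * sizes[["gap7"]] +
               idx[["gap7"]])
}

#' @export
print.rab_structure <- function(x, ...) {
  cat(sprintf("<rab_structure #%d> %s\n", x$structure_id,
              paste(sprintf("%s=%s", names(x$form_names), x$form_names),
                    collapse = ", ")))
  cat(sprintf("  processes: %d, free parameters: %d\n",
              x$n_processes, nrow(x$param_space)))
  invisible(x)
}

#' Enumerate candidate model structures
#'
#' Forms the Cartesian product of the per-slot rate-law alternatives in
#' canonical (lexicographic) order over the slot indices
#' `(gef5, gap5, gef7, gap7)`. With the built-in library this yields the
#' full candidate space of 3 x 3 x 7 x 2 = 126 unique structures.
#'
#' @param library A `rab_library`.
#' @param constraints Optional named list restricting slots to subsets of
#'   alternative indices, e.g. `list(gap7 = 1, gef5 = c(1, 2))`.
#' @return A tibble with one row per structure: `structure_id`, the four
#'   slot indices, the chosen form names, the process count `n_processes`,
#'   the number of free parameters `n_params`, and a list-column
#'   `structure` of [build_structure()] objects.
#' @export
#' @examples
#' nrow(enumerate_structures())                      # 126
#' nrow(enumerate_structures(constraints = list(gap7 = 1)))  # 63
enumerate_structures <- function(library = default_library(), constraints = NULL) {
  sizes <- slot_sizes(library)
  allowed <- lapply(names(sizes), function(s) seq_len(sizes[[s]]))
  names(allowed) <- names(sizes)
  if (!is.null(constraints)) {
    for (s in names(constraints)) {
      if (!s %in% names(sizes)) {
        stop("unknown slot '", s, "' in constraints", call. = FALSE)
      }
      v <- unique(as.integer(constraints[[s]]))
      if (length(v) == 0L || any(is.na(v)) || any(v < 1L | v > sizes[[s]])) {
        stop("invalid alternative index for slot '", s, "' (valid: 1..",
             sizes[[s]], ")", call. = FALSE)
      }
      allowed[[s]] <- sort(v)
    }
  }
  grid <- tidyr::expand_grid(
    gef5 = allowed$gef5, gap5 = allowed$gap5,
    gef7 = allowed$gef7, gap7 = allowed$gap7
  )
  out <- purrr::pmap(grid, build_structure, library = library)
  tibble::tibble(
    structure_id = vapply(out, `[[`, 1L, "structure_id"),
    grid,
    gef5_form = vapply(out, function(s) s$form_names[["gef5"]], ""),
    gap5_form = vapply(out, function(s) s$form_names[["gap5"]], ""),
    gef7_form = vapply(out, function(s) s$form_names[["gef7"]], ""),
    gap7_form = vapply(out, function(s) s$form_names[["gap7"]], ""),
    n_processes = vapply(out, `[[`, 1L, "n_processes"),
    n_params = vapply(out, function(s) nrow(s$param_space), 1L),
    structure = out
  )
}

#' Model complexity: the number of processes in a structure
#'
#' Counts the leaf process instances of a structure: the four fixed
#' GDI membrane association/dissociation processes (two per protein) plus
#' one per chosen rate-law component. GEF7 alternatives that combine
#' cross-activation with auto-activation contribute two components.
#'
#' @param structure A `rab_structure`.
#' @return A positive integer.
#' @export
complexity <- function(structure) {
  stopifnot(inherits(structure, "rab_structure"))
  structure$n_processes
}

#' Compile a structure into a derivative evaluator
#'
#' Returns the right-hand side of the modular kinetic system as an R
#' closure. Writing `GEF5`, `GAP5` etc. for the chosen rate laws evaluated
#' at the current active-state concentrations, the system is
#' \deqn{dr5/dt = K1 - (k1 + GEF5) r5 + GAP5 R5, \quad
#'       dR5/dt = GEF5 r5 - GAP5 R5}
#' and symmetrically for Rab7 with `K2`, `k2`, `GEF7`, `GAP7`. GEF7 is the
#' sum of its cross- and (optional) auto-activation components.
#'
#' [simulate_structure()] uses an equivalent compiled-C right-hand side for
#' speed; this closure is the reference evaluator and is convenient for
#' inspection and testing.
#'
#' @param structure A `rab_structure`.
#' @return `function(state, params)` mapping a state vector
#'   `(r5, R5, r7, R7)` and named parameters to the four time-derivatives.
#' @export
compile_rhs <- function(structure) {
  stopifnot(inherits(structure, "rab_structure"))
  comps <- structure$components
  h <- structure$hill_exponent
  needed <- c("K1", "k1", "K2", "k2",
              unlist(lapply(comps, function(cp) unname(cp$params))))

  function(state, params) {
    params <- unlist(params)
    missing <- setdiff(needed, names(params))
    if (length(missing) > 0L) {
      stop("missing parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    r5 <- state[[1]]; R5 <- state[[2]]; r7 <- state[[3]]; R7 <- state[[4]]
    rates <- c(gef5 = 0, gap5 = 0, gef7 = 0, gap7 = 0)
    for (cp in comps) {
      x <- switch(cp$regulator, R5 = R5, R7 = R7, none = 0)
      pars <- stats::setNames(params[cp$params], names(cp$params))
      rates[[cp$slot]] <- rates[[cp$slot]] + eval_form(cp$kind, x, pars, h)
    }
    c(
      params[["K1"]] - (params[["k1"]] + rates[["gef5"]]) * r5 + rates[["gap5"]] * R5,
      rates[["gef5"]] * r5 - rates[["gap5"]] * R5,
      params[["K2"]] - (params[["k2"]] + rates[["gef7"]]) * r7 + rates[["gap7"]] * R7,
      rates[["gef7"]] * r7 - rates[["gap7"]] * R7
    )
  }
}
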