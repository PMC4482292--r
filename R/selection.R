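#' Rank scored models into an error profile
#'
#' Sorts the models in ascending order of the chosen criterion value (stable
#' sort; ties broken by canonical structure id), detects the leading
#' indistinguishability plateau with [plateau_length()] and flags its
#' members.
#'
#' @param scores A `rab_scorecard` from [score_models()].
#' @param criterion Criterion id column to rank by (e.g. `"ERX"`).
#' @return A `rab_profile` tibble ordered by rank, with columns `rank`,
#'   `structure_id`, the slot choices, components `E`, `R`, `X`, `C`, the
#'   ranked `value` and `in_plateau`; the plateau length is stored in the
#'   `plateau_length` attribute.
#' @export
rank_models <- function(scores, criterion = "ERX") {
  if (!criterion %in% names(scores)) {
    stop("scores do not contain criterion '", criterion, "'", call. = FALSE)
  }
  v <- scores[[criterion]]
  if (anyNA(v)) {
    stop("missing criterion values for model(s): ",
         paste(scores$structure_id[is.na(v)], collapse = ", "), call. = FALSE)
  }
  ord <- order(v, scores$structure_id)
  prof <- scores[ord, ]
  prof$value <- prof[[criterion]]
  prof$rank <- seq_len(nrow(prof))
  pl <- plateau_length(prof$value)
  prof$in_plateau <- prof$rank <= pl
  keep <- intersect(c("rank", "structure_id", "gef5", "gap5", "gef7", "gap7",
                      "C", "E", "R", "X", "value", "in_plateau"), names(prof))
  prof <- prof[, keep]
  attr(prof, "criterion") <- criterion
  attr(prof, "alpha") <- attr(scores, "alpha")
  attr(prof, "beta") <- attr(scores, "beta")
  attr(prof, "plateau_length") <- pl
  class(prof) <- c("rab_profile", class(prof))
  prof
}

#' Length of the leading plateau of an error profile
#'
#' Scans the non-decreasing criterion values of a ranked profile for the
#' first pair of consecutive models whose relative difference exceeds 10%
#' (measured against the earlier, smaller value); the plateau consists of
#' the models before that jump. If no such jump exists the plateau spans the
#' whole profile. A step from an exact zero to a positive value counts as
#' exceeding the threshold.
#'
#' @param values Non-decreasing criterion values along increasing rank.
#' @param threshold Relative-difference threshold (default 0.10).
#' @return Integer plateau length in `1..length(values)`.
#' @export
#' @examples
#' plateau_length(c(0.40, 0.42, 0.43, 0.48, 0.90))  # 3
plateau_length <- function(values, threshold = 0.10) {
  n <- length(values)
  if (n == 0L) stop("empty profile", call. = FALSE)
  if (any(diff(values) < 0)) {
    stop("profile values must be non-decreasing", call. = FALSE)
  }
  for (i in seq_len(n - 1L)) {
    jump <- if (values[i] == 0) values[i + 1L] > 0
            else (values[i + 1L] - values[i]) / values[i] > threshold
    if (jump) return(i)
  }
  n
}

#' Per-group statistics of the plateau members
#'
#' Joins an externally supplied group annotation (e.g. the COT / IP / NOBS
#' bistability classes from prior stability analysis) onto the plateau
#' members of a ranked profile and reports, per label, the number of plateau
#' models and their average (1-based) rank. Labels with no plateau members
#' are reported with count 0 and `NA` mean rank.
#'
#' @param profile A `rab_profile` from [rank_models()].
#' @param annotation Data frame with columns `structure_id` and `label`
#'   covering every model in the profile.
#' @return Tibble with `label`, `n_plateau`, `mean_rank`.
#' @export
group_stats <- function(profile, annotation) {
  stopifnot(all(c("structure_id", "label") %in% names(annotation)))
  unlabeled <- setdiff(profile$structure_id, annotation$structure_id)
  if (length(unlabeled) > 0L) {
    stop("unlabeled model(s): ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  }
  plat <- dplyr::left_join(
    dplyr::filter(tibble::as_tibble(profile), .data$in_plateau),
    dplyr::distinct(annotation, .data$structure_id, .keep_all = TRUE),
    by = "structure_id"
  )
  stats <- dplyr::summarise(
    dplyr::group_by(plat, .data$label),
    n_plateau = dplyr::n(),
    mean_rank = mean(.data$rank),
    .groups = "drop"
  )
  all_labels <- tibble::tibble(label = unique(annotation$label))
  out <- dplyr::left_join(all_labels, stats, by = "label")
  out$n_plateau[is.na(out$n_plateau)] <- 0L
  out
}

#' Frequencies of rate-law choices among plateau models
#'
#' Tallies, for each regulatory slot (GEF5, GAP5, GEF7, GAP7), how often
#' each alternative rate law was chosen by the plateau members. Per slot the
#' counts sum to the plateau size; alternatives absent from the plateau are
#' reported with count 0.
#'
#' @param profile A `rab_profile` (only plateau rows are tallied), or any
#'   data frame with slot-index columns `gef5`, `gap5`, `gef7`, `gap7`
#'   (then all rows are tallied).
#' @param library The `rab_library` naming the alternatives.
#' @return Tibble with `slot`, `alternative` (index), `form` (name),
#'   `count`.
#' @export
component_frequencies <- function(profile, library = default_library()) {
  rows <- tibble::as_tibble(profile)
  if ("in_plateau" %in% names(rows)) rows <- rows[rows$in_plateau, ]
  if (nrow(rows) == 0L) stop("empty plateau", call. = FALSE)
  sizes <- slot_sizes(library)
  purrr::map_dfr(names(sizes), function(s) {
    counts <- tabulate(rows[[s]], nbins = sizes[[s]])
    tibble::tibble(
      slot = s,
      alternative = seq_len(sizes[[s]]),
      form = vapply(library$slots[[s]], `[[`, "", "name"),
      count = counts
    )
  })
}

#' Plot an error profile with its plateau
#'
#' Criterion value against model rank, plateau members highlighted.
#'
#' @param object A `rab_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rab_profile
#' @export
autoplot.rab_profile <- function(object, ...) {
  crit <- attr(object, "criterion")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rank, y = .data$value,
                               colour = .data$in_plateau)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::labs(x = "model rank", y = crit,
                  colour = "in plateau",
                  title = sprintf("Error profile (%s), plateau length %d",
                                  crit, attr(object, "plateau_length")))
}

#' Plateau sizes of several selection criteria on one fitted sweep
#'
#' Given one set of fitted models, scores and ranks them under a list of
#' criterion configurations and reports each criterion's plateau size. The
#' default configurations are the headline comparisons of the study: `E`,
#' `ER` at `alpha = 0.5`, `EX` at `alpha = 0.9` and `ERX` at `alpha = 0.5`.
#'
#' @param fits Result of [fit_all()].
#' @param dataset The fitted `rab_dataset`.
#' @param configs List of [criterion_config()]s.
#' @return Tibble with `criterion`, `alpha`, `beta`, `plateau_length`,
#'   `n_models`.
#' @export
benchmark_plateaus <- function(fits, dataset,
                               configs = list(
                                 criterion_config("E"),
                                 criterion_config("ER", alpha = 0.5),
                                 criterion_config("EX", alpha = 0.9),
                                 criterion_config("ERX", alpha = 0.5)
                               )) {
  purrr::map_dfr(configs, function(cfg) {
    sc <- score_models(fits, dataset, alpha = cfg$alpha, beta = cfg$beta,
                       complexity_mode = cfg$complexity_mode,
                       persistence = cfg$persistence)
    prof <- rank_models(sc, cfg$criterion)
    tibble::tibble(
      criterion = cfg$criterion, alpha = cfg$alpha, beta = cfg$beta,
      plateau_length = attr(prof, "plateau_length"),
      n_models = nrow(prof)
    )
  })
}

#' Write a ranking table to CSV
#'
#' Columns: rank, structure id, slot choices, complexity, the `E`/`R`/`X`
#' components, the ranked criterion value, the plateau flag and (optionally)
#' the group label. Numeric columns are written with 6 significant digits.
#'
#' @param profile A `rab_profile`.
#' @param path Output file.
#' @param annotation Optional data frame (`structure_id`, `label`).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(profile, path, annotation = NULL) {
  out <- tibble::as_tibble(profile)
  if (!is.null(annotation)) {
    out <- dplyr::left_join(out, annotation, by = "structure_id")
  }
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a structure group annotation from CSV
#'
#' Two columns: `structure_id`, `label` (e.g. COT, IP, NOBS, OTHER).
#'
#' @param path CSV file.
#' @return Tibble with `structure_id` (integer) and `label` (character).
#' @export
read_annotation <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("structure_id", "label") %in% names(a)))
  tibble::tibble(structure_id = as.integer(a$structure_id),
                 label = as.character(a$label))
}
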