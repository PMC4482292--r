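# A scorecard stub: ranking operates on any table with structure ids, slot
# choices and criterion columns.
stub_scores <- function(values, ids = seq_along(values)) {
  n <- length(values)
  tibble::tibble(
    structure_id = ids, gef5 = 1L, gap5 = 1L, gef7 = 1L, gap7 = 1L,
    C = 8L, E = values, R = 0.5, X = 0.5, ERX = values
  )
}

test_that("ranking sorts ascending with canonical-index tie-breaks", {
  prof <- rank_models(stub_scores(c(0.3, 0.1, 0.2)), "E")
  expect_equal(prof$structure_id, c(2L, 3L, 1L))
  expect_equal(prof$rank, 1:3)
  expect_true(all(diff(prof$value) >= 0))

  ties <- rank_models(stub_scores(c(0.2, 0.2, 0.2), ids = c(9L, 3L, 6L)), "E")
  expect_equal(ties$structure_id, c(3L, 6L, 9L))

  # idempotence: re-ranking a permutation gives the same profile
  perm <- stub_scores(c(0.5, 0.15, 0.3, 0.05))[c(3, 1, 4, 2), ]
  expect_equal(rank_models(perm, "E")$structure_id,
               rank_models(stub_scores(c(0.5, 0.15, 0.3, 0.05)), "E")$structure_id)

  expect_error(rank_models(stub_scores(c(0.1, NA)), "E"), "2")
  expect_error(rank_models(stub_scores(0.1), "nope"), "nope")
})

test_that("plateau detection matches the worked example and edge cases", {
  expect_equal(plateau_length(c(0.40, 0.42, 0.43, 0.48, 0.90)), 3)
  expect_equal(plateau_length(rep(0.7, 12)), 12)
  expect_equal(plateau_length(0.5), 1)
  # an exact zero followed by a positive value ends the plateau
  expect_equal(plateau_length(c(0, 0, 0.01, 0.011)), 2)
  expect_error(plateau_length(numeric(0)), "empty")
  expect_error(plateau_length(c(0.3, 0.2)), "non-decreasing")
})

test_that("plateau heuristic equals a brute-force scan on random profiles", {
  brute <- function(v, thr = 0.10) {
    for (i in seq_len(length(v) - 1)) {
      rel <- if (v[i] == 0) ifelse(v[i + 1] > 0, Inf, 0)
             else (v[i + 1] - v[i]) / v[i]
      if (rel > thr) return(i)
    }
    length(v)
  }
  set.seed(515)
  for (rep in 1:200) {
    v <- sort(stats::rgamma(sample(2:40, 1), shape = 2, rate = 4))
    expect_identical(plateau_length(v), brute(v))
  }
})

test_that("group statistics count and average ranks inside the plateau", {
  sc <- stub_scores(c(0.30, 0.31, 0.32, 0.33, 0.90, 0.95))
  prof <- rank_models(sc, "E")  # plateau: first 4 models
  expect_equal(attr(prof, "plateau_length"), 4)
  ann <- tibble::tibble(structure_id = 1:6,
                        label = c("COT", "COT", "IP", "OTHER", "NOBS", "IP"))
  gs <- group_stats(prof, ann)
  expect_equal(gs$n_plateau[gs$label == "COT"], 2L)
  expect_equal(gs$mean_rank[gs$label == "COT"], 1.5)
  expect_equal(gs$n_plateau[gs$label == "IP"], 1L)
  expect_equal(gs$mean_rank[gs$label == "IP"], 3)
  # label absent from the plateau: count 0, undefined mean rank
  expect_equal(gs$n_plateau[gs$label == "NOBS"], 0L)
  expect_true(is.na(gs$mean_rank[gs$label == "NOBS"]))
  # counts over labels sum to the plateau length
  expect_equal(sum(gs$n_plateau), 4L)

  # single-label plateau: mean rank (L + 1) / 2
  one <- group_stats(prof, tibble::tibble(structure_id = 1:6, label = "COT"))
  expect_equal(one$mean_rank, 2.5)

  expect_error(group_stats(prof, ann[-2, ]), "2")
})

test_that("component frequencies tally plateau structures per slot", {
  # two identical structures: their chosen alternatives count twice
  rows <- tibble::tibble(gef5 = c(2L, 2L), gap5 = c(3L, 3L),
                         gef7 = c(5L, 5L), gap7 = c(1L, 1L))
  freq <- component_frequencies(rows)
  expect_equal(freq$count[freq$slot == "gef5" & freq$alternative == 2], 2L)
  expect_equal(sum(freq$count[freq$slot == "gef5"]), 2L)
  expect_equal(freq$count[freq$slot == "gef7" & freq$alternative == 1], 0L)

  # the full candidate space is uniform within every slot
  freq126 <- component_frequencies(enumerate_structures())
  for (s in unique(freq126$slot)) {
    counts <- freq126$count[freq126$slot == s]
    expect_true(all(counts == counts[1]))
    expect_equal(sum(counts), 126L)
  }

  # hand-built plateau of three structures matches a manual tally
  rows3 <- tibble::tibble(gef5 = c(1L, 1L, 2L), gap5 = c(2L, 3L, 2L),
                          gef7 = c(7L, 7L, 7L), gap7 = c(1L, 2L, 1L))
  f3 <- component_frequencies(rows3)
  expect_equal(f3$count[f3$slot == "gef5"], c(2L, 1L, 0L))
  expect_equal(f3$count[f3$slot == "gap5"], c(0L, 2L, 1L))
  expect_equal(f3$count[f3$slot == "gef7"][7], 3L)
  expect_equal(f3$count[f3$slot == "gap7"], c(2L, 1L))

  # frequencies are invariant to within-plateau ordering
  expect_equal(component_frequencies(rows3[c(3, 1, 2), ]), f3)
})

test_that("ranking tables round-trip through CSV with annotations", {
  sc <- stub_scores(c(0.30, 0.31, 0.45))
  prof <- rank_models(sc, "E")
  ann <- tibble::tibble(structure_id = 1:3, label = c("COT", "IP", "NOBS"))
  path <- tempfile(fileext = ".csv")
  write_ranking(prof, path, annotation = ann)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$label, c("COT", "IP", "NOBS"))
  expect_equal(back$in_plateau, c(TRUE, TRUE, FALSE))

  apath <- tempfile(fileext = ".csv")
  utils::write.csv(ann, apath, row.names = FALSE)
  expect_equal(read_annotation(apath)$label, ann$label)
})
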