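toy_annotations <- function(m) {
  regions <- rep(c("H1", "ICL1", "H2"), length.out = 3)
  sizes <- diff(floor(seq(0, m, length.out = 4)))
  tibble::tibble(index = seq_len(m), name = paste0("ALA", seq_len(m)),
                 generic_number = NA_character_,
                 region = rep(c("H1", "ICL1", "H2"), times = sizes))
}

test_that("residue relevance is the mean of the three coordinate shares", {
  expect_equal(residue_relevance(c(0.3, 0.6, 0.0))$relevance, 0.3)
  expect_equal(residue_relevance(rep(0, 9))$relevance, rep(0, 3))
  expect_equal(residue_relevance(c(1, 1, 1, 2, 2, 2))$relevance, c(1, 2))
  expect_error(residue_relevance(rep(1, 4)), "multiple of 3")
})

test_that("residue aggregation conserves total relevance up to the 1/3", {
  withr::with_seed(13, {
    r <- rnorm(60)
    agg <- residue_relevance(r)
    expect_equal(sum(agg$relevance), sum(r) / 3)
  })
})

test_that("map averaging is the elementwise mean and permutation-invariant", {
  m1 <- tibble::tibble(res_index = 1:2, relevance = c(1, 0))
  m2 <- tibble::tibble(res_index = 1:2, relevance = c(0, 1))
  expect_equal(average_maps(list(m1))$relevance, c(1, 0))
  expect_equal(average_maps(list(m1, m2))$relevance, c(0.5, 0.5))
  expect_equal(average_maps(list(m2, m1, m2))$relevance,
               average_maps(list(m2, m2, m1))$relevance)
  expect_error(average_maps(list()), "no maps")
})

test_that("IQR fences flag exactly the planted outliers", {
  ann8 <- tibble::tibble(index = 1:8, name = paste0("ALA", 1:8),
                         generic_number = NA, region = "H1")
  map <- tibble::tibble(res_index = 1:8,
                        relevance = c(0, 0, 0, 0, 0, 0, 0, 10))
  # quartile oracle on the 8-vector (type-7 interpolation):
  # Q1 = 0, Q3 = 0, IQR = 0 -> fences at 0; only the 10 exceeds
  tab <- iqr_motifs(map, ann8)
  expect_identical(tab$res_index, 8L)
  expect_identical(tab$side, "above_upper")
  expect_identical(tab$residue, "ALA8")

  flat <- dplyr::mutate(map, relevance = 0.5)
  expect_identical(nrow(iqr_motifs(flat, ann8)), 0L)

  withr::with_seed(41, {
    m <- 100
    ann <- toy_annotations(m)
    rel <- runif(m, -0.01, 0.01)
    rel[c(10, 60)] <- 10
    rel[c(30, 90)] <- -10
    map <- tibble::tibble(res_index = 1:m, relevance = rel)
    tab <- iqr_motifs(map, ann)
    expect_setequal(tab$res_index, c(10L, 30L, 60L, 90L))
    expect_identical(tab$side[match(c(10, 60), tab$res_index)],
                     rep("above_upper", 2))
    expect_identical(tab$side[match(c(30, 90), tab$res_index)],
                     rep("below_lower", 2))
    # rows sorted by residue index and carrying regions
    expect_identical(tab$res_index, sort(tab$res_index))
    expect_identical(tab$region, ann$region[tab$res_index])
  })
  expect_error(iqr_motifs(map, toy_annotations(100), fence_factor = -1),
               "nonnegative")
  expect_error(iqr_motifs(map[1:3, ], ann8[1:3, ]), "at least 4")
})

test_that("fences match the quantile convention exactly", {
  withr::with_seed(55, {
    rel <- rnorm(50)
    map <- tibble::tibble(res_index = 1:50, relevance = rel)
    tab <- iqr_motifs(map, toy_annotations(50), fence_factor = 0.5)
    q <- stats::quantile(rel, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- c(q[1] - 0.5 * (q[2] - q[1]), q[2] + 0.5 * (q[2] - q[1]))
    expect_setequal(tab$res_index,
                    which(rel < fence[1] | rel > fence[2]))
  })
})

test_that("region summaries total and average per residue per frame", {
  ann <- tibble::tibble(index = 1:4, name = paste0("ALA", 1:4),
                        generic_number = NA,
                        region = c("H1", "H1", "ICL1", "ICL1"))
  one_frame <- tibble::tibble(row = 1L, res_index = 1:4,
                              relevance = c(0.2, -0.1, 0.05, 0.05))
  rs <- region_summary(one_frame, ann)
  expect_equal(rs$total_relevance[rs$region == "H1"], 0.1)
  expect_equal(rs$average_relevance[rs$region == "H1"], 0.05)
  # partition additivity
  expect_equal(sum(rs$total_relevance), sum(one_frame$relevance))
  # duplicating the frame doubles totals, preserves averages
  two <- dplyr::bind_rows(one_frame, dplyr::mutate(one_frame, row = 2L))
  rs2 <- region_summary(two, ann)
  expect_equal(rs2$total_relevance, 2 * rs$total_relevance)
  expect_equal(rs2$average_relevance, rs$average_relevance)
  expect_error(region_summary(dplyr::mutate(one_frame,
                                            res_index = c(1, 2, 3, 9)), ann),
               "unannotated")
})

test_that("region totals are additive over a refinement of the partition", {
  withr::with_seed(61, {
    m <- 32
    fm <- tibble::tibble(row = rep(1:3, each = m),
                         res_index = rep(1:m, 3),
                         relevance = rnorm(3 * m))
    coarse <- tibble::tibble(index = 1:m, name = paste0("ALA", 1:m),
                             generic_number = NA,
                             region = rep(c("H1", "H2"), each = m / 2))
    fine <- dplyr::mutate(coarse,
                          region = rep(c("H1", "ICL1", "H2", "ECL1"),
                                       each = m / 4))
    tot_coarse <- sum(region_summary(fm, coarse)$total_relevance)
    tot_fine <- sum(region_summary(fm, fine)$total_relevance)
    expect_equal(tot_coarse, tot_fine)
    rs_fine <- region_summary(fm, fine)
    expect_equal(sum(rs_fine$total_relevance[rs_fine$region %in%
                                               c("H1", "ICL1")]),
                 region_summary(fm, coarse)$total_relevance[1])
  })
})

test_that("explanation frames are correctly predicted, per state, seeded", {
  tt <- tiny_trained_model()
  info <- tibble::tibble(trajectory = rep(sprintf("t%02d", 1:9), each = 10),
                         label = tt$y)
  sel <- select_explanation_frames(tt$model, tt$x, info, n_traj = 9,
                                   per_state = 10, seed = 3)
  expect_identical(nrow(sel), 30L)
  expect_true(all(table(sel$label) == 10))
  pred <- predict(tt$model, tt$x[sel$row, ])
  expect_identical(pred, sel$label)
  sel2 <- select_explanation_frames(tt$model, tt$x, info, n_traj = 9,
                                    per_state = 10, seed = 3)
  expect_identical(sel, sel2)
  expect_error(
    select_explanation_frames(tt$model, tt$x, info, n_traj = 9,
                              per_state = 1000, seed = 3),
    "not enough correctly predicted")
})
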