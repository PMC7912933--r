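test_that("pair-level MeTRe follows the defining ratio", {
  expect_equal(metre_pair(0.05, 0.02, 0.03), 1)
  expect_equal(metre_pair(0.10, 0.02, 0.03), 2)
  expect_error(metre_pair(-0.1, 0.02, 0.03), "non-negative")
  expect_identical(metre_pair(0.05, 0, 0), Inf)
  expect_true(is.nan(metre_pair(0, 0, 0)))
})

test_that("threshold-mode MeTRe divides by the accepted threshold", {
  expect_equal(metre_pair_threshold(0.028, 0.014), 2)   # ITS threshold
  expect_equal(metre_pair_threshold(0, 0.014), 0)
  expect_equal(metre_pair_threshold(0.014, 0.014), 1)   # no-resolution boundary
  expect_error(metre_pair_threshold(0.1, 0), "Th must be > 0")
})

test_that("MeTRe is scale invariant in form 1 and linear in form 2", {
  set.seed(61)
  for (rep in 1:20) {
    b <- runif(1, 0.01, 0.3); wi <- runif(1, 0.001, 0.05)
    wj <- runif(1, 0.001, 0.05); c0 <- runif(1, 0.1, 10)
    expect_equal(metre_pair(c0 * b, c0 * wi, c0 * wj),
                 metre_pair(b, wi, wj))
    expect_equal(metre_pair_threshold(c0 * b, 0.014),
                 c0 * metre_pair_threshold(b, 0.014))
  }
})

test_that("MeTRe is monotone in separation and internal variability", {
  base <- metre_pair(0.06, 0.01, 0.02)
  expect_gt(metre_pair(0.07, 0.01, 0.02), base)
  expect_lt(metre_pair(0.06, 0.015, 0.02), base)
  expect_lt(metre_pair(0.06, 0.01, 0.025), base)
})

make_summary <- function(within, between_val = NULL, between = NULL) {
  species <- names(within)
  ns <- length(species)
  if (is.null(between)) {
    between <- matrix(between_val, ns, ns,
                      dimnames = list(species, species))
    diag(between) <- NA_real_
  }
  structure(list(within = within,
                 n_within = setNames(rep(1L, ns), species),
                 between = between,
                 n_between = matrix(1L, ns, ns,
                                    dimnames = list(species, species)),
                 gap_mode = "complete_deletion"),
            class = "group_dist_summary")
}

test_that("MeTRe matrices have a unit diagonal and are symmetric", {
  gs <- make_summary(c(X = 0.02, Y = 0.03), 0.05)
  m <- metre_matrix(gs)
  expect_identical(unname(diag(m)), c(1, 1))
  expect_equal(unname(m["X", "Y"]), 1)
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)

  set.seed(62)
  w <- setNames(runif(5, 0.001, 0.05), paste0("s", 1:5))
  bm <- random_sym_matrix(5, names(w)) / 4
  diag(bm) <- NA
  m2 <- metre_matrix(make_summary(w, between = bm))
  expect_identical(unname(diag(m2)), rep(1, 5))
  expect_equal(unclass(m2), t(unclass(m2)), ignore_attr = TRUE)
  m3 <- metre_matrix(make_summary(w, between = bm), "fixed_threshold",
                     Th = 0.014)
  expect_identical(unname(diag(m3)), rep(1, 5))
})

test_that("threshold mode equals actual mode with all within = Th/2", {
  set.seed(63)
  species <- paste0("s", 1:4)
  bm <- random_sym_matrix(4, species) / 5
  diag(bm) <- NA
  Th <- 0.014
  half <- setNames(rep(Th / 2, 4), species)
  mt <- metre_matrix(make_summary(half, between = bm), "fixed_threshold",
                     Th = Th)
  ma <- metre_matrix(make_summary(half, between = bm),
                     "actual_variability")
  expect_equal(unclass(mt), unclass(ma), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("fixed_threshold mode requires Th", {
  gs <- make_summary(c(X = 0.02, Y = 0.03), 0.05)
  expect_error(metre_matrix(gs, "fixed_threshold"), "requires Th")
})

test_that("singleton species use the fallback within when given", {
  gs <- make_summary(c(X = 0.02, Y = NA_real_), 0.06)
  m_na <- metre_matrix(gs)
  expect_true(is.na(m_na["X", "Y"]))
  m_fb <- metre_matrix(gs, fallback_within = 0.007)
  expect_equal(unname(m_fb["X", "Y"]), 0.06 / (0.02 + 0.007))
})

test_that("resolution uses the strict MeTRe > 1 rule", {
  gs <- make_summary(c(A = 0.01, B = 0.01, C = 0.01),
                     between = matrix(c(NA, 0.02, 0.02 + 2e-9,
                                        0.02, NA, 0.05,
                                        0.02 + 2e-9, 0.05, NA), 3, 3,
                                      dimnames = list(c("A", "B", "C"),
                                                      c("A", "B", "C"))))
  m <- metre_matrix(gs)
  expect_equal(unname(m["A", "B"]), 1)           # exactly at the boundary
  res <- classify_resolution(m)
  expect_false(res["A", "B"])                    # MeTRe <= 1: unresolved
  expect_true(res["A", "C"])                     # 1 + epsilon: resolved
  expect_false(any(diag(res)))
  expect_equal(res, t(res), ignore_attr = TRUE)
  # infinite resolves, undefined does not
  m2 <- metre_matrix(make_summary(c(X = 0, Y = 0), 0.05))
  res2 <- classify_resolution(m2)
  expect_true(res2["X", "Y"])
  m3 <- metre_matrix(make_summary(c(X = 0, Y = 0), 0))
  expect_false(classify_resolution(m3)["X", "Y"])
})

test_that("summaries average the unordered off-diagonal pairs", {
  gs <- make_summary(c(A = 0.01, B = 0.01, C = 0.01),
                     between = matrix(c(NA, 0.04, 0.08,
                                        0.04, NA, 0.06,
                                        0.08, 0.06, NA), 3, 3,
                                      dimnames = list(c("A", "B", "C"),
                                                      c("A", "B", "C"))))
  s <- summarize_metre(metre_matrix(gs))
  expect_equal(s$mean_off_diagonal, mean(c(2, 4, 3)))
  expect_equal(s$min, 2)
  expect_equal(s$max, 4)
  expect_equal(unname(s$per_species_mean["A"]), mean(c(2, 4)))
  expect_equal(s$n_unresolved_pairs, 0L)
  expect_true(s$min <= s$mean_off_diagonal &&
                s$mean_off_diagonal <= s$max)

  # single pair: mean == min == max; row mean arithmetic by hand
  s2 <- summarize_metre(metre_matrix(make_summary(c(X = 0.02, Y = 0.03),
                                                  0.05)))
  expect_equal(s2$mean_off_diagonal, 1)
  expect_equal(s2$min, s2$max)
  expect_equal(s2$n_unresolved_pairs, 1L)

  row <- c(0.5, 0.9, 1.2)
  gs3 <- make_summary(c(A = 0.01, B = 0.01, C = 0.01, D = 0.01),
                      between = {
                        bm <- matrix(NA_real_, 4, 4,
                                     dimnames = list(LETTERS[1:4],
                                                     LETTERS[1:4]))
                        bm["A", c("B", "C", "D")] <- row * 0.02
                        bm[c("B", "C", "D"), "A"] <- row * 0.02
                        bm["B", "C"] <- bm["C", "B"] <- 0.02
                        bm["B", "D"] <- bm["D", "B"] <- 0.02
                        bm["C", "D"] <- bm["D", "C"] <- 0.02
                        bm
                      })
  s3 <- summarize_metre(metre_matrix(gs3))
  expect_equal(unname(s3$per_species_mean["A"]), mean(row),
               tolerance = 1e-3)
})

test_that("infinite entries are excluded from means and counted", {
  gs <- make_summary(c(A = 0, B = 0.01, C = 0.01),
                     between = matrix(c(NA, 0.04, 0.04,
                                        0.04, NA, 0.04,
                                        0.04, 0.04, NA), 3, 3,
                                      dimnames = list(c("A", "B", "C"),
                                                      c("A", "B", "C"))))
  m <- metre_matrix(gs)
  expect_identical(unname(m["A", "B"]), 0.04 / 0.01)
  s <- summarize_metre(m)
  expect_equal(s$n_infinite, 0L)
  # zero within for both members of a pair -> infinite
  gs2 <- make_summary(c(A = 0, B = 0, C = 0.01), 0.04)
  s2 <- summarize_metre(metre_matrix(gs2))
  expect_equal(s2$n_infinite, 1L)
  expect_true(is.finite(s2$mean_off_diagonal))
})
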