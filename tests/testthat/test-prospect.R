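test_that("the default linguistic scale tiles [0,1] and maps terms", {
  sc <- linguistic_scale()
  expect_identical(map_linguistic("VG", sc), c(0.85, 1))
  expect_identical(map_linguistic("M", sc), c(0.4, 0.55))
  expect_error(map_linguistic("XX", sc), "Unknown")
  expect_identical(sc$lo[1], 0)
  expect_identical(sc$hi[nrow(sc)], 1)
  expect_identical(sc$hi[-nrow(sc)], sc$lo[-1])
  expect_error(linguistic_scale(terms = c("L", "H"), lo = c(0, 0.4),
                                hi = c(0.5, 1)), "tile")
})

test_that("gain/loss editing against the reference flips sign for costs", {
  expect_identical(delta_vs_reference(c(4, 7), c(5, 11), "gain"), c(-7, 2))
  expect_identical(delta_vs_reference(c(3, 3), c(3, 3), "gain"), c(0, 0))
  # cost criterion, value entirely below reference -> strictly positive
  d <- delta_vs_reference(c(1, 2), c(5, 11), "cost")
  expect_true(all(d > 0))
  expect_identical(d, c(3, 10))
})

test_that("value function shows loss aversion and S-shaped curvature", {
  p <- prospect_params()
  expect_identical(value_fn(0, p), 0)
  expect_identical(value_fn(1, p), 1)
  expect_identical(value_fn(-1, p), -p$lambda)
  # strictly increasing
  grid <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(value_fn(grid, p)) > 0))
  # concave for gains, convex for losses (second differences)
  gains <- value_fn(seq(0.1, 3, by = 0.1), p)
  expect_true(all(diff(diff(gains)) < 1e-12))
  losses <- value_fn(seq(-3, -0.1, by = 0.1), p)
  expect_true(all(diff(diff(losses)) > -1e-12))
  # loss branch magnitude dominates the gain branch by lambda at alpha=beta
  d <- seq(0.2, 2, by = 0.2)
  expect_true(all(abs(value_fn(-d, p)) >= p$lambda * value_fn(d, p) - 1e-12))
  expect_error(value_fn(Inf, p), "finite")
})

test_that("probability weighting fixes endpoints and matches the oracle", {
  p <- prospect_params()
  expect_identical(prob_weight(0, "gain", p), 0)
  expect_identical(prob_weight(1, "gain", p), 1)
  expect_identical(prob_weight(0, "loss", p), 0)
  expect_identical(prob_weight(1, "loss", p), 1)
  # high-precision direct evaluation at p = 0.5, chi = 0.61
  expect_equal(prob_weight(0.5, "gain", prospect_params(chi = 0.61)),
               0.42063935433575617, tolerance = 1e-12)
  # identity at curvature 1
  ident <- prospect_params(chi = 1, delta = 1)
  grid <- seq(0, 1, by = 0.05)
  expect_equal(prob_weight(grid, "gain", ident), grid, tolerance = 1e-12)
  expect_equal(prob_weight(grid, "loss", ident), grid, tolerance = 1e-12)
  # subcertainty: pi(p) + pi(1-p) <= 1 for curvature < 1
  w <- prob_weight(grid, "gain", p)
  expect_true(all(w + rev(w) <= 1 + 1e-9))
  expect_error(prob_weight(1.2, "gain", p), "0, 1")
})

test_that("parameter constructor enforces the stated ranges", {
  expect_error(prospect_params(alpha = 0), "alpha")
  expect_error(prospect_params(lambda = 0.5), "lambda")
  expect_error(prospect_params(chi = 0.2), "chi")
  expect_silent(prospect_params(alpha = 1, beta = 1, lambda = 1,
                                chi = 1, delta = 1))
})

test_that("interval prospect value reduces to expectation in the linear limit", {
  p <- prospect_params()
  expect_identical(prospect_value(list(c(0, 0)), 1, p), c(0, 0))
  lin <- prospect_params(alpha = 1, beta = 1, lambda = 1, chi = 1,
                         delta = 1)
  v <- prospect_value(list(c(1, 3), c(2, 4)), c(0.5, 0.5), lin)
  expect_equal(v, c(1.5, 3.5), tolerance = 1e-12)
  expect_error(prospect_value(list(c(0, 1)), c(0.4, 0.6)), "length")
  expect_error(prospect_value(list(c(0, 1), c(0, 1)), c(0.4, 0.4)),
               "sum to 1")
})

test_that("a worked column matches an element-wise recomputation", {
  # scheme x2, criterion c2: independent loop over frames
  case <- covid_case_matrix()
  p <- prospect_params()
  res <- cumulative_prospect(case$values, case$criteria, case$reference)
  got <- res$prospects[res$prospects$scheme == "x2" &
                         res$prospects$criterion == "c2", ]
  cell <- list(c(4, 7), c(6, 12), c(6, 11), c(9, 12))
  ref <- c(5, 11)
  lo <- hi <- 0
  for (x in cell) {
    d <- c(x[1] - ref[2], x[2] - ref[1])
    branch <- if (mean(d) >= 0) "gain" else "loss"
    w <- prob_weight(0.25, branch, p)
    vv <- value_fn(d, p)
    lo <- lo + w * vv[1]
    hi <- hi + w * vv[2]
  }
  expect_equal(got$lo, lo, tolerance = 1e-12)
  expect_equal(got$hi, hi, tolerance = 1e-12)
})

test_that("ranking is invariant to scheme relabeling and weight rescaling", {
  case <- covid_case_matrix()
  res <- cumulative_prospect(case$values, case$criteria, case$reference)
  relabel <- c(x1 = "s_c", x2 = "s_a", x3 = "s_b")
  v2 <- case$values
  v2$scheme <- unname(relabel[v2$scheme])
  res2 <- cumulative_prospect(v2, case$criteria, case$reference)
  expect_identical(unname(relabel[res$utilities$scheme]),
                   res2$utilities$scheme)
  expect_equal(res$utilities$utility, res2$utilities$utility,
               tolerance = 1e-12)
  # scaling weights then renormalising leaves the ranking unchanged
  c2 <- case$criteria
  c2$weight <- (c2$weight * 7) / sum(c2$weight * 7)
  res3 <- cumulative_prospect(case$values, c2, case$reference)
  expect_identical(res$utilities$scheme, res3$utilities$scheme)
})

test_that("utility decreases in the loss-aversion coefficient", {
  case <- covid_case_matrix()
  lambdas <- c(1, 1.5, 2.25, 4, 8)
  u <- vapply(lambdas, function(l) {
    r <- cumulative_prospect(case$values, case$criteria, case$reference,
                             params = prospect_params(lambda = l))
    r$utilities$utility[r$utilities$scheme == "x2"]
  }, numeric(1))
  expect_true(all(diff(u) < 0))
})

test_that("linear scalar limit equals the weighted mean deviation", {
  lin <- prospect_params(alpha = 1, beta = 1, lambda = 1, chi = 1,
                         delta = 1)
  values <- tidyr::expand_grid(scheme = c("s1", "s2"),
                               criterion = c("a", "b"),
                               frame = c("t1", "t2"))
  raw <- c(s1_a = 2, s1_b = 8, s2_a = 5, s2_b = 3)
  values$value <- lapply(seq_len(nrow(values)), function(i) {
    unname(raw[paste(values$scheme[i], values$criterion[i], sep = "_")])
  })
  criteria <- tibble::tibble(criterion = c("a", "b"),
                             type = "gain", weight = c(0.3, 0.7))
  reference <- list(a = 4, b = 4)
  res <- cumulative_prospect(values, criteria, reference, params = lin)
  u <- res$utilities
  expect_equal(u$utility[u$scheme == "s1"], 0.3 * (2 - 4) + 0.7 * (8 - 4),
               tolerance = 1e-12)
  expect_equal(u$utility[u$scheme == "s2"], 0.3 * (5 - 4) + 0.7 * (3 - 4),
               tolerance = 1e-12)
})

test_that("identical schemes tie and the tie is reported", {
  case <- covid_case_matrix()
  v <- case$values[case$values$scheme == "x1", ]
  v2 <- dplyr::bind_rows(v, dplyr::mutate(v, scheme = "x9"))
  res <- cumulative_prospect(v2, case$criteria, case$reference)
  expect_true(res$tie)
  expect_equal(res$utilities$utility[1], res$utilities$utility[2],
               tolerance = 1e-12)
})
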