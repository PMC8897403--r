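test_that("granulation builds valid coverings from raw attributes", {
  vals <- setNames(c("A", "A", "B", "B", "C", "C"), paste0("x", 1:6))
  cv <- granulate(vals, kind = "symbolic", id = "a1")
  expect_same_sets(cv$blocks,
                   list(c("x1", "x2"), c("x3", "x4"), c("x5", "x6")))

  num <- setNames(1:6, paste0("x", 1:6))
  cv2 <- granulate(num, kind = "numeric", delta = 0.2, id = "a2")
  # |a(y) - a(x)| <= 0.2 * 5 = 1
  blk_of <- function(x) cv2$blocks[vapply(cv2$blocks, function(b)
    x %in% b, logical(1))]
  expect_true(list(sort(c("x1", "x2"))) %in% cv2$blocks ||
                any(vapply(cv2$blocks, identical, logical(1),
                           c("x1", "x2"))))
  expect_true(any(vapply(cv2$blocks, identical, logical(1),
                         sort(c("x2", "x3", "x4")))))
  # zero range collapses to a single block covering the universe
  cv3 <- granulate(setNames(rep(5, 4), paste0("x", 1:4)),
                   kind = "numeric", delta = 0.5)
  expect_identical(cv3$blocks, list(paste0("x", 1:4)))
  expect_error(granulate(num, kind = "numeric", delta = 1.5), "delta")
  expect_error(granulate(character(0), kind = "symbolic"), "non-empty")
})

test_that("approximation pair brackets the target set", {
  p <- list(c("x1", "x2"), c("x3", "x4"), c("x5", "x6"))
  ap <- approximation_pair(p, c("x1", "x2", "x3"))
  expect_identical(ap$lower, c("x1", "x2"))
  expect_identical(ap$upper, c("x1", "x2", "x3", "x4"))
  u <- unlist(p)
  expect_identical(approximation_pair(p, u), list(lower = sort(u),
                                                  upper = sort(u)))
  empty <- approximation_pair(p, character(0))
  expect_length(empty$lower, 0)
  expect_length(empty$upper, 0)
  expect_error(approximation_pair(p, "zz"), "Unknown")
})

test_that("approximation duality holds on random partitions", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    u <- paste0("x", seq_len(n))
    p <- unname(split(u, sample(1:3, n, replace = TRUE)))
    x <- sample(u, sample(0:n, 1))
    ap <- approximation_pair(p, x)
    comp <- approximation_pair(p, setdiff(u, x))
    expect_identical(ap$lower, sort(setdiff(u, comp$upper)))
    expect_true(all(ap$lower %in% x))
    expect_true(all(x %in% ap$upper))
  }
})

test_that("neighbourhoods and descriptions follow the block structure", {
  tab <- worked_example_table()
  c5 <- tab$coverings$C5
  c1 <- tab$coverings$C1
  c2 <- tab$coverings$C2
  expect_identical(neighborhood(c5, "x1"), "x1")
  expect_identical(neighborhood(c1, "x1"), c("x1", "x2"))
  d5 <- descriptions(c5, "x1")
  expect_same_sets(d5$minimal, list(c("x1", "x2"), c("x1", "x3")))
  expect_same_sets(d5$maximal, list(c("x1", "x2", "x3")))
  d2 <- descriptions(c2, "x3")
  expect_identical(d2$minimal, list("x3"))
  expect_identical(d2$maximal, list("x3"))
  # on a partition, neighbourhood and both descriptions are the block of x
  expect_identical(neighborhood(c1, "x4"), c("x3", "x4"))
  d1 <- descriptions(c1, "x4")
  expect_identical(d1$minimal, d1$maximal)
  expect_error(neighborhood(c1, "zz"), "not covered")
})

test_that("x belongs to its neighbourhood, inside every containing block", {
  set.seed(7)
  for (i in 1:20) {
    tab <- random_table(seed = 100 + i)
    cv <- tab$coverings[[sample(length(tab$coverings), 1)]]
    x <- sample(tab$objects, 1)
    nb <- neighborhood(cv, x)
    expect_true(x %in% nb)
    for (b in cv$blocks) if (x %in% b) expect_true(all(nb %in% b))
  }
})

test_that("positive region collects certainly classified objects", {
  tab <- worked_example_table()
  expect_identical(positive_region(tab$coverings$C5, tab$decision),
                   paste0("x", 1:6))
  pos4 <- positive_region(tab$coverings$C4, tab$decision)
  expect_lt(length(pos4), 6)
  one_class <- decision_partition(list(D = paste0("x", 1:6)))
  expect_identical(positive_region(tab$coverings$C4, one_class),
                   paste0("x", 1:6))
})

test_that("effective blocks are exactly the class-contained blocks", {
  tab <- worked_example_table()
  eff <- effective_blocks(tab)
  expect_identical(nrow(eff[eff$covering_id == "C4", ]), 0L)
  expect_same_sets(eff$block[eff$covering_id == "C2"],
                   list("x3", c("x4", "x5"), "x6"))
  expect_same_sets(eff$block[eff$covering_id == "C1"],
                   list(c("x1", "x2"), c("x5", "x6")))
  # every effective block sits inside exactly one decision class
  for (i in seq_len(nrow(eff))) {
    inside <- vapply(tab$decision, function(cl)
      all(eff$block[[i]] %in% cl), logical(1))
    expect_identical(sum(inside), 1L)
    expect_identical(names(which(inside)), eff$decision_label[i])
  }
})

test_that("related family reproduces the worked-example sets", {
  fam <- related_family(worked_example_table())
  expect_identical(fam$per_object$x1, c("C1", "C3", "C5"))
  expect_identical(fam$per_object$x2, c("C1", "C5"))
  expect_identical(fam$per_object$x3, c("C2", "C5"))
  expect_identical(fam$per_object$x4, c("C2", "C5"))
  expect_identical(fam$per_object$x5, c("C1", "C2", "C3", "C5"))
  expect_identical(fam$per_object$x6, c("C1", "C2", "C3", "C5"))
  expect_same_sets(fam$family,
                   list(c("C1", "C3", "C5"), c("C1", "C5"),
                        c("C2", "C5"), c("C1", "C2", "C3", "C5")))
  expect_length(fam$uncovered, 0)
})

test_that("objects with no effective block are reported, not dropped", {
  # one covering whose only blocks straddle the classes except one
  tab <- covering_table(
    objects = c("a", "b", "c", "d"),
    coverings = list(covering("C1", list(c("a", "b"), c("b", "c", "d")))),
    decision = list(D1 = c("a", "b"), D2 = c("c", "d"))
  )
  fam <- related_family(tab)
  expect_identical(fam$uncovered, c("c", "d"))
  expect_identical(fam$family, list("C1"))
})

test_that("discernibility function yields exactly the printed reducts", {
  rf <- all_reducts(worked_example_table())
  expect_same_sets(rf$dnf_minimal, list("C5", c("C1", "C2")))
  single <- covering_table(
    objects = c("a", "b"),
    coverings = list(covering("C1", list("a", "b"))),
    decision = list(D1 = "a", D2 = "b"))
  expect_identical(all_reducts(single)$dnf_minimal, list("C1"))
})

test_that("inconsistent tables raise an explicit error", {
  tab <- covering_table(
    objects = c("a", "b"),
    coverings = list(covering("C1", list(c("a", "b")))),
    decision = list(D1 = "a", D2 = "b"))
  expect_error(all_reducts(tab), "inconsistent")
  expect_error(adre_reduce(tab), "inconsistent")
})

test_that("all_reducts agrees with power-set enumeration on random tables", {
  for (i in 1:60) {
    tab <- random_table(seed = 2000 + i)
    rf <- all_reducts(tab)
    expect_same_sets(rf$dnf_minimal, brute_force_reducts(tab))
    # every DNF term hits every clause and is minimal
    for (s in rf$dnf_minimal) {
      expect_true(all(vapply(rf$cnf, function(e) any(e %in% s),
                             logical(1))))
      for (v in s) {
        expect_false(all(vapply(rf$cnf, function(e)
          any(e %in% setdiff(s, v)), logical(1))) && length(s) > 1)
      }
    }
  }
})
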