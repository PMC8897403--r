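# Independent oracles and random-instance generators shared across tests.

# exhaustive enumeration over the power set of coverings: all minimal
# hitting sets of the table's related family
brute_force_reducts <- function(table) {
  fam <- related_family(table)$family
  ids <- names(table$coverings)
  ids <- ids[ids %in% unique(unlist(fam))]
  hits_all <- function(s) {
    all(vapply(fam, function(e) any(e %in% s), logical(1)))
  }
  subsets <- list()
  for (k in seq_along(ids)) {
    for (idx in asplit(utils::combn(length(ids), k), 2)) {
      s <- ids[idx]
      if (hits_all(s)) subsets[[length(subsets) + 1L]] <- sort(s)
    }
  }
  minimal <- Filter(function(s) {
    !any(vapply(subsets, function(t)
      length(t) < length(s) && all(t %in% s), logical(1)))
  }, subsets)
  unique(minimal)
}

# random covering decision table; regenerates until the related family is
# non-empty so reduct computation is defined
random_table <- function(seed, n_objects = NULL, n_coverings = NULL) {
  set.seed(seed)
  repeat {
    n <- n_objects %||% sample(4:12, 1)
    m <- n_coverings %||% sample(2:8, 1)
    objects <- paste0("x", seq_len(n))
    labels <- sample(c("D1", "D2", if (n > 6) "D3"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    coverings <- lapply(seq_len(m), function(i) {
      blocks <- list()
      uncovered <- objects
      while (length(uncovered) > 0L) {
        k <- sample(1:3, 1)
        blk <- unique(c(sample(uncovered, min(k, length(uncovered))),
                        sample(objects, sample(0:2, 1))))
        blocks[[length(blocks) + 1L]] <- blk
        uncovered <- setdiff(uncovered, blk)
      }
      covering(paste0("C", i), blocks, cost = sample(c(1, 1, 2, 3), 1))
    })
    tab <- covering_table(objects, coverings,
                          split(objects, factor(labels)))
    if (length(related_family(tab)$family) > 0L) return(tab)
  }
}

canon_sets <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(lengths(sets), vapply(sets, paste, "", collapse = ","))]
}

expect_same_sets <- function(a, b) {
  expect_identical(canon_sets(a), canon_sets(b))
}
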