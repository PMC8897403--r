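# Fixtures for the worked examples and seeded synthetic generators, so
# every stage of the pipeline is testable without external data.

#' Worked six-object reduction example
#'
#' The small covering decision table used throughout the reduction
#' walkthrough: six objects, five coverings (one per symbolic attribute,
#' unit costs) and two decision classes. Its related family has four
#' distinct members and its reducts are \{C5\} and \{C1, C2\}.
#'
#' @return A [covering_table()].
#' @export
worked_example_table <- function() {
  b <- function(...) c(...)
  covering_table(
    objects = paste0("x", 1:6),
    coverings = list(
      covering("C1", list(b("x1", "x2"), b("x3", "x4"), b("x5", "x6"))),
      covering("C2", list(b("x1", "x2", "x4"), b("x3"),
                          b("x1", "x2", "x4", "x5"), b("x4", "x5"),
                          b("x6"))),
      covering("C3", list(b("x1"), b("x2", "x3", "x4"), b("x5", "x6"))),
      covering("C4", list(b("x1", "x2", "x4"), b("x1", "x2", "x3", "x4"),
                          b("x3", "x4", "x5", "x6"), b("x3", "x5", "x6"))),
      covering("C5", list(b("x1", "x2"), b("x1", "x3"),
                          b("x1", "x2", "x3"), b("x4"), b("x5", "x6")))
    ),
    decision = list(D1 = c("x1", "x2", "x3"), D2 = c("x4", "x5", "x6"))
  )
}

#' COVID-19 rescue-scheme evaluation case
#'
#' The three-scheme, three-criterion, four-time-frame grey evaluation
#' matrix of the COVID-19 community rescue case: c1 the health status of
#' the infected case (scalar, gain), c2 the number of rescuers (interval,
#' gain), c3 the costs of rescue equipment and labour (linguistic pair,
#' cost). Criterion weights are (0.4, 0.45, 0.15) and the reference vector
#' is (6, [5, 11], [G, M]).
#'
#' @return A list with `values` (tibble `scheme`, `criterion`, `frame`,
#'   `value` list-column), `criteria` (tibble `criterion`, `type`,
#'   `weight`) and `reference` (named list).
#' @export
covid_case_matrix <- function() {
  entry <- function(scheme, criterion, frame, value) {
    tibble(scheme = scheme, criterion = criterion, frame = frame,
           value = list(value))
  }
  raw <- list(
    # frame, scheme, c1, c2, c3
    list("t1", "x1", 4, c(2, 5), c("VG", "MG")),
    list("t1", "x2", 4, c(4, 7), c("G", "MG")),
    list("t1", "x3", 5, c(3, 6), c("MG", "MP")),
    list("t2", "x1", 3, c(4, 6), c("G", "MG")),
    list("t2", "x2", 6, c(6, 12), c("MG", "M")),
    list("t2", "x3", 5, c(5, 9), c("MG", "M")),
    list("t3", "x1", 3, c(4, 6), c("G", "MG")),
    list("t3", "x2", 5, c(6, 11), c("MG", "M")),
    list("t3", "x3", 6, c(8, 15), c("MG", "M")),
    list("t4", "x1", 3, c(5, 6), c("G", "MG")),
    list("t4", "x2", 7, c(9, 12), c("M", "MP")),
    list("t4", "x3", 6, c(7, 10), c("MG", "M"))
  )
  values <- bind_rows(map(raw, function(r) {
    bind_rows(entry(r[[2]], "c1", r[[1]], r[[3]]),
              entry(r[[2]], "c2", r[[1]], r[[4]]),
              entry(r[[2]], "c3", r[[1]], r[[5]]))
  }))
  list(
    values = values,
    criteria = tibble(criterion = c("c1", "c2", "c3"),
                      type = c("gain", "gain", "cost"),
                      weight = c(0.4, 0.45, 0.15)),
    reference = list(c1 = 6, c2 = c(5, 11), c3 = c("G", "M"))
  )
}

#' Synthetic covering decision table with a planted reduct
#'
#' Emulates the structure of a preprocessed emergency decision table (by
#' default 81 events, 15 condition attributes, 3 response levels, mirroring
#' the scale of a provincial COVID-19 response dataset). The decision
#' partition is drawn first; `planted` "informative" coverings are built
#' from within-class blocks only (so all their blocks are effective and
#' they form a planted hitting set); the remaining coverings are noise,
#' built from class-straddling blocks that own no effective block. At
#' `consistency = 1` every object is covered by an effective block of an
#' informative covering; lower consistency contaminates that fraction of
#' informative blocks by merging across class boundaries.
#'
#' @param n_objects Number of objects (default 81).
#' @param n_coverings Total number of coverings (default 15).
#' @param blocks_per Integer range of within-class block sizes, default
#'   `c(2, 5)`.
#' @param consistency Fraction in [0, 1] of informative structure retained
#'   (default 1).
#' @param planted Number of informative coverings (default 3).
#' @param n_classes Number of decision classes (default 3).
#' @param cost_dist `"unit"` or `"uniform"` (costs drawn from U(0.5, 2)).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A [covering_table()] with attribute `informative` naming the
#'   planted coverings.
#' @export
synth_table <- function(n_objects = 81, n_coverings = 15,
                        blocks_per = c(2, 5), consistency = 1,
                        planted = 3, n_classes = 3,
                        cost_dist = c("unit", "uniform"), seed = 1) {
  cost_dist <- match.arg(cost_dist)
  if (planted > n_coverings) {
    abort("More planted coverings requested than total coverings.")
  }
  if (consistency < 0 || consistency > 1) {
    abort("`consistency` must lie in [0, 1].")
  }
  if (n_classes < 2 || n_objects < 2 * n_classes) {
    abort("Need at least two classes and two objects per class.")
  }
  local_seed(seed, {
    objects <- paste0("x", seq_len(n_objects))
    # decision partition first: every class non-empty
    labels <- paste0("D", seq_len(n_classes))
    assign <- c(labels, sample(labels, n_objects - n_classes, replace = TRUE))
    assign <- sample(assign)
    classes <- split(objects, factor(assign, levels = labels))

    chunk <- function(x, sizes_range) {
      x <- sample(x)
      out <- list()
      while (length(x) > 0L) {
        k <- min(length(x), sample(seq(sizes_range[1], sizes_range[2]), 1))
        out[[length(out) + 1L]] <- x[seq_len(k)]
        x <- x[-seq_len(k)]
      }
      out
    }

    informative <- map(seq_len(planted), function(i) {
      blocks <- unlist(map(classes, chunk, sizes_range = blocks_per),
                       recursive = FALSE)
      blocks <- unname(blocks)
      if (consistency < 1 && length(blocks) > 1L) {
        n_bad <- floor((1 - consistency) * length(blocks))
        if (n_bad > 0L) {
          # merge contaminated blocks with a block of another class
          bad <- sample(seq_along(blocks), n_bad)
          for (b in bad) {
            lab_b <- decision_label_of(decision_partition(classes),
                                       blocks[[b]][1])
            other <- setdiff(seq_along(blocks), b)
            straddler <- other[map_lgl(other, function(j) {
              decision_label_of(decision_partition(classes),
                                blocks[[j]][1]) != lab_b
            })]
            if (length(straddler)) {
              j <- straddler[sample.int(length(straddler), 1)]
              blocks[[b]] <- union(blocks[[b]], blocks[[j]])
            }
          }
        }
      }
      covering(paste0("A", i), blocks,
               cost = if (cost_dist == "unit") 1 else runif(1, 0.5, 2))
    })

    noise <- map(seq_len(n_coverings - planted), function(i) {
      blocks <- chunk(objects, c(max(2, blocks_per[1]), blocks_per[2]))
      # force every block to straddle classes so it cannot be effective
      lab <- map_chr(objects, function(x)
        decision_label_of(decision_partition(classes), x))
      names(lab) <- objects
      for (b in seq_along(blocks)) {
        if (length(unique(lab[blocks[[b]]])) == 1L) {
          lab_b <- lab[blocks[[b]][1]]
          donor <- sample(objects[lab != lab_b], 1)
          blocks[[b]] <- c(blocks[[b]], donor)
        }
      }
      covering(paste0("N", i), blocks,
               cost = if (cost_dist == "unit") 1 else runif(1, 0.5, 2))
    })

    tab <- covering_table(objects, c(informative, noise),
                          decision_partition(classes))
    attr(tab, "informative") <- map_chr(informative, "id")
    tab
  })
}

#' Synthetic grey evaluation matrix
#'
#' Emulates the structure of a grey multi-state evaluation matrix: a
#' mixture of scalar, interval and linguistic entries over schemes,
#' criteria and states, with per-criterion state probabilities drawn from
#' normalised gamma variates (a Dirichlet draw) summing to 1. Fully
#' deterministic under `seed`.
#'
#' @param n_schemes,n_criteria,n_frames Positive dimensions.
#' @param seed Integer seed.
#' @param scale A [linguistic_scale()] supplying the linguistic vocabulary.
#' @return A list with `values` (tibble `scheme`, `criterion`, `frame`,
#'   `value`), `criteria` (tibble with equal weights, last criterion a
#'   cost), `reference` (named list) and `probabilities` (tibble
#'   `criterion`, `frame`, `p`).
#' @export
synth_evaluation <- function(n_schemes = 3, n_criteria = 3, n_frames = 4,
                             seed = 1, scale = linguistic_scale()) {
  if (n_schemes < 1 || n_criteria < 1 || n_frames < 1) {
    abort("Dimensions must be positive.")
  }
  local_seed(seed, {
    schemes <- paste0("x", seq_len(n_schemes))
    crits <- paste0("c", seq_len(n_criteria))
    frames <- paste0("t", seq_len(n_frames))
    kind_of <- sample(c("scalar", "interval", "linguistic"), n_criteria,
                      replace = TRUE)
    draw <- function(kind) {
      switch(kind,
        scalar = round(runif(1, 0, 10), 1),
        interval = {
          a <- round(sort(runif(2, 0, 12)), 1)
          if (a[1] == a[2]) a[2] <- a[2] + 0.5
          a
        },
        linguistic = sort(sample(scale$term, 2)))
    }
    values <- bind_rows(map(schemes, function(s) {
      bind_rows(map(seq_along(crits), function(j) {
        bind_rows(map(frames, function(f) {
          tibble(scheme = s, criterion = crits[j], frame = f,
                 value = list(draw(kind_of[j])))
        }))
      }))
    }))
    reference <- setNames(map(kind_of, draw), crits)
    probabilities <- bind_rows(map(seq_along(crits), function(j) {
      g <- rgamma(n_frames, shape = 2)
      tibble(criterion = crits[j], frame = frames, p = g / sum(g))
    }))
    w <- rep(1 / n_criteria, n_criteria)
    criteria <- tibble(criterion = crits,
                       type = c(rep("gain", n_criteria - 1), "cost"),
                       weight = w)
    list(values = values, criteria = criteria, reference = reference,
         probabilities = probabilities)
  })
}
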