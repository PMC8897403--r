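# Multi-department aggregation: consensus matrix, similarity distance,
# department weighting and the comprehensive group prospect matrix.

check_prospect_df <- function(df, name) {
  df <- as_tibble(df)
  needed <- c("scheme", "criterion", "lo", "hi")
  if (!all(needed %in% names(df))) {
    abort(sprintf("`%s` must have columns %s.", name,
                  paste(needed, collapse = ", ")))
  }
  if (any(df$lo > df$hi + 1e-12)) abort("Interval entries need lo <= hi.")
  df
}

same_axes <- function(a, b) {
  setequal(paste(a$scheme, a$criterion), paste(b$scheme, b$criterion)) &&
    nrow(a) == nrow(b)
}

#' Group consensus prospect matrix
#'
#' The entry-wise arithmetic mean of the departments' interval prospect
#' matrices (mean of lower endpoints, mean of upper endpoints). When every
#' department submits the same matrix the consensus reproduces it exactly,
#' reflecting full acceptance of the shared opinion.
#'
#' @param matrices Tibble with columns `department`, `scheme`, `criterion`,
#'   `lo`, `hi` stacking the departments' prospect matrices, or a list of
#'   per-department tibbles (`scheme`, `criterion`, `lo`, `hi`).
#' @return Tibble `scheme`, `criterion`, `lo`, `hi`.
#' @export
consensus_matrix <- function(matrices) {
  df <- stack_departments(matrices)
  per_dept <- split(df, df$department)
  base <- per_dept[[1]]
  for (d in per_dept[-1]) {
    if (!same_axes(base, d)) {
      abort("All departments must share scheme and criterion axes.")
    }
  }
  df |>
    group_by(.data$scheme, .data$criterion) |>
    summarise(lo = mean(.data$lo), hi = mean(.data$hi), .groups = "drop")
}

stack_departments <- function(matrices) {
  if (is.data.frame(matrices)) {
    df <- as_tibble(matrices)
    if (!"department" %in% names(df)) {
      abort("Stacked input needs a `department` column.")
    }
    check_prospect_df(df, "matrices")
  } else {
    ids <- names(matrices) %||% paste0("dept", seq_along(matrices))
    bind_rows(map2(matrices, ids, function(m, id) {
      mutate(check_prospect_df(m, id), department = id, .before = 1)
    }))
  }
}

#' Distance between a department matrix and the consensus
#'
#' Sum over all scheme/criterion entries of the interval distance
#' `d([a, b], [c, e]) = (|a - c| + |b - e|) / 2`; zero exactly when the
#' department agrees with the consensus entry-wise.
#'
#' @param matrix_k A department's prospect matrix (tibble `scheme`,
#'   `criterion`, `lo`, `hi`).
#' @param consensus The [consensus_matrix()] (same columns and axes).
#' @return A single non-negative number.
#' @export
consensus_distance <- function(matrix_k, consensus) {
  a <- check_prospect_df(matrix_k, "matrix_k")
  b <- check_prospect_df(consensus, "consensus")
  if (!same_axes(a, b)) abort("Matrices must share scheme/criterion axes.")
  m <- inner_join(a, b, by = c("scheme", "criterion"),
                  suffix = c("", ".ref"))
  sum((abs(m$lo - m$lo.ref) + abs(m$hi - m$hi.ref)) / 2)
}

#' Department weights from consensus distances
#'
#' Inverse-distance weighting `w_k` proportional to `1 / (1 + d_k)`,
#' normalised to sum to 1: departments closer to the group consensus carry
#' more weight, and equal distances yield uniform weights.
#'
#' @param distances Non-negative numeric vector (optionally named by
#'   department).
#' @return Numeric weight vector summing to 1, names preserved.
#' @export
department_weights <- function(distances) {
  if (!is.numeric(distances) || any(distances < 0) || anyNA(distances)) {
    abort("`distances` must be non-negative numbers.")
  }
  w <- 1 / (1 + distances)
  w / sum(w)
}

#' Comprehensive group prospect matrix and scheme selection
#'
#' Aggregates the departments' interval prospect matrices into the
#' comprehensive matrix `V**` as the weighted entry-wise sum, with weights
#' derived from each department's distance to the group consensus (or
#' supplied explicitly). The selected scheme maximises the
#' criterion-weighted sum of interval midpoints of `V**`. A per-department
#' multiplier hook rescales influence, e.g. for departments with higher
#' collaboration capacity.
#'
#' @param matrices As in [consensus_matrix()].
#' @param criteria Tibble `criterion`, `weight` (and optionally `type`);
#'   weights must sum to 1.
#' @param weights Optional explicit department weights (summing to 1);
#'   by default derived via [department_weights()].
#' @param multipliers Optional named non-negative multipliers applied to
#'   the department weights before renormalisation.
#' @return An object of class `group_result`: list with `consensus`,
#'   `distances`, `weights`, `group_matrix`, `utilities`, `selected`.
#' @export
group_aggregate <- function(matrices, criteria, weights = NULL,
                            multipliers = NULL) {
  df <- stack_departments(matrices)
  criteria <- as_tibble(criteria)
  if (!all(c("criterion", "weight") %in% names(criteria))) {
    abort("`criteria` must have columns criterion and weight.")
  }
  if (abs(sum(criteria$weight) - 1) > 1e-8) {
    abort("Criterion weights must sum to 1.")
  }
  vstar <- consensus_matrix(df)
  depts <- unique(df$department)
  distances <- map_dbl(setNames(depts, depts), function(k) {
    consensus_distance(df[df$department == k,
                          c("scheme", "criterion", "lo", "hi")], vstar)
  })
  if (is.null(weights)) {
    weights <- department_weights(distances)
  } else {
    weights <- unlist(weights)
    if (length(weights) != length(depts)) {
      abort("One weight per department is required.")
    }
    if (is.null(names(weights))) names(weights) <- depts
    if (abs(sum(weights) - 1) > 1e-8) {
      abort("Department weights must sum to 1.")
    }
  }
  if (!is.null(multipliers)) {
    m <- rep(1, length(depts)); names(m) <- depts
    m[names(multipliers)] <- unlist(multipliers)
    if (any(m < 0)) abort("Multipliers must be non-negative.")
    weights <- weights * m
    weights <- weights / sum(weights)
  }
  vss <- df |>
    mutate(w = unname(weights[.data$department])) |>
    group_by(.data$scheme, .data$criterion) |>
    summarise(lo = sum(.data$w * .data$lo), hi = sum(.data$w * .data$hi),
              .groups = "drop")
  cw <- setNames(criteria$weight, criteria$criterion)
  utilities <- vss |>
    mutate(w = unname(cw[.data$criterion])) |>
    group_by(.data$scheme) |>
    summarise(utility = sum(.data$w * (.data$lo + .data$hi) / 2),
              .groups = "drop") |>
    arrange(desc(.data$utility)) |>
    mutate(rank = row_number())
  structure(list(consensus = vstar, distances = distances,
                 weights = weights, group_matrix = vss,
                 utilities = utilities,
                 selected = utilities$scheme[1]),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %d departments, selected: %s\n",
              length(x$weights), x$selected))
  cat("  weights:", paste(sprintf("%s=%.3f", names(x$weights), x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.group_result <- function(x, ...) x$utilities

#' @export
glance.group_result <- function(x, ...) {
  tibble(selected = x$selected, n_departments = length(x$weights),
         max_distance = max(x$distances),
         best_utility = x$utilities$utility[1])
}
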