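# Interval (grey) cumulative-prospect-theory evaluation of alternative
# schemes under multi-attribute, multi-state uncertainty.

#' Linguistic evaluation scale
#'
#' An ordered set of qualitative terms, each resolved to a closed interval
#' on [0, 1]. The default seven-point scale tiles the unit interval with
#' adjacent terms sharing endpoints: VP [0, 0.1], P [0.1, 0.25],
#' MP [0.25, 0.4], M [0.4, 0.55], MG [0.55, 0.7], G [0.7, 0.85],
#' VG [0.85, 1].
#'
#' @param terms Character vector of term labels, worst to best.
#' @param lo,hi Numeric vectors of interval endpoints, same length as
#'   `terms`; must be ordered, tile [0, 1] and share endpoints between
#'   adjacent terms.
#' @return A tibble of class `linguistic_scale` with columns `term`, `lo`,
#'   `hi`.
#' @export
linguistic_scale <- function(terms = c("VP", "P", "MP", "M", "MG", "G", "VG"),
                             lo = c(0, 0.1, 0.25, 0.4, 0.55, 0.7, 0.85),
                             hi = c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85, 1)) {
  if (length(terms) != length(lo) || length(lo) != length(hi)) {
    abort("`terms`, `lo` and `hi` must have equal length.")
  }
  if (any(lo >= hi)) abort("Each term interval needs lo < hi.")
  if (lo[1] != 0 || hi[length(hi)] != 1 ||
      (length(terms) > 1 && any(abs(hi[-length(hi)] - lo[-1]) > 1e-12))) {
    abort("Scale intervals must tile [0, 1] with shared endpoints.")
  }
  structure(tibble(term = as.character(terms), lo = lo, hi = hi),
            class = c("linguistic_scale", class(tibble())))
}

#' Resolve a linguistic term to its interval
#'
#' @param term A single term label present in the scale.
#' @param scale A [linguistic_scale()].
#' @return Numeric `c(lo, hi)`.
#' @export
map_linguistic <- function(term, scale = linguistic_scale()) {
  i <- match(term, scale$term)
  if (is.na(i)) abort(sprintf("Unknown linguistic term '%s'.", term))
  c(scale$lo[i], scale$hi[i])
}

# resolve any grey value to an interval c(lo, hi):
#   numeric length 1 -> degenerate interval; numeric length 2 -> interval;
#   character terms (1 or more) -> interval spanning min(lo)..max(hi) of
#   the mapped terms (the convention for paired entries like [G, M])
resolve_grey <- function(value, scale = linguistic_scale()) {
  if (is.numeric(value)) {
    if (length(value) == 1L) return(c(value, value))
    if (length(value) == 2L) {
      if (value[1] > value[2]) abort("Interval needs lo <= hi.")
      return(as.numeric(value))
    }
    abort("Numeric grey values must have length 1 or 2.")
  }
  if (is.character(value)) {
    ints <- map(value, map_linguistic, scale = scale)
    return(c(min(map_dbl(ints, 1)), max(map_dbl(ints, 2))))
  }
  abort("Grey values must be numeric or linguistic.")
}

#' Prospect-theory parameters
#'
#' Risk curvature for gains and losses (`alpha`, `beta`), loss aversion
#' (`lambda`), and probability-weighting curvature for the gain and loss
#' branches (`chi`, `delta`). Defaults are the canonical
#' Tversky--Kahneman estimates alpha = beta = 0.88, lambda = 2.25,
#' chi = 0.61, delta = 0.69. Weighting curvatures are restricted to
#' (0.28, 1] because the weighting function is monotone only there.
#'
#' @param alpha,beta Risk-curvature exponents in (0, 1].
#' @param lambda Loss-aversion coefficient, >= 1.
#' @param chi,delta Probability-weighting curvature for gains/losses,
#'   in (0.28, 1].
#' @return An object of class `prospect_params`.
#' @export
prospect_params <- function(alpha = 0.88, beta = 0.88, lambda = 2.25,
                            chi = 0.61, delta = 0.69) {
  chk <- function(x, nm, lo, hi, lo_open = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_open) x <= lo else x < lo) || x > hi) {
      abort(sprintf("`%s` must be a single number in %s%g, %g].",
                    nm, if (lo_open) "(" else "[", lo, hi))
    }
  }
  chk(alpha, "alpha", 0, 1); chk(beta, "beta", 0, 1)
  chk(lambda, "lambda", 1, Inf, lo_open = FALSE)
  chk(chi, "chi", 0.28, 1); chk(delta, "delta", 0.28, 1)
  structure(list(alpha = alpha, beta = beta, lambda = lambda,
                 chi = chi, delta = delta),
            class = "prospect_params")
}

#' @export
print.prospect_params <- function(x, ...) {
  cat(sprintf(
    "<prospect_params> alpha=%.3g beta=%.3g lambda=%.3g chi=%.3g delta=%.3g\n",
    x$alpha, x$beta, x$lambda, x$chi, x$delta))
  invisible(x)
}

#' Prospect-theory value function
#'
#' `v(d) = d^alpha` for gains (`d >= 0`) and `v(d) = -lambda * (-d)^beta`
#' for losses, relative to the reference point. Concave for gains, convex
#' for losses, steeper for losses (loss aversion). Vectorised over `d`.
#'
#' @param d Numeric vector of deviations from the reference point.
#' @param params A [prospect_params()].
#' @return Numeric vector of subjective values.
#' @export
value_fn <- function(d, params = prospect_params()) {
  if (!is.numeric(d) || anyNA(d) || any(!is.finite(d))) {
    abort("`d` must be finite numeric.")
  }
  ifelse(d >= 0, d^params$alpha, -params$lambda * (-d)^params$beta)
}

#' Prospect-theory probability weighting function
#'
#' `pi(p) = p^g / (p^g + (1-p)^g)^(1/g)` with curvature `g = chi` on the
#' gain branch and `g = delta` on the loss branch. Fixes 0 and 1, reduces
#' to the identity at curvature 1, and overweights small probabilities.
#' Vectorised over `p`.
#'
#' @param p Probabilities in [0, 1].
#' @param branch `"gain"` or `"loss"`.
#' @param params A [prospect_params()].
#' @return Numeric vector of decision weights.
#' @export
prob_weight <- function(p, branch = c("gain", "loss"),
                        params = prospect_params()) {
  branch <- match.arg(branch)
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  g <- if (branch == "gain") params$chi else params$delta
  w <- p^g / (p^g + (1 - p)^g)^(1 / g)
  w[p == 0] <- 0
  w[p == 1] <- 1
  w
}

#' Gain/loss deviation of a grey value from its reference
#'
#' Interval subtraction against the per-criterion reference point. For a
#' gain criterion the deviation is `[lo - ref_hi, hi - ref_lo]`; for a cost
#' criterion the sign is flipped (`[ref_lo - hi, ref_hi - lo]`) so that
#' falling below the reference counts as a gain.
#'
#' @param value,ref Intervals `c(lo, hi)` (scalars are accepted as
#'   degenerate intervals).
#' @param type `"gain"` or `"cost"`.
#' @return Interval `c(lo, hi)` of deviations.
#' @export
delta_vs_reference <- function(value, ref, type = c("gain", "cost")) {
  type <- match.arg(type)
  value <- resolve_grey(value)
  ref <- resolve_grey(ref)
  if (type == "gain") c(value[1] - ref[2], value[2] - ref[1])
  else c(ref[1] - value[2], ref[2] - value[1])
}

#' Interval prospect value over uncertain states
#'
#' Combines per-state deviation intervals with state probabilities:
#' each state's deviation is passed endpoint-wise through the value
#' function, weighted by the probability weight of its branch (gain when
#' the state's midpoint deviation is non-negative, loss otherwise), and
#' summed across states.
#'
#' @param deltas List of deviation intervals `c(lo, hi)`.
#' @param probs Numeric vector of state probabilities summing to 1.
#' @param params A [prospect_params()].
#' @return Interval `c(lo, hi)` prospect value.
#' @export
prospect_value <- function(deltas, probs, params = prospect_params()) {
  if (!is.list(deltas)) deltas <- list(deltas)
  if (length(deltas) != length(probs)) {
    abort("`deltas` and `probs` must have the same length.")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    abort("State probabilities must sum to 1.")
  }
  out <- c(0, 0)
  for (i in seq_along(deltas)) {
    d <- resolve_grey(deltas[[i]])
    branch <- if (mean(d) >= 0) "gain" else "loss"
    w <- prob_weight(probs[i], branch, params)
    out <- out + w * value_fn(d, params)
  }
  out
}

#' Cumulative prospect evaluation and ranking of schemes
#'
#' The full decision pipeline: every grey entry is resolved to an interval
#' under the linguistic scale, edited into a gain/loss deviation against
#' the per-criterion reference point, aggregated over states (or time
#' frames, equiprobable unless probabilities are supplied) into an interval
#' prospect value per scheme and criterion, and finally collapsed by
#' criterion-weighted midpoints into one cumulative prospect value per
#' scheme. Schemes are ranked by that value, largest first.
#'
#' @param values Tibble with columns `scheme`, `criterion`, `frame` and a
#'   list-column `value` of grey entries (scalar, `c(lo, hi)`, or one/two
#'   linguistic terms).
#' @param criteria Tibble with columns `criterion`, `type`
#'   (`"gain"`/`"cost"`) and `weight`; weights must sum to 1.
#' @param reference Named list mapping each criterion to its reference grey
#'   value (the decision-maker's expectation).
#' @param params A [prospect_params()].
#' @param scale A [linguistic_scale()].
#' @param probabilities Optional tibble with columns `criterion`, `frame`,
#'   `p` giving per-criterion state probabilities (default equiprobable).
#' @return An object of class `prospect_result`: list with `prospects`
#'   (tibble `scheme`, `criterion`, `lo`, `hi`, `midpoint`), `utilities`
#'   (tibble `scheme`, `utility`, `rank`), `selected`, `tie`, plus the
#'   inputs used.
#' @examples
#' case <- covid_case_matrix()
#' res <- cumulative_prospect(case$values, case$criteria, case$reference)
#' res$selected
#' @export
cumulative_prospect <- function(values, criteria, reference,
                                params = prospect_params(),
                                scale = linguistic_scale(),
                                probabilities = NULL) {
  values <- as_tibble(values)
  criteria <- as_tibble(criteria)
  needed <- c("scheme", "criterion", "frame", "value")
  if (!all(needed %in% names(values))) {
    abort(sprintf("`values` must have columns %s.",
                  paste(needed, collapse = ", ")))
  }
  if (!all(c("criterion", "type", "weight") %in% names(criteria))) {
    abort("`criteria` must have columns criterion, type, weight.")
  }
  if (abs(sum(criteria$weight) - 1) > 1e-8) {
    abort("Criterion weights must sum to 1.")
  }
  if (!all(criteria$type %in% c("gain", "cost"))) {
    abort("Criterion types must be 'gain' or 'cost'.")
  }
  missing_ref <- setdiff(criteria$criterion, names(reference))
  if (length(missing_ref)) {
    abort(sprintf("Reference vector lacks criteria: %s.",
                  paste(missing_ref, collapse = ", ")))
  }
  schemes <- unique(values$scheme)
  # every scheme x criterion must carry the same frames
  counts <- values |> count(.data$scheme, .data$criterion)
  if (length(unique(counts$n)) != 1L) {
    abort("Every scheme/criterion cell must have the same set of frames.")
  }
  prospects <- bind_rows(map(schemes, function(s) {
    bind_rows(map(seq_len(nrow(criteria)), function(j) {
      cj <- criteria$criterion[j]
      cell <- values[values$scheme == s & values$criterion == cj, ]
      cell <- cell[order(match(cell$frame, unique(values$frame))), ]
      ref_int <- resolve_grey(reference[[cj]], scale)
      deltas <- map(cell$value, function(v) {
        delta_vs_reference(resolve_grey(v, scale), ref_int,
                           type = criteria$type[j])
      })
      p <- if (is.null(probabilities)) {
        rep(1 / nrow(cell), nrow(cell))
      } else {
        pr <- probabilities[probabilities$criterion == cj, ]
        pr$p[match(cell$frame, pr$frame)]
      }
      v <- prospect_value(deltas, p, params)
      tibble(scheme = s, criterion = cj, lo = v[1], hi = v[2],
             midpoint = mean(v))
    }))
  }))
  w <- setNames(criteria$weight, criteria$criterion)
  utilities <- prospects |>
    mutate(w = unname(w[.data$criterion])) |>
    group_by(.data$scheme) |>
    summarise(utility = sum(.data$w * .data$midpoint), .groups = "drop") |>
    arrange(desc(.data$utility)) |>
    mutate(rank = row_number())
  tie <- nrow(utilities) > 1L &&
    isTRUE(all.equal(utilities$utility[1], utilities$utility[2]))
  structure(list(prospects = prospects, utilities = utilities,
                 selected = utilities$scheme[1], tie = tie,
                 criteria = criteria, params = params),
            class = "prospect_result")
}

#' @export
print.prospect_result <- function(x, ...) {
  cat("<prospect_result>\n")
  for (i in seq_len(nrow(x$utilities))) {
    cat(sprintf("  %s  U = %+.4f%s\n", x$utilities$scheme[i],
                x$utilities$utility[i],
                if (i == 1L && !x$tie) "  <- selected" else ""))
  }
  if (x$tie) cat("  (tie at the top; selection is by serialisation order)\n")
  invisible(x)
}

#' @describeIn cumulative_prospect Per-scheme cumulative prospect values.
#' @param x A `prospect_result`.
#' @param ... Unused.
#' @export
tidy.prospect_result <- function(x, ...) x$utilities

#' @describeIn cumulative_prospect One-row summary of the decision.
#' @export
glance.prospect_result <- function(x, ...) {
  tibble(selected = x$selected,
         n_schemes = nrow(x$utilities),
         n_criteria = nrow(x$criteria),
         best_utility = x$utilities$utility[1],
         tie = x$tie)
}
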