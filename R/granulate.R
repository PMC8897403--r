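# Information-granule generation: one covering per raw attribute column.

#' Granulate one attribute into a covering
#'
#' Symbolic attributes partition the universe by equal values. Numeric
#' attributes are granulated with a delta-neighbourhood: the block of object
#' `x` is every object whose value lies within `delta * range` of `x`'s
#' value, so `delta` controls granule width as a fraction of the attribute
#' range. Duplicate blocks are merged. A numeric attribute with zero range
#' yields a single block covering the universe.
#'
#' @param values Vector of attribute values, one per object, in universe
#'   order. Names, when present, are used as object ids; otherwise ids
#'   default to `x1, x2, ...`.
#' @param kind `"symbolic"` or `"numeric"`.
#' @param delta Granule width as a fraction of the attribute range, in
#'   (0, 1]. Required for numeric attributes; ignored for symbolic ones.
#' @param id Covering id, default `"C1"`.
#' @param cost Attribute acquisition cost, default 1.
#' @return A [covering()].
#' @examples
#' granulate(c(a = "A", b = "A", c = "B"), kind = "symbolic")
#' granulate(setNames(1:6, paste0("x", 1:6)), kind = "numeric", delta = 0.2)
#' @export
granulate <- function(values, kind = c("symbolic", "numeric"), delta = NULL,
                      id = "C1", cost = 1) {
  kind <- match.arg(kind)
  if (length(values) == 0L) abort("`values` must be non-empty.")
  objects <- names(values) %||% paste0("x", seq_along(values))
  if (anyDuplicated(objects)) abort("Object ids must be unique.")
  if (kind == "symbolic") {
    blocks <- unname(split(objects, factor(as.character(values))))
  } else {
    values <- as.numeric(values)
    if (anyNA(values)) abort("Numeric attribute contains missing values.")
    if (is.null(delta) || !is.numeric(delta) || length(delta) != 1L ||
        delta <= 0 || delta > 1) {
      abort("`delta` must be a single number in (0, 1].")
    }
    rng <- max(values) - min(values)
    if (rng == 0) {
      blocks <- list(objects)
    } else {
      blocks <- map(values, function(v) {
        objects[abs(values - v) <= delta * rng + 1e-12]
      })
    }
  }
  covering(id, blocks, cost)
}

#' Granulate a raw decision table into a covering decision table
#'
#' Applies [granulate()] column-wise to a data frame of raw attribute
#' values, producing one covering per condition attribute, and builds the
#' decision partition from the designated decision column.
#'
#' @param data Data frame, one row per object.
#' @param decision Name of the decision column.
#' @param objects Optional object ids (default `x1, x2, ...` in row order).
#' @param kinds Optional named character vector mapping attribute names to
#'   `"symbolic"`/`"numeric"`; by default numeric columns are numeric,
#'   everything else symbolic.
#' @param delta Granule width for numeric attributes (single value or named
#'   vector per attribute), default 0.15.
#' @param costs Optional named numeric vector of attribute costs.
#' @return A [covering_table()].
#' @export
granulate_table <- function(data, decision, objects = NULL, kinds = NULL,
                            delta = 0.15, costs = NULL) {
  data <- as.data.frame(data)
  if (!decision %in% names(data)) {
    abort(sprintf("Unknown decision column '%s'.", decision))
  }
  objects <- objects %||% paste0("x", seq_len(nrow(data)))
  attrs <- setdiff(names(data), decision)
  if (length(attrs) == 0L) abort("No condition attributes left.")
  coverings <- map(attrs, function(a) {
    col <- setNames(data[[a]], objects)
    kind <- if (!is.null(kinds) && a %in% names(kinds)) kinds[[a]]
            else if (is.numeric(col)) "numeric" else "symbolic"
    d <- if (length(delta) > 1L) delta[[a]] else delta
    cost <- if (!is.null(costs) && a %in% names(costs)) costs[[a]] else 1
    granulate(col, kind = kind, delta = d, id = a, cost = cost)
  })
  classes <- split(objects, factor(as.character(data[[decision]])))
  covering_table(objects, coverings, decision_partition(classes))
}
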