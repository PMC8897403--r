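# Containers for covering decision tables: a universe of objects, a family
# of coverings (one per condition attribute), and a decision partition.

#' Construct a covering of the universe
#'
#' A covering generalises a partition: a family of non-empty, possibly
#' overlapping blocks of objects whose union is the universe. Each covering
#' corresponds to one condition attribute and carries the cost of acquiring
#' that attribute's information.
#'
#' @param id Single string identifying the covering (attribute name).
#' @param blocks List of character vectors of object identifiers. Blocks must
#'   be non-empty; duplicate blocks are merged.
#' @param cost Positive acquisition cost, default 1.
#' @return An object of class `covering`.
#' @examples
#' covering("C1", list(c("x1", "x2"), c("x3", "x4")))
#' @export
covering <- function(id, blocks, cost = 1) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    abort("`id` must be a single non-empty string.")
  }
  if (!is.list(blocks) || length(blocks) == 0L) {
    abort("`blocks` must be a non-empty list of object-id vectors.")
  }
  blocks <- map(blocks, function(b) sort(unique(as.character(b))))
  if (any(lengths(blocks) == 0L)) {
    abort(sprintf("Covering '%s' contains an empty block.", id))
  }
  blocks <- unique(blocks)
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost <= 0) {
    abort("`cost` must be a single positive number.")
  }
  structure(list(id = id, blocks = blocks, cost = as.numeric(cost)),
            class = "covering")
}

#' Construct a decision partition
#'
#' @param classes Named list mapping each decision label to the character
#'   vector of objects in that class. Classes must be pairwise disjoint.
#' @return An object of class `decision_partition`.
#' @export
decision_partition <- function(classes) {
  if (!is.list(classes) || is.null(names(classes)) ||
      any(!nzchar(names(classes)))) {
    abort("`classes` must be a named list of object-id vectors.")
  }
  classes <- map(classes, function(x) sort(unique(as.character(x))))
  all_members <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    abort(sprintf("Decision classes overlap on: %s.",
                  paste(dup, collapse = ", ")))
  }
  structure(classes, class = "decision_partition")
}

#' Assemble a covering decision table
#'
#' Binds a universe, an ordered family of coverings (the condition
#' attributes) and a decision partition into one validated table. Every
#' covering must cover the universe exactly and the decision classes must
#' partition it.
#'
#' @param objects Character vector of unique object identifiers.
#' @param coverings List of [covering()] objects with unique ids.
#' @param decision A [decision_partition()] (or a named list coerced to one).
#' @return An object of class `covering_table`.
#' @examples
#' tab <- covering_table(
#'   objects = c("a", "b", "c", "d"),
#'   coverings = list(covering("C1", list(c("a", "b"), c("c", "d")))),
#'   decision = list(yes = c("a", "b"), no = c("c", "d"))
#' )
#' @export
covering_table <- function(objects, coverings, decision) {
  objects <- as.character(objects)
  if (length(objects) == 0L) abort("The universe must be non-empty.")
  if (anyDuplicated(objects)) abort("Object identifiers must be unique.")
  if (inherits(coverings, "covering")) coverings <- list(coverings)
  if (!all(map_lgl(coverings, inherits, "covering"))) {
    abort("`coverings` must be a list of covering objects.")
  }
  ids <- map_chr(coverings, "id")
  if (anyDuplicated(ids)) abort("Covering ids must be unique.")
  names(coverings) <- ids
  if (!inherits(decision, "decision_partition")) {
    decision <- decision_partition(decision)
  }
  for (cv in coverings) {
    members <- sort(unique(unlist(cv$blocks)))
    extra <- setdiff(members, objects)
    if (length(extra)) {
      abort(sprintf("Covering '%s' references unknown objects: %s.",
                    cv$id, paste(extra, collapse = ", ")))
    }
    missing <- setdiff(objects, members)
    if (length(missing)) {
      abort(sprintf("Covering '%s' does not cover objects: %s.",
                    cv$id, paste(missing, collapse = ", ")))
    }
  }
  dec_members <- sort(unlist(decision, use.names = FALSE))
  if (!identical(dec_members, sort(objects))) {
    abort("Decision classes must partition the universe exactly.")
  }
  structure(list(objects = objects, coverings = coverings,
                 decision = decision),
            class = "covering_table")
}

#' @export
print.covering <- function(x, ...) {
  cat(sprintf("<covering '%s'> %d blocks, cost %.3g\n",
              x$id, length(x$blocks), x$cost))
  invisible(x)
}

#' @export
print.covering_table <- function(x, ...) {
  cat(sprintf(
    "<covering_table> %d objects, %d coverings (%s), %d decision classes\n",
    length(x$objects), length(x$coverings),
    paste(names(x$coverings), collapse = ", "),
    length(x$decision)))
  invisible(x)
}

#' Tabular view of a covering decision table
#'
#' One row per (covering, block) pair, with the decision label attached when
#' the block lies inside a single decision class.
#'
#' @param x A `covering_table`.
#' @param ... Unused.
#' @return A tibble with columns `covering_id`, `block_index`, `block`
#'   (list-column), `size`, `cost`, `decision_label` (`NA` for blocks that
#'   straddle decision classes).
#' @export
tidy.covering_table <- function(x, ...) {
  rows <- imap(x$coverings, function(cv, id) {
    tibble(
      covering_id = id,
      block_index = seq_along(cv$blocks),
      block = cv$blocks,
      size = lengths(cv$blocks),
      cost = cv$cost,
      decision_label = map_chr(cv$blocks, function(b) {
        hit <- names(x$decision)[map_lgl(x$decision, function(cl)
          all(b %in% cl))]
        if (length(hit) == 1L) hit else NA_character_
      })
    )
  })
  bind_rows(rows)
}

# label of the decision class containing object x
decision_label_of <- function(decision, x) {
  names(decision)[map_lgl(decision, function(cl) x %in% cl)][1]
}

# restrict a table to a subset of objects; blocks are intersected with the
# subset, empties dropped, and each surviving block remembers its original
# index (attribute "origin" on each covering) so rules learned on the
# restriction can be matched against held-out objects.
table_subset <- function(table, objects) {
  objects <- intersect(table$objects, objects)
  coverings <- map(table$coverings, function(cv) {
    kept <- map(cv$blocks, intersect, objects)
    idx <- which(lengths(kept) > 0L)
    out <- covering(cv$id, kept[idx], cv$cost)
    # covering() dedupes; recompute origins against the deduped blocks
    origin <- map_int(out$blocks, function(b) {
      idx[which(map_lgl(kept[idx], identical, b))[1]]
    })
    attr(out, "origin") <- origin
    out
  })
  classes <- map(unclass(table$decision), intersect, objects)
  classes <- classes[lengths(classes) > 0L]
  tab <- covering_table(objects, coverings, decision_partition(classes))
  tab$coverings <- map2(tab$coverings, coverings, function(a, b) {
    attr(a, "origin") <- attr(b, "origin")
    a
  })
  tab
}
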