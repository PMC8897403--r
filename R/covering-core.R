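# Covering rough-set primitives: approximations, neighbourhoods,
# descriptions, positive region, effective approximation blocks, related
# families and exhaustive reduct computation via the discernibility function.

#' Lower and upper approximation of a set under a partition
#'
#' The lower approximation is the union of partition blocks contained in
#' `x_set`; the upper approximation is the union of blocks intersecting it.
#' Together they bracket the certain and possible members of the set.
#'
#' @param partition A `decision_partition` or a list of disjoint blocks
#'   partitioning the universe.
#' @param x_set Character vector of object ids (a subset of the universe).
#' @return A list with components `lower` and `upper` (sorted character
#'   vectors), satisfying `lower` ⊆ `x_set` ⊆ `upper`.
#' @examples
#' p <- list(c("x1", "x2"), c("x3", "x4"), c("x5", "x6"))
#' approximation_pair(p, c("x1", "x2", "x3"))
#' @export
approximation_pair <- function(partition, x_set) {
  blocks <- if (inherits(partition, "decision_partition")) {
    unname(unclass(partition))
  } else {
    unname(as.list(partition))
  }
  universe <- sort(unique(unlist(blocks)))
  x_set <- unique(as.character(x_set))
  unknown <- setdiff(x_set, universe)
  if (length(unknown)) {
    abort(sprintf("Unknown object ids: %s.", paste(unknown, collapse = ", ")))
  }
  lower <- unlist(keep(blocks, function(b) all(b %in% x_set)))
  upper <- unlist(keep(blocks, function(b) any(b %in% x_set)))
  list(lower = sort(unique(lower %||% character(0))),
       upper = sort(unique(upper %||% character(0))))
}

#' Neighbourhood of an object under a covering
#'
#' The intersection of all blocks of the covering that contain the object;
#' always contains the object itself. For a partition this is just the
#' object's block.
#'
#' @param cover A [covering()].
#' @param x A single object id.
#' @return Sorted character vector of object ids.
#' @export
neighborhood <- function(cover, x) {
  stopifnot(inherits(cover, "covering"))
  containing <- keep(cover$blocks, function(b) x %in% b)
  if (length(containing) == 0L) {
    abort(sprintf("Object '%s' is not covered by '%s'.", x, cover$id))
  }
  sort(Reduce(intersect, containing))
}

#' Minimal and maximal descriptions of an object
#'
#' Among the blocks containing `x`, the minimal description keeps those with
#' no proper containing sub-block, and the maximal description those with no
#' proper containing super-block.
#'
#' @inheritParams neighborhood
#' @return A list with components `minimal` and `maximal`, each a list of
#'   blocks (sorted character vectors).
#' @export
descriptions <- function(cover, x) {
  stopifnot(inherits(cover, "covering"))
  containing <- keep(cover$blocks, function(b) x %in% b)
  if (length(containing) == 0L) {
    abort(sprintf("Object '%s' is not covered by '%s'.", x, cover$id))
  }
  proper_subset <- function(a, b) length(a) < length(b) && all(a %in% b)
  minimal <- keep(containing, function(k) {
    !any(map_lgl(containing, function(s) proper_subset(s, k)))
  })
  maximal <- keep(containing, function(k) {
    !any(map_lgl(containing, function(s) proper_subset(k, s)))
  })
  list(minimal = minimal, maximal = maximal)
}

#' Positive region of a decision under one covering
#'
#' The set of objects whose covering neighbourhood lies entirely inside a
#' single decision class, i.e. the objects the covering classifies with
#' certainty. Equals the union over decision classes of the
#' neighbourhood-based lower approximation.
#'
#' @param cover A [covering()].
#' @param decision A [decision_partition()].
#' @return Sorted character vector of object ids.
#' @export
positive_region <- function(cover, decision) {
  stopifnot(inherits(cover, "covering"))
  universe <- sort(unique(unlist(cover$blocks)))
  inside <- map_lgl(universe, function(x) {
    nb <- neighborhood(cover, x)
    any(map_lgl(decision, function(cl) all(nb %in% cl)))
  })
  universe[inside]
}

# positive region of a set of coverings: union of single-covering regions
positive_region_set <- function(table, covering_ids) {
  regions <- map(table$coverings[covering_ids], positive_region,
                 decision = table$decision)
  sort(unique(unlist(regions))) %||% character(0)
}

#' Effective approximation blocks of a covering decision table
#'
#' A block is effective when it lies entirely inside one decision class; it
#' then supports a certain classification rule. Returns every (covering,
#' block) pair satisfying this.
#'
#' @param table A [covering_table()].
#' @return A tibble with columns `covering_id`, `block_index`, `block`
#'   (list-column) and `decision_label`.
#' @export
effective_blocks <- function(table) {
  stopifnot(inherits(table, "covering_table"))
  rows <- imap(table$coverings, function(cv, id) {
    lab <- map_chr(cv$blocks, function(b) {
      hit <- names(table$decision)[
        map_lgl(table$decision, function(cl) all(b %in% cl))]
      if (length(hit) == 1L) hit else NA_character_
    })
    keepers <- which(!is.na(lab))
    tibble(covering_id = id, block_index = keepers,
           block = cv$blocks[keepers], decision_label = lab[keepers])
  })
  bind_rows(rows)
}

#' Related family of a covering decision table
#'
#' For each object, the set of coverings owning an effective block containing
#' it; the deduplicated collection of those sets is the family of the table,
#' the input of reduct computation. Objects covered by no effective block
#' are reported in `uncovered`, never silently dropped.
#'
#' @param table A [covering_table()].
#' @return An object of class `related_family`: a list with `per_object`
#'   (named list of covering-id sets), `family` (list of distinct non-empty
#'   sets, in first-appearance order) and `uncovered` (character vector).
#' @export
related_family <- function(table) {
  stopifnot(inherits(table, "covering_table"))
  eff <- effective_blocks(table)
  per_object <- map(setNames(table$objects, table$objects), function(x) {
    owns <- map_lgl(eff$block, function(b) x %in% b)
    sort(unique(eff$covering_id[owns]))
  })
  uncovered <- names(per_object)[lengths(per_object) == 0L]
  family <- unique(unname(per_object[lengths(per_object) > 0L]))
  structure(list(per_object = per_object, family = family,
                 uncovered = uncovered),
            class = "related_family")
}

#' @export
print.related_family <- function(x, ...) {
  cat(sprintf("<related_family> %d objects, %d distinct sets%s\n",
              length(x$per_object), length(x$family),
              if (length(x$uncovered))
                sprintf(", %d uncovered", length(x$uncovered)) else ""))
  for (f in x$family) cat("  {", paste(f, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
tidy.related_family <- function(x, ...) {
  tibble(object = names(x$per_object),
         coverings = unname(x$per_object),
         n_coverings = lengths(x$per_object))
}

#' All reducts via the discernibility function
#'
#' Builds the conjunctive normal form with one clause per family member and
#' expands it to its minimal disjunctive normal form by distribution with
#' absorption. Each term of the minimal DNF is a reduct: a minimal set of
#' coverings hitting every related family, hence preserving the positive
#' region of the full table.
#'
#' @param table A [covering_table()].
#' @return An object of class `reduct_formula`: a list with `cnf` (list of
#'   clauses) and `dnf_minimal` (list of minimal covering-id sets, each
#'   sorted; the list ordered by size then lexicographically).
#' @export
all_reducts <- function(table) {
  fam <- related_family(table)
  if (length(fam$family) == 0L) {
    abort(paste("The table is inconsistent: no covering owns an effective",
                "block, so the related family is empty."))
  }
  cnf <- fam$family
  terms <- list(character(0))
  for (clause in cnf) {
    expanded <- list()
    for (s in terms) {
      for (v in clause) {
        expanded[[length(expanded) + 1L]] <-
          if (v %in% s) s else sort(c(s, v))
      }
    }
    expanded <- unique(expanded)
    # absorption: drop any term containing another term
    keep_term <- map_lgl(seq_along(expanded), function(i) {
      !any(map_lgl(seq_along(expanded), function(j) {
        i != j && length(expanded[[j]]) <= length(expanded[[i]]) &&
          all(expanded[[j]] %in% expanded[[i]]) &&
          !identical(expanded[[j]], expanded[[i]])
      }))
    })
    terms <- expanded[keep_term]
  }
  ord <- order(lengths(terms), map_chr(terms, paste, collapse = ","))
  structure(list(cnf = cnf, dnf_minimal = terms[ord]),
            class = "reduct_formula")
}

#' @export
print.reduct_formula <- function(x, ...) {
  cat(sprintf("<reduct_formula> %d clauses, %d reducts\n",
              length(x$cnf), length(x$dnf_minimal)))
  for (r in x$dnf_minimal) cat("  {", paste(r, collapse = ", "), "}\n")
  invisible(x)
}
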