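# A-DRE: family -> hypergraph -> cost-aware greedy minimum vertex cover ->
# minimal reduct, plus decision-rule extraction and ordered-rule
# classification.

#' Build the hypergraph of a related family
#'
#' Vertices are the coverings appearing in any family member (with their
#' costs); each distinct family member becomes one hyperedge. A reduct of
#' the decision table is exactly a minimal vertex set hitting every edge.
#'
#' @param family A [related_family()].
#' @param costs Named numeric vector of per-covering costs; coverings absent
#'   from it get cost 1.
#' @return An object of class `hypergraph`: list with `vertices` (tibble of
#'   `id`, `cost`, in first-appearance order) and `edges` (list of
#'   covering-id sets).
#' @export
build_hypergraph <- function(family, costs = NULL) {
  stopifnot(inherits(family, "related_family"))
  if (length(family$family) == 0L) {
    abort("Cannot build a hypergraph from an empty family.")
  }
  ids <- unique(unlist(family$family))
  cost <- map_dbl(ids, function(id) {
    if (!is.null(costs) && id %in% names(costs)) costs[[id]] else 1
  })
  if (any(cost <= 0)) abort("All covering costs must be positive.")
  structure(list(vertices = tibble(id = ids, cost = cost),
                 edges = unique(family$family)),
            class = "hypergraph")
}

#' Greedy minimum-cost vertex cover of a hypergraph
#'
#' Repeatedly selects the vertex maximising the ratio (number of currently
#' uncovered edges hit) / cost, breaking ties by input order, until every
#' edge is covered. The greedy cover is then pruned to minimality by
#' [prune_cover()] when `prune = TRUE`.
#'
#' @param h A [build_hypergraph()] result.
#' @param prune Drop redundant members after the greedy pass (default TRUE).
#' @return An object of class `reduct`: list with `covering_ids`,
#'   `total_cost` and `minimal` (logical).
#' @export
greedy_min_cost_cover <- function(h, prune = TRUE) {
  stopifnot(inherits(h, "hypergraph"))
  ids <- h$vertices$id
  cost <- setNames(h$vertices$cost, ids)
  uncovered <- h$edges
  chosen <- character(0)
  while (length(uncovered) > 0L) {
    hits <- map_dbl(ids, function(v) {
      sum(map_lgl(uncovered, function(e) v %in% e))
    })
    ratio <- hits / cost[ids]
    best <- which(ratio == max(ratio))[1]  # ties: lowest input index
    v <- ids[best]
    chosen <- c(chosen, v)
    uncovered <- discard(uncovered, function(e) v %in% e)
    ids <- setdiff(ids, v)
  }
  if (prune) chosen <- prune_cover(chosen, h$edges, cost)
  new_reduct(chosen, cost, h$edges)
}

# drop redundant members, highest cost first, while the set still hits all
# edges; the result is a minimal hitting set
prune_cover <- function(chosen, edges, cost) {
  hits_all <- function(s) all(map_lgl(edges, function(e) any(e %in% s)))
  for (v in chosen[order(-cost[chosen])]) {
    cand <- setdiff(chosen, v)
    if (length(cand) > 0L && hits_all(cand)) chosen <- cand
  }
  chosen
}

new_reduct <- function(ids, cost, edges) {
  hits_all <- function(s) all(map_lgl(edges, function(e) any(e %in% s)))
  minimal <- all(map_lgl(ids, function(v) !hits_all(setdiff(ids, v)))) ||
    length(ids) == 1L
  structure(list(covering_ids = ids,
                 total_cost = sum(cost[ids]),
                 minimal = minimal),
            class = "reduct")
}

#' @export
print.reduct <- function(x, ...) {
  cat(sprintf("<reduct> {%s}, total cost %.4g%s%s\n",
              paste(x$covering_ids, collapse = ", "), x$total_cost,
              if (isTRUE(x$minimal)) ", minimal" else "",
              if (!is.null(x$pos_preserved))
                sprintf(", positive region %s",
                        if (x$pos_preserved) "preserved" else "NOT preserved")
              else ""))
  invisible(x)
}

#' @export
tidy.reduct <- function(x, ...) {
  tibble(covering_id = x$covering_ids, total_cost = x$total_cost,
         minimal = x$minimal,
         pos_preserved = x$pos_preserved %||% NA)
}

#' Cost-aware attribute reduction of a covering decision table
#'
#' The full A-DRE reduction pipeline: compute the related family, transform
#' it into a hypergraph whose vertices carry attribute costs, run the greedy
#' minimum-cost vertex cover, and prune the cover to a minimal hitting set.
#' Positive-region preservation against the full covering family is
#' verified and reported in the result.
#'
#' @param table A [covering_table()].
#' @param costs Optional named cost vector overriding the coverings' own
#'   costs.
#' @return A `reduct` with the extra field `pos_preserved`.
#' @examples
#' tab <- worked_example_table()
#' adre_reduce(tab)
#' @export
adre_reduce <- function(table, costs = NULL) {
  stopifnot(inherits(table, "covering_table"))
  fam <- related_family(table)
  if (length(fam$family) == 0L) {
    abort(paste("The table is inconsistent (empty related family);",
                "no reduct exists."))
  }
  own_costs <- map_dbl(table$coverings, "cost")
  if (!is.null(costs)) own_costs[names(costs)] <- unlist(costs)
  h <- build_hypergraph(fam, own_costs)
  red <- greedy_min_cost_cover(h)
  red$pos_preserved <- setequal(
    positive_region_set(table, red$covering_ids),
    positive_region_set(table, names(table$coverings)))
  red$uncovered_objects <- fam$uncovered
  red
}

#' Extract ordered decision rules from a reduct
#'
#' One rule per effective block of each covering in the reduct. Support is
#' the fraction of the universe the antecedent matches; coverage the
#' fraction of the consequent class it matches. Rules are ranked by
#' coverage, then support (both descending), then covering cost (ascending),
#' then serialisation order, so classification by the first matching rule
#' favours the most influential rules. The default label is the majority
#' decision class.
#'
#' @param table A [covering_table()].
#' @param reduct A `reduct` or a character vector of covering ids.
#' @return A tibble of class `rule_list`: columns `rank`, `covering_id`,
#'   `block_index`, `block` (list-column), `decision_label`, `support`,
#'   `coverage`; attribute `default_label`.
#' @export
extract_rules <- function(table, reduct) {
  stopifnot(inherits(table, "covering_table"))
  ids <- if (inherits(reduct, "reduct")) reduct$covering_ids
         else as.character(reduct)
  if (length(ids) == 0L) abort("The reduct is empty; no rules to extract.")
  absent <- setdiff(ids, names(table$coverings))
  if (length(absent)) {
    abort(sprintf("Reduct coverings absent from the table: %s.",
                  paste(absent, collapse = ", ")))
  }
  eff <- effective_blocks(table)
  eff <- eff[eff$covering_id %in% ids, , drop = FALSE]
  n_u <- length(table$objects)
  class_sizes <- lengths(table$decision)
  cost <- map_dbl(table$coverings, "cost")
  rules <- eff |>
    mutate(support = lengths(.data$block) / n_u,
           coverage = lengths(.data$block) /
             unname(class_sizes[.data$decision_label]),
           cost = unname(cost[.data$covering_id]),
           key = map_chr(.data$block, paste, collapse = ",")) |>
    arrange(desc(.data$coverage), desc(.data$support), .data$cost,
            .data$key) |>
    mutate(rank = row_number()) |>
    select("rank", "covering_id", "block_index", "block", "decision_label",
           "support", "coverage")
  default_label <- names(which.max(lengths(table$decision)))
  structure(rules, default_label = default_label,
            class = c("rule_list", class(rules)))
}

#' Classify a record with an ordered rule list
#'
#' A record maps covering ids to block indices (which block of each covering
#' the observation falls in). The first rule, in rank order, whose covering
#' and block index the record reproduces supplies the label; when no rule
#' matches (including partial records), the rule list's default label is
#' returned. Matching the highest-ranked rule only avoids class conflicts
#' between overlapping rules.
#'
#' @param rules A [extract_rules()] result.
#' @param record Named list or vector mapping covering ids to block indices.
#' @return A single decision label.
#' @export
classify <- function(rules, record) {
  stopifnot(inherits(rules, "rule_list"))
  record <- unlist(record)
  for (i in seq_len(nrow(rules))) {
    cid <- rules$covering_id[i]
    if (cid %in% names(record) &&
        identical(as.integer(record[[cid]]),
                  as.integer(rules$block_index[i]))) {
      return(rules$decision_label[i])
    }
  }
  attr(rules, "default_label")
}

#' Cross-validated accuracy of the reduce-and-rule pipeline
#'
#' Stratified k-fold cross-validation of `adre_reduce()` +
#' `extract_rules()` + first-match classification. Within each fold the
#' table is restricted to the training objects, a reduct and rule list are
#' learned there, and each held-out object is classified by the first rule
#' whose originating block (in the full table) contains it. Deterministic
#' under `seed`.
#'
#' @param table A [covering_table()].
#' @param folds Number of folds (>= 2), default 5.
#' @param seed Integer seed fixing the fold assignment.
#' @return A single accuracy fraction in `[0, 1]`.
#' @export
evaluate_rules <- function(table, folds = 5, seed = 1) {
  stopifnot(inherits(table, "covering_table"))
  if (folds < 2) abort("`folds` must be at least 2.")
  if (length(table$objects) < folds) {
    abort("Too few objects for the requested number of folds.")
  }
  fold_of <- local_seed(seed, {
    assignment <- setNames(integer(length(table$objects)), table$objects)
    for (cl in table$decision) {
      shuffled <- sample(cl)
      assignment[shuffled] <- rep_len(seq_len(folds), length(shuffled))
    }
    assignment
  })
  correct <- 0L
  for (k in seq_len(folds)) {
    test_objs <- names(fold_of)[fold_of == k]
    train_objs <- setdiff(table$objects, test_objs)
    if (length(test_objs) == 0L) next
    train <- table_subset(table, train_objs)
    fam <- related_family(train)
    if (length(fam$family) == 0L) next  # fold unlearnable; counts as misses
    red <- adre_reduce(train)
    rules <- extract_rules(train, red)
    # map restricted block indices back to full-table blocks
    origin <- map(train$coverings, attr, "origin")
    default_label <- attr(rules, "default_label")
    for (x in test_objs) {
      pred <- default_label
      for (i in seq_len(nrow(rules))) {
        cid <- rules$covering_id[i]
        orig_idx <- origin[[cid]][rules$block_index[i]]
        if (x %in% table$coverings[[cid]]$blocks[[orig_idx]]) {
          pred <- rules$decision_label[i]
          break
        }
      }
      truth <- decision_label_of(table$decision, x)
      if (identical(pred, truth)) correct <- correct + 1L
    }
  }
  correct / length(table$objects)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
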