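# JSON / CSV / YAML readers and writers. JSON is the canonical interchange
# format; outputs are UTF-8, key-stable and newline-terminated so repeated
# runs diff cleanly.

#' Read a covering decision table from JSON
#'
#' Expects the canonical schema
#' `{"objects": [...], "coverings": [{"id", "cost", "blocks": [[...]]}],
#' "decision": {"label": [objects]}}` and validates all covering-table
#' invariants, naming any objects a covering fails to cover.
#'
#' @param path Path to a JSON file.
#' @return A [covering_table()].
#' @export
read_covering_table <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("objects", "coverings", "decision")) {
    if (is.null(x[[field]])) {
      abort(sprintf("Covering-table JSON lacks '%s'.", field))
    }
  }
  coverings <- map(x$coverings, function(cv) {
    covering(cv$id, map(cv$blocks, unlist), cost = cv$cost %||% 1)
  })
  covering_table(unlist(x$objects), coverings,
                 decision_partition(map(x$decision, unlist)))
}

#' Write a covering decision table to JSON
#'
#' @param table A [covering_table()].
#' @param path Output path (or connection).
#' @return `path`, invisibly.
#' @export
write_covering_table <- function(table, path) {
  stopifnot(inherits(table, "covering_table"))
  x <- list(
    objects = table$objects,
    coverings = map(unname(table$coverings), function(cv) {
      list(id = cv$id, cost = cv$cost, blocks = cv$blocks)
    }),
    decision = map(unclass(table$decision), identity)
  )
  write_stable_json(x, path)
}

#' Read a grey evaluation matrix from JSON
#'
#' Expects `{"schemes": [...], "criteria": [{"id", "type", "weight"}],
#' "frames": [...], "values": scheme -> criterion -> frame -> entry,
#' "reference": {...}, "probabilities": optional criterion -> frame -> p}`
#' where each entry is a number, a `[lo, hi]` pair, or one/two linguistic
#' terms.
#'
#' @param path Path to a JSON file.
#' @return A list with `values`, `criteria`, `reference` and (optionally)
#'   `probabilities`, as accepted by [cumulative_prospect()].
#' @export
read_evaluation <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("schemes", "criteria", "frames", "values", "reference")) {
    if (is.null(x[[field]])) {
      abort(sprintf("Evaluation JSON lacks '%s'.", field))
    }
  }
  schemes <- unlist(x$schemes)
  frames <- unlist(x$frames)
  criteria <- bind_rows(map(x$criteria, function(cr) {
    tibble(criterion = cr$id, type = cr$type, weight = cr$weight)
  }))
  values <- bind_rows(map(schemes, function(s) {
    bind_rows(map(criteria$criterion, function(cj) {
      bind_rows(map(frames, function(f) {
        v <- x$values[[s]][[cj]][[f]]
        if (is.null(v)) {
          abort(sprintf("Missing value for %s/%s/%s.", s, cj, f))
        }
        v <- unlist(v)
        if (is.numeric(v)) v <- as.numeric(v)
        tibble(scheme = s, criterion = cj, frame = f, value = list(v))
      }))
    }))
  }))
  probabilities <- NULL
  if (!is.null(x$probabilities)) {
    probabilities <- bind_rows(imap(x$probabilities, function(pf, cj) {
      tibble(criterion = cj, frame = names(pf),
             p = as.numeric(unlist(pf)))
    }))
  }
  reference <- map(x$reference, function(v) {
    v <- unlist(v)
    if (is.numeric(v)) as.numeric(v) else v
  })
  list(values = values, criteria = criteria, reference = reference,
       probabilities = probabilities)
}

#' Write a grey evaluation matrix to JSON
#'
#' @param eval_case A list with `values`, `criteria`, `reference` and
#'   optionally `probabilities` (as produced by [covid_case_matrix()] or
#'   [synth_evaluation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(eval_case, path) {
  values <- eval_case$values
  schemes <- unique(values$scheme)
  frames <- unique(values$frame)
  crits <- eval_case$criteria$criterion
  vals <- setNames(map(schemes, function(s) {
    setNames(map(crits, function(cj) {
      setNames(map(frames, function(f) {
        v <- values$value[values$scheme == s & values$criterion == cj &
                            values$frame == f]
        if (length(v) != 1L) {
          abort(sprintf("Expected one entry for %s/%s/%s.", s, cj, f))
        }
        v[[1]]
      }), frames)
    }), crits)
  }), schemes)
  x <- list(
    schemes = schemes,
    criteria = map(seq_len(nrow(eval_case$criteria)), function(i) {
      list(id = eval_case$criteria$criterion[i],
           type = eval_case$criteria$type[i],
           weight = eval_case$criteria$weight[i])
    }),
    frames = frames,
    values = vals,
    reference = eval_case$reference
  )
  if (!is.null(eval_case$probabilities)) {
    pr <- eval_case$probabilities
    x$probabilities <- setNames(map(crits, function(cj) {
      rows <- pr[pr$criterion == cj, ]
      setNames(as.list(rows$p), rows$frame)
    }), crits)
  }
  write_stable_json(x, path)
}

# canonical JSON writer: unboxed scalars, full IEEE round-trip precision
# (17 significant digits), trailing newline
write_stable_json <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `prospect` (alpha, beta, lambda, chi, delta), `scale`
#' (`terms`, `lo`, `hi`), `delta` (granulation width, scalar or per
#' attribute), `costs`, `folds`, `seed`, `log_level`. Missing keys fall
#' back to package defaults; present ones are validated on load.
#'
#' @param path Path to a YAML file (or `NULL` for all defaults).
#' @return A list with validated components `params`, `scale`, `delta`,
#'   `costs`, `folds`, `seed`, `log_level`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  params <- do.call(prospect_params, cfg$prospect %||% list())
  scale <- if (is.null(cfg$scale)) linguistic_scale() else {
    linguistic_scale(terms = unlist(cfg$scale$terms),
                     lo = unlist(cfg$scale$lo),
                     hi = unlist(cfg$scale$hi))
  }
  list(params = params, scale = scale,
       delta = cfg$delta %||% 0.15,
       costs = if (is.null(cfg$costs)) NULL else unlist(cfg$costs),
       folds = cfg$folds %||% 5,
       seed = cfg$seed %||% 1,
       log_level = cfg$log_level %||% "info")
}

#' Load a covering decision table from JSON or CSV
#'
#' JSON files must follow the canonical covering-table schema; CSV files
#' are raw attribute-value tables, granulated column-wise per the run
#' configuration.
#'
#' @param path Input file.
#' @param format `"json"` or `"csv"` (default guessed from the extension).
#' @param decision Decision column name (CSV only).
#' @param config A [read_run_config()] result supplying granulation width
#'   and costs.
#' @return A [covering_table()].
#' @export
load_table <- function(path, format = NULL, decision = "decision",
                       config = read_run_config()) {
  format <- format %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json")
  if (format == "json") return(read_covering_table(path))
  data <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  granulate_table(data, decision = decision, delta = config$delta,
                  costs = config$costs)
}
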