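#' @title Built-in list-learning experiment designs
#'
#' @description
#' Each design encodes one condition of one of the four 36-item list-learning
#' experiments: the boundary schedule (list positions at which the frame
#' colour updates, i.e. the first item of each new event) and the probe-pair
#' table used for recency judgments. Positions are 1-based; position 1 starts
#' the list and is never a boundary. A pair "straddles" a boundary when the
#' boundary position lies in `(pos_early, pos_late]`.
#'
#' @name experiment-designs
NULL

probe_tbl <- function(pairs, pair_type) {
  tibble::tibble(
    pos_early = vapply(pairs, `[`, numeric(1), 1L),
    pos_late = vapply(pairs, `[`, numeric(1), 2L),
    pair_type = pair_type
  )
}

#' Construct an experiment design
#'
#' @param name Design label.
#' @param n_items List length (36 in all built-in designs).
#' @param boundaries Integer vector of boundary positions (possibly empty).
#' @param probes Tibble with columns `pos_early`, `pos_late`, `pair_type`.
#' @param experiment Experiment id (1-4, or `NA` for ad-hoc designs).
#' @param condition Condition label.
#' @return An object of class `tom_design`.
#' @export
experiment_design <- function(name, n_items, boundaries, probes,
                              experiment = NA_integer_, condition = name) {
  n_items <- as.integer(n_items)
  if (length(n_items) != 1L || is.na(n_items) || n_items < 1L) {
    stop("`n_items` must be a single integer >= 1", call. = FALSE)
  }
  boundaries <- sort(unique(as.integer(boundaries)))
  probes <- tibble::as_tibble(probes)
  required <- c("pos_early", "pos_late", "pair_type")
  missing <- setdiff(required, names(probes))
  if (length(missing) > 0L) {
    stop("`probes` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  probes$pos_early <- as.integer(probes$pos_early)
  probes$pos_late <- as.integer(probes$pos_late)
  probes$pair_type <- as.character(probes$pair_type)
  experiment <- if (length(experiment) != 1L || is.na(experiment) ||
                      identical(experiment, "NA")) {
    NA_integer_
  } else {
    as.integer(experiment)
  }
  structure(
    list(name = name, experiment = experiment,
         condition = condition, n_items = n_items,
         boundaries = boundaries, probes = probes[, required]),
    class = "tom_design"
  )
}

#' @export
print.tom_design <- function(x, ...) {
  cat(sprintf("<tom_design> %s (experiment %s, condition %s)\n", x$name,
              x$experiment, x$condition))
  cat(sprintf("  %d items, boundaries at: %s\n", x$n_items,
              if (length(x$boundaries) == 0) "(none)"
              else paste(x$boundaries, collapse = ", ")))
  counts <- table(x$probes$pair_type)
  cat("  probes:", paste(sprintf("%s (%d)", names(counts), counts),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Canonical designs of the four experiments
#'
#' Returns the built-in design for one condition of one experiment:
#'
#' * Experiment 1 (`"boundary"`, `"no_boundary"`): frame colour changes every
#'   6 items (boundaries 7, 13, 19, 25, 31) or never. Six within-event pairs
#'   at local positions 2-4 of each event and five across-event pairs
#'   spanning one boundary with one intervening item; the no-boundary
#'   condition probes the identical list positions.
#' * Experiment 2 (`"standard"`): 4-item events (boundaries 5, 9, ..., 33).
#'   Nine within-event lag-1 pairs (local 2-4), four across-event lag-1 pairs
#'   (items 3'-1) and four across-event lag-3 pairs (items 3'-3), assigned to
#'   alternating boundaries.
#' * Experiment 3 (`"event4"`, `"event6"`): 4- vs 6-item events. Pair type 1:
#'   within pairs at identical list and local (2-4) positions in both
#'   conditions. Pair type 2: identical list positions, local 2-4 in event4
#'   vs 4-6 in event6. Pair type 3: four across pairs per condition, chosen
#'   item-disjoint and matched for mean list position (19 in both).
#' * Experiment 4 (`"schedule_336"`, `"schedule_633"`): event lengths
#'   3-3-6... vs 6-3-3... Within pairs at local 1-3 of 3-item events (early)
#'   vs local 4-6 of 6-item events (late), at absolute positions that swap
#'   roles between the two schedules; short-lag across pairs at the five
#'   boundary positions shared by both schedules, split into earlier/later
#'   local positions; and five longer-lag across pairs per schedule.
#'
#' @param experiment Experiment id in 1-4.
#' @param condition Condition label (case-insensitive; spaces/underscores
#'   ignored, so `"Event 4"` and `"event4"` are equivalent).
#' @return A `tom_design`.
#' @export
#' @examples
#' builtin_design(3, "Event4")
builtin_design <- function(experiment, condition) {
  experiment <- as.integer(experiment)
  key <- gsub("[^a-z0-9]", "", tolower(condition))
  pick <- function(choices) {
    if (!key %in% names(choices)) {
      stop(sprintf("unknown condition \"%s\" for experiment %d (available: %s)",
                   condition, experiment,
                   paste(names(choices), collapse = ", ")), call. = FALSE)
    }
    choices[[key]]
  }
  if (is.na(experiment) || !experiment %in% 1:4) {
    stop("`experiment` must be 1, 2, 3 or 4", call. = FALSE)
  }
  switch(
    as.character(experiment),
    "1" = {
      cond <- pick(c(boundary = "boundary", noboundary = "no_boundary"))
      probes <- dplyr::bind_rows(
        probe_tbl(list(c(2, 4), c(8, 10), c(14, 16), c(20, 22), c(26, 28),
                       c(32, 34)), "within"),
        probe_tbl(list(c(5, 7), c(11, 13), c(17, 19), c(23, 25), c(29, 31)),
                  "across")
      )
      experiment_design(
        name = paste0("exp1_", cond), n_items = 36,
        boundaries = if (cond == "boundary") seq(7, 31, by = 6) else integer(0),
        probes = probes, experiment = 1, condition = cond)
    },
    "2" = {
      cond <- pick(c(standard = "standard"))
      probes <- dplyr::bind_rows(
        probe_tbl(lapply(1:9, function(k) c(4 * k - 2, 4 * k)), "within_lag1"),
        probe_tbl(lapply(c(1, 3, 5, 7), function(k) c(4 * k - 1, 4 * k + 1)),
                  "across_lag1"),
        probe_tbl(lapply(c(2, 4, 6, 8), function(k) c(4 * k - 1, 4 * k + 3)),
                  "across_lag3")
      )
      experiment_design(
        name = "exp2_standard", n_items = 36,
        boundaries = seq(5, 33, by = 4), probes = probes,
        experiment = 2, condition = cond)
    },
    "3" = {
      cond <- pick(c(event4 = "event4", event6 = "event6"))
      shared <- dplyr::bind_rows(
        probe_tbl(list(c(2, 4), c(14, 16), c(26, 28)), "pairtype1"),
        probe_tbl(list(c(10, 12), c(22, 24), c(34, 36)), "pairtype2")
      )
      across <- if (cond == "event4") {
        probe_tbl(list(c(3, 7), c(11, 15), c(23, 27), c(31, 35)), "pairtype3")
      } else {
        probe_tbl(list(c(5, 9), c(11, 15), c(23, 27), c(29, 33)), "pairtype3")
      }
      experiment_design(
        name = paste0("exp3_", cond), n_items = 36,
        boundaries = if (cond == "event4") seq(5, 33, by = 4)
                     else seq(7, 31, by = 6),
        probes = dplyr::bind_rows(shared, across),
        experiment = 3, condition = cond)
    },
    "4" = {
      cond <- pick(c(schedule336 = "schedule_336", schedule633 = "schedule_633",
                     "336336336" = "schedule_336", "633633633" = "schedule_633"))
      early_at <- list(c(4, 6), c(16, 18), c(28, 30))
      late_at <- list(c(10, 12), c(22, 24), c(34, 36))
      if (cond == "schedule_336") {
        boundaries <- c(4, 7, 13, 16, 19, 25, 28, 31)
        within_early <- early_at
        within_late <- late_at
        across_early <- list(c(5, 7), c(17, 19), c(29, 31))
        across_late <- list(c(11, 13), c(23, 25))
        across_long <- list(c(1, 6), c(8, 14), c(9, 15), c(20, 26), c(21, 27))
      } else {
        boundaries <- c(7, 10, 13, 19, 22, 25, 31, 34)
        within_early <- late_at
        within_late <- early_at
        across_early <- list(c(11, 13), c(23, 25))
        across_late <- list(c(5, 7), c(17, 19), c(29, 31))
        across_long <- list(c(3, 8), c(14, 20), c(15, 21), c(26, 32), c(27, 33))
      }
      probes <- dplyr::bind_rows(
        probe_tbl(within_early, "within_early"),
        probe_tbl(within_late, "within_late"),
        probe_tbl(across_early, "across_early"),
        probe_tbl(across_late, "across_late"),
        probe_tbl(across_long, "across_long")
      )
      experiment_design(
        name = paste0("exp4_", cond), n_items = 36, boundaries = boundaries,
        probes = probes, experiment = 4, condition = cond)
    }
  )
}

#' All built-in designs
#'
#' @return A named list of the seven `tom_design` objects covering every
#'   condition of the four experiments.
#' @export
builtin_designs <- function() {
  specs <- list(c(1, "boundary"), c(1, "no_boundary"), c(2, "standard"),
                c(3, "event4"), c(3, "event6"),
                c(4, "schedule_336"), c(4, "schedule_633"))
  out <- lapply(specs, function(s) builtin_design(as.integer(s[1]), s[2]))
  names(out) <- vapply(out, function(d) d$name, character(1))
  out
}

n_straddled <- function(design, pos_early, pos_late) {
  vapply(seq_along(pos_early), function(i) {
    sum(design$boundaries > pos_early[i] & design$boundaries <= pos_late[i])
  }, numeric(1))
}

is_within_type <- function(pair_type) {
  grepl("^within", pair_type) | pair_type %in% c("pairtype1", "pairtype2")
}

#' Validate an experiment design
#'
#' Checks position bounds, boundary bounds, the straddle rules (within-type
#' pairs never cross a boundary; across-type pairs cross exactly one — the
#' latter only in designs that have boundaries, since a no-boundary baseline
#' keeps the position-matched labels of its boundary counterpart), and
#' item-disjointness of the probe pairs within each pair type. Cross-type
#' item sharing — which the published short-event designs cannot avoid at
#' their printed pair counts — is reported only under `strict = TRUE`.
#'
#' @param design A `tom_design`.
#' @param strict Also report items shared between different pair types.
#' @return Character vector of violations; empty when the design is valid.
#' @export
#' @examples
#' validate_design(builtin_design(1, "boundary"))
validate_design <- function(design, strict = FALSE) {
  stopifnot(inherits(design, "tom_design"))
  v <- character(0)
  p <- design$probes
  n_t <- design$n_items
  bad_bounds <- which(!(p$pos_early >= 1 & p$pos_early < p$pos_late &
                          p$pos_late <= n_t))
  for (i in bad_bounds) {
    v <- c(v, sprintf("probe %d: positions (%d, %d) violate 1 <= early < late <= %d",
                      i, p$pos_early[i], p$pos_late[i], n_t))
  }
  bad_b <- design$boundaries[design$boundaries < 2 | design$boundaries > n_t]
  for (b in bad_b) {
    v <- c(v, sprintf("boundary position %d outside 2..%d", b, n_t))
  }
  ok <- setdiff(seq_len(nrow(p)), bad_bounds)
  if (length(ok) > 0L) {
    ns <- n_straddled(design, p$pos_early[ok], p$pos_late[ok])
    within <- is_within_type(p$pair_type[ok])
    for (j in seq_along(ok)) {
      i <- ok[j]
      if (within[j] && ns[j] != 0) {
        v <- c(v, sprintf("within-type probe (%d, %d, %s) straddles %d boundary(ies)",
                          p$pos_early[i], p$pos_late[i], p$pair_type[i], ns[j]))
      }
      if (!within[j] && length(design$boundaries) > 0L && ns[j] != 1) {
        v <- c(v, sprintf("across-type probe (%d, %d, %s) straddles %d boundary(ies), expected 1",
                          p$pos_early[i], p$pos_late[i], p$pair_type[i], ns[j]))
      }
    }
  }
  for (tp in unique(p$pair_type)) {
    items <- c(p$pos_early[p$pair_type == tp], p$pos_late[p$pair_type == tp])
    dup <- unique(items[duplicated(items)])
    for (d in dup) {
      v <- c(v, sprintf("item %d probed more than once within pair type %s", d, tp))
    }
  }
  if (strict) {
    by_type <- split(c(p$pos_early, p$pos_late), rep(p$pair_type, 2L))
    types <- names(by_type)
    if (length(types) > 1L) {
      for (i in seq_len(length(types) - 1L)) {
        for (j in (i + 1L):length(types)) {
          shared <- intersect(by_type[[i]], by_type[[j]])
          for (s in shared) {
            v <- c(v, sprintf("item %d shared between pair types %s and %s",
                              s, types[i], types[j]))
          }
        }
      }
    }
  }
  v
}

#' Read / write a design as JSON
#'
#' The on-disk schema is `{name, experiment, condition, n_items,
#' boundary_positions, probes: [{pos_early, pos_late, pair_type}]}`. Reading
#' re-checks the schema and the design invariants and fails naming the
#' offending field.
#'
#' @param path File path.
#' @return `read_design()` returns a `tom_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
read_design <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (field in c("name", "n_items", "boundary_positions", "probes")) {
    if (is.null(obj[[field]])) {
      stop(sprintf("design file %s: missing field `%s`", path, field),
           call. = FALSE)
    }
  }
  probes <- tibble::as_tibble(obj$probes)
  for (col in c("pos_early", "pos_late", "pair_type")) {
    if (is.null(probes[[col]])) {
      stop(sprintf("design file %s: probes missing column `%s`", path, col),
           call. = FALSE)
    }
  }
  design <- experiment_design(
    name = obj$name, n_items = obj$n_items,
    boundaries = obj$boundary_positions, probes = probes,
    experiment = if (is.null(obj$experiment)) NA_integer_ else obj$experiment,
    condition = if (is.null(obj$condition)) obj$name else obj$condition)
  v <- validate_design(design)
  bad <- grep("violate|outside", v, value = TRUE)
  if (length(bad) > 0L) {
    stop(sprintf("design file %s is invalid: %s", path,
                 paste(bad, collapse = "; ")), call. = FALSE)
  }
  design
}

#' @rdname read_design
#' @param design A `tom_design` to serialize.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "tom_design"))
  obj <- list(
    name = design$name,
    experiment = if (is.na(design$experiment)) NULL else design$experiment,
    condition = design$condition, n_items = design$n_items,
    boundary_positions = design$boundaries,
    probes = design$probes
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
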