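#' @title Recency-judgment predictions from context trajectories
#'
#' @description
#' To judge which of two probed items came later, the model reinstates each
#' item's learning context and compares it to a reference context — by
#' default the first context of the list. With `R1`/`R2` the Dice
#' similarities of the earlier/later item's context to the reference and
#' `d = 1 - R` the dissimilarities, the memory index is
#' `MI = d2 - d1`. A positive MI means the later item's context is more
#' dissimilar to the first context, i.e. the model orders the pair correctly;
#' its magnitude is the accuracy proxy. MI is kept continuous (it is never
#' thresholded into simulated choices) and no sequential scanning stage is
#' modelled.
#'
#' @name memory-model
NULL

# dissimilarity of every trajectory row to a reference row
dissim_to_ref <- function(contexts, ref_row) {
  ref <- contexts[ref_row, ]
  n_ref <- sum(ref)
  active <- rowSums(contexts)
  if (n_ref == 0 || any(active + n_ref == 0)) {
    stop("all-zero context encountered; Dice similarity undefined",
         call. = FALSE)
  }
  1 - 2 * as.vector(contexts %*% ref) / (active + n_ref)
}

#' Memory index of one probe pair on one trajectory
#'
#' @param traj A `context_trajectory`.
#' @param pair A one-row data frame (or list) with `pos_early` and `pos_late`.
#' @param reference `"first"` (default) or `"last"`: which context row serves
#'   as the strategic reference point.
#' @return A one-row tibble with `R1`, `R2`, `d1`, `d2` and `MI` (arbitrary
#'   units).
#' @export
#' @examples
#' set.seed(1)
#' traj <- simulate_trajectory(builtin_design(1, "boundary"), model_params())
#' memory_index(traj, list(pos_early = 5, pos_late = 7))
memory_index <- function(traj, pair, reference = c("first", "last")) {
  stopifnot(inherits(traj, "context_trajectory"))
  reference <- match.arg(reference)
  n_t <- nrow(traj$contexts)
  pos_early <- as.integer(pair$pos_early)
  pos_late <- as.integer(pair$pos_late)
  if (pos_early < 1L || pos_late < 1L || pos_early > n_t || pos_late > n_t) {
    stop("probe positions outside the trajectory", call. = FALSE)
  }
  ref_row <- if (reference == "first") 1L else n_t
  d <- dissim_to_ref(traj$contexts, ref_row)
  tibble::tibble(
    pos_early = pos_early, pos_late = pos_late,
    R1 = 1 - d[pos_early], R2 = 1 - d[pos_late],
    d1 = d[pos_early], d2 = d[pos_late],
    MI = d[pos_late] - d[pos_early]
  )
}

new_mi_table <- function(summary, iterations, params, reference, metric = "mi") {
  structure(
    list(summary = summary, iterations = iterations, params = params,
         reference = reference, metric = metric),
    class = "mi_table"
  )
}

#' @export
print.mi_table <- function(x, ...) {
  cat(sprintf("<mi_table> metric = %s, reference = %s, n_iter = %d\n",
              x$metric, x$reference, x$summary$n_iter[1]))
  print(x$summary)
  invisible(x)
}

summarize_iterations <- function(iters) {
  out <- dplyr::summarise(
    dplyr::group_by(iters, .data$experiment, .data$condition, .data$pair_type),
    mean_mi = mean(.data$mi),
    se_mi = stats::sd(.data$mi) / sqrt(dplyr::n()),
    n_iter = dplyr::n(),
    .groups = "drop"
  )
  out
}

simulate_condition_impl <- function(design, params, reference, seed,
                                    step_fun, metric) {
  if (!is.null(seed)) set.seed(seed)
  p <- design$probes
  types <- sort(unique(p$pair_type))
  per_iter <- matrix(NA_real_, nrow = params$n_iter, ncol = length(types),
                     dimnames = list(NULL, types))
  ref_row <- if (reference == "first") 1L else design$n_items
  for (i in seq_len(params$n_iter)) {
    traj <- step_fun()
    if (metric == "mi") {
      d <- dissim_to_ref(traj$contexts, ref_row)
      mi <- d[p$pos_late] - d[p$pos_early]
    } else {
      mi <- vapply(seq_len(nrow(p)), function(j) {
        .dice(traj$contexts[p$pos_early[j], ], traj$contexts[p$pos_late[j], ])
      }, numeric(1))
    }
    per_iter[i, ] <- vapply(types, function(tp) mean(mi[p$pair_type == tp]),
                            numeric(1))
  }
  iters <- tibble::tibble(
    experiment = design$experiment,
    condition = design$condition,
    pair_type = rep(types, each = params$n_iter),
    iter = rep(seq_len(params$n_iter), times = length(types)),
    mi = as.vector(per_iter)
  )
  new_mi_table(summarize_iterations(iters), iters, params, reference, metric)
}

#' Simulate a condition and summarize the memory index per pair type
#'
#' Runs `params$n_iter` independent context trajectories over the design; on
#' each iteration the MI of every probe pair is computed and pairs of the
#' same type are averaged. The summary reports the mean and Monte-Carlo
#' standard error of these per-iteration type means, and the per-iteration
#' values are kept for paired contrasts downstream.
#'
#' @param design A [experiment_design()] object.
#' @param params A [model_params()] object.
#' @param reference `"first"` or `"last"` reference context.
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return An object of class `mi_table` with elements `summary`
#'   (experiment, condition, pair_type, mean_mi, se_mi, n_iter) and
#'   `iterations` (per-iteration type means).
#' @export
simulate_condition <- function(design, params = model_params(),
                               reference = c("first", "last"), seed = NULL) {
  stopifnot(inherits(design, "tom_design"), inherits(params, "tcr_params"))
  reference <- match.arg(reference)
  simulate_condition_impl(
    design, params, reference, seed,
    step_fun = function() simulate_trajectory(design, params),
    metric = "mi")
}

#' Simulate a condition under the random-shift alternative model
#'
#' The trajectory drifts at `alt$p_base` off boundaries and at
#' `alt$p_boundary` on boundary steps, with no reinstatement. The metric is
#' either this package's memory index (`"mi"`) or the contextual similarity
#' of the two probed items themselves (`"pair_similarity"`), the quantity the
#' random-shift account uses as its accuracy index.
#'
#' @param design A [experiment_design()] object.
#' @param alt An [alt_params()] object.
#' @param params A [model_params()] object (feature count, iterations).
#' @param metric `"pair_similarity"` or `"mi"`.
#' @param reference Reference context for the `"mi"` metric.
#' @param seed Optional integer seed.
#' @return An `mi_table`; for `"pair_similarity"` the `mean_mi` column holds
#'   the mean pair similarity.
#' @export
simulate_alternative <- function(design, alt = alt_params(),
                                 params = model_params(),
                                 metric = c("pair_similarity", "mi"),
                                 reference = c("first", "last"), seed = NULL) {
  stopifnot(inherits(design, "tom_design"), inherits(alt, "tcr_alt_params"))
  metric <- match.arg(metric)
  reference <- match.arg(reference)
  simulate_condition_impl(
    design, params, reference, seed,
    step_fun = function() simulate_trajectory_alt(design, alt, params),
    metric = metric)
}

#' Combine per-condition MI tables into one
#'
#' @param tables List of `mi_table` objects sharing parameters, reference and
#'   metric.
#' @return A single `mi_table`.
#' @export
bind_mi_tables <- function(tables) {
  new_mi_table(
    summary = dplyr::bind_rows(lapply(tables, `[[`, "summary")),
    iterations = dplyr::bind_rows(lapply(tables, `[[`, "iterations")),
    params = tables[[1]]$params,
    reference = tables[[1]]$reference,
    metric = tables[[1]]$metric
  )
}

#' Run the full four-experiment simulation suite
#'
#' Simulates every built-in condition with shared parameters and a single
#' master seed (conditions are run sequentially on one RNG stream, so the
#' whole table is deterministic given the seed).
#'
#' @param params A [model_params()] object.
#' @param reference `"first"` or `"last"` reference context.
#' @param seed Master seed (default 1).
#' @return An `mi_table` covering all experiments and conditions.
#' @export
#' @examples
#' \donttest{
#' suite <- run_experiment_suite(model_params(p = 0.02, lam = 0.2,
#'                                            n_iter = 200), seed = 1)
#' suite$summary
#' }
run_experiment_suite <- function(params = model_params(),
                                 reference = c("first", "last"), seed = 1L) {
  reference <- match.arg(reference)
  if (!is.null(seed)) set.seed(seed)
  tables <- lapply(builtin_designs(), simulate_condition,
                   params = params, reference = reference, seed = NULL)
  bind_mi_tables(tables)
}
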