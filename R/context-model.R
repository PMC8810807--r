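#' @title Binary temporal-context dynamics
#'
#' @description
#' The temporal context is a vector of binary elements. Between items it
#' drifts: each element flips state (active to inactive or back) with
#' probability `p`. At an event boundary it resets: a proportion `lam` of the
#' elements is copied back from the very first context of the list, while the
#' remaining elements drift as usual. Because flips are symmetric Bernoulli
#' events, this per-element stochastic rule is the binary-valued realization
#' of the convex-combination update
#' `C_t = (1 - lam) * ((1 - p) * C_{t-1} + p * C_IN) + lam * C_1`,
#' which keeps every context strictly 0/1 so that Dice similarity stays
#' well defined.
#'
#' Sampling order inside [reset_context()] is fixed: the flip mask is drawn
#' first, the copy mask second. With `lam = 0` the copy mask selects nothing,
#' so a reset step reproduces [drift_context()] exactly under the same seed.
#'
#' @name context-model
NULL

check_context <- function(x, name = "context") {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary (0/1) vector", name), call. = FALSE)
  }
  invisible(x)
}

#' Draw an initial context vector
#'
#' Elements are independent Bernoulli draws with the configured activation
#' density (default 0.5). The distribution of the first context is a free
#' modelling choice; all downstream quantities are similarities, which are
#' insensitive to relabelling active/inactive for symmetric densities.
#'
#' @param params A [model_params()] object.
#' @return Integer vector of 0/1 of length `params$n_features`.
#' @export
#' @examples
#' set.seed(1)
#' c1 <- init_context(model_params())
#' table(c1)
init_context <- function(params = model_params()) {
  stopifnot(inherits(params, "tcr_params"))
  as.integer(stats::runif(params$n_features) < params$init_density)
}

#' Drift a context vector one step
#'
#' Each element independently flips state with probability `p`, otherwise it
#' is copied unchanged.
#'
#' @param prev Binary context vector at the previous time point.
#' @param p Drift rate in `[0, 1]`.
#' @return Binary vector of the same length.
#' @export
drift_context <- function(prev, p) {
  check_context(prev, "prev")
  check_rate(p, "p")
  flip <- stats::runif(length(prev)) < p
  out <- as.integer(prev)
  out[flip] <- 1L - out[flip]
  out
}

#' Reset a context vector at an event boundary
#'
#' With probability `lam` an element is copied from the first context of the
#' list; otherwise it undergoes the ordinary drift update of `prev`. The flip
#' mask is drawn before the copy mask (see [context-model]).
#'
#' @param prev Binary context vector at the previous time point.
#' @param first Binary context vector of the first time point (`C_1`).
#' @param p Drift rate in `[0, 1]`.
#' @param lam Reset rate in `[0, 1]`.
#' @return Binary vector of the same length.
#' @export
reset_context <- function(prev, first, p, lam) {
  check_context(prev, "prev")
  check_context(first, "first")
  if (length(prev) != length(first)) {
    stop("`prev` and `first` must have the same length", call. = FALSE)
  }
  check_rate(p, "p")
  check_rate(lam, "lam")
  out <- drift_context(prev, p)
  copy <- stats::runif(length(prev)) < lam
  out[copy] <- as.integer(first)[copy]
  out
}

#' Simulate one context trajectory over a design's list
#'
#' Row 1 is a freshly drawn initial context. Each later row is a drift step,
#' except rows at the design's boundary positions, which are reset steps
#' against row 1. The boundary item itself carries the post-reset context;
#' position 1 is never a boundary.
#'
#' @param design A [experiment_design()] object (only its list length and
#'   boundary positions are used).
#' @param params A [model_params()] object.
#' @return An object of class `context_trajectory`: a list with `contexts`
#'   (T x F binary matrix) and `boundary_flags` (logical vector of length T).
#' @export
#' @examples
#' set.seed(1)
#' traj <- simulate_trajectory(builtin_design(1, "boundary"), model_params())
#' dim(traj$contexts)
simulate_trajectory <- function(design, params = model_params()) {
  stopifnot(inherits(design, "tom_design"), inherits(params, "tcr_params"))
  n_t <- design$n_items
  flags <- logical(n_t)
  flags[design$boundaries] <- TRUE
  contexts <- matrix(0L, nrow = n_t, ncol = params$n_features)
  contexts[1L, ] <- init_context(params)
  if (n_t > 1L) {
    for (t in 2:n_t) {
      contexts[t, ] <- if (flags[t]) {
        reset_context(contexts[t - 1L, ], contexts[1L, ], params$p, params$lam)
      } else {
        drift_context(contexts[t - 1L, ], params$p)
      }
    }
  }
  structure(list(contexts = contexts, boundary_flags = flags),
            class = "context_trajectory")
}

#' Simulate a trajectory under the random-shift alternative model
#'
#' Context drifts at `alt$p_base` on non-boundary steps and at the elevated
#' rate `alt$p_boundary` on boundary steps; nothing is reinstated.
#'
#' @param design A [experiment_design()] object.
#' @param alt An [alt_params()] object.
#' @param params A [model_params()] object (feature count and init density).
#' @return A `context_trajectory`.
#' @export
simulate_trajectory_alt <- function(design, alt = alt_params(),
                                    params = model_params()) {
  stopifnot(inherits(design, "tom_design"), inherits(alt, "tcr_alt_params"),
            inherits(params, "tcr_params"))
  n_t <- design$n_items
  flags <- logical(n_t)
  flags[design$boundaries] <- TRUE
  contexts <- matrix(0L, nrow = n_t, ncol = params$n_features)
  contexts[1L, ] <- init_context(params)
  if (n_t > 1L) {
    for (t in 2:n_t) {
      rate <- if (flags[t]) alt$p_boundary else alt$p_base
      contexts[t, ] <- drift_context(contexts[t - 1L, ], rate)
    }
  }
  structure(list(contexts = contexts, boundary_flags = flags),
            class = "context_trajectory")
}

#' @export
print.context_trajectory <- function(x, ...) {
  cat(sprintf("<context_trajectory> %d time points x %d features, %d boundaries\n",
              nrow(x$contexts), ncol(x$contexts), sum(x$boundary_flags)))
  invisible(x)
}

#' Dice similarity of two binary vectors
#'
#' `2 * |A intersect B| / (|A| + |B|)` over the active-element sets. Two
#' all-zero vectors have no active elements at all, which leaves the
#' coefficient undefined; that degenerate input raises an error rather than
#' silently returning 0.
#'
#' @param a,b Binary vectors of equal length.
#' @return A similarity in `[0, 1]`.
#' @export
#' @examples
#' dice_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0))
dice_similarity <- function(a, b) {
  check_context(a, "a")
  check_context(b, "b")
  if (length(a) != length(b)) {
    stop("`a` and `b` must have the same length", call. = FALSE)
  }
  .dice(as.integer(a), as.integer(b))
}

# fast path: assumes validated integer 0/1 input
.dice <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom == 0L) {
    stop("Dice similarity is undefined for two all-zero vectors", call. = FALSE)
  }
  2 * sum(a & b) / denom
}

#' Representational dissimilarity matrix of a trajectory
#'
#' Symmetric T x T matrix with entry `(i, j) = 1 - dice(C_i, C_j)` and zeros
#' on the diagonal.
#'
#' @param traj A `context_trajectory`.
#' @return A numeric T x T matrix.
#' @export
dissimilarity_matrix <- function(traj) {
  stopifnot(inherits(traj, "context_trajectory"))
  m <- traj$contexts
  n_t <- nrow(m)
  active <- rowSums(m)
  if (any(active == 0)) {
    stop("trajectory contains an all-zero context row; dissimilarity is undefined",
         call. = FALSE)
  }
  # 2 * (M M^T) / (|row i| + |row j|), elements being 0/1
  inter <- tcrossprod(m)
  denom <- outer(active, active, `+`)
  d <- 1 - 2 * inter / denom
  diag(d) <- 0
  d
}

#' Monte-Carlo average dissimilarity matrix for a design
#'
#' Averages [dissimilarity_matrix()] over `n_iter` independently simulated
#' trajectories; with boundaries present the average shows the within-event
#' block structure of the context code.
#'
#' @param design A [experiment_design()] object.
#' @param params A [model_params()] object (`n_iter` iterations are run).
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return A numeric T x T matrix.
#' @export
average_dissimilarity <- function(design, params = model_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- matrix(0, design$n_items, design$n_items)
  for (i in seq_len(params$n_iter)) {
    acc <- acc + dissimilarity_matrix(simulate_trajectory(design, params))
  }
  acc / params$n_iter
}
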