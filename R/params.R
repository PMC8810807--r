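#' Model parameters for the temporal-context signal
#'
#' Bundles the parameters of the binary context model: the number of binary
#' features, the drift rate `p` (per-step probability that an element flips
#' state), the reset rate `lam` (proportion of the first context reinstated at
#' an event boundary), and the number of Monte-Carlo iterations used when a
#' condition is simulated repeatedly.
#'
#' @param n_features Number of binary context features (default 100).
#' @param p Drift rate in `[0, 1]`: per-element flip probability at a
#'   non-boundary step.
#' @param lam Reset rate in `[0, 1]`: per-element probability of copying the
#'   first context at a boundary step.
#' @param n_iter Number of independently seeded model iterations (default
#'   1000).
#' @param init_density Probability that an element of the initial context is
#'   active (default 0.5).
#'
#' @return An object of class `tcr_params` (a named list).
#' @export
#' @examples
#' model_params(p = 0.02, lam = 0.2)
model_params <- function(n_features = 100L, p = 0.02, lam = 0.2,
                         n_iter = 1000L, init_density = 0.5) {
  n_features <- as.integer(n_features)
  n_iter <- as.integer(n_iter)
  if (length(n_features) != 1L || is.na(n_features) || n_features < 1L) {
    stop("`n_features` must be a single integer >= 1", call. = FALSE)
  }
  if (length(n_iter) != 1L || is.na(n_iter) || n_iter < 1L) {
    stop("`n_iter` must be a single integer >= 1", call. = FALSE)
  }
  check_rate(p, "p")
  check_rate(lam, "lam")
  check_rate(init_density, "init_density")
  structure(
    list(n_features = n_features, p = p, lam = lam, n_iter = n_iter,
         init_density = init_density),
    class = "tcr_params"
  )
}

#' Parameters of the random-shift alternative model
#'
#' The alternative account of boundary dynamics replaces reinstatement with a
#' random sharp shift: context drifts at a low base rate everywhere and at an
#' elevated rate on boundary steps, with no pull back toward the first
#' context.
#'
#' @param p_base Non-boundary drift rate (default 0.01).
#' @param p_boundary Boundary-step drift rate (default 0.08).
#'
#' @return An object of class `tcr_alt_params`.
#' @export
alt_params <- function(p_base = 0.01, p_boundary = 0.08) {
  check_rate(p_base, "p_base")
  check_rate(p_boundary, "p_boundary")
  if (p_base > p_boundary) {
    stop("`p_base` must not exceed `p_boundary`", call. = FALSE)
  }
  structure(list(p_base = p_base, p_boundary = p_boundary),
            class = "tcr_alt_params")
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

#' @export
print.tcr_params <- function(x, ...) {
  cat(sprintf(
    "<tcr_params> F = %d features, p = %g, lam = %g, n_iter = %d, init_density = %g\n",
    x$n_features, x$p, x$lam, x$n_iter, x$init_density))
  invisible(x)
}

#' @export
print.tcr_alt_params <- function(x, ...) {
  cat(sprintf("<tcr_alt_params> p_base = %g, p_boundary = %g\n",
              x$p_base, x$p_boundary))
  invisible(x)
}
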