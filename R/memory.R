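#' Decay scale of the delayed-payoff acceptance probability
#'
#' The delayed variant uses a payoff from `tau` steps in the past with
#' probability `nu = exp(-tau / s)`.  The scale `s = -100 / log(0.01)`
#' (about 21.7147) is fixed so that a payoff 100 steps old is chosen with
#' probability exactly 1%.
#'
#' @return The scale `s`.
#' @export
delay_scale <- function() -100 / log(0.01)

#' Memory length implied by the geometric weight cutoff
#'
#' In the weighted-moving-average payoff, the payoff `m` rounds back carries
#' weight `alpha^m`.  Lags whose weight falls below the cutoff (0.01 by
#' default) are dropped; the memory length `M` is the largest lag retained,
#' i.e. the largest `m` with `alpha^m >= threshold` (the comparison is
#' inclusive: a weight exactly at the cutoff is kept).
#'
#' @param alpha Decay factor, `0 <= alpha < 1`.
#' @param threshold Weight cutoff in `(0, 1)`, default `0.01`.
#' @return Integer `M >= 0`; `M = 0` for `alpha = 0` (only the current
#'   payoff survives).
#' @examples
#' memory_length(0.5)   # 6
#' memory_length(0.95)  # 89
#' @export
memory_length <- function(alpha, threshold = 0.01) {
  stopifnot(is.numeric(alpha), length(alpha) == 1,
            is.numeric(threshold), length(threshold) == 1)
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1); the alpha -> 1 limit is handled by the ",
         "capacity cap in memory_config()", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (alpha == 0) return(0L)
  # largest m with alpha^m >= threshold; guard the log division against
  # floating error by checking the neighbors directly
  m <- floor(log(threshold) / log(alpha))
  while (alpha^(m + 1) >= threshold) m <- m + 1
  while (m > 0 && alpha^m < threshold) m <- m - 1
  as.integer(m)
}

#' Acceptance probability of a delayed payoff
#'
#' Probability `nu = exp(-tau / s)` with which the payoff `tau` steps in the
#' past is used instead of the current one; `s = -100 / log(0.01)` so that
#' `nu(100) = 0.01`.  Strictly decreasing in `tau`, with `nu(0) = 1`.
#'
#' @param tau Non-negative delay (vectorised).
#' @return Probabilities in `(0, 1]`.
#' @examples
#' delay_acceptance(c(0, 50, 100))  # 1, 0.1, 0.01
#' @export
delay_acceptance <- function(tau) {
  stopifnot(is.numeric(tau))
  if (any(tau < 0)) stop("tau must be non-negative", call. = FALSE)
  exp(-tau / delay_scale())
}

#' Configure the payoff-memory rule
#'
#' Three variants of the effective ("final") payoff entering the imitation
#' rule:
#' \describe{
#'   \item{`none`}{the current payoff, i.e. the memoryless baseline.}
#'   \item{`averaged`}{a geometrically weighted moving average of the payoff
#'     history, \deqn{P_i = \frac{P_{0,i} + \sum_{m=1}^{M} \alpha^m P_{m,i}}
#'     {1 + \sum_{m=1}^{M} \alpha^m},} where lags with weight below
#'     `weight_threshold` are dropped (see [memory_length()]).}
#'   \item{`delayed`}{with probability `nu = exp(-tau/s)` the single payoff
#'     from `tau` steps back is used; otherwise the current payoff.}
#' }
#' `averaged` with `alpha = 0`, `delayed` with `tau = 0` and `none` are all
#' equivalent to the memoryless baseline.
#'
#' @param variant `"none"`, `"averaged"` or `"delayed"`.
#' @param alpha Decay factor of the averaged variant, `0 <= alpha <= 1`.
#'   The limiting case `alpha = 1` (all past payoffs, equal weight) is
#'   admitted through the `max_window` capacity cap.
#' @param tau Integer delay of the delayed variant, `tau >= 0`.
#' @param weight_threshold Geometric weight cutoff, default 0.01.
#' @param max_window Hard cap on retained payoff-history entries (default
#'   500), relevant only as `alpha -> 1` where the cutoff-implied window
#'   diverges.
#' @return A `memory_config` with the derived quantities: memory length `M`,
#'   acceptance probability `nu`, decay scale `s`, the payoff-record capacity
#'   (`max(M, tau)` per-round records; entry 0 is always the fresh payoff of
#'   the current evaluation), and the weak/strong classification lag
#'   (`ceiling(M/2)` for the averaged variant — the middle of the averaging
#'   window — `tau` for the delayed variant, 0 otherwise).  One memory
#'   "round" is one full Monte Carlo step: every player's payoff is recorded
#'   once per MCS.
#' @examples
#' memory_config("averaged", alpha = 0.9)
#' memory_config("delayed", tau = 3)
#' @export
memory_config <- function(variant = c("none", "averaged", "delayed"),
                          alpha = 0, tau = 0,
                          weight_threshold = 0.01, max_window = 500) {
  variant <- match.arg(variant)
  stopifnot(max_window >= 1)
  M <- 0L
  nu <- 1.0
  if (variant == "averaged") {
    if (alpha < 0 || alpha > 1)
      stop("alpha must lie in [0, 1]", call. = FALSE)
    M <- if (alpha == 1) as.integer(max_window - 1)
         else min(memory_length(alpha, weight_threshold),
                  as.integer(max_window - 1))
  } else if (variant == "delayed") {
    if (tau < 0 || tau != as.integer(tau))
      stop("tau must be a non-negative integer", call. = FALSE)
    tau <- as.integer(tau)
    nu <- delay_acceptance(tau)
  }
  structure(
    list(
      variant = variant, alpha = alpha, tau = as.integer(tau),
      weight_threshold = weight_threshold, max_window = as.integer(max_window),
      M = as.integer(M), nu = nu, s = delay_scale(),
      capacity = switch(variant, none = 0L, averaged = M,
                        delayed = as.integer(tau)),
      lag = switch(variant, none = 0L,
                   averaged = as.integer(ceiling(M / 2)),
                   delayed = as.integer(tau))
    ),
    class = "memory_config"
  )
}

#' @export
print.memory_config <- function(x, ...) {
  detail <- switch(x$variant,
    none = "memoryless baseline",
    averaged = sprintf("alpha = %g, M = %d", x$alpha, x$M),
    delayed = sprintf("tau = %d, nu = %.4g", x$tau, x$nu))
  cat(sprintf("<memory_config> variant %s (%s)\n", x$variant, detail))
  invisible(x)
}

#' Weighted moving average of a payoff history
#'
#' Evaluates the averaged effective payoff
#' \deqn{P = \frac{\sum_{m=0}^{M} \alpha^m P_m}{\sum_{m=0}^{M} \alpha^m}}
#' over a newest-first payoff history.  When fewer than `M + 1` entries are
#' available (early in a run) the sum truncates to the available entries and
#' renormalises, so the result is always a convex combination of the entries
#' used.
#'
#' @param history Numeric vector of past payoffs, newest first (`history[1]`
#'   is the current payoff `P_0`).
#' @param alpha Decay factor.
#' @param M Memory length; defaults to the cutoff-implied
#'   [memory_length()] of `alpha`.
#' @return The weighted average, within `[min, max]` of the entries used.
#' @examples
#' averaged_payoff(c(1, 0, 0, 0, 0, 0, 0), alpha = 0.5)  # 1 / 1.984375
#' @export
averaged_payoff <- function(history, alpha, M = memory_length(alpha)) {
  if (length(history) < 1) stop("empty payoff history", call. = FALSE)
  k <- min(length(history), M + 1)
  w <- alpha^(0:(k - 1))  # alpha = 0 gives c(1, 0, 0, ...): current only
  sum(w * history[seq_len(k)]) / sum(w)
}

#' Effective payoff under a memory configuration
#'
#' Applies the configured memory rule to a payoff history: the current payoff
#' (`none`), the weighted moving average (`averaged`), or — with probability
#' `nu` — the payoff `tau` steps back (`delayed`; the oldest available entry
#' substitutes when the history is still shorter than `tau + 1`).
#'
#' Only the delayed variant consumes randomness: exactly one uniform draw per
#' call, taken from `u` if supplied or from the global RNG otherwise.
#'
#' @param history Numeric vector of past payoffs, newest first.
#' @param config A [memory_config()].
#' @param u Optional uniform in `[0, 1)` standing in for the acceptance draw
#'   (used by scripted-stream tests).
#' @return The effective payoff.
#' @export
effective_payoff <- function(history, config, u = NULL) {
  if (length(history) < 1) stop("empty payoff history", call. = FALSE)
  switch(config$variant,
    none = history[1],
    averaged = averaged_payoff(history, config$alpha, config$M),
    delayed = {
      if (is.null(u)) u <- runif(1)
      if (u < config$nu) history[min(config$tau + 1, length(history))]
      else history[1]
    })
}
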