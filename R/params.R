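#' Payoff parameters of the two-strategy social dilemma
#'
#' The game is parameterised by the temptation `T` and the sucker's payoff
#' `S`, with the reward fixed at `R = 1` and the punishment at `P = 0`.  A
#' pairwise encounter pays the focal player `R` (C meets C), `S` (C meets D),
#' `T` (D meets C) or `P` (D meets D).
#'
#' @param T Temptation to defect, `0 <= T <= 2`.
#' @param S Sucker's payoff, `-1 <= S <= 1`.
#' @return An object of class `game_params`: a list with elements `T`, `S`,
#'   `R = 1`, `P = 0` and the dilemma class (see [dilemma_class()]).
#' @examples
#' game_params(T = 1.3, S = -0.1)  # a prisoner's dilemma
#' @export
game_params <- function(T = 1, S = 0) {
  stopifnot(is.numeric(T), length(T) == 1, is.finite(T),
            is.numeric(S), length(S) == 1, is.finite(S))
  if (T < 0 || T > 2) stop("T must lie in [0, 2]", call. = FALSE)
  if (S < -1 || S > 1) stop("S must lie in [-1, 1]", call. = FALSE)
  structure(
    list(T = T, S = S, R = 1, P = 0, dilemma = dilemma_class(T, S)),
    class = "game_params"
  )
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("<game_params> T = %g, S = %g (R = 1, P = 0), dilemma: %s\n",
              x$T, x$S, ifelse(is.na(x$dilemma), "boundary", x$dilemma)))
  invisible(x)
}

#' Classify a (T, S) pair into a social dilemma quadrant
#'
#' With `R = 1` and `P = 0` fixed, the `T`-`S` plane splits into four open
#' quadrants: the prisoner's dilemma (`T > 1`, `S < 0`), the snowdrift game
#' (`T > 1`, `S > 0`), the stag-hunt game (`T < 1`, `S < 0`) and the harmony
#' game (`T < 1`, `S > 0`).  Points on the boundaries `T = 1` or `S = 0` are
#' degenerate games belonging to no quadrant and classify as `NA`; quadrant
#' averages are taken over strictly interior cells only.
#'
#' @param T,S Numeric vectors (recycled) of temptation and sucker's payoffs.
#' @return A character vector with values `"PD"`, `"SD"`, `"SH"`, `"HG"`
#'   or `NA`.
#' @examples
#' dilemma_class(c(1.5, 1.5, 0.5, 0.5, 1), c(-0.5, 0.5, -0.5, 0.5, 0.3))
#' @export
dilemma_class <- function(T, S) {
  n <- max(length(T), length(S))
  out <- rep(NA_character_, n)
  T <- rep_len(T, n)
  S <- rep_len(S, n)
  out[T > 1 & S < 0] <- "PD"
  out[T > 1 & S > 0] <- "SD"
  out[T < 1 & S < 0] <- "SH"
  out[T < 1 & S > 0] <- "HG"
  out
}
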