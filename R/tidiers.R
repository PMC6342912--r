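#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a game run into its trajectory
#'
#' @param x A `game_run` from [run_game()].
#' @param ... Unused.
#' @return The `rho_C` trajectory as a tibble (`mcs`, `rho_c`).
#' @export
tidy.game_run <- function(x, ...) x$trajectory

#' One-row summary of a game run
#'
#' @param x A `game_run`.
#' @param ... Unused.
#' @return A one-row tibble: lattice size, variant and memory parameter,
#'   payoffs, noise, stationary `rho_C`, absorption status, MCS run.
#' @export
glance.game_run <- function(x, ...) {
  tibble::tibble(
    L = x$final_state$L, variant = x$mem$variant,
    alpha = ifelse(x$mem$variant == "averaged", x$mem$alpha, NA_real_),
    tau = ifelse(x$mem$variant == "delayed", x$mem$tau, NA_integer_),
    T = x$params$T, S = x$params$S, K = x$dyn$K,
    rho_stationary = x$rho_stationary,
    absorbed = x$absorbed, mcs = x$mcs
  )
}
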