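# Deterministic per-cell seed hashed from the cell's parameters and replicate
# seed, so a cell's result depends on nothing else — not on the rest of the
# grid nor on execution order.  Kept below 2^31; exact in double arithmetic.
cell_seed <- function(T, S, par, seed) {
  h <- (round(T * 1000) * 73856093 + round((S + 1) * 1000) * 19349663 +
        round(par * 1000) * 83492791 + seed * 40503) %% 2147483629
  as.integer(h) + 1L
}

run_one_cell <- function(T, S, mem, L, seed, dyn) {
  tryCatch({
    set.seed(seed)
    state <- lattice_random(L)
    run <- run_game(state, game_params(T, S), mem, dyn)
    tibble::tibble(rho_c = run$rho_stationary, absorbed = run$absorbed,
                   mcs = run$mcs)
  }, error = function(e) {
    # a failing cell is reported, not fatal to the rest of the sweep
    warning(sprintf("cell T=%g S=%g seed=%d failed: %s", T, S, seed,
                    conditionMessage(e)), call. = FALSE)
    tibble::tibble(rho_c = NA_real_, absorbed = NA, mcs = NA_integer_)
  })
}

#' Sweep the T-S plane
#'
#' Runs the lattice game from independent random 50/50 initial states for
#' every combination of temptation `T`, sucker's payoff `S`, memory
#' parameter and replicate seed, and reports the stationary cooperator
#' fraction of each run.  Each cell's RNG seed is hashed from its own
#' parameters and replicate seed, so results depend on nothing but the cell
#' itself: execution order and grid layout are irrelevant, and rerunning the
#' same grid reproduces the table exactly.
#'
#' @param T_values,S_values Numeric grids over `[0, 2]` and `[-1, 1]`.
#' @param variant Memory variant, `"none"`, `"averaged"` or `"delayed"`.
#' @param alpha Decay factors to sweep (averaged variant).
#' @param tau Delays to sweep (delayed variant).
#' @param L Linear lattice size.
#' @param seeds Integer replicate seeds.
#' @param K Fermi selection noise.
#' @param relaxation_steps,measure_steps Per-run MCS budget; the desk-scale
#'   defaults (2000 + 1000 at `L = 100`) preserve the qualitative structure
#'   of the full-scale phase diagrams at a fraction of the cost.
#' @return A `mem_sweep` tibble with one row per
#'   `(T, S, parameter, seed)` run: `variant`, `alpha`, `tau`, `T`, `S`,
#'   `dilemma`, `seed`, `rho_c`, `absorbed`, `mcs`.
#' @examples
#' \donttest{
#' sw <- run_sweep(c(1.1, 1.3), c(-0.1, 0.1), variant = "none",
#'                 L = 30, seeds = 1, relaxation_steps = 100,
#'                 measure_steps = 50)
#' quadrant_average(sw)
#' }
#' @export
run_sweep <- function(T_values, S_values,
                      variant = c("none", "averaged", "delayed"),
                      alpha = 0, tau = 0, L = 100, seeds = 1:5, K = 0.1,
                      relaxation_steps = 2000, measure_steps = 1000) {
  variant <- match.arg(variant)
  stopifnot(length(T_values) >= 1, length(S_values) >= 1, length(seeds) >= 1)
  if (any(T_values < 0 | T_values > 2)) stop("T values must lie in [0, 2]")
  if (any(S_values < -1 | S_values > 1)) stop("S values must lie in [-1, 1]")
  par_values <- switch(variant, none = 0, averaged = alpha, delayed = tau)
  grid <- tidyr::expand_grid(par = par_values, T = T_values, S = S_values,
                             seed = seeds)
  dyn <- dynamics_config(K = K, relaxation_steps = relaxation_steps,
                         measure_steps = measure_steps,
                         stop_at_absorption = TRUE)
  res <- purrr::pmap(grid, function(par, T, S, seed) {
    mem <- switch(variant,
      none = memory_config("none"),
      averaged = memory_config("averaged", alpha = par),
      delayed = memory_config("delayed", tau = par))
    run_one_cell(T, S, mem, L, cell_seed(T, S, par, seed), dyn)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$variant <- variant
  out$alpha <- if (variant == "averaged") out$par else NA_real_
  out$tau <- if (variant == "delayed") out$par else NA_integer_
  out$dilemma <- dilemma_class(out$T, out$S)
  out <- out[, c("variant", "alpha", "tau", "T", "S", "dilemma", "seed",
                 "rho_c", "absorbed", "mcs")]
  class(out) <- c("mem_sweep", class(out))
  out
}

#' Average cooperation level per social dilemma quadrant
#'
#' Averages the stationary cooperator fraction over all `(T, S)` cells lying
#' strictly inside a dilemma quadrant (boundary games `T = 1` or `S = 0` are
#' excluded): first over replicate seeds within a cell, then unweighted over
#' cells.
#'
#' @param sweep A `mem_sweep` tibble from [run_sweep()].
#' @param dilemma Optional subset of `"PD"`, `"SD"`, `"SH"`, `"HG"`; an error
#'   if the sweep has no interior cell of a requested class.
#' @return A tibble with `variant`, `alpha`, `tau`, `dilemma`, `mean_rho`,
#'   `n_cells`.
#' @export
quadrant_average <- function(sweep, dilemma = NULL) {
  dat <- dplyr::filter(sweep, !is.na(.data$dilemma))
  if (!is.null(dilemma)) {
    missing <- setdiff(dilemma, unique(dat$dilemma))
    if (length(missing) > 0)
      stop("no interior cells in quadrant(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    dat <- dplyr::filter(dat, .data$dilemma %in% !!dilemma)
  }
  per_cell <- dplyr::summarise(
    dplyr::group_by(dat, .data$variant, .data$alpha, .data$tau,
                    .data$dilemma, .data$T, .data$S),
    cell_rho = mean(.data$rho_c), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_cell, .data$variant, .data$alpha, .data$tau,
                    .data$dilemma),
    mean_rho = mean(.data$cell_rho), n_cells = dplyr::n(), .groups = "drop")
}

#' Cooperation gain relative to the memoryless baseline
#'
#' For quadrant-average curves indexed by the delay `tau`, subtracts each
#' dilemma's `tau = 0` level, giving the cooperation promotion attributable
#' to the memory rule (0 at `tau = 0` by construction).
#'
#' @param curves A tibble from [quadrant_average()] with a `tau` column
#'   containing a `tau = 0` entry for every dilemma.
#' @return `curves` with an added `delta_rho` column.
#' @export
delta_vs_baseline <- function(curves) {
  if (!"tau" %in% names(curves) || all(is.na(curves$tau)))
    stop("curves must be indexed by tau", call. = FALSE)
  dplyr::mutate(
    dplyr::group_by(curves, .data$dilemma),
    delta_rho = {
      base <- .data$mean_rho[.data$tau == 0]
      if (length(base) != 1)
        stop("tau = 0 baseline missing for some dilemma", call. = FALSE)
      .data$mean_rho - base
    }
  ) |> dplyr::ungroup()
}

#' Prepared-domain fixation experiment
#'
#' Starts each run from a circular cooperative domain surrounded by
#' defectors and evolves with absorption stopping until the lattice fixates
#' (all-C or all-D) or the MCS cap is reached.  Runs that do not absorb
#' within the cap are reported as `"unresolved"` together with their final
#' `rho_C` — never dropped.
#'
#' @param T,S Game payoffs.
#' @param mem A [memory_config()].
#' @param L Linear lattice size (default 101, an odd size centring the
#'   domain exactly).
#' @param radius Domain radius (default 25).
#' @param seeds Integer replicate seeds.
#' @param K Fermi selection noise.
#' @param max_mcs MCS cap per run.
#' @return A tibble with one row per seed: `seed`, `outcome`
#'   (`"C-fixation"`, `"D-fixation"` or `"unresolved"`), `final_rho`, `mcs`.
#' @export
run_fixation <- function(T, S, mem, L = 101, radius = 25, seeds = 1:10,
                         K = 0.1, max_mcs = 30000) {
  params <- game_params(T, S)
  dyn <- dynamics_config(K = K, relaxation_steps = max_mcs, measure_steps = 0,
                         stop_at_absorption = TRUE)
  purrr::map_dfr(seeds, function(s) {
    run <- run_game(lattice_circular(L, radius), params, mem, dyn, seed = s)
    rho <- rho_c(run$final_state)
    tibble::tibble(
      seed = s,
      outcome = if (run$absorbed && rho == 1) "C-fixation"
                else if (run$absorbed && rho == 0) "D-fixation"
                else "unresolved",
      final_rho = rho, mcs = run$mcs)
  })
}

#' Replicate-averaged invasion rates between subgroups
#'
#' Launches replicate runs from random initial states, records the invasion
#' ledger of each (per-MCS successful adoptions on the 8 directed subgroup
#' channels) and averages channel counts per MCS over replicates.  Runs that
#' absorb early contribute zero counts for the remaining window.
#'
#' @param T,S Game payoffs.
#' @param mem A [memory_config()].
#' @param L Linear lattice size.
#' @param seeds Integer replicate seeds.
#' @param mcs Window length in MCS.
#' @param K Fermi selection noise.
#' @return A tibble `mcs`, `channel`, `rate` (mean successful adoptions per
#'   MCS per replicate).
#' @export
run_invasion <- function(T, S, mem, L = 100, seeds = 1:5, mcs = 1000,
                         K = 0.1) {
  params <- game_params(T, S)
  window <- as.integer(mcs)
  dyn <- dynamics_config(K = K, relaxation_steps = window, measure_steps = 0,
                         stop_at_absorption = TRUE)
  leds <- purrr::map(seeds, function(s) {
    set.seed(s)
    state <- lattice_random(L)
    run <- run_game(state, params, mem, dyn, record_ledger = TRUE)
    # absorbed runs contribute zero counts for the rest of the window
    tidyr::complete(run$ledger, mcs = seq_len(window),
                    channel = LEDGER_CHANNELS,
                    fill = list(count = 0L))
  })
  dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(leds), .data$mcs, .data$channel),
    rate = sum(.data$count) / length(seeds), .groups = "drop")
}

#' Net rate on a directed subgroup channel pair
#'
#' For a subgroup pair such as `D_C` and `C_C`, computes the per-MCS net
#' invasion rate `rate(DC<-CC) - rate(CC<-DC)`: positive values mean the
#' cooperating side of the pair is gaining ground.
#'
#' @param invasion A tibble from [run_invasion()].
#' @param pair Length-2 character vector, `c(invaded, invader)` in compact
#'   labels (`"DC"`, `"CC"`, ...); default the weak-defector/strong-cooperator
#'   pair whose sustained sign distinguishes cooperation-promoting regimes.
#' @return A tibble `mcs`, `net`.
#' @export
channel_net <- function(invasion, pair = c("DC", "CC")) {
  fwd <- paste0(pair[1], "<-", pair[2])
  bwd <- paste0(pair[2], "<-", pair[1])
  wide <- tidyr::pivot_wider(
    dplyr::filter(invasion, .data$channel %in% c(fwd, bwd)),
    names_from = "channel", values_from = "rate", values_fill = 0)
  for (col in c(fwd, bwd)) if (!col %in% names(wide)) wide[[col]] <- 0
  tibble::tibble(mcs = wide$mcs,
                 net = wide[[fwd]] - wide[[bwd]])
}
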