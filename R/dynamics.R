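#' Configure the Monte Carlo dynamics
#'
#' @param K Selection noise of the Fermi imitation rule, `K > 0`; the
#'   field-standard value 0.1 is the default.
#' @param relaxation_steps Full Monte Carlo steps (MCS; one MCS = `L^2`
#'   elementary steps) run before measurement.
#' @param measure_steps MCS over which the stationary cooperator fraction is
#'   time-averaged.
#' @param stop_at_absorption Stop as soon as the lattice is homogeneous
#'   (all-C or all-D).  These states are absorbing, so the absorbed value is
#'   exactly the stationary average; stopping early only saves work.
#' @return A `dynamics_config`.
#' @export
dynamics_config <- function(K = 0.1, relaxation_steps = 10000,
                            measure_steps = 20000,
                            stop_at_absorption = TRUE) {
  if (K <= 0) stop("K must be positive", call. = FALSE)
  if (relaxation_steps < 0 || measure_steps < 0)
    stop("step counts must be non-negative", call. = FALSE)
  structure(
    list(K = K,
         relaxation_steps = as.integer(relaxation_steps),
         measure_steps = as.integer(measure_steps),
         stop_at_absorption = isTRUE(stop_at_absorption)),
    class = "dynamics_config"
  )
}

#' Fermi strategy-adoption probability
#'
#' Probability that the focal player adopts the neighbor's strategy,
#' \deqn{W = \frac{1}{1 + \exp[(P_i - P_j)/K]},}
#' strictly decreasing in the focal payoff advantage `P_i - P_j`.  In the
#' `K -> 0` limit only better-performing neighbors are imitated; large `K`
#' randomises adoption.  The guarded form never overflows, even for
#' `|P_i - P_j| / K` in the hundreds (routine at `K = 0.1`).
#'
#' @param p_i Effective payoff of the focal (potentially imitating) player.
#' @param p_j Effective payoff of the neighbor (vectorised with `p_i`).
#' @param K Selection noise, `K > 0`.
#' @return Probabilities in `(0, 1)`.
#' @examples
#' fermi_probability(1, 2, K = 0.1)  # worse focal: adoption near-certain
#' @export
fermi_probability <- function(p_i, p_j, K = 0.1) {
  if (K <= 0) stop("K must be positive", call. = FALSE)
  stopifnot(all(is.finite(p_i)), all(is.finite(p_j)))
  x <- (p_i - p_j) / K
  ifelse(x > 0, exp(-x) / (1 + exp(-x)), 1 / (1 + exp(x)))
}

#' Seed payoff records from the initial configuration
#'
#' Fills every player's payoff records as if the starting configuration had
#' always existed: each history holds the player's payoff against its current
#' neighborhood, repeated to capacity.  This puts the memory rule in force
#' from the very first elementary step — bulk defectors begin with the low
#' payoff of mutual defection on record — rather than letting the early
#' dynamics run memoryless while histories build up.  [run_game()] applies
#' the same seeding by default.
#'
#' @param state A `lattice_state`.
#' @param params A [game_params()].
#' @param mem A [memory_config()].
#' @return The state with filled payoff records.
#' @export
prefill_histories <- function(state, params, mem) {
  if (mem$capacity > 0) {
    L <- state$L
    for (idx in seq_len(L * L)) {
      site <- c((idx - 1L) %/% L + 1L, (idx - 1L) %% L + 1L)
      state$payoff_history[[idx]] <-
        rep(accrue_payoff(state, site, params), mem$capacity)
    }
  }
  state
}

# Effective payoff over completed rounds, mirroring the compiled core: the
# averaged variant applies the geometric weights to the per-round records
# (latest completed round first); the delayed variant returns the record tau
# rounds back with probability nu, else the latest record.  The fresh
# mid-step evaluation stands in only while no records exist.
eff_from_records <- function(fresh, recs, mem, u = NULL) {
  switch(mem$variant,
    none = fresh,
    averaged = if (length(recs) == 0) fresh
               else averaged_payoff(recs, mem$alpha, mem$M),
    delayed = {
      if (length(recs) == 0) fresh
      else if (u < mem$nu) recs[min(mem$tau, length(recs))]
      else recs[1]
    })
}

# Push a fresh payoff onto a site's newest-first history, respecting capacity.
push_payoff <- function(state, idx, value, capacity) {
  h <- c(value, state$payoff_history[[idx]])
  if (length(h) > capacity) h <- h[seq_len(capacity)]
  state$payoff_history[[idx]] <- h
  state
}

#' One elementary Monte Carlo step (reference R implementation)
#'
#' Performs the three-part elementary move: (1) a uniformly random focal site
#' `i` accrues its payoff against its four neighbors; (2) a uniformly random
#' neighbor `j` of `i` does the same; (3) effective payoffs are formed under
#' the memory rule from the per-round payoff records that
#' [monte_carlo_step()] appends once per MCS (the fresh evaluation stands in
#' while no records exist) and `i` adopts `s_j` with the Fermi probability
#' `W(P_i, P_j, K)`.
#'
#' Uniform draws are consumed in the fixed order: focal site, neighbor
#' choice, (delayed variant only) memory acceptance for `i` then `j`, and the
#' adoption Bernoulli — which is consumed even when both players already
#' agree, so RNG streams stay aligned across configurations.  This pure-R
#' path is the readable reference; [run_game()] runs the same dynamics in
#' compiled code and is bit-compatible with it on a shared RNG stream.
#'
#' @param state A `lattice_state`.
#' @param params A [game_params()].
#' @param mem A [memory_config()].
#' @param dyn A [dynamics_config()].
#' @param u Optional numeric vector of scripted uniforms for this step (3
#'   draws, or 5 for the delayed variant).
#' @return A list with the updated `state` and `event` — `NULL` when focal
#'   and neighbor already agreed, otherwise a one-row tibble recording the
#'   pair, their weak/strong subgroups just before adoption, `W`, and whether
#'   the strategy was adopted.
#' @export
elementary_step <- function(state, params, mem, dyn, u = NULL) {
  L <- state$L
  N <- L * L
  need <- if (mem$variant == "delayed") 5L else 3L
  if (is.null(u)) u <- runif(need)
  if (length(u) < need) stop("scripted uniform stream exhausted", call. = FALSE)
  ui <- 0L
  draw <- function() {
    ui <<- ui + 1L
    u[ui]
  }

  i0 <- min(floor(draw() * N), N - 1)  # 0-based row-major site index
  i <- c(i0 %/% L + 1L, i0 %% L + 1L)
  k <- min(floor(draw() * 4), 3)
  j <- neighbors(state, i)[k + 1L, ]

  idx_i <- (i[1] - 1L) * L + i[2]
  idx_j <- (j[1] - 1L) * L + j[2]

  p_raw_i <- accrue_payoff(state, i, params)
  p_raw_j <- accrue_payoff(state, j, params)

  u_mem_i <- if (mem$variant == "delayed") draw() else NULL
  p_eff_i <- eff_from_records(p_raw_i, state$payoff_history[[idx_i]],
                              mem, u_mem_i)
  u_mem_j <- if (mem$variant == "delayed") draw() else NULL
  p_eff_j <- eff_from_records(p_raw_j, state$payoff_history[[idx_j]],
                              mem, u_mem_j)

  W <- fermi_probability(p_eff_i, p_eff_j, dyn$K)
  u_adopt <- draw()  # always consumed

  s_i <- state$strategies[i[1], i[2]]
  s_j <- state$strategies[j[1], j[2]]
  event <- NULL
  if (s_i != s_j) {
    sub_i <- classify_subgroup(state, i, mem)
    sub_j <- classify_subgroup(state, j, mem)
    adopted <- u_adopt < W
    if (adopted) state$strategies[i[1], i[2]] <- s_j
    event <- tibble::tibble(
      mcs = state$time, i_row = i[1], i_col = i[2],
      j_row = j[1], j_col = j[2],
      s_i = ifelse(s_i == STRAT_C, "C", "D"),
      s_j = ifelse(s_j == STRAT_C, "C", "D"),
      sub_i = sub_i, sub_j = sub_j,
      p_eff_i = p_eff_i, p_eff_j = p_eff_j, W = W, adopted = adopted
    )
  }
  list(state = state, event = event)
}

#' One full Monte Carlo step (reference R implementation)
#'
#' Repeats [elementary_step()] `L^2` times — one strategy-revision
#' opportunity per player on average — then closes the round: every player's
#' payoff against the end-of-sweep configuration is appended to its payoff
#' records (the "one round back" entries of the memory rule), the per-MCS
#' strategy record used by the weak/strong classification is appended, and
#' the clock advances by one MCS.
#'
#' @inheritParams elementary_step
#' @param u Optional scripted uniform vector covering all `L^2` steps.
#' @return A list with the updated `state` and `events`, a tibble of all
#'   focal/neighbor disagreement events of the sweep.
#' @export
monte_carlo_step <- function(state, params, mem, dyn, u = NULL) {
  N <- state$L^2
  per <- if (mem$variant == "delayed") 5L else 3L
  events <- vector("list", N)
  for (s in seq_len(N)) {
    us <- if (is.null(u)) NULL else u[((s - 1) * per + 1):(s * per)]
    step <- elementary_step(state, params, mem, dyn, us)
    state <- step$state
    events[[s]] <- step$event
  }
  L <- state$L
  if (mem$capacity > 0) {  # per-MCS payoff records, end-of-sweep state
    for (idx in seq_len(N)) {
      site <- c((idx - 1L) %/% L + 1L, (idx - 1L) %% L + 1L)
      state <- push_payoff(state, idx, accrue_payoff(state, site, params),
                           mem$capacity)
    }
  }
  if (mem$lag > 0) {
    flat <- as.vector(t(state$strategies))  # row-major site order
    for (idx in seq_len(N)) {
      h <- c(flat[idx], state$strategy_history[[idx]])
      if (length(h) > mem$lag) h <- h[seq_len(mem$lag)]
      state$strategy_history[[idx]] <- h
    }
  }
  state$time <- state$time + 1L
  list(state = state, events = dplyr::bind_rows(events))
}

LEDGER_CHANNELS <- c("DD<-CC", "DC<-CC", "DD<-CD", "DC<-CD",
                     "CC<-DD", "CD<-DD", "CC<-DC", "CD<-DC")

#' Run the lattice game
#'
#' Evolves a lattice through `relaxation_steps + measure_steps` full Monte
#' Carlo steps of asynchronous Fermi-rule imitation with the configured
#' payoff-memory rule, starting from the supplied strategy configuration
#' (payoff records seeded from it by default, see [prefill_histories()]).
#' The stationary cooperator fraction is the time average
#' of `rho_C` over the measurement window, or the absorbed value if the run
#' hit a homogeneous state first.  The inner loop runs in compiled code and
#' consumes R's global uniform stream, so `seed` makes runs bit-reproducible
#' (and bit-identical to the pure-R [monte_carlo_step()] path).
#'
#' @param state Initial `lattice_state` ([lattice_random()],
#'   [lattice_circular()] or [read_lattice()]).
#' @param params A [game_params()].
#' @param mem A [memory_config()]; default memoryless.
#' @param dyn A [dynamics_config()].
#' @param seed Optional integer seed applied before the run.
#' @param prefill_history Seed every player's payoff records from the
#'   initial configuration (default); set `FALSE` to start with empty
#'   histories that build up during the run.
#' @param record_ledger Record the invasion ledger: per-MCS counts of
#'   successful adoptions on each of the 8 directed subgroup channels.
#' @param record_trace Record every elementary step (site choices, raw and
#'   effective payoffs, `W`, adoption) — only sensible for small runs.
#' @param uniforms Optional scripted uniform vector replacing the RNG
#'   entirely (oracle tests).
#' @return A `game_run` object; see [tidy.game_run()] and
#'   [glance.game_run()].
#' @examples
#' run <- run_game(lattice_random(30, seed = 1), game_params(T = 1.05, S = 0.05),
#'                 dyn = dynamics_config(relaxation_steps = 50, measure_steps = 50),
#'                 seed = 2)
#' glance(run)
#' @export
run_game <- function(state, params, mem = memory_config("none"),
                     dyn = dynamics_config(), seed = NULL,
                     prefill_history = TRUE,
                     record_ledger = FALSE, record_trace = FALSE,
                     uniforms = NULL) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "game_params"),
            inherits(mem, "memory_config"), inherits(dyn, "dynamics_config"))
  if (!is.null(seed)) set.seed(seed)
  variant_code <- match(mem$variant, c("none", "averaged", "delayed")) - 1L
  res <- cpp_run(state$strategies, params$T, params$S, dyn$K,
                 variant_code, mem$alpha, mem$tau, mem$M, mem$nu, mem$lag,
                 dyn$relaxation_steps, dyn$measure_steps,
                 dyn$stop_at_absorption, prefill_history,
                 record_ledger, record_trace, uniforms)
  final <- new_lattice_state(res$strategies, time = res$mcs)
  ledger <- NULL
  if (record_ledger) {
    lm <- res$ledger
    colnames(lm) <- LEDGER_CHANNELS
    ledger <- tibble::as_tibble(lm)
    ledger$mcs <- seq_len(nrow(lm))
    ledger <- tidyr::pivot_longer(ledger, -"mcs", names_to = "channel",
                                  values_to = "count")
  }
  trace <- if (record_trace) tibble::as_tibble(res$trace) else NULL
  structure(
    list(
      final_state = final,
      trajectory = tibble::tibble(mcs = seq_len(res$mcs), rho_c = res$rho),
      rho_stationary = res$rho_stationary,
      absorbed = res$absorbed,
      absorbed_at = if (res$absorbed) res$absorbed_at else NA_integer_,
      mcs = res$mcs,
      ledger = ledger, trace = trace,
      params = params, mem = mem, dyn = dyn, seed = seed
    ),
    class = "game_run"
  )
}

#' @export
print.game_run <- function(x, ...) {
  cat(sprintf(
    "<game_run> %d x %d, %s, T = %g, S = %g: rho_C = %.4f after %d MCS%s\n",
    x$final_state$L, x$final_state$L, x$mem$variant, x$params$T, x$params$S,
    x$rho_stationary, x$mcs,
    if (x$absorbed) sprintf(" (absorbed at %d)", x$absorbed_at) else ""))
  invisible(x)
}
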