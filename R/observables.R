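SUBGROUPS <- c("C_C", "C_D", "D_D", "D_C")

#' Weak/strong subgroup of a player
#'
#' Players are classified by comparing their current strategy with their
#' strategy at a variant-specific reference lag in the past: `ceiling(M/2)`
#' MCS (the middle of the averaging window) for the averaged variant, `tau`
#' MCS for the delayed variant.  Strategies that agree with the reference are
#' *strong* (`C_C`, `D_D`); those that differ are *weak* (`C_D` — a
#' cooperator that was a defector in the considered past — and `D_C`).
#' Players whose per-MCS strategy record is still shorter than the lag are
#' classified against their oldest record; with no record at all (time 0)
#' every player is strong.
#'
#' @param state A `lattice_state` whose strategy history is maintained (see
#'   [monte_carlo_step()]).
#' @param site `c(row, column)`, 1-based.
#' @param mem A [memory_config()] (supplies the reference lag).
#' @return One of `"C_C"`, `"C_D"`, `"D_D"`, `"D_C"`.
#' @export
classify_subgroup <- function(state, site, mem) {
  cur <- state$strategies[site[1], site[2]]
  ref <- cur
  if (mem$lag > 0) {
    idx <- (site[1] - 1L) * state$L + site[2]  # row-major site label
    h <- state$strategy_history[[idx]]
    if (length(h) > 0) ref <- h[min(mem$lag, length(h))]
  }
  if (cur == STRAT_C) {
    if (ref == STRAT_C) "C_C" else "C_D"
  } else {
    if (ref == STRAT_D) "D_D" else "D_C"
  }
}

#' Subgroup census of the lattice
#'
#' @inheritParams classify_subgroup
#' @return A tibble with one row per subgroup (`C_C`, `C_D`, `D_D`, `D_C`)
#'   and its site count `n`; counts always sum to `L^2`.
#' @export
subgroup_counts <- function(state, mem) {
  L <- state$L
  labs <- vapply(seq_len(L * L), function(idx) {
    site <- c((idx - 1L) %/% L + 1L, (idx - 1L) %% L + 1L)
    classify_subgroup(state, site, mem)
  }, character(1))
  tibble::tibble(
    subgroup = SUBGROUPS,
    n = vapply(SUBGROUPS, function(s) sum(labs == s), integer(1))
  )
}

#' Invasion ledger between weak/strong subgroups
#'
#' An empty ledger for the 8 directed invasion channels (invaded `<-`
#' invader) between subgroups of opposing strategies, e.g. `"DD<-CC"`: a
#' strong defector adopting cooperation from a strong cooperator.  Channels
#' whose invader cooperates are cooperator-gain channels; the accumulated
#' (gain - loss) over any window exactly equals the change in the lattice's
#' cooperator count over that window.
#'
#' @return A zero-row tibble with columns `mcs`, `channel`, `count`.
#' @seealso [record_event()], [ledger_net_gain()]; [run_game()] with
#'   `record_ledger = TRUE` produces the same structure in compiled code.
#' @export
invasion_ledger <- function() {
  tibble::tibble(mcs = integer(), channel = character(), count = integer())
}

#' Record an adoption event in an invasion ledger
#'
#' Increments the (invader -> invaded) channel for a successful adoption;
#' unsuccessful attempts leave the ledger unchanged.  Subgroups are those
#' taken just before the adoption (as [elementary_step()] reports them).
#'
#' @param ledger A ledger tibble (see [invasion_ledger()]).
#' @param event A one-row event tibble from [elementary_step()]; must involve
#'   players of differing strategies.
#' @return The updated ledger.
#' @export
record_event <- function(ledger, event) {
  if (is.null(event) || nrow(event) == 0) return(ledger)
  if (event$s_i == event$s_j)
    stop("same-strategy events are not invasions", call. = FALSE)
  if (!event$adopted) return(ledger)
  chan <- paste0(gsub("_", "", event$sub_i), "<-", gsub("_", "", event$sub_j))
  hit <- ledger$mcs == event$mcs & ledger$channel == chan
  if (any(hit)) {
    ledger$count[hit] <- ledger$count[hit] + 1L
  } else {
    ledger <- dplyr::bind_rows(
      ledger,
      tibble::tibble(mcs = event$mcs, channel = chan, count = 1L))
  }
  ledger
}

#' Net cooperator gain recorded in a ledger
#'
#' Sums successful adoptions on cooperator-gain channels (a defector adopted
#' C) minus those on cooperator-loss channels.  This bookkeeping is exact:
#' over any window it equals the change in cooperator count.
#'
#' @param ledger A ledger tibble (`mcs`, `channel`, `count`).
#' @param per_mcs Return a per-MCS tibble instead of the total.
#' @return Integer net gain, or a tibble (`mcs`, `net`) when `per_mcs`.
#' @export
ledger_net_gain <- function(ledger, per_mcs = FALSE) {
  gain <- substr(ledger$channel, 5, 5) == "C"  # invader cooperates
  signed <- ifelse(gain, ledger$count, -ledger$count)
  if (!per_mcs) return(sum(signed))
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(mcs = ledger$mcs, signed = signed), .data$mcs),
    net = sum(.data$signed), .groups = "drop")
}

#' Stationary average of a cooperator-fraction trajectory
#'
#' Arithmetic mean of the last `window` values of a `rho_C` time series; when
#' the run absorbed earlier (homogeneous lattice), the absorbed value — which
#' the series can never leave — is returned instead.
#'
#' @param rho Numeric `rho_C` series, one value per MCS.
#' @param window Number of trailing MCS to average over; must not exceed the
#'   series length.
#' @param absorbed_value Absorbed `rho_C` (0 or 1) if the run fixated, else
#'   `NULL`.
#' @return The stationary cooperator fraction.
#' @export
stationary_average <- function(rho, window, absorbed_value = NULL) {
  if (!is.null(absorbed_value)) return(absorbed_value)
  if (window < 1 || window > length(rho))
    stop("measurement window must lie within the trajectory", call. = FALSE)
  mean(rho[(length(rho) - window + 1):length(rho)])
}

#' Export an invasion ledger as delimited text
#'
#' Writes `mcs`, `channel`, `count` plus the per-MCS net cooperator gain as
#' tab-separated text.
#'
#' @param ledger A ledger tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  net <- ledger_net_gain(ledger, per_mcs = TRUE)
  out <- dplyr::left_join(ledger, net, by = "mcs")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
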