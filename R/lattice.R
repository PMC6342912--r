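#' @useDynLib memlattice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

STRAT_C <- 1L
STRAT_D <- 0L

new_lattice_state <- function(strategies, time = 0L) {
  L <- nrow(strategies)
  structure(
    list(
      L = L,
      strategies = strategies,           # integer matrix, 1 = C, 0 = D
      time = as.integer(time),           # elapsed full Monte Carlo steps
      payoff_history = vector("list", L * L),   # newest first, per site
      strategy_history = vector("list", L * L)  # per-MCS records, newest first
    ),
    class = "lattice_state"
  )
}

#' Random 50/50 initial lattice
#'
#' Builds a toroidal `L` x `L` lattice where every site is independently a
#' cooperator or a defector with probability 1/2, the standard random initial
#' condition for stationary-state measurements.
#'
#' @param L Linear lattice size (sites per side), `L >= 3`.
#' @param seed Optional integer seed; when supplied the global RNG is seeded
#'   before drawing, so equal seeds give identical lattices.
#' @return A `lattice_state`: the strategy grid plus (initially empty) per-site
#'   payoff and strategy histories and the elapsed time in Monte Carlo steps.
#' @examples
#' st <- lattice_random(20, seed = 1)
#' rho_c(st)
#' @export
lattice_random <- function(L, seed = NULL) {
  stopifnot(is.numeric(L), length(L) == 1, L == as.integer(L))
  if (L < 3) stop("L must be at least 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(L)
  strat <- matrix(as.integer(runif(L * L) < 0.5), L, L)
  new_lattice_state(strat)
}

#' Prepared circular cooperative domain
#'
#' Builds the prepared initial condition used in fixation experiments: a round
#' cooperative domain of the given radius, centred on the lattice, surrounded
#' by defectors.  A site is a cooperator iff its Euclidean distance from the
#' central site is at most `radius` (inclusive).
#'
#' @param L Linear lattice size, `L >= 3`.
#' @param radius Domain radius in lattice units, `0 <= radius <= L/2`
#'   (larger domains would wrap around the torus).  Default `L/4`, a sizable
#'   but non-wrapping domain.
#' @return A `lattice_state`.
#' @examples
#' st <- lattice_circular(101, radius = 3)
#' sum(st$strategies)  # 29 cooperators
#' @export
lattice_circular <- function(L, radius = floor(L / 4)) {
  stopifnot(is.numeric(L), length(L) == 1, L == as.integer(L))
  if (L < 3) stop("L must be at least 3", call. = FALSE)
  if (radius < 0 || radius > L / 2)
    stop("radius must lie in [0, L/2]", call. = FALSE)
  L <- as.integer(L)
  ctr <- floor(L / 2) + 1L  # 1-based centre
  rows <- matrix(seq_len(L), L, L)
  cols <- matrix(seq_len(L), L, L, byrow = TRUE)
  inside <- (rows - ctr)^2 + (cols - ctr)^2 <= radius^2
  new_lattice_state(matrix(as.integer(inside), L, L))
}

#' Von Neumann neighbors of a lattice site
#'
#' Returns the four orthogonally adjacent sites of `site` on the periodic
#' lattice, in the fixed order up, down, left, right (up = row - 1).  Random
#' neighbor selection during the dynamics draws uniformly over this order.
#'
#' @param state A `lattice_state`.
#' @param site Integer vector `c(row, column)`, 1-based.
#' @return A 4 x 2 integer matrix of `(row, column)` pairs, rows ordered
#'   up, down, left, right.
#' @examples
#' neighbors(lattice_random(5, seed = 1), c(1, 1))
#' @export
neighbors <- function(state, site) {
  L <- state$L
  r <- site[1]; c <- site[2]
  if (r < 1 || r > L || c < 1 || c > L)
    stop("site out of range", call. = FALSE)
  wrap <- function(x) ((x - 1L) %% L) + 1L
  m <- rbind(
    up    = c(wrap(r - 1L), c),
    down  = c(wrap(r + 1L), c),
    left  = c(r, wrap(c - 1L)),
    right = c(r, wrap(c + 1L))
  )
  storage.mode(m) <- "integer"
  colnames(m) <- c("row", "col")
  m
}

#' Accrued payoff of a site against its four neighbors
#'
#' Sums the pairwise game payoff of the focal site against each of its four
#' von Neumann neighbors: C vs C pays R = 1, C vs D pays S, D vs C pays T,
#' D vs D pays P = 0.
#'
#' @param state A `lattice_state`.
#' @param site `c(row, column)`, 1-based.
#' @param params A [game_params()] object.
#' @return A single payoff in `[4 * min(S, 0), 4 * max(T, 1)]`.
#' @examples
#' st <- lattice_circular(9, radius = 2)
#' accrue_payoff(st, c(5, 5), game_params(T = 1.3, S = -0.1))
#' @export
accrue_payoff <- function(state, site, params) {
  nb <- neighbors(state, site)
  s_i <- state$strategies[site[1], site[2]]
  # summed pairwise in neighbor order, matching the compiled core bit-for-bit
  total <- 0
  for (k in 1:4) {
    s_j <- state$strategies[nb[k, 1], nb[k, 2]]
    total <- total +
      if (s_i == STRAT_C) (if (s_j == STRAT_C) params$R else params$S)
      else                (if (s_j == STRAT_C) params$T else params$P)
  }
  total
}

#' Fraction of cooperators on the lattice
#'
#' @param state A `lattice_state`.
#' @return `N_C / L^2`, in `[0, 1]`.
#' @export
rho_c <- function(state) {
  mean(state$strategies == STRAT_C)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d x %d, t = %d MCS, rho_C = %.4f\n",
              x$L, x$L, x$time, rho_c(x)))
  invisible(x)
}

#' Tidy a lattice snapshot
#'
#' @param x A `lattice_state`.
#' @param ... Unused.
#' @return A tibble with one row per site: `row`, `col`, `strategy`
#'   (`"C"`/`"D"`).
#' @export
as_tibble.lattice_state <- function(x, ...) {
  L <- x$L
  tibble::tibble(
    row = rep(seq_len(L), times = L),
    col = rep(seq_len(L), each = L),
    strategy = ifelse(as.vector(x$strategies) == STRAT_C, "C", "D")
  )
}

#' Write / read a lattice snapshot as delimited text
#'
#' One line per lattice row, cells in `{C, D}` separated by spaces.
#'
#' @param state A `lattice_state`.
#' @param path File path.
#' @return `write_lattice` returns `path` invisibly; `read_lattice` returns a
#'   `lattice_state` with empty histories and `time = 0`.
#' @export
write_lattice <- function(state, path) {
  chr <- ifelse(state$strategies == STRAT_C, "C", "D")
  writeLines(apply(chr, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  L <- length(rows)
  if (any(lengths(rows) != L)) stop("snapshot is not square", call. = FALSE)
  strat <- t(vapply(rows, function(r) as.integer(r == "C"), integer(L)))
  if (any(!unlist(rows) %in% c("C", "D")))
    stop("snapshot contains symbols other than C/D", call. = FALSE)
  new_lattice_state(strat)
}
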