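# Independent brute-force oracles, written deliberately apart from the
# package implementation: explicit payoff-matrix lookups, plain loops, naive
# formula evaluation.

# Payoff of the site at (r, c) against its four neighbors, via an explicit
# 2x2 payoff matrix indexed by (focal strategy, neighbor strategy).
oracle_accrue <- function(grid, r, c, T, S) {
  L <- nrow(grid)
  # rows: focal D, C; cols: opponent D, C
  paymat <- matrix(c(0, S, T, 1), nrow = 2,
                   dimnames = list(c("D", "C"), c("D", "C")))
  lab <- function(s) if (s == 1) "C" else "D"
  wrap <- function(x) ((x - 1) %% L) + 1
  total <- 0
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- grid[wrap(r + d[1]), wrap(c + d[2])]
    total <- total + paymat[lab(grid[r, c]), lab(nb)]
  }
  total
}

# Memory length by direct enumeration of the geometric weights.
oracle_memory_length <- function(alpha, threshold = 0.01) {
  if (alpha == 0) return(0L)
  m <- 0L
  while (alpha^(m + 1) >= threshold) m <- m + 1L
  m
}

# Finite-sum evaluation of the weighted moving average over a newest-first
# history, truncating to the available entries.
oracle_averaged <- function(history, alpha, M = oracle_memory_length(alpha)) {
  k <- min(length(history), M + 1)
  num <- 0
  den <- 0
  for (m in 0:(k - 1)) {
    num <- num + alpha^m * history[m + 1]
    den <- den + alpha^m
  }
  num / den
}

# Hand-coded reference simulator for the memoryless game: consumes the same
# scripted uniform stream as the package core (focal site, neighbor index,
# adoption Bernoulli per elementary step) and returns the per-step trace.
oracle_mcs_none <- function(grid, T, S, K, u) {
  L <- nrow(grid)
  N <- L * L
  wrap <- function(x) ((x - 1) %% L) + 1
  trace <- vector("list", N)
  pos <- 0
  nxt <- function() {
    pos <<- pos + 1
    u[pos]
  }
  for (step in seq_len(N)) {
    idx <- floor(nxt() * N)            # 0-based row-major
    ri <- idx %/% L + 1
    ci <- idx %% L + 1
    nbrs <- list(c(wrap(ri - 1), ci), c(wrap(ri + 1), ci),
                 c(ri, wrap(ci - 1)), c(ri, wrap(ci + 1)))
    nb <- nbrs[[floor(nxt() * 4) + 1]]
    p_i <- oracle_accrue(grid, ri, ci, T, S)
    p_j <- oracle_accrue(grid, nb[1], nb[2], T, S)
    W <- 1 / (1 + exp((p_i - p_j) / K))
    u_adopt <- nxt()
    s_i <- grid[ri, ci]
    s_j <- grid[nb[1], nb[2]]
    adopted <- (s_i != s_j) && (u_adopt < W)
    if (adopted) grid[ri, ci] <- s_j
    trace[[step]] <- data.frame(
      focal = as.integer(idx),
      neighbor = as.integer((nb[1] - 1) * L + (nb[2] - 1)),
      p_raw_i = p_i, p_raw_j = p_j, W = W,
      s_i = s_i, s_j = s_j, adopted = as.integer(adopted))
  }
  list(grid = grid, trace = do.call(rbind, trace))
}

# Count of integer offsets within Euclidean distance `radius` of the origin.
oracle_disc_count <- function(radius) {
  n <- 0
  for (dx in -ceiling(radius):ceiling(radius))
    for (dy in -ceiling(radius):ceiling(radius))
      if (dx^2 + dy^2 <= radius^2) n <- n + 1
  n
}

# Deterministic all-C / all-D lattices for absorbing-state checks.
make_uniform_lattice <- function(L, strategy) {
  st <- lattice_circular(L, 0)
  st$strategies[, ] <- if (strategy == "C") 1L else 0L
  st
}
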