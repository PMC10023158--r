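# Independent oracles used across the suite. These deliberately re-derive
# quantities with different code paths than the package implementation.

# complex-arithmetic oracle for preferred direction and DSI
oracle_vector_sum <- function(directions, response) {
  z <- sum(response * exp(1i * directions * pi / 180))
  list(pd = (Arg(z) * 180 / pi) %% 360,
       dsi = Mod(z) / sum(response))
}

# circular trapezoid oracle for tuning-curve area (degrees domain / 360)
oracle_trap_area <- function(directions, response) {
  d <- c(directions, directions[1] + 360)
  m <- c(response, response[1])
  sum(diff(d) * (head(m, -1) + tail(m, -1)) / 2) / 360
}

# naive step-by-step forward-Euler reference integrator (no vectorized
# precomputation; spiking rule written independently)
oracle_euler <- function(set, j, gain_ex = 1, gain_in = 1, spiking = TRUE) {
  dt_ms <- set$dt * 1000
  n <- nrow(set$g_in)
  v <- numeric(n)
  v[1] <- set$E_rest_mv
  n_ref <- as.integer(round(set$t_refr_s / set$dt))
  spikes <- 0L
  i <- 1L
  while (i < n) {
    gex <- gain_ex * set$g_ex[i]
    gin <- gain_in * set$g_in[i, j]
    dv <- dt_ms / set$C_pf *
      (gex * (set$E_ex_mv - v[i]) + gin * (set$E_in_mv - v[i]) +
         set$G_rest_ns * (set$E_rest_mv - v[i]))
    vn <- v[i] + dv
    if (spiking && vn > set$V_thresh_mv) {
      spikes <- spikes + 1L
      v[i + 1L] <- vn
      stopv <- min(n, i + 1L + n_ref)
      if (i + 2L <= stopv) v[(i + 2L):stopv] <- set$E_rest_mv
      i <- i + 1L + n_ref
    } else {
      v[i + 1L] <- vn
      i <- i + 1L
    }
  }
  list(vm = v, n_spikes = spikes)
}

# brute-force all-pairs distance histogram (unnormalized DRP bin counts)
oracle_pair_histogram <- function(xy, edges) {
  n <- nrow(xy)
  counts <- numeric(length(edges) - 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
      k <- findInterval(dd, edges, rightmost.closed = FALSE)
      if (k >= 1 && k <= length(counts) && dd < edges[k + 1L]) {
        counts[k] <- counts[k] + 1
      }
    }
  }
  counts
}

# small helper: a directional_response from a bare vector
dr <- function(x, ...) directional_response(x, ...)
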