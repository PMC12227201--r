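#' Population firing rates from a spike raster
#'
#' Per-neuron spike counts divided by the window length, summarized per
#' recording window by the population mean and standard deviation. Windows of
#' 5 s (long) and 1 s (short) are the conventional choices.
#'
#' @param raster A data.frame with columns `neuron` (1-based id) and `t_ms`.
#' @param window Window length (s).
#' @param population Integer vector of neuron ids forming the population.
#' @param t_from,t_to Analysis span (s); defaults to `[0, max spike time]`
#'   rounded up to a whole window.
#' @return A data.frame with one row per window: `t` (window end, s),
#'   `rate_mean`, `rate_sd` (Hz).
#' @export
firing_rates <- function(raster, window = 5, population,
                         t_from = 0, t_to = NULL) {
  stopifnot(window > 0, length(population) > 0)
  t_s <- raster$t_ms / 1000
  if (is.null(t_to))
    t_to <- if (nrow(raster)) ceiling(max(t_s) / window) * window else window
  n_win <- max(1L, as.integer(round((t_to - t_from) / window)))
  keep <- raster$neuron %in% population & t_s > t_from & t_s <= t_to
  wi <- pmin(n_win, floor((t_s[keep] - t_from) / window) + 1L)
  ni <- match(raster$neuron[keep], population)
  counts <- matrix(0, nrow = length(population), ncol = n_win)
  if (length(wi))
    for (k in seq_along(wi))
      counts[ni[k], wi[k]] <- counts[ni[k], wi[k]] + 1
  rates <- counts / window
  data.frame(t = t_from + seq_len(n_win) * window,
             rate_mean = colMeans(rates),
             rate_sd = apply(rates, 2, stats::sd))
}

#' Block-averaged connectivity
#'
#' Mean entry of a connectivity matrix over a (rows x cols) block:
#' `Gamma = 1/(m n) * sum A_ij` over postsynaptic ids `rows_pop` and
#' presynaptic ids `cols_pop`. When the two populations are identical the
#' diagonal is excluded from the average (autapses are impossible by
#' construction). Multapses make values above 1 possible in principle.
#'
#' @param A Connectivity matrix (rows postsynaptic, columns presynaptic);
#'   dense or sparse.
#' @param rows_pop,cols_pop Integer id vectors selecting the block.
#' @return The block mean (a fraction for 0/1 counts).
#' @export
block_connectivity <- function(A, rows_pop, cols_pop = rows_pop) {
  stopifnot(length(rows_pop) > 0, length(cols_pop) > 0)
  B <- A[rows_pop, cols_pop, drop = FALSE]
  tot <- sum(B)
  n_pairs <- length(rows_pop) * length(cols_pop)
  if (identical(sort(rows_pop), sort(cols_pop))) {
    tot <- tot - sum(Matrix::diag(B))
    n_pairs <- n_pairs - length(rows_pop)
  }
  if (n_pairs == 0) return(NA_real_)
  as.numeric(tot) / n_pairs
}

#' Effective connectivity from a weight matrix
#'
#' Block average of the weight matrix expressed in unit synapses: the summed
#' weights are divided by the uniform unit weight (0.1 mV), so that with
#' uniform 0.1 mV weights effective and structural connectivity coincide
#' exactly.
#'
#' @param W Weight matrix (mV; rows postsynaptic).
#' @inheritParams block_connectivity
#' @param unit_w Unit synaptic weight (mV).
#' @return Block-averaged equivalent number of unit synapses per pair.
#' @export
effective_connectivity <- function(W, rows_pop, cols_pop = rows_pop,
                                   unit_w = 0.1) {
  block_connectivity(W / unit_w, rows_pop, cols_pop)
}

#' Per-neuron synapse counts
#'
#' Input (in-degree) and output (out-degree) synapse numbers from the
#' structural connectivity matrix: row sums are inputs, column sums outputs.
#'
#' @param A Count matrix (rows postsynaptic).
#' @return A data.frame with `neuron`, `indegree`, `outdegree`.
#' @export
synapse_counts <- function(A) {
  data.frame(neuron = seq_len(nrow(A)),
             indegree = as.numeric(Matrix::rowSums(A)),
             outdegree = as.numeric(Matrix::colSums(A)))
}

#' Signed deviation area of a trace from its target
#'
#' Trapezoidal integral of `(trace(t) - target)` over `[t_from, t_to]`, the
#' recovery index used to score perturbation outcomes (target 10%
#' connectivity, or the 7.9 Hz setpoint rate). Endpoint values are obtained
#' by linear interpolation when `t_from`/`t_to` fall between grid points.
#' The area is additive over adjacent intervals.
#'
#' @param t Time grid (s), increasing.
#' @param y Trace values on the grid.
#' @param target Target level.
#' @param t_from,t_to Integration bounds (within the grid span).
#' @return Signed area in units of `y` times seconds.
#' @export
deviation_area <- function(t, y, target, t_from = min(t), t_to = max(t)) {
  stopifnot(length(t) == length(y), t_from < t_to,
            t_from >= min(t), t_to <= max(t))
  keep <- t > t_from & t < t_to
  tt <- c(t_from, t[keep], t_to)
  yy <- c(stats::approx(t, y, t_from)$y, y[keep],
          stats::approx(t, y, t_to)$y) - target
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' Joint activity / synapse-number histogram
#'
#' 2-D histogram of per-neuron firing rate against in-degree, the summary
#' used to visualize the bimodal outcome of unstabilized biphasic growth
#' (silent isolated neurons versus active neurons near the setpoint).
#'
#' @param rates Per-neuron firing rates (Hz).
#' @param indegrees Per-neuron input synapse counts.
#' @param rate_breaks,indegree_breaks Break vectors or bin counts as accepted
#'   by [base::cut()]-style binning via [base::findInterval()]; default 20
#'   equal bins over each range.
#' @return A list with `counts` (matrix rate-bins x indegree-bins),
#'   `rate_breaks`, `indegree_breaks`.
#' @export
activity_synapse_heatmap <- function(rates, indegrees,
                                     rate_breaks = 20, indegree_breaks = 20) {
  stopifnot(length(rates) == length(indegrees))
  mk <- function(x, br) {
    if (length(br) == 1) {
      rng <- range(x)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      br <- seq(rng[1], rng[2], length.out = br + 1)
    }
    br
  }
  rb <- mk(rates, rate_breaks); ib <- mk(indegrees, indegree_breaks)
  ri <- pmin(length(rb) - 1, pmax(1, findInterval(rates, rb,
                                                  rightmost.closed = TRUE)))
  ii <- pmin(length(ib) - 1, pmax(1, findInterval(indegrees, ib,
                                                  rightmost.closed = TRUE)))
  counts <- matrix(0L, length(rb) - 1, length(ib) - 1)
  for (k in seq_along(ri))
    counts[ri[k], ii[k]] <- counts[ri[k], ii[k]] + 1L
  list(counts = counts, rate_breaks = rb, indegree_breaks = ib)
}
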