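#' Homeostatic scaling of synaptic weights
#'
#' Discrete update of the multiplicative, cell-autonomous scaling rule: every
#' synapse onto postsynaptic neuron j is multiplied by
#' `1 + rho * dt * (epsilon - C_j)` (with `sign = -1`, the drive is reversed
#' to the `(C_j - epsilon)` convention). All synapses onto the same neuron
#' scale by the same factor, so weight ratios within a neuron's input are
#' preserved. Weights are clamped at `w_min`. In the continuous limit with
#' constant calcium the weight follows
#' `w(t) = w0 * exp(rho * (epsilon - C) * t)`.
#'
#' @param store A [synapse_store()].
#' @param C_post Per-excitatory-neuron calcium concentrations (indexed by
#'   `store$post`).
#' @param dt Step (s).
#' @param params A [scaling_params()].
#' @return The updated `synapse_store`.
#' @export
scale_weights <- function(store, C_post, dt, params = scaling_params()) {
  stopifnot(inherits(store, "synapse_store"), dt > 0)
  if (params$rho == 0 || length(store$w) == 0) return(store)
  f <- pmax(0, 1 + params$rho * dt * params$sign *
              (params$epsilon - C_post[store$post]))
  store$w <- pmax(params$w_min, store$w * f)
  store
}

#' Structural and effective weight matrices of a store
#'
#' `count_matrix` gives the synapse-count matrix (entry (i, j) = number of
#' synapses from presynaptic neuron j onto postsynaptic neuron i: columns are
#' presynaptic, rows postsynaptic). `effective_weight_matrix` sums the
#' individual weights per pair, in mV.
#'
#' @param store A [synapse_store()].
#' @param n_e Number of excitatory neurons (matrix dimension).
#' @return A sparse `dgCMatrix` (n_e x n_e).
#' @export
count_matrix <- function(store, n_e) {
  Matrix::sparseMatrix(i = store$post, j = store$pre,
                       x = rep(1, length(store$pre)),
                       dims = c(n_e, n_e))
}

#' @rdname count_matrix
#' @export
effective_weight_matrix <- function(store, n_e) {
  Matrix::sparseMatrix(i = store$post, j = store$pre, x = store$w,
                       dims = c(n_e, n_e))
}
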