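#' Write / read connectivity snapshots
#'
#' A snapshot consists of the E-E synapse-count matrix and the matched weight
#' matrix (same sparsity pattern) in Matrix Market format, plus a small JSON
#' manifest linking the files to the simulation time and configuration.
#' Round-tripping is lossless.
#'
#' @param net An `hsp_network` (or pass `store` + `n_e` explicitly).
#' @param dir Output directory (created if missing).
#' @param tag File-name tag; defaults to the current simulation time.
#' @param store,n_e Alternative input: a [synapse_store()] and the number of
#'   excitatory neurons.
#' @param t Snapshot time (s) recorded in the manifest.
#' @return (Invisibly) the manifest path.
#' @export
write_snapshot <- function(net = NULL, dir, tag = NULL,
                           store = network_store(net),
                           n_e = net$config$N_E,
                           t = if (is.null(net)) NA_real_ else net$state$t_now_s) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(tag)) tag <- sprintf("t%010.3f", t)
  fc <- file.path(dir, paste0("counts_", tag, ".mtx"))
  fw <- file.path(dir, paste0("weights_", tag, ".mtx"))
  Matrix::writeMM(count_matrix(store, n_e), fc)
  Matrix::writeMM(effective_weight_matrix(store, n_e), fw)
  man <- list(tag = tag, t = t, n_e = n_e,
              n_synapses = length(store$pre),
              counts = basename(fc), weights = basename(fw))
  fm <- file.path(dir, paste0("snapshot_", tag, ".json"))
  jsonlite::write_json(man, fm, auto_unbox = TRUE, digits = NA)
  invisible(fm)
}

#' @rdname write_snapshot
#' @param manifest Path to the snapshot manifest JSON.
#' @return `read_snapshot`: list with `counts` and `weights` sparse matrices,
#'   `store` reconstructed from them, and the manifest fields.
#' @export
read_snapshot <- function(manifest) {
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  counts <- methods::as(Matrix::readMM(file.path(dir, man$counts)), "CsparseMatrix")
  weights <- methods::as(Matrix::readMM(file.path(dir, man$weights)), "CsparseMatrix")
  tw <- Matrix::mat2triplet(weights)
  tc <- Matrix::mat2triplet(counts)
  o <- order(tc$j, tc$i)
  pre <- rep(tc$j[o], tc$x[o]); post <- rep(tc$i[o], tc$x[o])
  ow <- order(tw$j, tw$i)
  w <- rep(tw$x[ow] / tc$x[o], tc$x[o])   # mean weight per pair
  list(counts = counts, weights = weights,
       store = synapse_store(pre, post, w),
       t = man$t, n_e = man$n_e, tag = man$tag)
}

#' Write / read a spike raster
#'
#' Two-column tab-separated raster: `neuron_id` (0-based, excitatory ids
#' before inhibitory ids) and `spike_time_ms`.
#'
#' @param raster Data.frame with `neuron` (1-based) and `t_ms`.
#' @param path Output file.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(
    data.frame(neuron_id = raster$neuron - 1L, spike_time_ms = raster$t_ms),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @return `read_raster`: the raster data.frame (1-based ids).
#' @export
read_raster <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("neuron_id", "spike_time_ms") %in% names(d)))
    stop("not a raster file: ", path)
  data.frame(neuron = d$neuron_id + 1L, t_ms = d$spike_time_ms)
}

#' Write / read a recorded trace table
#'
#' Tab-separated table of the per-window population rates and block
#' connectivities recorded by [run_phase()].
#'
#' @param trace The `net$trace` data.frame.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t")

#' Write a run manifest
#'
#' Records the full configuration, parameters, seeds and package version of a
#' run next to its outputs.
#'
#' @param net An `hsp_network`.
#' @param path Output JSON path.
#' @param seed The seed(s) used.
#' @param extra Named list of additional fields.
#' @export
write_manifest <- function(net, path, seed = NA, extra = list()) {
  man <- c(list(
    package = "hspnet",
    version = as.character(utils::packageVersion("hspnet")),
    seed = seed,
    t_now_s = net$state$t_now_s,
    config = unclass(net$config),
    neuron = unclass(net$neuron),
    calcium = unclass(net$calcium),
    rule_axonal = unclass(net$rule_axonal),
    rule_dendritic = unclass(net$rule_dendritic),
    scaling = unclass(net$scaling),
    subpop = net$subpop), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a declarative run configuration
#'
#' YAML key-value file whose field names mirror the model tables
#' (`tau_m`, `t_ref`, `V_rest`, `V_reset`, `V_th`, `C_mem`; `N_E`, `N_I`,
#' `p_static`, `J_E`, `J_I`, `J_ext`, `r_ext`, `delay`, `dt`; `tau_Ca`,
#' `beta_Ca`; and a `rule:` block with `variant`, `nu`, `epsilon`, `eta`,
#' `nu_multiplier`). Missing fields fall back to the defaults.
#'
#' @param path YAML file.
#' @return List with `config`, `neuron`, `calcium`, `rule`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(fun, keys) {
    a <- y[intersect(keys, names(y))]
    do.call(fun, a)
  }
  rule <- if (!is.null(y$rule)) {
    do.call(growth_rule, y$rule[intersect(
      c("variant", "nu", "epsilon", "eta", "nu_multiplier"), names(y$rule))])
  } else rule_linear()
  list(
    config = take(network_config, c("N_E", "N_I", "p_static", "J_E", "J_I",
                                    "J_ext", "r_ext", "delay", "dt")),
    neuron = take(neuron_params, c("tau_m", "t_ref", "V_rest", "V_reset",
                                   "V_th", "C_mem")),
    calcium = take(calcium_params, c("tau_Ca", "beta_Ca")),
    rule = rule)
}
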