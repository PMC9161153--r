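#' Save and load centroid-force record sets
#'
#' Record sets serialize to a schema-versioned JSON document (one
#' object per record: geometry, mean/classical forces, SEMs,
#' metadata), so training data are portable plain text.
#'
#' @param records list of \code{centroid_force_record}s (or a
#'   \code{training_set}).
#' @param path file path.
#' @return \code{save_records}: the path, invisibly;
#'   \code{load_records}: the list of records.
#' @export
save_records <- function(records, path) {
  if (inherits(records, "centroid_force_record")) records <- list(records)
  doc <- list(
    schema = "mlcmd_records",
    version = 1L,
    records = lapply(records, function(r) list(
      elements = r$geometry$elements,
      positions = r$geometry$positions,
      masses = r$geometry$masses,
      cell = r$geometry$cell,
      mean_force = r$mean_force,
      force_sem = r$force_sem,
      classical_force = r$classical_force,
      converged = r$converged,
      meta = r$meta)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_records
#' @export
load_records <- function(path) {
  doc <- jsonlite::read_json(path)   # no simplification: stable shapes
  if (!identical(doc$schema, "mlcmd_records"))
    stop("not an mlcmd record file: ", path)
  lapply(doc$records, function(r) {
    geom <- molecular_configuration(unlist(r$elements),
                                    .as_mat3(r$positions),
                                    masses = unlist(r$masses),
                                    cell = if (length(r$cell)) unlist(r$cell))
    centroid_force_record(geom, .as_mat3(r$mean_force),
                          .as_mat3(r$classical_force),
                          force_sem = .as_mat3(r$force_sem),
                          meta = lapply(r$meta, function(z)
                            if (is.list(z)) unlist(z) else z))
  })
}

.as_mat3 <- function(x) {
  m <- if (is.list(x)) do.call(rbind, lapply(x, unlist)) else as.matrix(x)
  matrix(as.numeric(m), ncol = 3)
}

#' Save and load a trained correction model
#'
#' The full model bundle (descriptor parameters, feature scaling,
#' per-element network weights, training metadata) in versioned JSON.
#'
#' @param model a \code{correction_model}.
#' @param path file path.
#' @return \code{save_correction_model}: the path, invisibly;
#'   \code{load_correction_model}: the model.
#' @export
save_correction_model <- function(model, path) {
  doc <- list(
    schema = "mlcmd_correction_model",
    version = 1L,
    params = unclass(model$params),
    hidden = model$hidden,
    elements = model$elements,
    feature_scale = model$feature_scale,
    meta = model$meta,
    nets = lapply(model$nets, function(n)
      list(W1 = n$W1, b1 = n$b1, W2 = n$W2, b2 = n$b2, w3 = n$w3)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_correction_model
#' @export
load_correction_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "mlcmd_correction_model"))
    stop("not an mlcmd model file: ", path)
  params <- doc$params
  params$embed <- if (!is.null(params$embed))
    stats::setNames(unlist(params$embed), params$elements)
  class(params) <- "descriptor_params"
  nets <- lapply(doc$nets, function(n)
    list(W1 = as.matrix(n$W1), b1 = as.numeric(n$b1),
         W2 = as.matrix(n$W2), b2 = as.numeric(n$b2),
         w3 = as.numeric(n$w3)))
  structure(list(params = params, hidden = unlist(doc$hidden),
                 nets = nets, elements = unlist(doc$elements),
                 feature_scale = if (length(doc$feature_scale))
                   as.numeric(doc$feature_scale),
                 meta = as.list(doc$meta)),
            class = "correction_model")
}

#' Read a simulation configuration file
#'
#' YAML schema with blocks \code{system} (potential kind and
#' parameters), \code{thermostat} (friction, temperature),
#' \code{beads}, \code{seeds}, \code{cutoffs} — the file interface the
#' command-line tools consume.  Unknown keys are preserved.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  yaml::read_yaml(path)
}

#' Build a potential from a config block
#'
#' @param block list with \code{kind} and its parameters (as from
#'   [read_config()]).
#' @return a \code{potential_surface}.
#' @export
potential_from_config <- function(block) {
  kind <- block$kind
  if (is.null(kind)) stop("potential block needs a 'kind'")
  args <- block[setdiff(names(block), "kind")]
  fn <- switch(kind,
    harmonic1d = harmonic1d, quartic1d = quartic1d, morse1d = morse1d,
    free1d = free1d, lj_coulomb_cluster = lj_coulomb_cluster,
    toywater3 = toywater3, periodic_pair_fluid = periodic_pair_fluid,
    ideal = ideal_gas,
    stop("unknown potential kind: ", kind))
  do.call(fn, args)
}
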