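# Dataset container and persistence. A dataset is the training-set artifact:
# a header (atoms, masses, state count, units, phase reference, provenance)
# plus one record per data point (flat geometry, electronic properties,
# phase log, source tag). Persisted with R's native serialization plus an
# md5 checksum over the payload so truncated or tampered files are rejected
# on load.

.dataset_schema <- "mlphotodyn-dataset-1"

#' Create a dataset
#'
#' @param header List with (at least) `n_states`, `n_dof`, `masses_au`;
#'   optionally `atoms`, `units`, `phase_reference`, `provenance`,
#'   `descriptor`.
#' @param records List of records, each a list with `x` (flat Bohr
#'   coordinates), `props` ([elecprops()]), optional `phase` and `source`
#'   (`"normal_mode"`, `"adaptive"` or `"manual"`).
#' @return Object of class `"pd_dataset"`.
#' @export
new_dataset <- function(header, records = list()) {
  stopifnot(is.list(header), !is.null(header$n_states), !is.null(header$n_dof))
  header$units <- header$units %||% list(length = "Bohr", energy = "Hartree")
  header$schema <- .dataset_schema
  ds <- structure(list(header = header, records = list()), class = "pd_dataset")
  for (r in records) ds <- append_record(ds, r)
  ds
}

#' @rdname new_dataset
#' @param ds A dataset.
#' @param record A record (see `records`).
#' @export
append_record <- function(ds, record) {
  stopifnot(inherits(ds, "pd_dataset"))
  if (length(record$x) != ds$header$n_dof)
    stop("record geometry has ", length(record$x), " dof, header says ",
         ds$header$n_dof)
  if (length(record$props$energies) != ds$header$n_states)
    stop("record state count does not match header")
  record$source <- record$source %||% "manual"
  ds$records[[length(ds$records) + 1L]] <- record
  ds
}

#' @export
print.pd_dataset <- function(x, ...) {
  src <- table(vapply(x$records, function(r) r$source %||% "manual", character(1)))
  cat(sprintf("<pd_dataset> %d records, %d states, %d dof (%s)\n",
              length(x$records), x$header$n_states, x$header$n_dof,
              paste(names(src), src, sep = ":", collapse = ", ")))
  invisible(x)
}

payload_md5 <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

#' Read / write datasets (and other package objects) with checksums
#'
#' Lossless round trip of all numeric fields; the stored md5 checksum of the
#' payload is verified on load and mismatches (truncation, corruption) abort
#' without a partial load.
#'
#' @param ds Dataset (or any package object) to write.
#' @param path File path.
#' @return `read_dataset()` returns the dataset; `write_dataset()` the path,
#'   invisibly.
#' @export
write_dataset <- function(ds, path) {
  saveRDS(list(schema = .dataset_schema, payload = ds,
               checksum = payload_md5(ds)), path, version = 2)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read dataset file ", path,
                                           ": ", conditionMessage(e)))
  if (!identical(obj$schema, .dataset_schema))
    stop("unsupported dataset schema: ", obj$schema %||% "<missing>")
  if (!identical(payload_md5(obj$payload), obj$checksum))
    stop("checksum mismatch in ", path, "; refusing partial/corrupt load")
  obj$payload
}

#' Build a dataset by evaluating a provider on a list of geometries
#'
#' @param provider An `es_provider`.
#' @param geometries List of flat coordinate vectors (Bohr).
#' @param source Source tag stored on every record.
#' @param atoms Optional element labels for the header.
#' @return A [new_dataset()] whose header carries the provider's state
#'   count, dof and masses.
#' @export
evaluate_dataset <- function(provider, geometries, source = "manual",
                             atoms = NULL) {
  header <- list(n_states = provider$n_states, n_dof = provider$n_dof,
                 masses_au = provider$masses, atoms = atoms %||% provider$atoms,
                 provenance = provider$name %||% class(provider)[1],
                 descriptor = if (provider$n_dof == 1) "coordinate" else "inverse_distance")
  recs <- lapply(geometries, function(x)
    list(x = as.numeric(x), props = eval_properties(provider, x),
         source = source))
  new_dataset(header, recs)
}

#' Write a population table as delimited text
#'
#' @param pop Population data frame.
#' @param path Output path (tab-separated).
#' @return The path, invisibly.
#' @export
write_populations <- function(pop, path) {
  utils::write.table(pop, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_populations
#' @export
read_populations <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
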