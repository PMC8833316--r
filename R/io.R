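EPOCH_SCHEMA_VERSION <- "1.0"

#' Write / read the epoch container
#'
#' Serialises an [epoch_set()] to the package's native container (R
#' serialisation with an explicit schema version): data array
#' `trials x channels x samples`, time axis, sampling rate, subject/group
#' labels, padding and ground-truth attributes.  Round-trips are lossless
#' to float precision; files with a missing required field or an
#' unsupported schema version are rejected with a message naming the
#' problem.
#'
#' @param path File path (conventionally `.epochs.rds`).
#' @param epochs An [epoch_set()].
#' @return `read_epochs` returns the [epoch_set()]; `write_epochs` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(path, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  obj <- list(schema = "megosc-epochs", schema_version = EPOCH_SCHEMA_VERSION,
              data = epochs$data, times = epochs$times, fs = epochs$fs,
              subject = epochs$subject, group = epochs$group,
              pad_s = epochs$pad_s, truth = epochs$truth)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "megosc-epochs"))
    stop("not a megosc epoch container: ", path)
  if (!identical(obj$schema_version, EPOCH_SCHEMA_VERSION))
    stop("unsupported epoch schema version '", obj$schema_version,
         "' (this build reads ", EPOCH_SCHEMA_VERSION, ")")
  for (f in c("data", "times", "fs", "subject", "pad_s"))
    if (is.null(obj[[f]])) stop("epoch container missing field '", f, "'")
  epoch_set(obj$data, obj$times, obj$fs, subject = obj$subject,
            group = obj$group, pad_s = obj$pad_s,
            truth = if (is.null(obj$truth)) list() else obj$truth)
}

# Small dependency-free FNV-1a hash of a serialised object, for embedding
# a config fingerprint in result bundles.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
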