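#' Load a parameter configuration
#'
#' Reads a structured (YAML) parameter file, merges it over the constructor
#' defaults, validates, and rejects unknown keys. Nested sections (field /
#' trace / adaptation / noise / integration) are flattened before merging, so
#' configs can be organized either flat or by section.
#'
#' @param path Path to the configuration file.
#' @return A `field_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config-error: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (nm in names(raw)) {
    if (is.list(raw[[nm]])) flat <- c(flat, raw[[nm]]) else flat[nm] <- raw[[nm]]
  }
  flat <- lapply(flat, function(x) if (is.integer(x)) as.numeric(x) else x)
  known <- names(formals(field_params))
  unknown <- setdiff(names(flat), known)
  if (length(unknown))
    stop("config-error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(field_params, flat)
}

#' Write a table to comma-separated text
#'
#' UTF-8, header row, stable column order, numeric fields serialized at full
#' double precision so the matching reader round-trips losslessly.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path) {
  out <- rows
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O failure writing ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Input path.
#' @return A data.frame with numeric columns restored.
#' @export
read_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (nm in names(d)) {
    if (is.character(d[[nm]])) {
      suppress <- suppressWarnings(as.numeric(d[[nm]]))
      if (!anyNA(suppress) && length(d[[nm]]) > 0 &&
          !all(d[[nm]] %in% c("TRUE", "FALSE"))) d[[nm]] <- suppress
      if (all(d[[nm]] %in% c("TRUE", "FALSE")) && length(d[[nm]]) > 0)
        d[[nm]] <- as.logical(d[[nm]])
    }
  }
  d
}

#' Export an activation record as a table
#'
#' One row per sampled instant: `time_ms`, `frame_index`, then one column per
#' sampled grid position.
#'
#' @param record An `activation_record` with a stored field time course.
#' @return A data.frame.
#' @export
record_to_table <- function(record) {
  if (is.null(record$u_trace))
    stop("record has no stored field time course", call. = FALSE)
  u <- as.data.frame(record$u_trace)
  n <- ncol(u)
  pos <- (seq_len(n) - (n + 1) / 2)
  names(u) <- sprintf("x_%+d", round(pos))
  cbind(data.frame(time_ms = record$times,
                   frame_index = record$frame_index), u)
}

#' Manifest describing a reproducible run
#'
#' @param params The resolved `field_params`.
#' @param master_seed Master seed of the run.
#' @param outputs Character vector of output file paths.
#' @return A list; write it with `yaml::write_yaml()` alongside the outputs.
#' @export
run_manifest <- function(params, master_seed, outputs = character()) {
  list(package_version = as.character(utils::packageVersion("visfield")),
       params = unclass(params),
       params_hash = params_hash(params),
       master_seed = master_seed,
       outputs = outputs,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
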