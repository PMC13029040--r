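# Column schemas for the CSV formats the package reads and writes.
# All files are comma-separated UTF-8 with a mandatory header and "."
# decimal marks.
table_schemas <- list(
  fr_observations = c("prey_conc", "ingestion_rate"),
  dilution = c("fraction", "apparent_growth"),
  experiments = c("replicate_id", "C_control_initial", "C_control_final",
                  "C_treatment_initial", "C_treatment_final", "t", "Z",
                  "M_control_mean", "M_treatment_mean",
                  "P_control_mean", "P_treatment_mean"),
  cs_inputs = c("g_micro_control", "g_micro_treatment",
                "B_meso", "B_micro"),
  trajectory = c("time", "N", "P", "M", "Z")
)

#' Read and validate a package CSV table
#'
#' Reads one of the documented CSV schemas and validates the header and
#' cell types. Error messages name the offending column and row.
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header row).
#' @param schema_name One of \code{"fr_observations"}, \code{"dilution"},
#'   \code{"experiments"}, \code{"cs_inputs"}, \code{"trajectory"}.
#' @return A data.frame with the schema's columns, numeric except
#'   \code{replicate_id}.
#' @export
read_table <- function(path, schema_name) {
  if (!schema_name %in% names(table_schemas))
    stop("unknown schema '", schema_name, "'; known schemas: ",
         paste(names(table_schemas), collapse = ", "))
  cols <- table_schemas[[schema_name]]
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("empty table: ", path)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  num_cols <- setdiff(cols, "replicate_id")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (any(is.na(df[[cl]])) || length(bad))
      stop("non-numeric or missing value in column '", cl, "', row ",
           paste(utils::head(c(which(is.na(df[[cl]])), bad), 1),
                 collapse = ", "), " of ", path)
    df[[cl]] <- v
  }
  df
}

#' Write a package CSV table
#'
#' Writes with full double precision (>= 15 significant digits) so that
#' a read/write round-trip is value-identical.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a JSON run configuration
#'
#' Reads a JSON configuration with optional blocks \code{params} (NPMZ
#' parameters), \code{state0}, \code{thermal}, \code{design}, plus scalar
#' fields \code{t_end}, \code{output_dt}, \code{seed}, \code{units} and
#' \code{schema_version}. Unknown keys (at the top level or inside a
#' block) are rejected, and block contents are validated by the
#' corresponding constructors, so an out-of-bounds value is reported with
#' its field name.
#'
#' @param path Path to a JSON file.
#' @return A list with validated components: \code{params}
#'   ([npmz_params] or NULL), \code{state0} (named vector or NULL),
#'   \code{thermal} ([thermal_config] or NULL), \code{design}
#'   ([experiment_design] or NULL), and the scalar fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("params", "state0", "thermal", "design", "t_end",
             "output_dt", "seed", "units", "schema_version")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  check_block <- function(block, ctor, name) {
    if (is.null(block)) return(NULL)
    allowed <- names(formals(ctor))
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop("unknown key(s) in '", name, "' block: ",
           paste(extra, collapse = ", "))
    do.call(ctor, as.list(block))
  }
  params <- check_block(raw$params, npmz_params, "params")
  thermal <- check_block(raw$thermal, thermal_config, "thermal")
  design <- check_block(raw$design, experiment_design, "design")
  state0 <- NULL
  if (!is.null(raw$state0)) {
    need <- c("N", "P", "M", "Z")
    if (!all(need %in% names(raw$state0)))
      stop("'state0' block must name all of N, P, M, Z")
    state0 <- npmz_state(raw$state0$N, raw$state0$P,
                         raw$state0$M, raw$state0$Z)
  }
  list(params = params, state0 = state0, thermal = thermal,
       design = design,
       t_end = raw$t_end %||% 30, output_dt = raw$output_dt %||% 0.1,
       seed = raw$seed %||% 1L, units = raw$units %||% "cells_per_mL",
       schema_version = raw$schema_version %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
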