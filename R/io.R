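#' Write a mesh with nodal fields as legacy VTK ASCII
#'
#' POLYDATA with triangle polygons and one SCALARS point-data section per
#' field, readable by ParaView and friends.
#'
#' @param mesh a [build_sphere_mesh()] object.
#' @param fields named list of per-node numeric vectors (may be empty).
#' @param path output file.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, fields = list(), path, title = "polarisim surface") {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", fields[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write trajectory scalar series and kymograph as CSV
#'
#' @param summary_df a [trajectory_summary()] data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(summary_df, path) {
  utils::write.csv(summary_df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @param kymo a [kymograph()] matrix.
#' @export
write_kymograph_csv <- function(kymo, path) {
  df <- data.frame(time = as.numeric(rownames(kymo)), kymo,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run metadata sidecar
#'
#' Writes a small YAML sidecar with the configuration digest, seed,
#' solver statistics and package version, next to a run's outputs.
#'
#' @param path output file.
#' @param config the configuration list the run used.
#' @param seed integer seed.
#' @param stats solver statistics (any list).
#' @param extra additional named entries.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, config, seed, stats = list(),
                               extra = list()) {
  digest <- sum(utf8ToInt(paste(deparse(config), collapse = "")) *
                  seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %% 2^31
  meta <- c(list(config_hash = digest, seed = seed,
                 package_version = as.character(utils::packageVersion("polarisim")),
                 stats = stats), extra)
  yaml::write_yaml(meta, path)
  invisible(path)
}

# ---- parameter configuration files ------------------------------------

param_units <- c(
  k_cat_A = "1/s", k_cat_B = "1/s",
  K_A = "molecules/um^2", K_B = "molecules/um^2",
  k_on_R = "um^3/s", k_on_X = "um^3/s", k_on_B = "um^3/s",
  k_off_AR = "1/s", k_off_AX = "1/s", k_off_B = "1/s",
  A_tot = "molecules", B_tot = "molecules",
  X_tot = "molecules/um^2", D = "um^2/s",
  R = "um", S_area = "um^2", V_cyt = "um^3")

#' Read and write model-parameter configuration files
#'
#' Parameters are stored as flat key/value YAML where every entry records
#' its numeric `value`, its `unit` as a string, and a `provenance` note.
#' The reader validates against the known schema: unknown keys and
#' entries without a unit or provenance are rejected, and the unit string
#' must match the package's internal unit for that key.
#'
#' @param path file path.
#' @param params a [polarity_params()] object (for writing).
#' @param provenance single string or named character vector of
#'   provenance notes recorded on write.
#' @return `read_params_config()` returns a [polarity_params()] object
#'   (with the default constant-zero signal; signal schedules belong to
#'   scenario files); `write_params_config()` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$parameters))
    stop("config must have a 'parameters' block")
  entries <- raw$parameters
  unknown <- setdiff(names(entries), names(param_units))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  vals <- list()
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (is.null(e$value) || is.null(e$unit) || is.null(e$provenance))
      stop("parameter '", nm, "' must record value, unit and provenance")
    if (!identical(e$unit, param_units[[nm]]))
      stop("parameter '", nm, "' has unit '", e$unit, "', expected '",
           param_units[[nm]], "'")
    vals[[nm]] <- as.numeric(e$value)
  }
  args <- vals[intersect(names(vals),
                         names(formals(polarity_params)))]
  p <- do.call(polarity_params, args)
  if (!is.null(vals$S_area)) p$S_area <- vals$S_area
  if (!is.null(vals$V_cyt)) p$V_cyt <- vals$V_cyt
  p$chi <- p$S_area / p$V_cyt
  validate_params(p)
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path, provenance = "assumed") {
  keys <- setdiff(names(param_units), c("S_area", "V_cyt"))
  prov <- if (length(provenance) == 1L)
    setNames(rep(provenance, length(keys)), keys) else provenance
  entries <- lapply(keys, function(nm) {
    list(value = params[[nm]], unit = param_units[[nm]],
         provenance = unname(prov[[nm]]))
  })
  names(entries) <- keys
  yaml::write_yaml(list(parameters = entries), path)
  invisible(path)
}
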