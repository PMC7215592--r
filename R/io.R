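#' HDF5 container for 2DES datasets and results
#'
#' The single authoritative on-disk format of the package. Layout:
#' \preformatted{
#' /axes/excitation_cm1   1D float64, attribute units = "cm^-1"
#' /axes/emission_cm1     1D float64, attribute units = "cm^-1"
#' /axes/t2_fs            1D float64, attribute units = "fs"
#' /data/cube             3D float64, order excitation x emission x time
#' /meta                  group, attribute json = JSON string with
#'                        schema_version, preset, seed, temperature, ...
#' /fit                   optional: taus, das (3D stack), offset, ssr,
#'                        config (JSON string)
#' /cls                   optional: t2_fs, slope, n_columns, fit (JSON)
#' /coherence             optional: frequency_cm1, amplitude, peaks columns,
#'                        beat maps
#' }
#'
#' @name container
#' @keywords internal
NULL

SCHEMA_VERSION <- "1.0"

.h5_write_units <- function(path, dataset, units) {
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, dataset)
  on.exit({ rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid) }, add = TRUE)
  rhdf5::h5writeAttribute(units, did, "units")
}

#' Write a dataset (and optional results) to an HDF5 container
#'
#' Content is deterministic given identical inputs. Existing files are
#' overwritten.
#'
#' @param ds A `dataset_2des`.
#' @param path Output file path.
#' @param fit Optional `global_fit_result`.
#' @param cls Optional list with `trace` (`cls_trace`) and optionally `fit`
#'   (`cls_fit`).
#' @param coherence Optional list with `spectrum` (`coherence_spectrum`) and
#'   optionally `peaks` (`peak_list`) and `beat_maps` (list of `beat_map`).
#' @return `path`, invisibly.
#' @export
write_container <- function(ds, path, fit = NULL, cls = NULL, coherence = NULL) {
  stopifnot(inherits(ds, "dataset_2des"))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "axes")
  rhdf5::h5write(as.numeric(ds$excitation), path, "axes/excitation_cm1")
  rhdf5::h5write(as.numeric(ds$emission), path, "axes/emission_cm1")
  rhdf5::h5write(as.numeric(ds$time), path, "axes/t2_fs")
  .h5_write_units(path, "axes/excitation_cm1", "cm^-1")
  .h5_write_units(path, "axes/emission_cm1", "cm^-1")
  .h5_write_units(path, "axes/t2_fs", "fs")
  rhdf5::h5createGroup(path, "data")
  rhdf5::h5write(ds$cube, path, "data/cube")
  rhdf5::h5createGroup(path, "meta")
  meta <- c(list(schema_version = SCHEMA_VERSION), ds$meta)
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  rhdf5::h5writeAttribute(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)),
                          gid, "json")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)

  if (!is.null(fit)) {
    stopifnot(inherits(fit, "global_fit_result"))
    rhdf5::h5createGroup(path, "fit")
    rhdf5::h5write(fit$taus, path, "fit/taus")
    das_stack <- simplify2array(lapply(fit$das, function(m) m$amplitude))
    rhdf5::h5write(das_stack, path, "fit/das")
    if (!is.null(fit$offset)) rhdf5::h5write(fit$offset$amplitude, path, "fit/offset")
    rhdf5::h5write(fit$ssr, path, "fit/ssr")
    rhdf5::h5write(as.character(jsonlite::toJSON(unclass(fit$config),
                                                 auto_unbox = TRUE)),
                   path, "fit/config")
  }
  if (!is.null(cls)) {
    rhdf5::h5createGroup(path, "cls")
    rhdf5::h5write(cls$trace$t2_fs, path, "cls/t2_fs")
    rhdf5::h5write(cls$trace$slope, path, "cls/slope")
    rhdf5::h5write(cls$trace$n_columns, path, "cls/n_columns")
    if (!is.null(cls$fit)) {
      rhdf5::h5write(as.character(jsonlite::toJSON(unclass(cls$fit),
                                                   auto_unbox = TRUE)),
                     path, "cls/fit")
    }
  }
  if (!is.null(coherence)) {
    rhdf5::h5createGroup(path, "coherence")
    rhdf5::h5write(as.numeric(coherence$spectrum$frequency), path,
                   "coherence/frequency_cm1")
    rhdf5::h5write(coherence$spectrum$amplitude, path, "coherence/amplitude")
    if (!is.null(coherence$peaks)) {
      rhdf5::h5write(coherence$peaks$nu_cm1, path, "coherence/peak_nu_cm1")
      rhdf5::h5write(coherence$peaks$amplitude, path, "coherence/peak_amplitude")
      rhdf5::h5write(coherence$peaks$prominence, path, "coherence/peak_prominence")
    }
    if (!is.null(coherence$beat_maps)) {
      rhdf5::h5createGroup(path, "coherence/beat_maps")
      for (bm in coherence$beat_maps) {
        rhdf5::h5write(bm$map$amplitude, path,
                       sprintf("coherence/beat_maps/nu_%04.0f", bm$nu))
      }
    }
  }
  invisible(path)
}

#' Read a 2DES dataset from an HDF5 container
#'
#' Validates the layout (required groups, schema version, axis/cube shape
#' agreement) and returns the dataset; missing pieces raise errors naming
#' the violation.
#'
#' @param path Path to a container written by [write_container()].
#' @return A `dataset_2des`.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  idx <- rhdf5::h5ls(path)
  present <- paste(sub("^/$", "", idx$group), idx$name, sep = "/")
  for (need in c("/axes/excitation_cm1", "/axes/emission_cm1", "/axes/t2_fs",
                 "/data/cube")) {
    if (!(need %in% present)) stop("container is missing ", need)
  }
  if (!("/meta" %in% present)) stop("container is missing /meta")
  meta_json <- rhdf5::h5readAttributes(path, "meta")$json
  if (is.null(meta_json)) stop("container /meta lacks the json attribute")
  meta <- jsonlite::fromJSON(meta_json)
  if (is.null(meta$schema_version)) stop("container metadata lacks schema_version")
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION)) {
    stop("unsupported schema_version ", meta$schema_version,
         " (supported: ", SCHEMA_VERSION, ")")
  }
  ex <- as.numeric(rhdf5::h5read(path, "axes/excitation_cm1"))
  em <- as.numeric(rhdf5::h5read(path, "axes/emission_cm1"))
  t2 <- as.numeric(rhdf5::h5read(path, "axes/t2_fs"))
  cube <- rhdf5::h5read(path, "data/cube")
  if (!all(dim(cube) == c(length(ex), length(em), length(t2)))) {
    stop("cube shape ", paste(dim(cube), collapse = " x "),
         " does not match axis lengths ",
         paste(c(length(ex), length(em), length(t2)), collapse = " x "))
  }
  meta$schema_version <- NULL
  dataset_2des(ex, em, t2, cube, meta = as.list(meta))
}

#' Read optional result groups from a container
#'
#' @param path Container path.
#' @return A list with any of `fit` (taus, das array, offset, ssr, config),
#'   `cls` (t2_fs, slope, n_columns, fit), `coherence` (frequency_cm1,
#'   amplitude, peaks) that are present; missing groups are NULL.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  idx <- rhdf5::h5ls(path)
  present <- paste(sub("^/$", "", idx$group), idx$name, sep = "/")
  out <- list(fit = NULL, cls = NULL, coherence = NULL)
  if ("/fit/taus" %in% present) {
    out$fit <- list(
      taus = as.numeric(rhdf5::h5read(path, "fit/taus")),
      das = rhdf5::h5read(path, "fit/das"),
      offset = if ("/fit/offset" %in% present) rhdf5::h5read(path, "fit/offset"),
      ssr = as.numeric(rhdf5::h5read(path, "fit/ssr")),
      config = jsonlite::fromJSON(as.character(rhdf5::h5read(path, "fit/config"))))
  }
  if ("/cls/slope" %in% present) {
    out$cls <- list(
      t2_fs = as.numeric(rhdf5::h5read(path, "cls/t2_fs")),
      slope = as.numeric(rhdf5::h5read(path, "cls/slope")),
      n_columns = as.numeric(rhdf5::h5read(path, "cls/n_columns")),
      fit = if ("/cls/fit" %in% present) {
        jsonlite::fromJSON(as.character(rhdf5::h5read(path, "cls/fit")))
      })
  }
  if ("/coherence/amplitude" %in% present) {
    out$coherence <- list(
      frequency_cm1 = as.numeric(rhdf5::h5read(path, "coherence/frequency_cm1")),
      amplitude = as.numeric(rhdf5::h5read(path, "coherence/amplitude")),
      peaks = if ("/coherence/peak_nu_cm1" %in% present) {
        data.frame(
          nu_cm1 = as.numeric(rhdf5::h5read(path, "coherence/peak_nu_cm1")),
          amplitude = as.numeric(rhdf5::h5read(path, "coherence/peak_amplitude")),
          prominence = as.numeric(rhdf5::h5read(path, "coherence/peak_prominence")))
      })
  }
  out
}

#' Export one population-time slice as CSV
#'
#' Dialect: the first header cell is the literal
#' `"emission_cm1 \\ excitation_cm1"`, the remaining header cells are the
#' excitation wavenumbers; each following row starts with an emission
#' wavenumber followed by the amplitudes of that emission row across
#' excitation.
#'
#' @param ds A `dataset_2des`.
#' @param t2 Population time of the slice, fs (nearest sample used).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_slice_csv <- function(ds, t2, path) {
  m <- slice_map(ds, t2)
  tab <- cbind(as.numeric(m$emission), t(m$amplitude))
  colnames(tab) <- c("emission_cm1 \\ excitation_cm1",
                     format(as.numeric(m$excitation), trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export a CLS trace as CSV
#'
#' Columns: `t2_fs`, `slope`, `n_columns`.
#'
#' @param trace A `cls_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_cls_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("t2_fs", "slope", "n_columns")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a coherence spectrum as CSV
#'
#' Columns: `frequency_cm1`, `amplitude`.
#'
#' @param spec A `coherence_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(frequency_cm1 = as.numeric(spec$frequency),
                              amplitude = spec$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a peak list as CSV
#'
#' @param peaks A `peak_list`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_peaks_csv <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

.runconfig_defaults <- function() {
  list(seed = NULL,
       fit = list(n_exp = 2L, t2_min = 10, tau_bounds = c(20, 50000),
                  n_starts = 8L, include_offset = TRUE, tol = 1e-10),
       cls = list(column_method = "parabolic", min_rel_intensity = 0.2,
                  weighted = TRUE),
       fsc = list(window_function = "hann", pad_factor = 4L,
                  normalize_input = TRUE, aggregate = "mean"))
}

#' Read and validate a run configuration (JSON or YAML)
#'
#' The document may set any of `input`, `output`, `seed`, `preset`, and the
#' nested sections `fit`, `cls`, `fsc` mirroring [global_fit_config()],
#' [cls_config()] and [fsc_config()]. Unknown keys (at the top level or
#' inside a section) are rejected; omitted keys take the package defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("run config must be .json, .yaml or .yml, got .", ext)
  }
  defaults <- .runconfig_defaults()
  allowed_top <- c("input", "output", "seed", "preset", names(defaults))
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  for (section in c("fit", "cls", "fsc")) {
    if (!is.null(raw[[section]])) {
      bad <- setdiff(names(raw[[section]]), names(defaults[[section]]))
      if (length(bad)) {
        stop("unknown key(s) in run-config section '", section, "': ",
             paste(bad, collapse = ", "))
      }
      defaults[[section]] <- utils::modifyList(defaults[[section]],
                                               raw[[section]])
    }
  }
  for (k in c("input", "output", "seed", "preset")) {
    if (!is.null(raw[[k]])) defaults[[k]] <- raw[[k]]
  }
  defaults
}
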