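# External interfaces: YAML patient config, delimited-text waveforms,
# legacy-VTK field export, JSON correlation report.

#' Write a patient model configuration
#'
#' Serializes the full forward-model specification (trunk, kidney, tissue
#' resistivities, perfusion cases) to a single YAML document with explicit
#' units (lengths in mm, resistivities in Ohm*m).
#'
#' @param path Output file.
#' @param torso,kidney Model specs.
#' @param tissues A [tissue_table()].
#' @param cases List of [perfusion_case()]s.
#' @return `path`, invisibly.
#' @export
write_patient_config <- function(path, torso = torso_spec(),
                                 kidney = kidney_spec(),
                                 tissues = tissue_table(),
                                 cases = default_perfusion_cases()) {
  doc <- list(
    units = list(length = "mm", resistivity = "ohm.m"),
    torso = unclass(torso),
    kidney = unclass(kidney),
    tissues_ohm_m = as.list(unclass(tissues)),
    perfusion_cases = lapply(unname(cases), function(cs)
      list(name = cs$name,
           cortex_blood_fraction = cs$cortex_blood_fraction,
           before = as.list(cs$before), after = as.list(cs$after)))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a patient model configuration
#'
#' @param path A YAML file written by [write_patient_config()].
#' @return List with validated `torso`, `kidney`, `tissues`, `cases`.
#' @export
read_patient_config <- function(path) {
  doc <- yaml::read_yaml(path)
  t <- doc$torso
  k <- doc$kidney
  torso <- torso_spec(major_axis = t$major_axis, minor_axis = t$minor_axis,
                      h_subc = t$h_subc, h_m = t$h_m,
                      axial_length = t$axial_length,
                      background_tissue = t$background_tissue)
  kidney <- kidney_spec(semi_axes = unlist(k$semi_axes), h_c = k$h_c,
                        depth = k$depth, lateral_offset = k$lateral_offset,
                        capsule_margin = k$capsule_margin)
  tissues <- do.call(tissue_table, doc$tissues_ohm_m)
  cases <- lapply(doc$perfusion_cases, function(cs)
    perfusion_case(cs$name, cs$cortex_blood_fraction,
                   after = unlist(cs$after), before = unlist(cs$before)))
  names(cases) <- vapply(cases, `[[`, "", "name")
  list(torso = torso, kidney = kidney, tissues = tissues, cases = cases)
}

#' Write a waveform as delimited text
#'
#' Two tab-separated columns (time_s, value) preceded by `#` header lines
#' carrying units and vessel metadata.
#'
#' @param w A two-column time/value data frame (velocity waveform, flow
#'   curve, blood-volume curve or impedance waveform).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(is.data.frame(w), ncol(w) >= 2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(w)[1:2], collapse = "\t")),
             con)
  if (!is.null(attr(w, "role")))
    writeLines(sprintf("# vessel: %s S_cm2: %g", attr(w, "role"),
                       attr(w, "S_cm2") %||% NA), con)
  utils::write.table(w[, 1:2], con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a delimited-text waveform
#'
#' @param path File written by [write_waveform()] (or any two-column
#'   delimited text; `#` lines are ignored).
#' @return Data frame with `time_s` and `value`.
#' @export
read_waveform <- function(path) {
  df <- utils::read.table(path, comment.char = "#", sep = "\t",
                          col.names = c("time_s", "value"))
  df
}

#' Write a correlation report
#'
#' Small JSON document with the Pearson correlation between the
#' blood-volume and impedance waveforms and the sample size.
#'
#' @param path Output file.
#' @param r Correlation coefficient.
#' @param n Number of aligned samples.
#' @param meta Optional named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(path, r, n, meta = list()) {
  doc <- c(list(pearson_r = r, n_samples = n), meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a field to legacy VTK structured points
#'
#' Writes a label grid, conductivity field or potential field as ASCII
#' legacy-VTK STRUCTURED_POINTS for inspection in ParaView.
#'
#' @param x A `label_grid`, `conductivity_field` or `potential_field`.
#' @param path Output `.vtk` file.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(x, path) {
  if (inherits(x, "label_grid")) {
    vals <- as.integer(x$labels); name <- "tissue_label"; type <- "int"
    h <- x$h; dims <- x$dims; origin <- x$origin
  } else if (inherits(x, "conductivity_field")) {
    vals <- as.numeric(x$sigma); name <- "sigma_S_per_m"; type <- "double"
    h <- x$h; dims <- x$dims; origin <- x$origin
  } else if (inherits(x, "potential_field")) {
    vals <- as.numeric(x$phi); vals[is.na(vals)] <- 0
    name <- "phi_V"; type <- "double"
    h <- x$field$h; dims <- x$field$dims; origin <- x$field$origin
  } else stop("cannot export objects of class ", class(x)[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "renalimp field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", h, h, h),
               sprintf("POINT_DATA %d", prod(dims)),
               sprintf("SCALARS %s %s 1", name, type),
               "LOOKUP_TABLE default"), con)
  writeLines(format(vals, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}
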