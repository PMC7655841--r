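#' Read an instrument curve export
#'
#' Reads a delimited text export with header columns `time_s`, `force_mN`,
#' `depth_nm` and an optional `segment` column.
#'
#' @param path Path to the CSV file.
#' @return A [force_displacement()] record.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "force_mN", "depth_nm")
  if (!all(need %in% names(df))) {
    stop_input(sprintf("curve file must have columns %s", paste(need, collapse = ", ")))
  }
  force_displacement(df$time_s, df$force_mN, df$depth_nm, segment = df$segment)
}

#' @param record A [force_displacement()] record.
#' @param path Output path.
#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}

#' Read a pillar-geometry configuration file
#'
#' Parses a flat `key = value` text file with keys `D1_um`, `D2_um`, `h_um`,
#' `taper_deg`, `poisson` (any of `D2_um`/`taper_deg` may be omitted, see
#' [pillar_geometry()]). Lines starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return A [pillar_geometry()].
#' @export
read_geometry_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop_input("geometry file lines must be `key = value`")
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, character(1), 2L)))
  names(vals) <- keys
  get_or <- function(k, default = NULL) if (k %in% keys) unname(vals[k]) else default
  pillar_geometry(
    D1 = get_or("D1_um", 2),
    D2 = get_or("D2_um"),
    h = get_or("h_um", 6),
    taper = get_or("taper_deg", if (is.null(get_or("D2_um"))) 2.5 else NULL),
    nu = get_or("poisson", 0.3)
  )
}

#' Write a mechanical summary as JSON
#'
#' One JSON document per pillar, with all scalar summary fields and the
#' geometry.
#'
#' @param summary A `"mechanical_summary"` from [reduce_curve()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  x <- unclass(summary)
  x$geometry <- unclass(x$geometry)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a strength sample from CSV
#'
#' @param path Path to a CSV with a strength column and optional group column.
#' @param strength_col,group_col Column names.
#' @return A data frame with columns `strength` and `group`.
#' @export
read_strengths_csv <- function(path, strength_col = "sigma_Y", group_col = "group") {
  df <- utils::read.csv(path)
  if (!strength_col %in% names(df)) {
    stop_input(sprintf("no column '%s' in %s", strength_col, path))
  }
  data.frame(
    strength = df[[strength_col]],
    group = if (group_col %in% names(df)) as.character(df[[group_col]]) else "all"
  )
}
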