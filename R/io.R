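# Geometry file I/O.  CSV dialect: header s_m,area_m2,perimeter_m,x_m,y_m,z_m,region
# JSON: {name, variant, stations:[{s,area,perimeter,x,y,z,region}, ...]}

CSV_HEADER <- c("s_m", "area_m2", "perimeter_m", "x_m", "y_m", "z_m", "region")

fmt_num <- function(v) sprintf("%.17g", v)

#' Write an airway to CSV
#'
#' Numbers are written with 17 significant digits so write/read round-trips
#' are bit-identical.
#'
#' @param x an [airway()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airway_csv <- function(x, path) {
  validate_airway(x)
  lines <- c(paste(CSV_HEADER, collapse = ","),
             paste(fmt_num(x$s), fmt_num(x$area), fmt_num(x$perimeter),
                   fmt_num(x$x), fmt_num(x$y), fmt_num(x$z), x$region,
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an airway from CSV
#'
#' Validates all airway invariants and reports the offending row on failure.
#'
#' @param path CSV file written by [write_airway_csv()].
#' @param name,variant metadata for the constructed airway.
#' @export
read_airway_csv <- function(path, name = basename(path), variant = "custom") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rep("numeric", 6L), "character"))
  if (!identical(names(df), CSV_HEADER))
    stop("bad geometry CSV header; expected ",
         paste(CSV_HEADER, collapse = ","))
  names(df) <- c("s", "area", "perimeter", "x", "y", "z", "region")
  airway(df, name = name, variant = variant)
}

#' Write an airway to JSON
#' @param x an [airway()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_airway_json <- function(x, path) {
  validate_airway(x)
  obj <- list(name = airway_name(x), variant = airway_variant(x),
              stations = as.data.frame(unclass(x),
                                       stringsAsFactors = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read an airway from JSON
#' @param path JSON file written by [write_airway_json()].
#' @export
read_airway_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$stations)) stop("no 'stations' field in ", path)
  airway(obj$stations, name = obj$name %||% basename(path),
         variant = obj$variant %||% "custom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
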