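#' Read and write tissue layouts as CSV
#'
#' Layout files have the header `type,x_um,y_um,radius_um` with `type` one of
#' vessel/tumor/stromal; coordinates live in the domain frame (by default
#' `[-500, 500]^2` um). Coordinates round-trip to 6 decimals.
#'
#' @param layout A `tissue_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns a
#'   `tissue_layout`.
#' @export
write_layout <- function(layout, path) {
  df <- tibble::tibble(type = layout$type,
                       x_um = round(layout$x_um, 6),
                       y_um = round(layout$y_um, 6),
                       radius_um = round(layout$radius_um, 6))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_layout
#' @param params Model parameters (supply the element radii for validation).
#' @export
read_layout <- function(path, params = ox_params()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    type = readr::col_character(), x_um = readr::col_double(),
    y_um = readr::col_double(), radius_um = readr::col_double()))
  bad <- which(!df$type %in% c("vessel", "tumor", "stromal"))
  if (length(bad))
    stop(sprintf("unknown element type `%s` at line %d of %s",
                 df$type[bad[1]], bad[1] + 1L, path), call. = FALSE)
  counts <- c(sum(df$type == "vessel"), sum(df$type == "tumor"),
              sum(df$type == "stromal"))
  areas <- pi * c(params$R_V, params$R_T, params$R_S)^2 * counts
  comp <- tissue_composition(areas[1] / domain_area(params) * 100,
                             areas[2] / domain_area(params) * 100,
                             areas[3] / domain_area(params) * 100)
  new_layout(tibble::as_tibble(df), comp, NA_integer_, relaxed = NA)
}

#' Read and write oxygen fields
#'
#' A field file is a headerless CSV matrix of nodal values preceded by one
#' comment line `#meta {json}` carrying `dx`, `domain` and the unit.
#'
#' @param field An `oxygen_field`.
#' @param path File path.
#' @export
write_field <- function(field, path) {
  meta <- jsonlite::toJSON(list(dx = field$dx, domain = field$domain,
                                units = "mmHg"), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", meta), con)
  utils::write.table(field$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#meta "))
    stop("not a field file (missing #meta header): ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(sub("^#meta ", "", first))
  vals <- as.matrix(utils::read.table(path, sep = ",", skip = 1,
                                      header = FALSE))
  dimnames(vals) <- NULL
  structure(list(values = vals, dx = meta$dx, domain = meta$domain),
            class = "oxygen_field")
}

#' Read and write measured pO2 series
#'
#' Series files are CSV with columns `t_min,po2_mmHg` (9 rows).
#'
#' @param series A series tibble.
#' @param path File path.
#' @export
write_roi_series <- function(series, path) {
  readr::write_csv(series[c("t_min", "po2_mmHg")], path)
  invisible(path)
}

#' @rdname write_roi_series
#' @export
read_roi_series <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t_min = readr::col_double(), po2_mmHg = readr::col_double()))
  if (any(df$po2_mmHg < 0)) stop("series values must be non-negative", call. = FALSE)
  attr(df, "anchor") <- max(df$po2_mmHg)
  df
}

#' Read and write schedules and fits as JSON
#'
#' @param x An `ox_schedule` or `schedule_fit`.
#' @param path File path.
#' @export
write_schedule <- function(x, path) {
  obj <- if (inherits(x, "schedule_fit")) {
    list(kind = x$schedule$kind, boundaries_min = x$schedule$boundaries,
         rates = x$schedule$rates, gof = x$gof, gof_form = x$gof_form,
         simulated_mmHg = x$simulated$po2_mmHg,
         target_mmHg = x$target$po2_mmHg)
  } else {
    list(kind = x$kind, boundaries_min = x$boundaries, rates = x$rates)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @param params Model parameters (rate bound validation).
#' @export
read_schedule <- function(path, params = ox_params()) {
  obj <- jsonlite::fromJSON(path)
  new_schedule(obj$kind, obj$rates, params)
}
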