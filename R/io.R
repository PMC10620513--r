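#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write / read detected cells as CSV
#'
#' Cells are written with 0-based pixel-center coordinates (x = column,
#' y = row) and, alongside, a JSON sidecar echoing the detection parameters
#' so every cell table is traceable to the settings that produced it.
#'
#' @param cells Cell tibble from [detect_cells_stack()].
#' @param path CSV path; the sidecar is written to `<path>.params.json`.
#' @param params Optional [detection_params()] list to echo.
#' @return `write_cells_csv` returns `path` invisibly; `read_cells_csv`
#'   returns the cell tibble.
#' @export
write_cells_csv <- function(cells, path, params = NULL) {
  readr::write_csv(cells, path)
  if (!is.null(params))
    jsonlite::write_json(unclass(params), paste0(path, ".params.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    section_index = readr::col_integer(),
    ap_mm = readr::col_double(),
    x_px = readr::col_double(),
    y_px = readr::col_double(),
    size_px = readr::col_integer(),
    region_id = readr::col_integer()
  ))
}
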