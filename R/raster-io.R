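#' Read a habitat grid from an Esri ASCII raster
#'
#' Reads the plain-text Esri ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/optional `NODATA_value` header followed by row-major
#' cell values, top row first). Values must lie in \[0, 1\]; NODATA cells are
#' treated as habitat 0.
#'
#' @param path Path to an `.asc` file.
#' @return A `tort_habitat` grid.
#' @export
read_raster <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", trimws(lines[[i]]))) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    hdr[[tolower(parts[[1]])]] <- as.numeric(parts[[2]])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) abort(paste0("malformed raster: missing ", key))
  }
  body <- lines[seq(i, length(lines))]
  rows <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (length(rows) != hdr$nrows ||
      any(lengths(rows) != hdr$ncols)) {
    abort("malformed raster: grid is not rectangular with the declared size")
  }
  values <- do.call(rbind, rows)
  if (!is.null(hdr$nodata_value)) {
    values[values == hdr$nodata_value] <- 0
  }
  if (any(values < 0 | values > 1)) {
    abort("raster values outside [0, 1] are not valid habitat suitabilities")
  }
  habitat_grid(values, cell_size = hdr$cellsize)
}

#' Write a habitat grid or surface layer to an Esri ASCII raster
#'
#' Values are written with 17 significant digits so a write/read round-trip is
#' bit-exact for double precision values.
#'
#' @param x A `tort_habitat`, a `tort_surface` (its resistance layer is
#'   converted back to habitat as `1 - resistance`), or a numeric matrix.
#' @param path Output path.
#' @export
write_raster <- function(x, path) {
  if (inherits(x, "tort_surface")) {
    values <- 1 - x$resistance
    cell_size <- x$cell_size
  } else if (inherits(x, "tort_habitat")) {
    values <- x$values
    cell_size <- x$cell_size
  } else {
    values <- as.matrix(x)
    cell_size <- 1
  }
  hdr <- c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", format(cell_size, digits = 17)),
    paste("NODATA_value", -9999))
  body <- apply(values, 1, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
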