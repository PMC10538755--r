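#' Degrade habitat suitability with a disturbance conversion factor
#'
#' Applies the multiplicative habitat-degradation rule used to build
#' disturbance-adjusted resistance surfaces: a cell containing a disturbance
#' with conversion factor `f` keeps `habitat - habitat * f` of its original
#' suitability. A factor of 1 (urban/solar) removes the habitat entirely; a
#' factor of 0 leaves it unchanged.
#'
#' @param habitat Numeric vector of habitat suitability values in \[0, 1\].
#' @param conversion_factor Numeric vector (recycled) of conversion factors in
#'   \[0, 1\].
#' @return Adjusted habitat suitability, same length as `habitat`.
#' @examples
#' apply_conversion(0.5, 0.75) # railway/interstate: 0.125
#' @export
apply_conversion <- function(habitat, conversion_factor) {
  check_unit(habitat, "habitat")
  check_unit(conversion_factor, "conversion_factor")
  habitat - habitat * conversion_factor
}

#' Convert adjusted habitat suitability to movement resistance
#'
#' Resistance is the inverse (complement) of habitat suitability: a perfect
#' habitat cell (1) has resistance 0, a fully degraded cell (0) has
#' resistance 1 and is impassable.
#'
#' @param adjusted_habitat Numeric vector in \[0, 1\].
#' @return `1 - adjusted_habitat`.
#' @export
resistance_from_habitat <- function(adjusted_habitat) {
  check_unit(adjusted_habitat, "adjusted_habitat")
  1 - adjusted_habitat
}

#' Carrying capacity of a 1 km^2 cell from habitat suitability
#'
#' Bins habitat suitability into the stepped tortoise density scale used for
#' the heterogeneous landscapes: 0 tortoises for no habitat, 1 for marginal
#' habitat (up to 0.20), then 3, 6, 9, ... 24 in 0.1-wide bins up to perfect
#' habitat. Bins are half-open on the left and closed on the right.
#'
#' @param habitat Numeric vector of habitat suitability in \[0, 1\].
#' @return Integer vector of per-cell carrying capacities.
#' @examples
#' carrying_capacity(c(0, 0.25, 0.95)) # 0, 3, 24
#' @export
carrying_capacity <- function(habitat) {
  check_unit(habitat, "habitat")
  k_by_bin <- c(1L, 1L, 3L, 6L, 9L, 12L, 15L, 18L, 21L, 24L)
  bin <- findInterval(habitat, seq(0, 0.9, by = 0.1), left.open = TRUE,
                      rightmost.closed = FALSE)
  out <- ifelse(habitat == 0, 0L, k_by_bin[pmax(bin, 1L)])
  as.integer(out)
}

new_surface <- function(resistance, k, culvert_cells = integer(0),
                        scenario = "custom", density = NA_character_,
                        cell_size = 1) {
  stopifnot(is.matrix(resistance), all(dim(resistance) == dim(k)))
  structure(
    list(resistance = resistance, carrying_capacity = k,
         culvert_cells = as.integer(culvert_cells),
         scenario = scenario, density = density, cell_size = cell_size,
         n_rows = nrow(resistance), n_cols = ncol(resistance)),
    class = "tort_surface")
}

#' Build one of the hypothetical scenario landscapes
#'
#' Constructs a 25 x 25 (by default) resistance surface:
#' * `no_barrier`: uniform open habitat, resistance 0 everywhere;
#' * `barrier`: a one-cell-wide, full-length impassable column (resistance 1,
#'   carrying capacity 0) bisecting the grid, standing in for an unfenced
#'   interstate or railway;
#' * `culverts`: the barrier plus `n_culverts` passable culvert cells
#'   (resistance 0.7, carrying capacity 3) evenly spaced along the barrier.
#'
#' All open-habitat cells carry the per-cell carrying capacity implied by the
#' density class: 3 (low), 14 (moderate) or 24 (high) tortoises per km^2.
#'
#' @param scenario One of `"no_barrier"`, `"barrier"`, `"culverts"`.
#' @param density One of `"low"`, `"moderate"`, `"high"`.
#' @param n_culverts Number of culverts embedded in the barrier (default 3).
#' @param n_rows,n_cols Grid dimensions (default 25 x 25, 1 km cells).
#' @return A `tort_surface` object.
#' @examples
#' surf <- build_scenario_surface("culverts", density = "moderate")
#' sum(surf$carrying_capacity)
#' @export
build_scenario_surface <- function(scenario = c("no_barrier", "barrier", "culverts"),
                                   density = c("low", "moderate", "high"),
                                   n_culverts = 3L,
                                   n_rows = 25L, n_cols = 25L) {
  scenario <- match.arg(scenario)
  density <- match.arg(density)
  k_cell <- c(low = 3L, moderate = 14L, high = 24L)[[density]]
  resistance <- matrix(0, n_rows, n_cols)
  k <- matrix(k_cell, n_rows, n_cols)
  culverts <- integer(0)
  if (scenario != "no_barrier") {
    bc <- barrier_column(n_cols)
    resistance[, bc] <- 1
    k[, bc] <- 0L
    if (scenario == "culverts") {
      if (n_culverts > n_rows) {
        abort("more culverts requested than barrier cells available")
      }
      rows <- round(seq(1, n_rows, length.out = n_culverts + 2L))
      rows <- rows[seq(2L, n_culverts + 1L)]
      resistance[rows, bc] <- 0.7
      k[rows, bc] <- 3L
      culverts <- cell_id(as.integer(rows), bc, n_cols)
    }
  }
  new_surface(resistance, k, culverts, scenario, density)
}

barrier_column <- function(n_cols) as.integer(ceiling(n_cols / 2))

#' Build a heterogeneous (disturbance-adjusted) resistance surface
#'
#' Starting from a habitat-suitability grid, applies each disturbance layer's
#' conversion factor to the cells it covers (sequentially, i.e.
#' multiplicatively when layers overlap), then derives per-cell resistance
#' (`1 - adjusted habitat`) and carrying capacity ([carrying_capacity()]).
#'
#' @param habitat A habitat grid from [habitat_grid()] or [read_raster()].
#' @param layers A list of disturbance layers from [disturbance_layer()].
#' @return A `tort_surface`.
#' @export
build_heterogeneous_surface <- function(habitat, layers = list()) {
  stopifnot(inherits(habitat, "tort_habitat"))
  adj <- habitat$values
  for (layer in layers) {
    stopifnot(inherits(layer, "tort_disturbance"))
    if (!all(dim(layer$intensity) == dim(adj))) {
      abort("disturbance layer is not co-registered with the habitat grid")
    }
    f <- layer$conversion_factor * layer$intensity
    adj <- apply_conversion(adj, f)
  }
  new_surface(resistance_from_habitat(adj),
              matrix(carrying_capacity(adj), nrow(adj), ncol(adj)),
              scenario = "heterogeneous")
}

#' Create a habitat-suitability grid
#'
#' @param values Numeric matrix of habitat suitability in \[0, 1\].
#' @param cell_size Cell edge length in km (default 1).
#' @return A `tort_habitat` object.
#' @export
habitat_grid <- function(values, cell_size = 1) {
  values <- as.matrix(values)
  check_unit(values, "habitat")
  structure(list(values = values, n_rows = nrow(values),
                 n_cols = ncol(values), cell_size = cell_size),
            class = "tort_habitat")
}

#' Create a disturbance layer
#'
#' A disturbance layer marks cells degraded by an anthropogenic feature and
#' carries the conversion factor for that feature class: 1.00 for urban/solar
#' development, 0.75 for a railway or interstate, 0.25 for minor roads and for
#' utility rights-of-way. For minor roads the `intensity` grid scales the
#' factor by per-cell road length relative to the maximum across the grid, so
#' the applied penalty sits at or below the class maximum.
#'
#' @param kind One of `"urban_solar"`, `"rail_interstate"`, `"minor_road"`,
#'   `"right_of_way"`.
#' @param mask Logical or 0/1 matrix of affected cells, or (for minor roads)
#'   a non-negative matrix of per-cell road length.
#' @param conversion_factor Optional override of the class factor.
#' @return A `tort_disturbance` object.
#' @export
disturbance_layer <- function(kind = c("urban_solar", "rail_interstate",
                                       "minor_road", "right_of_way"),
                              mask, conversion_factor = NULL) {
  kind <- match.arg(kind)
  default_factor <- c(urban_solar = 1, rail_interstate = 0.75,
                      minor_road = 0.25, right_of_way = 0.25)[[kind]]
  conversion_factor <- conversion_factor %||% default_factor
  check_unit(conversion_factor, "conversion_factor")
  intensity <- as.matrix(mask) * 1
  if (any(intensity < 0)) abort("disturbance intensity must be non-negative")
  if (kind == "minor_road") {
    mx <- max(intensity)
    if (mx > 0) intensity <- intensity / mx
  } else if (any(intensity > 1)) {
    abort("disturbance mask must be 0/1 or in [0, 1]")
  }
  structure(list(kind = kind, intensity = intensity,
                 conversion_factor = conversion_factor),
            class = "tort_disturbance")
}

check_unit <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", what, "` must be in [0, 1]"))
  }
  invisible(x)
}

#' @export
print.tort_surface <- function(x, ...) {
  cat("<tort_surface> ", x$n_rows, "x", x$n_cols, " cells, scenario: ",
      x$scenario, if (!is.na(x$density)) paste0(", density: ", x$density),
      "\n", sep = "")
  cat("  habitable cells: ", sum(x$resistance < 1),
      ", total carrying capacity: ", sum(x$carrying_capacity),
      if (length(x$culvert_cells)) paste0(", culverts: ", length(x$culvert_cells)),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a resistance surface into a tibble of cells
#'
#' @param x A `tort_surface`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `row`, `col`, `cell`, `resistance`,
#'   `carrying_capacity`, `culvert`.
#' @export
as_tibble.tort_surface <- function(x, ...) {
  ids <- seq_len(x$n_rows * x$n_cols)
  rows <- cell_row(ids, x$n_cols)
  cols <- cell_col(ids, x$n_cols)
  tibble(cell = ids, row = rows, col = cols,
         resistance = x$resistance[cbind(rows, cols)],
         carrying_capacity = x$carrying_capacity[cbind(rows, cols)],
         culvert = ids %in% x$culvert_cells)
}

#' @rdname as_tibble.tort_surface
#' @param object A `tort_surface`.
#' @export
autoplot.tort_surface <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$resistance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$culvert),
                        colour = "white", shape = 4, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (km)", y = "row (km)", fill = "resistance")
}
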