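#' Area polygon layers
#'
#' An `area_layer` holds a named set of non-overlapping areas (tract-like or
#' zip-like), each a polygon (possibly multi-part, possibly with holes) with a
#' unique area id and a county grouping id. Geometry is stored as a list
#' column of ring lists; each ring is a closed `n x 2` matrix of
#' longitude-latitude vertices (longitude first, as in GeoJSON).
#'
#' @param areas Tibble with columns `area_id`, `county_id`, `geometry`
#'   (list of ring lists).
#' @param layer_name Name for the layer (e.g. `"tract"` or `"zip"`).
#' @return An `area_layer` object.
#' @export
area_layer <- function(areas, layer_name = "layer") {
  stopifnot(is.data.frame(areas),
            all(c("area_id", "county_id", "geometry") %in% names(areas)))
  areas <- as_tibble(areas)
  areas$area_id <- as.character(areas$area_id)
  areas$county_id <- as.character(areas$county_id)
  if (anyDuplicated(areas$area_id)) {
    abort("duplicate area ids in layer")
  }
  areas$geometry <- lapply(areas$geometry, function(rings) lapply(rings, close_ring))
  areas$bbox <- lapply(areas$geometry, rings_bbox)
  structure(list(layer_name = layer_name, areas = areas), class = "area_layer")
}

#' @export
print.area_layer <- function(x, ...) {
  cat("<area_layer '", x$layer_name, "': ", nrow(x$areas), " areas, ",
      dplyr::n_distinct(x$areas$county_id), " counties>\n", sep = "")
  invisible(x)
}

#' Load an area layer from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features. Each
#' feature must carry the area-id and county-id properties. Unclosed rings are
#' closed with a warning; duplicate area ids or non-polygon geometries are
#' errors.
#'
#' @param source Path to a GeoJSON file, or an already-parsed list.
#' @param area_id,county_id Property names holding the ids.
#' @param layer_name Name for the resulting layer; defaults to the GeoJSON
#'   `name` member, if present.
#' @return An [area_layer()].
#' @export
load_area_layer <- function(source, area_id = "area_id", county_id = "county_id",
                            layer_name = NULL) {
  gj <- if (is.character(source)) {
    jsonlite::read_json(source)
  } else {
    source
  }
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    abort("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  rows <- lapply(feats, function(f) {
    props <- f$properties
    if (is.null(props[[area_id]])) {
      abort(paste0("feature missing '", area_id, "' property"))
    }
    geom <- f$geometry
    rings <- switch(geom$type %||% "",
      Polygon = lapply(geom$coordinates, coords_to_ring),
      MultiPolygon = unlist(lapply(geom$coordinates, function(part) {
        lapply(part, coords_to_ring)
      }), recursive = FALSE),
      abort(paste0("non-polygon geometry: ", geom$type %||% "<missing>"))
    )
    unclosed <- !vapply(rings, ring_closed, logical(1))
    if (any(unclosed)) {
      warn(paste0("auto-closing ", sum(unclosed), " unclosed ring(s) in area ",
                  props[[area_id]]))
      rings <- lapply(rings, close_ring)
    }
    tibble(
      area_id = as.character(props[[area_id]]),
      county_id = as.character(props[[county_id]] %||% NA_character_),
      geometry = list(rings)
    )
  })
  areas <- bind_rows(rows)
  area_layer(areas, layer_name = layer_name %||% (gj$name %||% "layer"))
}

coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt) c(pt[[1L]], pt[[2L]])))
  storage.mode(m) <- "double"
  m
}

#' Write an area layer as GeoJSON
#'
#' @param layer An [area_layer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_area_layer <- function(layer, path) {
  feats <- lapply(seq_len(nrow(layer$areas)), function(i) {
    rings <- layer$areas$geometry[[i]]
    coords <- lapply(rings, function(r) {
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1L], r[j, 2L]))
    })
    list(
      type = "Feature",
      properties = list(area_id = layer$areas$area_id[i],
                        county_id = layer$areas$county_id[i]),
      geometry = list(type = "Polygon", coordinates = coords)
    )
  })
  gj <- list(type = "FeatureCollection", name = layer$layer_name, features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a rectangular grid layer
#'
#' Constructs a toy tract-like layer: `rows` x `cols` axis-aligned square
#' cells of side `cell_size` degrees, tiling the rectangle anchored at
#' `origin` (its lower-left corner) without gaps or overlap. Counties are
#' coarse blocks: `counties_per_side` must divide both `rows` and `cols`, and
#' each county is a contiguous block of cells.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param cell_size Cell side length in degrees (> 0).
#' @param origin Length-2 numeric, lower-left corner as `c(lon, lat)`.
#' @param counties_per_side Number of county blocks along each side.
#' @param layer_name Layer name.
#' @return An [area_layer()] with zero-padded area ids (`A001`, ...) and
#'   county ids (`C01`, ...).
#' @examples
#' make_grid_layer(2, 2, 1, c(0, 0), 1)
#' @export
make_grid_layer <- function(rows, cols, cell_size = 1, origin = c(0, 0),
                            counties_per_side = 1, layer_name = "grid") {
  if (rows < 1 || cols < 1) abort("`rows` and `cols` must be >= 1")
  if (cell_size <= 0) abort("`cell_size` must be > 0")
  if (rows %% counties_per_side != 0 || cols %% counties_per_side != 0) {
    abort("`counties_per_side` must divide both `rows` and `cols`")
  }
  idx <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  block_r <- rows / counties_per_side
  block_c <- cols / counties_per_side
  areas <- tibble(
    area_id = sprintf("A%03d", seq_len(nrow(idx))),
    county_id = sprintf("C%02d",
      (ceiling(idx$row / block_r) - 1L) * counties_per_side +
        ceiling(idx$col / block_c)),
    geometry = lapply(seq_len(nrow(idx)), function(i) {
      x0 <- origin[1L] + (idx$col[i] - 1L) * cell_size
      y0 <- origin[2L] + (idx$row[i] - 1L) * cell_size
      x1 <- x0 + cell_size; y1 <- y0 + cell_size
      # counterclockwise exterior ring, closed
      list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
                  ncol = 2L, byrow = TRUE))
    })
  )
  area_layer(areas, layer_name = layer_name)
}
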