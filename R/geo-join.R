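#' Build a bounding-box tree index over an area layer
#'
#' A static hierarchical bounding-box tree (R-tree style, bulk-loaded by
#' recursive median splits on bbox centers). A point query returns every area
#' whose bounding box contains the point — a superset of the areas actually
#' containing it, so candidates are always filtered by an exact containment
#' test. Completeness (never missing a containing polygon) is the contract;
#' over-returning is allowed.
#'
#' @param layer An [area_layer()].
#' @param leaf_size Maximum number of areas per leaf node.
#' @return A `spatial_index` object.
#' @export
build_spatial_index <- function(layer, leaf_size = 8L) {
  if (!inherits(layer, "area_layer")) abort("`layer` must be an area_layer")
  n <- nrow(layer$areas)
  if (n == 0L) abort("cannot index an empty layer")
  bb <- do.call(rbind, layer$areas$bbox)  # xmin ymin xmax ymax
  tree <- bbtree_build(seq_len(n), bb, leaf_size)
  structure(list(tree = tree, bboxes = bb, layer_name = layer$layer_name),
            class = "spatial_index")
}

bbtree_build <- function(idx, bb, leaf_size) {
  node_bbox <- c(min(bb[idx, 1L]), min(bb[idx, 2L]),
                 max(bb[idx, 3L]), max(bb[idx, 4L]))
  if (length(idx) <= leaf_size) {
    return(list(bbox = node_bbox, leaf = TRUE, ids = idx))
  }
  cx <- (bb[idx, 1L] + bb[idx, 3L]) / 2
  cy <- (bb[idx, 2L] + bb[idx, 4L]) / 2
  # split on the wider axis at the median center
  wide_x <- (node_bbox[3L] - node_bbox[1L]) >= (node_bbox[4L] - node_bbox[2L])
  ord <- if (wide_x) order(cx, cy, idx) else order(cy, cx, idx)
  half <- ceiling(length(idx) / 2)
  left <- idx[ord[seq_len(half)]]
  right <- idx[ord[-seq_len(half)]]
  list(bbox = node_bbox, leaf = FALSE,
       children = list(bbtree_build(left, bb, leaf_size),
                       bbtree_build(right, bb, leaf_size)))
}

# indices of areas whose bbox contains the point
query_index <- function(index, lon, lat) {
  out <- integer()
  stack <- list(index$tree)
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    b <- node$bbox
    if (lon < b[1L] || lon > b[3L] || lat < b[2L] || lat > b[4L]) next
    if (node$leaf) {
      ids <- node$ids
      bb <- index$bboxes
      hit <- lon >= bb[ids, 1L] & lon <= bb[ids, 3L] &
        lat >= bb[ids, 2L] & lat <= bb[ids, 4L]
      out <- c(out, ids[hit])
    } else {
      stack <- c(stack, node$children)
    }
  }
  out
}

#' Assign a point to the area containing it
#'
#' Runs the exact even-odd containment test on the index candidates. Boundary
#' points count as inside; when a point lies on a shared boundary so that more
#' than one polygon contains it, the lexicographically smallest area id wins
#' and the tie is reported via a message.
#'
#' @param lon,lat Point coordinates in degrees (longitude first).
#' @param index A `spatial_index` from [build_spatial_index()].
#' @param layer The [area_layer()] the index was built from.
#' @param quiet Suppress tie messages.
#' @return The containing `area_id`, or `NA_character_` if the point falls
#'   outside every polygon.
#' @export
assign_area <- function(lon, lat, index, layer, quiet = FALSE) {
  cand <- query_index(index, lon, lat)
  if (length(cand) == 0L) return(NA_character_)
  hits <- cand[vapply(cand, function(i) {
    point_in_polygon(lon, lat, layer$areas$geometry[[i]])
  }, logical(1))]
  if (length(hits) == 0L) return(NA_character_)
  ids <- sort(layer$areas$area_id[hits])
  if (length(ids) > 1L && !quiet) {
    inform(paste0("boundary tie at (", lon, ", ", lat, "): ",
                  paste(ids, collapse = ", "), " -> ", ids[1L]))
  }
  ids[1L]
}

# brute-force oracle: scan every polygon, same tie-break
assign_area_brute <- function(lon, lat, layer) {
  hits <- which(vapply(seq_len(nrow(layer$areas)), function(i) {
    b <- layer$areas$bbox[[i]]
    lon >= b[1L] && lon <= b[3L] && lat >= b[2L] && lat <= b[4L] &&
      point_in_polygon(lon, lat, layer$areas$geometry[[i]])
  }, logical(1)))
  if (length(hits) == 0L) return(NA_character_)
  sort(layer$areas$area_id[hits])[1L]
}

#' Spatially join posts to tract-like and zip-like layers
#'
#' Assigns each post the id of the containing area in each supplied layer
#' (columns `tract_id` and `zip_id`); posts outside every polygon are left
#' unassigned (`NA`). A join report per layer records assigned/unassigned
#' counts and the assigned fraction, retrievable with [join_report()].
#'
#' @param posts A post tibble with `lon`, `lat`.
#' @param tract_layer,zip_layer [area_layer()] objects; `zip_layer` optional.
#' @return The post tibble with `tract_id` (and `zip_id`) columns and a
#'   `join_report` attribute.
#' @export
spatial_join <- function(posts, tract_layer, zip_layer = NULL) {
  layers <- list(tract_id = tract_layer)
  if (!is.null(zip_layer)) layers$zip_id <- zip_layer
  reports <- list()
  for (colname in names(layers)) {
    layer <- layers[[colname]]
    index <- build_spatial_index(layer)
    ids <- vapply(seq_len(nrow(posts)), function(i) {
      assign_area(posts$lon[i], posts$lat[i], index, layer, quiet = TRUE)
    }, character(1))
    posts[[colname]] <- ids
    n_assigned <- sum(!is.na(ids))
    reports[[colname]] <- tibble(
      layer = layer$layer_name,
      n_assigned = n_assigned,
      n_unassigned = nrow(posts) - n_assigned,
      assigned_fraction = if (nrow(posts) > 0) n_assigned / nrow(posts) else NA_real_
    )
  }
  attr(posts, "join_report") <- bind_rows(reports)
  posts
}

#' Retrieve the join report attached by [spatial_join()]
#'
#' @param posts The tibble returned by [spatial_join()].
#' @return A tibble with one row per layer.
#' @export
join_report <- function(posts) {
  rep <- attr(posts, "join_report")
  if (is.null(rep)) abort("no join report attached; run spatial_join() first")
  rep
}
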