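# Spatial containers: polygon layers, point layers and the landscape bundle.
# Polygons are open rings (n x 2 matrices, metres, last vertex not repeated);
# only simple rings without holes are supported, which is all the synthetic
# generator produces and all the exposure algebra requires.

#' Construct a polygon layer
#'
#' A minimal planar polygon layer: a list of open polygon rings (two-column
#' matrices of x/y coordinates in metres, final vertex not repeated) plus a
#' data frame of per-polygon properties.
#'
#' @param polygons list of numeric matrices, each `n x 2` with `n >= 3`.
#' @param props data frame with one row per polygon (may have zero columns).
#' @return an object of class `poly_layer`.
#' @export
poly_layer <- function(polygons, props = NULL) {
  stopifnot(is.list(polygons))
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L || anyNA(p))
      stop("each polygon must be a numeric n x 2 matrix with n >= 3 and no NAs")
  }
  if (is.null(props)) props <- data.frame(row.names = seq_along(polygons))
  if (nrow(props) != length(polygons))
    stop("props must have one row per polygon")
  structure(list(polygons = polygons, props = props), class = "poly_layer")
}

#' @export
print.poly_layer <- function(x, ...) {
  cat("<poly_layer> ", length(x$polygons), " polygons; properties: ",
      paste(names(x$props), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.poly_layer <- function(x) length(x$polygons)

#' Polygon areas of a layer
#' @param layer a [poly_layer()].
#' @return numeric vector of areas in square metres (shoelace formula).
#' @export
layer_areas <- function(layer) {
  vapply(layer$polygons, ring_area_cpp, numeric(1))
}

rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

bbox_of <- function(ring) {
  c(xmin = min(ring[, 1]), ymin = min(ring[, 2]),
    xmax = max(ring[, 1]), ymax = max(ring[, 2]))
}

#' Bundle the four study layers into a landscape
#'
#' @param land_cover [poly_layer()] with a `category` property taking the six
#'   crop categories (see [crop_categories()]) plus `NonCrop`.  Must
#'   tessellate the extent.
#' @param facilities data frame with columns `x`, `y`, `group` (point layer
#'   of industrial facilities).
#' @param urban_areas [poly_layer()] with a `population` property.
#' @param tracts [poly_layer()] with `ses` and `tract_id` properties; must
#'   tessellate the extent.
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param validate check the tessellation invariants (area conservation);
#'   on by default.
#' @return an object of class `landscape`.
#' @export
landscape <- function(land_cover, facilities, urban_areas, tracts, extent,
                      validate = TRUE) {
  stopifnot(inherits(land_cover, "poly_layer"), inherits(tracts, "poly_layer"),
            inherits(urban_areas, "poly_layer"), is.data.frame(facilities),
            length(extent) == 4L)
  if (is.null(land_cover$props$category)) stop("land_cover needs a 'category' property")
  if (is.null(tracts$props$ses)) stop("tracts need an 'ses' property")
  if (is.null(urban_areas$props$population) && length(urban_areas) > 0L)
    stop("urban_areas need a 'population' property")
  if (!all(c("x", "y") %in% names(facilities)))
    stop("facilities need 'x' and 'y' columns")
  obj <- structure(list(land_cover = land_cover, facilities = facilities,
                        urban_areas = urban_areas, tracts = tracts,
                        extent = as.numeric(extent)),
                   class = "landscape")
  if (validate) validate_landscape(obj)
  obj
}

#' @export
print.landscape <- function(x, ...) {
  e <- x$extent
  cat(sprintf("<landscape> extent %.1f x %.1f km\n",
              (e[3] - e[1]) / 1000, (e[4] - e[2]) / 1000))
  cat("  land cover:", length(x$land_cover), "polygons |",
      "facilities:", nrow(x$facilities), "|",
      "urban areas:", length(x$urban_areas), "|",
      "tracts:", length(x$tracts), "\n")
  invisible(x)
}

#' Check landscape tessellation invariants
#'
#' Verifies that the land-cover and tract layers each partition the study
#' extent: polygon areas sum to the extent area (relative tolerance `tol`).
#' Pairwise non-overlap is implied for layers whose areas sum exactly to the
#' extent while jointly covering it; generator output is grid-based so this
#' holds by construction.
#'
#' @param x a [landscape()].
#' @param tol relative area tolerance.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_landscape <- function(x, tol = 1e-6) {
  e <- x$extent
  a_ext <- (e[3] - e[1]) * (e[4] - e[2])
  if (a_ext <= 0) stop("non-positive extent")
  for (nm in c("land_cover", "tracts")) {
    a <- sum(layer_areas(x[[nm]]))
    if (abs(a - a_ext) > tol * a_ext)
      stop(sprintf("%s areas sum to %.6g, extent is %.6g (rel err %.2g)",
                   nm, a, a_ext, abs(a - a_ext) / a_ext))
  }
  invisible(TRUE)
}

#' The crop land-cover categories
#'
#' The six cultivated-land subcategories of the crop index, in canonical
#' order; all other land cover is `NonCrop`.
#' @return character vector of length 6.
#' @export
crop_categories <- function() {
  c("Irrigated", "Rice", "Vineyards", "Fruits", "Olives", "Heterogeneous")
}

land_cover_levels <- function() c(crop_categories(), "NonCrop")

# ---------------------------------------------------------------- GeoJSON IO

ring_to_geojson_coords <- function(ring) {
  closed <- rbind(ring, ring[1L, , drop = FALSE])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

#' Write a polygon or point layer as GeoJSON
#'
#' Layers are written as FeatureCollections with the per-feature properties
#' taken from the layer's property columns.  Output is deterministic (fixed
#' 10-digit coordinate formatting), so identical layers produce byte-identical
#' files.
#'
#' @param layer a [poly_layer()] or a data frame with `x`/`y` columns (points).
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_geojson <- function(layer, path) {
  if (inherits(layer, "poly_layer")) {
    feats <- lapply(seq_along(layer$polygons), function(i) {
      list(type = "Feature",
           properties = as.list(layer$props[i, , drop = FALSE]),
           geometry = list(type = "Polygon",
                           coordinates = list(ring_to_geojson_coords(layer$polygons[[i]]))))
    })
  } else if (is.data.frame(layer)) {
    prop_cols <- setdiff(names(layer), c("x", "y"))
    feats <- lapply(seq_len(nrow(layer)), function(i) {
      list(type = "Feature",
           properties = as.list(layer[i, prop_cols, drop = FALSE]),
           geometry = list(type = "Point",
                           coordinates = c(layer$x[i], layer$y[i])))
    })
  } else stop("layer must be a poly_layer or a point data frame")
  gj <- list(type = "FeatureCollection", features = feats)
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 10, pretty = FALSE)
  writeLines(txt, path)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection written by [write_geojson()]
#'
#' Supports Polygon (single outer ring, no holes) and Point geometries.
#'
#' @param path GeoJSON file path.
#' @return a [poly_layer()] for polygon collections, a data frame for point
#'   collections.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("not a FeatureCollection")
  feats <- gj$features
  if (length(feats) == 0L) stop("empty FeatureCollection")
  gtype <- feats[[1L]]$geometry$type
  props <- do.call(rbind, lapply(feats, function(f) {
    as.data.frame(lapply(f$properties, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  if (identical(gtype, "Polygon")) {
    polys <- lapply(feats, function(f) {
      rings <- f$geometry$coordinates
      if (length(rings) > 1L) stop("polygon holes are not supported")
      m <- do.call(rbind, lapply(rings[[1L]], function(xy) unlist(xy)))
      # drop the closing vertex
      if (isTRUE(all.equal(m[1L, ], m[nrow(m), ], tolerance = 1e-12)))
        m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y")
      m
    })
    poly_layer(polys, props)
  } else if (identical(gtype, "Point")) {
    xy <- do.call(rbind, lapply(feats, function(f) unlist(f$geometry$coordinates)))
    out <- data.frame(x = xy[, 1], y = xy[, 2])
    if (!is.null(props) && ncol(props) > 0L) out <- cbind(out, props)
    out
  } else stop("unsupported geometry type: ", gtype)
}

#' Write a landscape's four layers to a directory
#'
#' Writes `landcover.geojson`, `facilities.geojson`, `urban.geojson`,
#' `tracts.geojson` and `extent.json`.
#'
#' @param x a [landscape()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_landscape <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geojson(x$land_cover, file.path(dir, "landcover.geojson"))
  write_geojson(x$facilities, file.path(dir, "facilities.geojson"))
  write_geojson(x$urban_areas, file.path(dir, "urban.geojson"))
  write_geojson(x$tracts, file.path(dir, "tracts.geojson"))
  jsonlite::write_json(list(extent = x$extent), file.path(dir, "extent.json"),
                       auto_unbox = FALSE, digits = 10)
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#' @param dir directory containing the layer files.
#' @return a [landscape()].
#' @export
read_landscape <- function(dir) {
  ext <- unlist(jsonlite::fromJSON(file.path(dir, "extent.json"))$extent)
  landscape(read_geojson(file.path(dir, "landcover.geojson")),
            read_geojson(file.path(dir, "facilities.geojson")),
            read_geojson(file.path(dir, "urban.geojson")),
            read_geojson(file.path(dir, "tracts.geojson")),
            ext)
}

#' Read/write the subjects table
#'
#' Subjects are exchanged as CSV with the canonical column set
#' `id,x,y,sex,birth_year,region,status,subgroup,same_address,geocode_valid`.
#'
#' @param subjects subjects data frame.
#' @param path CSV path.
#' @return the data frame (read) or `path` invisibly (write).
#' @export
write_subjects <- function(subjects, path) {
  write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("same_address" %in% names(df)) df$same_address <- as.logical(df$same_address)
  if ("geocode_valid" %in% names(df)) df$geocode_valid <- as.logical(df$geocode_valid)
  df
}
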