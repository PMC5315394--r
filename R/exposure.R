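# Crop exposure: area-fraction indices inside a circular buffer around each
# residence.  Exact geometry via convex clipping of land-cover polygons
# against a polygonal buffer; an independent Monte-Carlo estimator serves as
# a brute-force oracle.

crop_cols <- function() tolower(crop_categories())

#' Crop indices in a circular buffer
#'
#' For each residence, the percentage of the buffer covered by each of the
#' six crop categories, plus their total, the Global Crop Index (GCI).
#' Values are percentage points in \[0, 100\]; `NonCrop` land (and any part of
#' the buffer outside the mapped layer) counts as zero.  The circular buffer
#' is approximated by a regular polygon with `segments` sides (>= 64); the
#' polygon's own area is the denominator, so full containment yields exactly
#' 100.
#'
#' Overlapping polygons within the layer are malformed input (the land-cover
#' tessellation is a partition); if the summed clipped areas exceed the
#' buffer area the affected points are recomputed by a deterministic
#' Monte-Carlo union estimate and a warning is raised.
#'
#' @param x,y residence coordinates in metres (vectors).
#' @param land_cover a [poly_layer()] with a `category` property.
#' @param radius_m buffer radius in metres (> 0), default 1000.
#' @param segments buffer polygon segments (>= 64).
#' @return data frame with columns `gci`, `irrigated`, `rice`, `vineyards`,
#'   `fruits`, `olives`, `heterogeneous` (percentage points); attribute
#'   `radius_m`.  Rows with `NA` coordinates give `NA` indices.
#' @export
crop_index <- function(x, y, land_cover, radius_m = 1000, segments = 64) {
  if (radius_m <= 0) stop("radius_m must be positive")
  if (segments < 64) stop("buffer needs at least 64 segments")
  stopifnot(length(x) == length(y))
  lvls <- land_cover_levels()
  out <- as.data.frame(matrix(0, length(x), length(crop_cols()),
                              dimnames = list(NULL, crop_cols())))
  if (length(land_cover) == 0L) {
    warning("empty land-cover layer: returning all-zero crop indices")
    res <- cbind(gci = rep(0, length(x)), out)
    res[is.na(x) | is.na(y), ] <- NA_real_
    attr(res, "radius_m") <- radius_m
    return(res)
  }
  cat_idx <- match(land_cover$props$category, lvls)
  if (anyNA(cat_idx)) stop("unknown land-cover category")
  areas <- buffer_category_areas_cpp(x, y, radius_m, as.integer(segments),
                                     land_cover$polygons,
                                     as.integer(cat_idx), length(lvls))
  buf_area <- attr(areas, "buffer_area")

  # malformed input: overlapping polygons double-count area
  tot <- rowSums(areas)
  bad <- which(!is.na(tot) & tot > buf_area * (1 + 1e-9))
  pct <- 100 * areas / buf_area
  if (length(bad)) {
    warning(sprintf(paste0("overlapping land-cover polygons detected at %d ",
                           "point(s); using Monte-Carlo union estimate"),
                    length(bad)))
    for (i in bad) {
      mc <- mc_category_fractions(x[i], y[i], radius_m, land_cover,
                                  n_samples = 2e5, seed = 1L)
      pct[i, ] <- 100 * mc
    }
  }
  pct <- pmin(pmax(pct, 0), 100)
  colnames(pct) <- c(crop_cols(), "noncrop")
  res <- data.frame(gci = pmin(rowSums(pct[, crop_cols(), drop = FALSE]), 100))
  res <- cbind(res, as.data.frame(pct[, crop_cols(), drop = FALSE]))
  res[is.na(x) | is.na(y), ] <- NA_real_
  attr(res, "radius_m") <- radius_m
  res
}

# R-side even-odd point-in-ring test, vectorized over points; kept separate
# from (and independent of) the compiled geometry.
pip_r <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# fractions of uniformly sampled buffer points falling in each category's
# polygon union; returns a named vector over land_cover_levels()
mc_category_fractions <- function(x, y, radius_m, land_cover, n_samples, seed) {
  set.seed(seed)
  th <- runif(n_samples, 0, 2 * pi)
  rr <- radius_m * sqrt(runif(n_samples))
  px <- x + rr * cos(th)
  py <- y + rr * sin(th)
  lvls <- land_cover_levels()
  hits <- matrix(FALSE, n_samples, length(lvls))
  for (p in seq_along(land_cover$polygons)) {
    ring <- land_cover$polygons[[p]]
    b <- bbox_of(ring)
    cand <- which(px >= b[1] & px <= b[3] & py >= b[2] & py <= b[4])
    if (!length(cand)) next
    ci <- match(land_cover$props$category[p], lvls)
    inside <- pip_r(px[cand], py[cand], ring)
    hits[cand[inside], ci] <- TRUE
  }
  colMeans(hits)
}

#' Monte-Carlo oracle for the crop index
#'
#' Brute-force estimator of the buffer crop fractions by uniform sampling of
#' points in the circular buffer and point-in-polygon membership counting
#' (union semantics per category).  Independent of the exact clipping code
#' path; standard error is at most 0.5 percentage points at `n_samples =
#' 1e5`.
#'
#' @param x,y a single residence coordinate.
#' @param land_cover a [poly_layer()] with a `category` property.
#' @param radius_m buffer radius (> 0).
#' @param n_samples number of sampled points (>= 1e4).
#' @param seed integer seed.
#' @return one-row data frame shaped like [crop_index()] output.
#' @export
crop_index_oracle <- function(x, y, land_cover, radius_m = 1000,
                              n_samples = 1e5, seed = 1) {
  if (radius_m <= 0) stop("radius_m must be positive")
  if (n_samples < 1e4) stop("n_samples must be >= 1e4")
  stopifnot(length(x) == 1L, length(y) == 1L)
  if (length(land_cover) == 0L) {
    warning("empty land-cover layer: returning all-zero crop indices")
    res <- as.data.frame(as.list(setNames(rep(0, 7), c("gci", crop_cols()))))
    attr(res, "radius_m") <- radius_m
    return(res)
  }
  frac <- mc_category_fractions(x, y, radius_m, land_cover, n_samples, seed)
  pct <- 100 * frac[seq_along(crop_cols())]
  res <- data.frame(gci = sum(pct))
  res <- cbind(res, as.data.frame(as.list(setNames(pct, crop_cols()))))
  attr(res, "radius_m") <- radius_m
  res
}

#' Scale a crop index for the regression model
#'
#' The model covariate is the index divided by 10, so a unit coefficient
#' exponentiates to the odds ratio per 10-percentage-point increase in
#' cultivated land.
#'
#' @param index a [crop_index()] data frame or a numeric vector of
#'   percentage points.
#' @return numeric vector, `gci / 10`.
#' @export
scale_for_model <- function(index) {
  g <- if (is.data.frame(index)) index$gci else index
  g / 10
}
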