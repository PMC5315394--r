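# Shared fixtures and independent R-side oracles for the test suite.
# Oracles here deliberately avoid the package's compiled geometry.

# small study configuration that keeps simulations fast; overrides win
tiny_config <- function(...) {
  args <- list(extent_m = 20000, n_cells = 100, n_tracts = 64,
               n_facilities = 12, n_urban = 6, pool_size = 4000,
               n_cases = 80, birth_years = 2000:2005,
               regions = c("A", "B", "C"),
               region_weights = c(1, 1, 1) / 3,
               urban_meanlog = log(12000))
  user <- list(...)
  args[names(user)] <- user
  do.call(study_config, args)
}

# axis-aligned rectangle ring (open)
rect_ring_test <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# one-polygon layer covering [0, L]^2
square_layer <- function(category, L = 10000) {
  poly_layer(list(cbind(c(0, L, L, 0), c(0, 0, L, L))),
             data.frame(category = category, stringsAsFactors = FALSE))
}

# two half-plane rectangles split at x = split_x over [0, L]^2
halfplane_layer <- function(left = "Irrigated", right = "NonCrop",
                            split_x = 5000, L = 10000) {
  poly_layer(list(cbind(c(0, split_x, split_x, 0), c(0, 0, L, L)),
                  cbind(c(split_x, L, L, split_x), c(0, 0, L, L))),
             data.frame(category = c(left, right), stringsAsFactors = FALSE))
}

# regular polygon approximating a disc (independent of the package buffer)
disc_ring <- function(cx, cy, r, n = 512) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# even-odd ray-casting point-in-polygon, plain R (test oracle)
pip_oracle <- function(px, py, ring) {
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

# exhaustive O(n*m) nearest-facility distance (test oracle)
nearest_oracle <- function(px, py, fx, fy) {
  vapply(seq_along(px), function(i) {
    sqrt(min((px[i] - fx)^2 + (py[i] - fy)^2))
  }, numeric(1))
}

# rule-level reimplementation of the environment classification (test oracle)
classify_oracle <- function(px, py, facilities, urban_areas, D_m, outer_m,
                            pop_threshold = 10000) {
  d <- nearest_oracle(px, py, facilities$x, facilities$y)
  u <- rep(FALSE, length(px))
  for (p in seq_along(urban_areas$polygons)) {
    if (urban_areas$props$population[p] < pop_threshold) next
    u <- u | pip_oracle(px, py, urban_areas$polygons[[p]])
  }
  ifelse(u & d <= D_m, "intersection",
  ifelse(!u & d <= D_m, "industrial",
  ifelse(u, "urban",
  ifelse(d <= outer_m, "ring", "rural"))))
}

# small synthetic analysis data set for direct model fits (no geometry)
fake_analysis_data <- function(n = 800, n_regions = 3, seed = 42,
                               beta_gci10 = 0, p0 = 0.3) {
  set.seed(seed)
  region <- sample(LETTERS[seq_len(n_regions)], n, replace = TRUE)
  gci <- ifelse(runif(n) < 0.5, 0, runif(n, 0, 100))
  env <- sample(c("rural", "industrial", "intersection", "urban", "ring"),
                n, replace = TRUE)
  ses_q <- sample(paste0("Q", 1:4), n, replace = TRUE)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  birth_year <- sample(2000:2009, n, replace = TRUE)
  lp <- qlogis(p0) + beta_gci10 * gci / 10
  status <- ifelse(runif(n) < plogis(lp), "case", "control")
  data.frame(status = status, env = env, ses_q = ses_q, gci = gci,
             sex = sex, birth_year = birth_year, region = region,
             stringsAsFactors = FALSE)
}
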