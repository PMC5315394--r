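# Synthetic landscape, population and outcome generators.  Everything is a
# pure function of (config, seed).

# jittered grid breaks: monotone, cover [0, L] exactly, random within-cell
# perturbation so the partition is not a regular lattice.
jitter_breaks <- function(n, L) {
  if (n < 1L) stop("need at least one cell per axis")
  inner <- seq_len(n - 1L) / n
  if (n > 1L) inner <- inner + runif(n - 1L, -0.3, 0.3) / n
  c(0, inner, 1) * L
}

grid_layer <- function(n_cells, L) {
  nx <- max(1L, ceiling(sqrt(n_cells)))
  ny <- max(1L, round(n_cells / nx))
  xs <- jitter_breaks(nx, L)
  ys <- jitter_breaks(ny, L)
  polys <- vector("list", nx * ny)
  cx <- numeric(nx * ny); cy <- numeric(nx * ny)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      polys[[k]] <- rect_ring(xs[i], ys[j], xs[i + 1L], ys[j + 1L])
      cx[k] <- (xs[i] + xs[i + 1L]) / 2
      cy[k] <- (ys[j] + ys[j + 1L]) / 2
    }
  }
  list(polys = polys, cx = cx, cy = cy)
}

facility_groups <- function() {
  c("chemical", "metal", "food", "energy", "waste", "mineral")
}

#' Generate a synthetic landscape
#'
#' Builds the four study layers over a square extent: a land-cover
#' tessellation (jittered rectangular partition, i.i.d. category labels from
#' the configured mixture), a uniform facility point process, urban polygons
#' with log-normal populations and area proportional to population, and a
#' census-tract tessellation with SES values uniform on the configured range.
#' Optional per-region overrides (`region_crop_weights`, `region_ses_range`)
#' apply to cells/tracts whose centre falls in that region's band.
#'
#' @param config a [study_config()].
#' @param seed integer seed; the landscape is a pure function of
#'   (config, seed).
#' @return a [landscape()].
#' @export
generate_landscape <- function(config, seed) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  L <- config$extent_m
  lvls <- land_cover_levels()

  # land cover
  g <- grid_layer(config$n_cells, L)
  n <- length(g$polys)
  cat_lab <- character(n)
  if (is.null(config$region_crop_weights)) {
    cat_lab <- sample(lvls, n, replace = TRUE, prob = config$crop_weights)
  } else {
    reg <- region_of_x(g$cx, config)
    for (r in unique(reg)) {
      w <- config$region_crop_weights[[r]]
      if (is.null(w)) w <- config$crop_weights else w <- w[lvls]
      idx <- which(reg == r)
      cat_lab[idx] <- sample(lvls, length(idx), replace = TRUE, prob = w)
    }
  }
  land_cover <- poly_layer(g$polys,
                           data.frame(category = cat_lab, stringsAsFactors = FALSE))

  # facilities
  nf <- config$n_facilities
  facilities <- data.frame(
    x = runif(nf, 0, L), y = runif(nf, 0, L),
    group = sample(facility_groups(), nf, replace = TRUE),
    stringsAsFactors = FALSE)

  # urban areas: squares sized by population, clipped to the extent
  nu <- config$n_urban
  pop <- pmax(1000, round(rlnorm(nu, config$urban_meanlog, config$urban_sdlog)))
  side <- sqrt(pop * config$area_per_capita)
  ux <- runif(nu, 0, L); uy <- runif(nu, 0, L)
  upolys <- lapply(seq_len(nu), function(i) {
    rect_ring(max(0, ux[i] - side[i] / 2), max(0, uy[i] - side[i] / 2),
              min(L, ux[i] + side[i] / 2), min(L, uy[i] + side[i] / 2))
  })
  urban_areas <- poly_layer(upolys, data.frame(population = pop))

  # tracts
  gt <- grid_layer(config$n_tracts, L)
  nt <- length(gt$polys)
  ses <- runif(nt, config$ses_range[1], config$ses_range[2])
  if (!is.null(config$region_ses_range)) {
    reg <- region_of_x(gt$cx, config)
    for (r in names(config$region_ses_range)) {
      idx <- which(reg == r)
      rr <- config$region_ses_range[[r]]
      if (length(idx)) ses[idx] <- runif(length(idx), rr[1], rr[2])
    }
  }
  tracts <- poly_layer(gt$polys,
                       data.frame(tract_id = sprintf("T%04d", seq_len(nt)),
                                  ses = ses, stringsAsFactors = FALSE))

  landscape(land_cover, facilities, urban_areas, tracts,
            extent = c(0, 0, L, L))
}

# Draw residence coordinates for subjects with given region labels, using the
# current RNG stream.  With probability urban_weight a subject is placed
# uniformly inside a population-weighted urban polygon of its region band,
# otherwise uniformly over the band.
place_in_region <- function(region, landscape, config) {
  n <- length(region)
  L <- config$extent_m
  bands <- region_bands(config)
  rownames(bands) <- bands$region
  x <- numeric(n); y <- numeric(n)
  in_town <- runif(n) < config$urban_weight
  up <- landscape$urban_areas
  ub <- if (length(up) > 0L) t(vapply(up$polygons, bbox_of, numeric(4))) else
    matrix(numeric(0), 0, 4)
  ucx <- if (nrow(ub)) (ub[, 1] + ub[, 3]) / 2 else numeric(0)
  for (r in unique(region)) {
    ridx <- which(region == r)
    b <- bands[r, ]
    # candidate urban polygons: centre in this band, clipped to the band
    cand <- which(ucx >= b$xmin & ucx < b$xmax)
    town <- ridx[in_town[ridx]]
    open <- ridx[!in_town[ridx]]
    if (length(cand) == 0L) { open <- ridx; town <- integer(0) }
    if (length(town)) {
      pick <- cand[sample.int(length(cand), length(town), replace = TRUE,
                              prob = up$props$population[cand])]
      xlo <- pmax(ub[pick, 1], b$xmin); xhi <- pmin(ub[pick, 3], b$xmax)
      bad <- xlo >= xhi  # polygon sticks out of the band entirely
      x[town] <- xlo + runif(length(town)) * pmax(0, xhi - xlo)
      y[town] <- ub[pick, 2] + runif(length(town)) * (ub[pick, 4] - ub[pick, 2])
      if (any(bad)) {
        nb <- sum(bad)
        x[town[bad]] <- runif(nb, b$xmin, b$xmax)
        y[town[bad]] <- runif(nb, 0, L)
      }
    }
    if (length(open)) {
      x[open] <- runif(length(open), b$xmin, b$xmax)
      y[open] <- runif(length(open), 0, L)
    }
  }
  data.frame(x = x, y = y)
}

#' Generate a synthetic population-at-risk pool
#'
#' Subjects carry the matching variables (sex, birth year, region), planar
#' residence coordinates and a geocode-validity flag; a configured fraction
#' (default 2%) gets invalid geocodes (`NA` coordinates), mirroring failed
#' address geocoding.  Regions are vertical bands of the extent; the region
#' label is drawn from the configured marginal and the residence placed
#' within the label's band, concentrated in urban polygons with probability
#' `urban_weight`.
#'
#' @param landscape a [landscape()].
#' @param n pool size (>= 1).
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return subjects data frame (all `status = "control"`).
#' @export
generate_population <- function(landscape, n, config, seed) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  region <- sample(config$regions, n, replace = TRUE,
                   prob = config$region_weights)
  pos <- place_in_region(region, landscape, config)
  sex <- ifelse(runif(n) < config$sex_prob_m, "M", "F")
  birth_year <- sample(config$birth_years, n, replace = TRUE)
  geocode_valid <- runif(n) >= config$invalid_fraction
  pos$x[!geocode_valid] <- NA_real_
  pos$y[!geocode_valid] <- NA_real_
  data.frame(id = sprintf("S%06d", seq_len(n)),
             x = pos$x, y = pos$y, sex = sex, birth_year = birth_year,
             region = region, status = "control",
             subgroup = NA_character_, same_address = TRUE,
             geocode_valid = geocode_valid, stringsAsFactors = FALSE)
}

#' Sample case status from the logistic outcome model
#'
#' Each subject's case probability follows
#' `logit(p) = intercept + log(OR_gci) * gci/10 + quartile and environment
#' terms + sex and year terms + region intercept`, with the region intercept
#' drawn once per region from a zero-mean normal with sd `region_sd`.
#' Exactly `n_cases` subjects are sampled as cases, proportionally to these
#' probabilities (weighted sampling without replacement), mirroring a
#' registry of fixed case count.  Cases receive subgroup labels from the
#' configured multinomial, independently of exposure.
#'
#' Subjects whose profile is incomplete (invalid geocodes) get zero case
#' weight: the study's cases are the successfully geocoded ones.
#'
#' @param pool subjects data frame from [generate_population()].
#' @param profiles exposure profiles aligned 1:1 with `pool` (see
#'   [exposure_profiles()]); must contain `gci`, `env` and either `ses_q` or
#'   `ses_value` (quartiles then computed over the pool).
#' @param params a [true_params()] object.
#' @param n_cases number of cases (< pool size).
#' @param seed integer seed.
#' @param subgroup_probs named subgroup multinomial (defaults to the registry
#'   shares).
#' @param region_cases optional named integer vector of per-region case
#'   totals (summing to `n_cases`): cases are then drawn region by region,
#'   still proportionally to the model probabilities within each region.
#'   This mirrors a registry with a fixed regional case distribution and
#'   keeps the matched design feasible; `NULL` (default) samples globally.
#' @return list with elements `cases` and `pool` (the remaining controls),
#'   plus `region_effects` (the realized region intercepts).
#' @export
assign_outcomes <- function(pool, profiles, params, n_cases, seed,
                            subgroup_probs = NULL, region_cases = NULL) {
  stopifnot(inherits(params, "true_params"))
  if (nrow(profiles) != nrow(pool))
    stop("profiles must be aligned 1:1 with pool")
  if (n_cases >= nrow(pool)) stop("n_cases must be smaller than the pool")
  if (is.null(subgroup_probs)) {
    sg <- registry_subgroup_counts()
    subgroup_probs <- setNames(sg$cases / sum(sg$cases), sg$subgroup)
  }
  set.seed(seed)

  ses_q <- profiles$ses_q
  if (is.null(ses_q)) {
    qq <- ses_quartiles(profiles$ses_value[!is.na(profiles$ses_value)])
    ses_q <- ses_quartile(profiles$ses_value, qq)
  }
  regions <- sort(unique(pool$region))
  u <- setNames(rnorm(length(regions), 0, params$region_sd), regions)

  b_ses <- c(Q1 = 0, log(params$or_ses_q))
  b_env <- c(rural = 0, log(params$or_env))
  yc <- pool$birth_year - mean(pool$birth_year)
  lp <- params$intercept +
    log(params$or_gci_per10) * profiles$gci / 10 +
    b_ses[as.character(ses_q)] +
    b_env[as.character(profiles$env)] +
    log(params$or_sex) * (pool$sex == "M") +
    log(params$or_year) * yc +
    u[pool$region]
  p <- plogis(lp)
  p[is.na(p)] <- 0
  if (sum(p > 0) < n_cases) stop("not enough subjects with positive case weight")
  if (is.null(region_cases)) {
    idx <- sample.int(nrow(pool), n_cases, prob = p)
  } else {
    if (abs(sum(region_cases) - n_cases) > 0)
      stop("region_cases must sum to n_cases")
    idx <- integer(0)
    for (r in names(region_cases)) {
      rid <- which(pool$region == r)
      if (sum(p[rid] > 0) < region_cases[[r]])
        stop("not enough weighted subjects in region ", r)
      idx <- c(idx, rid[sample.int(length(rid), region_cases[[r]],
                                   prob = p[rid])])
    }
  }

  cases <- pool[idx, , drop = FALSE]
  cases$status <- "case"
  cases$subgroup <- sample(names(subgroup_probs), n_cases, replace = TRUE,
                           prob = subgroup_probs)
  rest <- pool[-idx, , drop = FALSE]
  rownames(cases) <- rownames(rest) <- NULL
  list(cases = cases, pool = rest, region_effects = u)
}

#' Relocate a fraction of cases after outcome assignment
#'
#' Emulates residential mobility between birth and diagnosis: a configured
#' fraction of cases is moved to a fresh residence drawn from the population
#' placement model within the same region, independently of exposure, and
#' flagged `same_address = FALSE`.  The main analysis then measures movers'
#' exposure at the diagnosis address, the same-address sensitivity analysis
#' excludes them.
#'
#' @param cases case subjects data frame.
#' @param landscape a [landscape()].
#' @param config a [study_config()] (uses `mover_fraction`, placement knobs).
#' @param seed integer seed.
#' @return the cases data frame with updated coordinates and `same_address`.
#' @export
apply_moves <- function(cases, landscape, config, seed) {
  set.seed(seed)
  mover <- runif(nrow(cases)) < config$mover_fraction
  mover[!cases$geocode_valid] <- FALSE
  if (any(mover)) {
    pos <- place_in_region(cases$region[mover], landscape, config)
    cases$x[mover] <- pos$x
    cases$y[mover] <- pos$y
  }
  cases$same_address <- !mover
  cases
}
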