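# Study configuration, true simulation parameters and registry reference
# counts used as default simulation marginals.

#' Reference case counts by tumor subgroup
#'
#' Distribution of the 714 childhood CNS tumor cases by ICCC-3 Group III
#' subgroup in the Spanish registry study population (RETI-SEHOP, five
#' autonomous regions, 1996-2011), used as the default subgroup multinomial
#' of the outcome simulator.
#'
#' @return data frame with columns `subgroup`, `cases`, `boys`, `girls`,
#'   `same_address` (cases with the same address at birth and at diagnosis).
#' @export
registry_subgroup_counts <- function() {
  data.frame(
    subgroup = c("ependymoma", "astrocytoma", "iiet", "other_gliomas",
                 "other_specified", "unspecified"),
    cases = c(94L, 258L, 171L, 88L, 72L, 31L),
    boys = c(55L, 129L, 102L, 38L, 46L, 14L),
    girls = c(39L, 129L, 69L, 50L, 26L, 17L),
    same_address = c(55L, 112L, 78L, 40L, 28L, 19L),
    stringsAsFactors = FALSE
  )
}

#' Reference case counts by autonomous region
#'
#' Regional distribution of the same registry study population, used as the
#' default region marginal of the population simulator.
#'
#' @return data frame with columns `region`, `total`, `boys`, `girls`.
#' @export
registry_region_counts <- function() {
  data.frame(
    region = c("Aragon", "Catalonia", "Madrid", "Navarre", "BasqueCountry"),
    total = c(52L, 343L, 201L, 35L, 83L),
    boys = c(30L, 178L, 111L, 23L, 42L),
    girls = c(22L, 165L, 90L, 12L, 41L),
    stringsAsFactors = FALSE
  )
}

#' True odds ratios for the outcome simulator
#'
#' The generating parameters of the logistic outcome model.  Defaults are the
#' adjusted point estimates of the full-study (Total CNS) model: OR 1.22 per
#' 10 percentage points of crop index, SES quartile ORs 0.97/1.01/1.37
#' (Q2/Q3/Q4 vs Q1), environment ORs 0.96 (industrial), 1.20 (intersection),
#' 0.90 (urban) vs rural; the non-urban 2-5 km ring, sex and birth year
#' default to null.  `intercept` is the baseline log-odds (rural, Q1, zero
#' crop); with the default -7 the outcome is rare everywhere so case sampling
#' weights are proportional to the exposure odds.  `region_sd` is the
#' standard deviation of the zero-mean normal region intercept.
#'
#' @param or_gci_per10 OR per 10 percentage points of the crop index.
#' @param or_ses_q length-3 positive vector: Q2, Q3, Q4 vs Q1.
#' @param or_env named length-4 positive vector: industrial, intersection,
#'   urban, ring vs rural.
#' @param or_sex OR for male vs female.
#' @param or_year OR per birth year (centered).
#' @param intercept baseline log-odds.
#' @param region_sd sd of the region random intercept (log-odds scale).
#' @return object of class `true_params`.
#' @export
true_params <- function(or_gci_per10 = 1.22,
                        or_ses_q = c(Q2 = 0.97, Q3 = 1.01, Q4 = 1.37),
                        or_env = c(industrial = 0.96, intersection = 1.20,
                                   urban = 0.90, ring = 1.00),
                        or_sex = 1.0, or_year = 1.0,
                        intercept = -7, region_sd = 0.15) {
  or_ses_q <- setNames(as.numeric(or_ses_q), c("Q2", "Q3", "Q4"))
  or_env <- setNames(as.numeric(or_env),
                     c("industrial", "intersection", "urban", "ring"))
  stopifnot(or_gci_per10 > 0, all(or_ses_q > 0), all(or_env > 0),
            or_sex > 0, or_year > 0, is.finite(region_sd), region_sd >= 0)
  structure(list(or_gci_per10 = or_gci_per10, or_ses_q = or_ses_q,
                 or_env = or_env, or_sex = or_sex, or_year = or_year,
                 intercept = intercept, region_sd = region_sd),
            class = "true_params")
}

#' Null true parameters (all odds ratios 1)
#' @param region_sd region random-intercept sd (default 0).
#' @param intercept baseline log-odds.
#' @return a [true_params()] object with every OR equal to 1.
#' @export
null_params <- function(region_sd = 0, intercept = -7) {
  true_params(or_gci_per10 = 1, or_ses_q = c(1, 1, 1),
              or_env = c(1, 1, 1, 1), or_sex = 1, or_year = 1,
              intercept = intercept, region_sd = region_sd)
}

#' Study configuration
#'
#' All thresholds, radii, sample sizes and generator parameters for one
#' pipeline run.  Defaults reproduce the reference study design: 714 cases
#' matched 1:6 (4284 controls) across five regions with the registry region
#' marginal, a 1-km exposure buffer, industrial distance D = 2 km with a 5-km
#' outer (rural) threshold, control-based SES quartiles, 2% invalid geocodes
#' and a 53.5% post-outcome mover fraction (332 of 714 cases keep their birth
#' address).
#'
#' @param extent_m side of the square study extent in metres.
#' @param n_cells approximate number of land-cover polygons.
#' @param n_tracts approximate number of census tracts.
#' @param n_facilities number of industrial facility points.
#' @param n_urban number of urban polygons.
#' @param crop_weights named mixture weights over the land-cover categories
#'   (six crop categories plus NonCrop); must sum to 1.
#' @param ses_range range of the census-tract SES variable.
#' @param urban_pop_threshold minimum population for a polygon to count as
#'   urban in the environment classification.
#' @param urban_meanlog,urban_sdlog log-normal parameters of urban populations.
#' @param area_per_capita square metres of urban polygon per inhabitant.
#' @param pool_size size of the simulated population-at-risk pool.
#' @param urban_weight probability that a subject lives inside an urban
#'   polygon (the remainder is uniform over the region band).
#' @param invalid_fraction fraction of pool subjects with invalid geocodes.
#' @param sex_prob_m probability of sex M.
#' @param birth_years integer vector of possible birth years.
#' @param regions character vector of region names.
#' @param region_weights region marginal (defaults to the registry case
#'   shares).
#' @param region_crop_weights optional named list: per-region override of
#'   `crop_weights` applied to land-cover cells whose centre falls in that
#'   region's band (e.g. a crop-free region).
#' @param region_ses_range optional named list: per-region override of
#'   `ses_range` for tracts whose centre falls in that region's band.
#' @param n_cases number of cases to sample.
#' @param ratio controls per case.
#' @param birth_year_window matching window on birth year (0 = exact).
#' @param radius_m crop-index buffer radius in metres.
#' @param buffer_segments number of segments of the polygonal buffer (>= 64).
#' @param D_m industrial exposure distance in metres.
#' @param outer_m outer (rural) distance in metres.
#' @param D_list distances for the sensitivity sweep, metres.
#' @param urban_buffer_m optional buffer around urban polygons when testing
#'   urban membership (default 0).
#' @param quartile_reference `"controls"` or `"all"`: population whose SES
#'   distribution defines the quartile cut-points.
#' @param mover_fraction fraction of cases relocated after outcome
#'   assignment (diagnosis address differs from birth address).
#' @param stratify_cases_by_region fix per-region case totals at the region
#'   marginal (largest-remainder allocation), mirroring a registry with a
#'   fixed regional case distribution; default `TRUE`.
#' @param subgroup_probs named numeric vector of subgroup probabilities for
#'   cases (defaults to the registry shares).
#' @param params a [true_params()] object.
#' @param analyses which report sections [run_study()] computes; any subset
#'   of `c("main", "subgroups", "crops", "sweep", "same_address", "regions")`.
#' @param year_coding `"linear"` or `"categorical"` birth-year fixed effect.
#' @return object of class `study_config`.
#' @export
study_config <- function(extent_m = 50000, n_cells = 2500, n_tracts = 400,
                         n_facilities = 40, n_urban = 15,
                         crop_weights = c(Irrigated = 0.15, Rice = 0.02,
                                          Vineyards = 0.04, Fruits = 0.08,
                                          Olives = 0.06, Heterogeneous = 0.10,
                                          NonCrop = 0.55),
                         ses_range = c(0.46, 1.57),
                         urban_pop_threshold = 10000,
                         urban_meanlog = log(20000), urban_sdlog = 1,
                         area_per_capita = 250,
                         pool_size = 45000, urban_weight = 0.7,
                         invalid_fraction = 0.02, sex_prob_m = 0.512,
                         birth_years = 1996:2011,
                         regions = registry_region_counts()$region,
                         region_weights = registry_region_counts()$total /
                           sum(registry_region_counts()$total),
                         region_crop_weights = NULL,
                         region_ses_range = NULL,
                         n_cases = 714, ratio = 6, birth_year_window = 0,
                         radius_m = 1000, buffer_segments = 64,
                         D_m = 2000, outer_m = 5000,
                         D_list = c(1000, 1500, 2000, 2500, 3000, 4000, 5000),
                         urban_buffer_m = 0,
                         quartile_reference = c("controls", "all"),
                         mover_fraction = 1 - 332 / 714,
                         stratify_cases_by_region = TRUE,
                         subgroup_probs = NULL,
                         params = true_params(),
                         analyses = c("main", "subgroups", "crops", "sweep",
                                      "same_address", "regions"),
                         year_coding = c("linear", "categorical")) {
  quartile_reference <- match.arg(quartile_reference)
  year_coding <- match.arg(year_coding)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (extent_m <= 0) stop("extent_m must be positive")
  if (is.null(names(crop_weights)) ||
      !setequal(names(crop_weights), land_cover_levels()))
    stop("crop_weights must be named with the six crop categories plus NonCrop")
  crop_weights <- crop_weights[land_cover_levels()]
  if (length(crop_weights) == 0L || any(crop_weights < 0) ||
      abs(sum(crop_weights) - 1) > 1e-8)
    stop("crop_weights must be non-negative and sum to 1")
  stopifnot(radius_m > 0, D_m > 0, outer_m > 0, D_m <= outer_m,
            buffer_segments >= 64, ratio >= 1, n_cases >= 1,
            pool_size > n_cases, invalid_fraction >= 0, invalid_fraction < 1,
            mover_fraction >= 0, mover_fraction <= 1,
            length(regions) == length(region_weights),
            all(region_weights > 0), diff(ses_range) > 0)
  if (is.null(subgroup_probs)) {
    sg <- registry_subgroup_counts()
    subgroup_probs <- setNames(sg$cases / sum(sg$cases), sg$subgroup)
  }
  structure(list(
    extent_m = extent_m, n_cells = n_cells, n_tracts = n_tracts,
    n_facilities = n_facilities, n_urban = n_urban,
    crop_weights = crop_weights, ses_range = ses_range,
    urban_pop_threshold = urban_pop_threshold,
    urban_meanlog = urban_meanlog, urban_sdlog = urban_sdlog,
    area_per_capita = area_per_capita,
    pool_size = pool_size, urban_weight = urban_weight,
    invalid_fraction = invalid_fraction, sex_prob_m = sex_prob_m,
    birth_years = as.integer(birth_years),
    regions = as.character(regions),
    region_weights = as.numeric(region_weights) / sum(region_weights),
    region_crop_weights = region_crop_weights,
    region_ses_range = region_ses_range,
    n_cases = as.integer(n_cases), ratio = as.integer(ratio),
    birth_year_window = as.integer(birth_year_window),
    radius_m = radius_m, buffer_segments = as.integer(buffer_segments),
    D_m = D_m, outer_m = outer_m, D_list = D_list,
    urban_buffer_m = urban_buffer_m,
    quartile_reference = quartile_reference,
    mover_fraction = mover_fraction,
    stratify_cases_by_region = isTRUE(stratify_cases_by_region),
    subgroup_probs = subgroup_probs,
    params = params, analyses = analyses, year_coding = year_coding
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  extent %.0f km, %d land-cover cells, %d tracts, %d facilities, %d urban areas\n",
              x$extent_m / 1000, x$n_cells, x$n_tracts, x$n_facilities, x$n_urban))
  cat(sprintf("  pool %d, cases %d, ratio 1:%d, regions: %s\n",
              x$pool_size, x$n_cases, x$ratio, paste(x$regions, collapse = ", ")))
  cat(sprintf("  buffer %.0f m, D %.0f m, outer %.0f m, quartiles on %s\n",
              x$radius_m, x$D_m, x$outer_m, x$quartile_reference))
  invisible(x)
}

#' Read / write a study configuration as YAML
#'
#' Serializes every scalar and vector field; `params` is nested.  Fields
#' absent from the file take their [study_config()] defaults.
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); a `study_config` (read).
#' @export
write_config <- function(config, path) {
  lst <- unclass(config)
  lst$params <- unclass(lst$params)
  # named numeric vectors must stay maps in YAML
  lst$params$or_ses_q <- as.list(lst$params$or_ses_q)
  lst$params$or_env <- as.list(lst$params$or_env)
  lst$crop_weights <- as.list(lst$crop_weights)
  lst$subgroup_probs <- as.list(lst$subgroup_probs)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$params)) {
    pp <- lst$params
    lst$params <- true_params(pp$or_gci_per10, unlist(pp$or_ses_q),
                              unlist(pp$or_env), pp$or_sex, pp$or_year,
                              pp$intercept, pp$region_sd)
  }
  if (!is.null(lst$crop_weights)) lst$crop_weights <- unlist(lst$crop_weights)
  if (!is.null(lst$subgroup_probs)) lst$subgroup_probs <- unlist(lst$subgroup_probs)
  do.call(study_config, lst)
}

# x-interval bands of the extent, one per region, widths proportional to the
# region weights.  Returns a data.frame(region, xmin, xmax).
region_bands <- function(config) {
  w <- config$region_weights
  br <- c(0, cumsum(w)) * config$extent_m
  data.frame(region = config$regions,
             xmin = br[-length(br)], xmax = br[-1L],
             stringsAsFactors = FALSE)
}

region_of_x <- function(x, config) {
  b <- region_bands(config)
  idx <- findInterval(x, c(b$xmin, config$extent_m), rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(b)] <- nrow(b)
  b$region[idx]
}
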