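# Study orchestration: simulate or ingest, derive exposures, match, fit the
# main/subgroup/crop analyses, the D sweep and the two sensitivity analyses.

# deterministic largest-remainder allocation of n cases to regions
allocate_region_cases <- function(n, regions, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1L
  }
  setNames(as.integer(base), regions)
}

#' Per-subject exposure profiles
#'
#' Derives every analysis covariate for a subjects table: crop indices in the
#' buffer, distance to the nearest facility, urban membership, environment
#' category and census-tract SES.  Subjects with invalid geocodes get `NA`
#' profiles.
#'
#' @param subjects subjects data frame with `x`, `y`.
#' @param landscape a [landscape()].
#' @param config a [study_config()].
#' @return data frame aligned with `subjects`: `id`, `gci`, the six crop
#'   columns, `d_nearest_facility_m`, `in_urban`, `env`, `tract_id`,
#'   `ses_value`.
#' @export
exposure_profiles <- function(subjects, landscape, config) {
  ci <- crop_index(subjects$x, subjects$y, landscape$land_cover,
                   radius_m = config$radius_m,
                   segments = config$buffer_segments)
  env <- classify_environment(subjects$x, subjects$y, landscape$facilities,
                              landscape$urban_areas, D_m = config$D_m,
                              outer_m = config$outer_m,
                              urban_pop_threshold = config$urban_pop_threshold,
                              urban_buffer_m = config$urban_buffer_m)
  ses <- assign_ses(subjects$x, subjects$y, landscape$tracts)
  data.frame(id = subjects$id, ci, env = env$category,
             d_nearest_facility_m = env$d_nearest_facility_m,
             in_urban = env$in_urban, ses, stringsAsFactors = FALSE)
}

#' Simulate one complete matched study
#'
#' Runs the generator stages in order -- landscape, population pool, pool
#' exposure profiles, outcome assignment, post-outcome case relocation,
#' 1:`ratio` matching, SES quartiles -- and assembles the analysis data set of
#' cases plus matched controls with all model covariates.  Stage seeds are
#' derived deterministically from `seed` (landscape `seed+1`, population
#' `seed+2`, outcomes `seed+3`, movers `seed+4`, matching `seed+5`).
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return object of class `study_data`: list with `data` (analysis data
#'   frame), `landscape`, `quartiles` (the [ses_quartiles()] used), `config`,
#'   `seed` and bookkeeping counts.
#' @export
simulate_study <- function(config, seed) {
  stopifnot(inherits(config, "study_config"))
  ls <- generate_landscape(config, seed + 1L)
  pool <- generate_population(ls, config$pool_size, config, seed + 2L)
  prof <- exposure_profiles(pool, ls, config)
  region_cases <- if (config$stratify_cases_by_region)
    allocate_region_cases(config$n_cases, config$regions,
                          config$region_weights) else NULL
  oc <- assign_outcomes(pool, prof, config$params, config$n_cases, seed + 3L,
                        subgroup_probs = config$subgroup_probs,
                        region_cases = region_cases)
  cases <- apply_moves(oc$cases, ls, config, seed + 4L)
  matched <- match_controls(cases, oc$pool, ratio = config$ratio,
                            seed = seed + 5L,
                            birth_year_window = config$birth_year_window)

  controls <- oc$pool[match(matched$control_id, oc$pool$id), , drop = FALSE]
  study <- rbind(cases, controls)
  rownames(study) <- NULL
  # exposures at the analysis address: recompute (movers relocated)
  sprof <- exposure_profiles(study, ls, config)

  ref <- if (config$quartile_reference == "controls")
    sprof$ses_value[study$status == "control"] else sprof$ses_value
  qq <- ses_quartiles(ref)
  data <- cbind(study, sprof[, setdiff(names(sprof), "id"), drop = FALSE])
  data$ses_q <- ses_quartile(data$ses_value, qq)
  data$gci10 <- data$gci / 10

  structure(list(data = data, landscape = ls, quartiles = qq,
                 config = config, seed = seed,
                 n_pool = nrow(pool),
                 region_effects = oc$region_effects),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> %d cases + %d matched controls (pool %d), seed %d\n",
              sum(x$data$status == "case"), sum(x$data$status == "control"),
              x$n_pool, x$seed))
  invisible(x)
}

subgroup_fits <- function(data, ...) {
  subs <- sort(unique(data$subgroup[data$status == "case"]))
  fits <- list()
  for (s in subs) {
    keep <- data$status == "control" |
      (data$status == "case" & data$subgroup == s)
    fits[[s]] <- tryCatch(fit_mixed_logistic(data[keep, , drop = FALSE], ...),
                          error = function(e)
                            structure(list(error = conditionMessage(e)),
                                      class = "ccfit_error"))
  }
  fits
}

ok_fits <- function(fits) fits[vapply(fits, inherits, logical(1), "ccfit")]

#' Same-address sensitivity analysis
#'
#' Refits the models on the cases whose diagnosis address equals their birth
#' address (`same_address = TRUE`) plus all controls.  Movers are simply
#' excluded: their birth address is unknown by design.
#'
#' @param data analysis data frame (from [simulate_study()]'s `$data`) with a
#'   `same_address` column.
#' @param subgroups also refit per tumor subgroup.
#' @param ... passed to [fit_mixed_logistic()].
#' @return list with `fits` (named list: `all` plus subgroups) and `table`
#'   (the [or_table()]); subgroups with no remaining cases are flagged in
#'   `insufficient`.
#' @export
same_address_sensitivity <- function(data, subgroups = TRUE, ...) {
  keep <- data$status == "control" | data$same_address
  d <- data[keep, , drop = FALSE]
  fits <- list(all = fit_mixed_logistic(d, ...))
  insufficient <- character(0)
  if (subgroups) {
    sf <- subgroup_fits(d, ...)
    bad <- !vapply(sf, inherits, logical(1), "ccfit")
    insufficient <- names(sf)[bad]
    fits <- c(fits, sf[!bad])
    lost <- setdiff(unique(data$subgroup[data$status == "case"]), names(sf))
    insufficient <- c(insufficient, lost)
  }
  list(fits = fits, table = or_table(fits), insufficient = insufficient)
}

#' Leave-one-region-out sensitivity analysis
#'
#' Refits the full model excluding each region in turn and reports the crop
#' index OR and the SES Q4-vs-Q1 OR per exclusion.
#'
#' @param data analysis data frame.
#' @param ... passed to [fit_mixed_logistic()].
#' @return data frame with one row per excluded region: `region_excluded`,
#'   `or_gci`, `gci_lo`, `gci_hi`, `or_ses_q4`, `ses_lo`, `ses_hi`, `error`.
#' @export
leave_one_region_out <- function(data, ...) {
  regions <- sort(unique(data$region))
  if (length(regions) < 3L) stop("need at least 3 regions")
  rows <- lapply(regions, function(r) {
    d <- data[data$region != r, , drop = FALSE]
    if (!any(d$status == "case"))
      return(data.frame(region_excluded = r, or_gci = NA_real_,
                        gci_lo = NA_real_, gci_hi = NA_real_,
                        or_ses_q4 = NA_real_, ses_lo = NA_real_,
                        ses_hi = NA_real_, error = "no cases left",
                        stringsAsFactors = FALSE))
    tryCatch({
      f <- fit_mixed_logistic(d, ...)
      tt <- f$terms
      g <- tt[tt$variable == f$exposure, ][1, ]
      s <- tt[tt$variable == "ses_q" & tt$level == "Q4", ]
      data.frame(region_excluded = r,
                 or_gci = g$or, gci_lo = g$ci_lo, gci_hi = g$ci_hi,
                 or_ses_q4 = if (nrow(s)) s$or else NA_real_,
                 ses_lo = if (nrow(s)) s$ci_lo else NA_real_,
                 ses_hi = if (nrow(s)) s$ci_hi else NA_real_,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(region_excluded = r, or_gci = NA_real_, gci_lo = NA_real_,
                 gci_hi = NA_real_, or_ses_q4 = NA_real_, ses_lo = NA_real_,
                 ses_hi = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full study pipeline
#'
#' Executes every stage under one configuration: simulation (or an ingested
#' `study_data`), the main model, per-subgroup models, crop-specific models,
#' the D sensitivity sweep, the same-address sensitivity analysis and the
#' leave-one-region-out analysis, as selected by `config$analyses`.
#' Everything is reproducible from (config, seed); with `outdir` set, all
#' intermediates and tables are written to disk along with a JSON manifest.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @param outdir optional output directory.
#' @param sim optional pre-built [simulate_study()] result (ingest mode).
#' @return object of class `study_report`.
#' @export
run_study <- function(config, seed = 1L, outdir = NULL, sim = NULL) {
  if (is.null(sim)) sim <- simulate_study(config, seed)
  data <- sim$data
  an <- config$analyses
  out <- list(config = config, seed = seed, sim = sim)

  fit_args <- list(year_coding = config$year_coding)
  main_fit <- do.call(fit_mixed_logistic, c(list(data), fit_args))
  out$fits <- list(all = main_fit)

  if ("subgroups" %in% an)
    out$fits <- c(out$fits, ok_fits(do.call(subgroup_fits, c(list(data), fit_args))))
  out$table_main <- or_table(out$fits)

  if ("crops" %in% an) {
    cf <- list()
    for (crop in crop_cols()) {
      cf[[crop]] <- tryCatch(
        do.call(fit_mixed_logistic, c(list(data, exposure = crop), fit_args)),
        error = function(e) NULL)
    }
    cf <- cf[!vapply(cf, is.null, logical(1))]
    out$fits_crops <- cf
    out$table_crops <- if (length(cf)) or_table(cf) else NULL
  }

  if ("sweep" %in% an)
    out$sweep <- do.call(d_sweep,
      c(list(data, sim$landscape$facilities, sim$landscape$urban_areas,
             D_list = config$D_list, outer_m = config$outer_m,
             urban_pop_threshold = config$urban_pop_threshold,
             urban_buffer_m = config$urban_buffer_m), fit_args))

  if ("same_address" %in% an)
    out$same_address <- do.call(same_address_sensitivity,
                                c(list(data), fit_args))

  if ("regions" %in% an && length(unique(data$region)) >= 3L)
    out$regions <- do.call(leave_one_region_out, c(list(data), fit_args))

  out <- structure(out, class = "study_report")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$sim)
  f <- x$fits$all
  tt <- f$terms
  g <- tt[tt$variable == f$exposure, ][1, ]
  s <- tt[tt$variable == "ses_q" & tt$level == "Q4", ]
  cat(sprintf("  main model (%s): GCI OR per 10 points = %.3f (%.3f, %.3f)\n",
              f$method, g$or, g$ci_lo, g$ci_hi))
  if (nrow(s))
    cat(sprintf("  SES Q4 vs Q1 OR = %.3f (%.3f, %.3f)\n", s$or, s$ci_lo, s$ci_hi))
  cat("  sections:", paste(intersect(c("table_main", "table_crops", "sweep",
                                       "same_address", "regions"), names(x)),
                           collapse = ", "), "\n")
  invisible(x)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf)
  unname(tools::md5sum(tf))
}

write_report <- function(rep, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_landscape(rep$sim$landscape, file.path(outdir, "landscape"))
  write_subjects(rep$sim$data, file.path(outdir, "analysis.csv"))
  write.csv(rep$table_main, file.path(outdir, "table_main.csv"), row.names = FALSE)
  if (!is.null(rep$table_crops))
    write.csv(rep$table_crops, file.path(outdir, "table_crops.csv"), row.names = FALSE)
  if (!is.null(rep$sweep))
    write.csv(rep$sweep, file.path(outdir, "sweep.csv"), row.names = FALSE)
  if (!is.null(rep$same_address))
    write.csv(rep$same_address$table, file.path(outdir, "table_same_address.csv"),
              row.names = FALSE)
  if (!is.null(rep$regions))
    write.csv(rep$regions, file.path(outdir, "leave_one_region_out.csv"),
              row.names = FALSE)
  write_config(rep$config, file.path(outdir, "config.yaml"))
  manifest <- list(config_hash = config_hash(rep$config), seed = rep$seed,
                   n_cases = rep$fits$all$n_cases,
                   n_controls = rep$fits$all$n_controls,
                   dropped = rep$fits$all$dropped,
                   method = rep$fits$all$method)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
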