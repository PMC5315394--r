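# Individual control matching: `ratio` controls per case on sex, birth year
# and region, without reuse across cases, with in-stratum replacement of
# invalid geocodes.

#' Match controls to cases
#'
#' For each case, draws `ratio` controls uniformly without replacement from
#' the pool members sharing its stratum (sex, birth year within
#' `birth_year_window`, region).  Draws include subjects with invalid
#' geocodes, which are then discarded and replaced from the same stratum
#' until `ratio` valid controls are found, mirroring the replacement of
#' failed geocodes during control selection.  Controls are never reused
#' across cases; output is deterministic given the seed.
#'
#' @param cases case subjects data frame (`id`, `sex`, `birth_year`,
#'   `region`).
#' @param pool control pool data frame (same columns plus `geocode_valid`;
#'   a missing `geocode_valid` column is treated as all valid).
#' @param ratio controls per case (>= 1), default 6.
#' @param seed integer seed (optional).
#' @param birth_year_window match birth year within +/- this many years
#'   (0 = exact).
#' @return data frame with one row per matched control: `case_id`,
#'   `control_id`, `sex`, `birth_year` (the case's), `region`.  Errors if a
#'   stratum has fewer eligible controls than needed, naming the stratum and
#'   shortfall.
#' @export
match_controls <- function(cases, pool, ratio = 6, seed = NULL,
                           birth_year_window = 0) {
  stopifnot(ratio >= 1)
  need_cols <- c("id", "sex", "birth_year", "region")
  if (!all(need_cols %in% names(cases)) || !all(need_cols %in% names(pool)))
    stop("cases and pool need columns id, sex, birth_year, region")
  if (!is.null(seed)) set.seed(seed)
  valid <- if ("geocode_valid" %in% names(pool)) pool$geocode_valid else
    rep(TRUE, nrow(pool))
  used <- rep(FALSE, nrow(pool))

  key <- function(sex, year, region) paste(sex, year, region, sep = "|")
  pool_key <- key(pool$sex, pool$birth_year, pool$region)
  by_key <- split(seq_len(nrow(pool)), pool_key)

  eligible_idx <- function(i) {
    if (birth_year_window == 0) {
      idx <- by_key[[key(cases$sex[i], cases$birth_year[i], cases$region[i])]]
      if (is.null(idx)) integer(0) else idx
    } else {
      which(pool$sex == cases$sex[i] & pool$region == cases$region[i] &
              abs(pool$birth_year - cases$birth_year[i]) <= birth_year_window)
    }
  }

  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    idx <- eligible_idx(i)
    idx <- idx[!used[idx]]
    n_valid <- sum(valid[idx])
    if (n_valid < ratio)
      stop(sprintf(
        "stratum (%s, %s, %s) exhausted: %d eligible valid controls, %d needed",
        cases$sex[i], cases$birth_year[i], cases$region[i], n_valid, ratio))
    # first draw from the whole stratum, then replace invalid geocodes
    first <- idx[sample.int(length(idx), min(ratio, length(idx)))]
    chosen <- first[valid[first]]
    while (length(chosen) < ratio) {
      rest <- setdiff(idx[valid[idx]], chosen)
      extra <- rest[sample.int(length(rest), ratio - length(chosen))]
      chosen <- c(chosen, extra)
    }
    used[chosen] <- TRUE
    out[[i]] <- data.frame(case_id = cases$id[i], control_id = pool$id[chosen],
                           sex = cases$sex[i], birth_year = cases$birth_year[i],
                           region = cases$region[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
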