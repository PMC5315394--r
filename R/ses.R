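# Census-tract socioeconomic status: point-to-tract attribute join and
# study-wide quartile categorization.

#' Assign census-tract SES to residences
#'
#' Point-in-polygon join: each residence receives the SES value of its
#' containing tract.  Tracts partition the extent; a point on a shared
#' boundary resolves to the first tract in layer order (deterministic).
#'
#' @param x,y residence coordinates in metres.
#' @param tracts a [poly_layer()] with `ses` and `tract_id` properties.
#' @return data frame with columns `tract_id`, `ses_value` (`NA` rows for
#'   `NA` coordinates).
#' @export
assign_ses <- function(x, y, tracts) {
  stopifnot(inherits(tracts, "poly_layer"), length(x) == length(y))
  idx <- locate_polygon_cpp(x, y, tracts$polygons)
  miss <- is.na(idx) & !(is.na(x) | is.na(y))
  if (any(miss))
    stop(sprintf("%d point(s) fall in no tract; tracts must partition the extent",
                 sum(miss)))
  tid <- tracts$props$tract_id
  if (is.null(tid)) tid <- sprintf("T%04d", seq_along(tracts$polygons))
  data.frame(tract_id = tid[idx], ses_value = tracts$props$ses[idx],
             stringsAsFactors = FALSE)
}

#' Quartile cut-points of the SES distribution
#'
#' Empirical 25/50/75 percentiles of the reference distribution (linear
#' interpolation between order statistics, the default R type-7 convention,
#' fixed for reproducibility).  The reference population is typically the
#' controls, so that control counts split into near-equal quarters.
#'
#' @param values numeric SES values of the reference population (>= 4
#'   distinct values).
#' @return object of class `ses_quartiles`: list with `cutpoints` (named
#'   length-3 numeric) and `n`.
#' @export
ses_quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 4L)
    stop("need at least 4 distinct SES values to compute quartiles")
  cp <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(cutpoints = setNames(cp, c("q25", "q50", "q75")),
                 n = length(values)),
            class = "ses_quartiles")
}

#' @export
print.ses_quartiles <- function(x, ...) {
  cat(sprintf("<ses_quartiles> cut-points %.4g / %.4g / %.4g (reference n = %d)\n",
              x$cutpoints[1], x$cutpoints[2], x$cutpoints[3], x$n))
  invisible(x)
}

#' Label SES values with quartile categories
#'
#' Half-open intervals: Q1 = below q25, Q2 = \[q25, q50), Q3 = \[q50, q75),
#' Q4 = q75 and above.  Values outside the reference range clamp to Q1/Q4.
#'
#' @param values numeric SES values to label.
#' @param quartiles a [ses_quartiles()] object.
#' @return factor with levels Q1..Q4.
#' @export
ses_quartile <- function(values, quartiles) {
  stopifnot(inherits(quartiles, "ses_quartiles"))
  q <- findInterval(values, quartiles$cutpoints) + 1L
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}
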