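# Mixed unconditional logistic regression for the matched case-control
# analysis, plus crude-OR verification utilities and report tables.

#' Fit the mixed unconditional logistic model
#'
#' Fits `case ~ environment + SES quartile + crop index/10 + sex + birth
#' year` with a zero-mean normal random intercept per region, by maximizing
#' the marginal likelihood (adaptive Gauss-Hermite quadrature via
#' [lme4::glmer()]; `nAGQ = 1` is the Laplace approximation).  Matching
#' factors enter as covariates (unconditional analysis).  Wald 95% CIs are
#' computed on the log-odds scale as `estimate +/- 1.96 * SE` and
#' exponentiated.
#'
#' A random intercept over few regions is statistically fragile: when the
#' mixed fit is singular (variance estimate at the zero boundary) or fails,
#' the function automatically falls back to ordinary logistic regression with
#' region as a fixed factor, recorded in `$method`.  With a single region the
#' fit is plain logistic regression and agrees with [stats::glm()]
#' coefficients exactly.
#'
#' @param data analysis data frame with columns `status` (`"case"` /
#'   `"control"`), `env`, `ses_q`, `sex`, `birth_year`, `region` and the
#'   exposure column (percentage points 0-100).
#' @param exposure name of the exposure column, default `"gci"`; crop
#'   subcategory columns (e.g. `"irrigated"`) substitute the index.
#' @param random_region use a region random intercept (default) rather than a
#'   fixed factor.
#' @param nAGQ adaptive Gauss-Hermite quadrature points (1 = Laplace).
#' @param year_coding `"linear"` (centered continuous, default) or
#'   `"categorical"` birth-year effect.
#' @param crop_only drop the environment and SES terms (crop-only model).
#' @param keep_model keep the underlying `glmer`/`glm` object in `$model`.
#' @return object of class `ccfit`: term table (log-odds estimates, SEs, ORs,
#'   Wald CIs), region intercept sd `sigma_region`, category counts,
#'   convergence flag, complete-case drop count and fit method.
#' @seealso [or_table()], [crude_or()]
#' @export
fit_mixed_logistic <- function(data, exposure = "gci", random_region = TRUE,
                               nAGQ = 1, year_coding = c("linear", "categorical"),
                               crop_only = FALSE, keep_model = FALSE) {
  year_coding <- match.arg(year_coding)
  need <- c("status", "sex", "birth_year", "region", exposure)
  if (!crop_only) need <- c(need, "env", "ses_q")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))

  d <- data[, unique(need), drop = FALSE]
  cc <- complete.cases(d)
  dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  d$case <- as.integer(d$status == "case")
  d$x10 <- d[[exposure]] / 10
  d$region <- factor(d$region)
  if (nlevels(droplevels(d$region)) < 1L) stop("no regions in data")
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$yearc <- if (year_coding == "linear") d$birth_year - mean(d$birth_year)
             else factor(d$birth_year)
  if (!crop_only) {
    d$env <- droplevels(factor(d$env, levels = env_levels()))
    d$ses_q <- droplevels(factor(d$ses_q, levels = paste0("Q", 1:4)))
  }

  rhs <- c(if (!crop_only) c("env", "ses_q"), "x10", "sex", "yearc")
  # drop constant columns (e.g. single-sex or single-year strata)
  rhs <- rhs[vapply(rhs, function(v) {
    x <- d[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))]
  n_regions <- nlevels(droplevels(d$region))

  method <- NULL; fit <- NULL; sigma <- NA_real_
  converged <- TRUE; notes <- character(0)

  if (random_region && n_regions >= 2L) {
    f <- as.formula(paste("case ~", paste(rhs, collapse = " + "),
                          "+ (1 | region)"))
    fit <- tryCatch(
      withCallingHandlers(
        lme4::glmer(f, data = d, family = binomial(), nAGQ = nAGQ),
        warning = function(w) {
          notes <<- c(notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          notes <<- c(notes, trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        }),
      error = function(e) { notes <<- c(notes, conditionMessage(e)); NULL })
    if (!is.null(fit)) {
      sigma <- sqrt(as.numeric(lme4::VarCorr(fit)$region))
      if (lme4::isSingular(fit, tol = 1e-4)) {
        notes <- c(notes, "singular fit (region variance at boundary)")
        fit <- NULL
      } else {
        method <- "glmer"
        converged <- length(fit@optinfo$conv$lme4) == 0L
      }
    }
  }
  if (is.null(fit)) {
    # fixed-effects-region fallback (or plain logistic with one region)
    rhs2 <- c(rhs, if (n_regions >= 2L) "region")
    f <- as.formula(paste("case ~", paste(rhs2, collapse = " + ")))
    fit <- withCallingHandlers(
      glm(f, data = d, family = binomial()),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    method <- if (n_regions >= 2L) "glm_region_fixed" else "glm"
    converged <- fit$converged
    if (is.na(sigma) || method == "glm") sigma <- if (method == "glm") 0 else sigma
  }

  est <- if (inherits(fit, "glmerMod")) lme4::fixef(fit) else coef(fit)
  vc <- withCallingHandlers(
    as.matrix(vcov(fit)),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  se <- sqrt(diag(vc))[names(est)]
  # flag separation-like pathologies
  if (any(abs(est) > 15) || any(se > 100)) {
    converged <- FALSE
    notes <- c(notes, "implausibly large estimates: possible separation")
  }

  terms <- data.frame(term = names(est), estimate = as.numeric(est),
                      se = as.numeric(se), stringsAsFactors = FALSE)
  terms$or <- exp(terms$estimate)
  terms$ci_lo <- exp(terms$estimate - 1.96 * terms$se)
  terms$ci_hi <- exp(terms$estimate + 1.96 * terms$se)
  terms$variable <- ifelse(grepl("^env", terms$term), "env",
                    ifelse(grepl("^ses_q", terms$term), "ses_q",
                    ifelse(terms$term == "x10", exposure,
                    ifelse(grepl("^sex", terms$term), "sex",
                    ifelse(grepl("^yearc", terms$term), "birth_year",
                    ifelse(grepl("^region", terms$term), "region",
                           "intercept"))))))
  terms$level <- ifelse(terms$variable == "env", sub("^env", "", terms$term),
                 ifelse(terms$variable == "ses_q", sub("^ses_q", "", terms$term),
                 ifelse(terms$variable == exposure, "per 10 points",
                 ifelse(terms$variable == "sex", sub("^sex", "", terms$term),
                 ifelse(terms$variable == "region", sub("^region", "", terms$term),
                        "")))))

  counts <- category_counts(d, exposure, crop_only)

  structure(list(
    terms = terms, sigma_region = sigma, method = method,
    converged = converged, notes = notes,
    exposure = exposure, crop_only = crop_only,
    n_cases = sum(d$case == 1L), n_controls = sum(d$case == 0L),
    dropped = dropped, counts = counts, nAGQ = nAGQ,
    year_coding = year_coding,
    model = if (keep_model) fit else NULL
  ), class = "ccfit")
}

category_counts <- function(d, exposure, crop_only) {
  rows <- list()
  add <- function(variable, level, sel) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level,
      n_controls = sum(sel & d$case == 0L), n_cases = sum(sel & d$case == 1L),
      stringsAsFactors = FALSE)
  }
  if (!crop_only) {
    for (lv in levels(d$env)) add("env", lv, d$env == lv)
    for (lv in levels(d$ses_q)) add("ses_q", lv, d$ses_q == lv)
  }
  add(exposure, "> 0", d[[exposure]] > 0)
  out <- do.call(rbind, rows)
  base <- c(env = nrow(d), ses_q = nrow(d))
  out$pct_controls <- 100 * out$n_controls / sum(d$case == 0L)
  out$pct_cases <- 100 * out$n_cases / sum(d$case == 1L)
  out
}

#' @export
print.ccfit <- function(x, digits = 3, ...) {
  cat(sprintf("<ccfit> %s | exposure: %s | %d cases / %d controls",
              x$method, x$exposure, x$n_cases, x$n_controls))
  if (x$dropped > 0) cat(sprintf(" | %d rows dropped (missing covariates)", x$dropped))
  cat("\n")
  if (!is.na(x$sigma_region))
    cat(sprintf("  region intercept sd: %.3f\n", x$sigma_region))
  if (!x$converged) cat("  WARNING: fit flagged as non-converged\n")
  tt <- x$terms[x$terms$variable != "intercept" & x$terms$variable != "region", ]
  out <- data.frame(term = tt$term,
                    OR = round(tt$or, digits),
                    `95% CI` = sprintf("(%.*f, %.*f)", digits, tt$ci_lo,
                                       digits, tt$ci_hi),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ccfit <- function(object, ...) {
  setNames(object$terms$estimate, object$terms$term)
}

#' @export
confint.ccfit <- function(object, parm, level = 0.95, ...) {
  z <- -qnorm((1 - level) / 2)
  m <- cbind(lower = object$terms$estimate - z * object$terms$se,
             upper = object$terms$estimate + z * object$terms$se)
  rownames(m) <- object$terms$term
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
summary.ccfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ccfit")
}

#' @export
print.summary.ccfit <- function(x, ...) {
  print(x$fit)
  cat("\nCategory counts:\n")
  print(x$fit$counts, row.names = FALSE, digits = 3)
  if (length(x$fit$notes)) {
    cat("\nNotes:\n")
    for (n in unique(x$fit$notes)) cat(" -", n, "\n")
  }
  invisible(x)
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the Woolf log-scale 95%
#' confidence interval `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' A verification utility for printed count tables.
#'
#' @param a exposed cases.
#' @param b unexposed cases.
#' @param c exposed controls.
#' @param d unexposed controls.
#' @param haldane apply the Haldane-Anscombe 0.5 correction to zero cells
#'   instead of erroring.
#' @return list with `or`, `ci_lo`, `ci_hi` and the (possibly corrected)
#'   counts, class `crude_or`.
#' @export
crude_or <- function(a, b, c, d, haldane = FALSE) {
  k <- c(a = a, b = b, c = c, d = d)
  if (any(k < 0)) stop("counts must be non-negative")
  if (any(k == 0)) {
    if (!haldane) stop("zero cell; set haldane = TRUE for the 0.5 correction")
    k <- k + 0.5
  }
  or <- (k["a"] * k["d"]) / (k["b"] * k["c"])
  se <- sqrt(sum(1 / k))
  structure(list(or = unname(or),
                 ci_lo = unname(exp(log(or) - 1.96 * se)),
                 ci_hi = unname(exp(log(or) + 1.96 * se)),
                 counts = k),
            class = "crude_or")
}

#' @export
print.crude_or <- function(x, ...) {
  cat(sprintf("crude OR = %.4f (95%% CI %.4f, %.4f)\n", x$or, x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Odds-ratio report table
#'
#' Assembles the per-category counts (with percentages), odds ratios and 95%
#' CIs of one or more fitted models into one long table, including the count
#' of subjects with a positive crop index.  Reference categories are reported
#' with OR 1 and no interval.
#'
#' @param fits a [fit_mixed_logistic()] result or a named list of them (e.g.
#'   one per tumor subgroup).
#' @return data frame with columns `subgroup`, `variable`, `level`,
#'   `n_controls`, `pct_controls`, `n_cases`, `pct_cases`, `or`, `ci_lo`,
#'   `ci_hi`.
#' @export
or_table <- function(fits) {
  if (inherits(fits, "ccfit")) fits <- list(all = fits)
  stopifnot(length(fits) > 0, all(vapply(fits, inherits, logical(1), "ccfit")))
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  out <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    tab <- f$counts
    tab$subgroup <- nm
    tt <- f$terms
    key_t <- paste(tt$variable, tt$level)
    key_c <- paste(tab$variable, tab$level)
    m <- match(key_c, key_t)
    tab$or <- tt$or[m]
    tab$ci_lo <- tt$ci_lo[m]
    tab$ci_hi <- tt$ci_hi[m]
    # reference levels: OR identically 1
    ref <- tab$variable == "env" & tab$level == "rural" |
           tab$variable == "ses_q" & tab$level == "Q1"
    tab$or[ref] <- 1
    # the exposure term's OR applies to the ">0" count row
    er <- tab$variable == f$exposure
    et <- tt$variable == f$exposure
    if (any(er) && any(et)) {
      tab$or[er] <- tt$or[et][1]
      tab$ci_lo[er] <- tt$ci_lo[et][1]
      tab$ci_hi[er] <- tt$ci_hi[et][1]
    }
    out[[nm]] <- tab[, c("subgroup", "variable", "level", "n_controls",
                         "pct_controls", "n_cases", "pct_cases",
                         "or", "ci_lo", "ci_hi")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
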