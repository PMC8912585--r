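#' Pearson screening of candidate climate-window predictors
#'
#' Correlates the response with every candidate predictor and ranks
#' candidates by absolute correlation (ties keep the candidate
#' order). Zero-variance candidates and candidates with fewer than 5
#' complete pairs are skipped with a message.
#'
#' @param data Data frame holding the response and predictor columns,
#'   one row per year (or per month for monthly EVI).
#' @param response Name of the response column.
#' @param candidates Character vector of predictor column names;
#'   defaults to every other numeric column except `year`/`month`.
#' @return Tibble with `name`, `n`, `r`, `p` sorted by decreasing
#'   absolute correlation.
#' @export
pearson_screen <- function(data, response, candidates = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(candidates)) {
    candidates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                          c(response, "year", "month"))
  }
  y <- data[[response]]
  rows <- purrr::map(candidates, function(nm) {
    x <- data[[nm]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 5L) {
      message("pearson_screen: fewer than 5 complete pairs for ", nm,
              "; skipped")
      return(NULL)
    }
    if (stats::sd(x[ok]) < 1e-12) {
      message("pearson_screen: zero-variance predictor ", nm,
              "; skipped")
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(name = nm, n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value)
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  out[order(-abs(out$r)), , drop = FALSE]
}

# Candidate shortlist from a screening table. Climate-window families
# (T_*, Pr_*, RD_*) are heavily redundant, so a plain overall top-k
# lets one family crowd out every other variable; instead each
# variable family contributes its floor(k / n_families) best windows
# and the remaining slots go to the best of the rest, mirroring
# per-parameter screening.
screen_top <- function(screened, k) {
  fam <- sub("_.*$", "", screened$name)
  if (dplyr::n_distinct(fam) == 1L || nrow(screened) <= k) {
    return(utils::head(screened$name, k))
  }
  per_fam <- max(1L, floor(k / dplyr::n_distinct(fam)))
  picked <- unlist(lapply(split(screened$name, fam)[unique(fam)],
                          utils::head, per_fam), use.names = FALSE)
  rest <- setdiff(screened$name, picked)
  out <- c(picked, utils::head(rest, max(0L, k - length(picked))))
  screened$name[screened$name %in% out]  # restore |r| order
}

# Variance inflation factor of `candidate` against the columns in
# `selected`, computed from the R^2 of regressing one on the others.
candidate_vif <- function(data, candidate, selected) {
  if (length(selected) == 0L) return(1)
  f <- stats::reformulate(selected, response = candidate)
  r2 <- suppressWarnings(summary(stats::lm(f, data = data))$r.squared)
  if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
}

#' Stepwise multiple linear regression on screened climate windows
#'
#' Forward-backward stepwise selection on the top-`k` Pearson-screened
#' candidates: a candidate enters when its partial t-test p-value is
#' below `p_enter`, terms are removed when their p-value rises above
#' `p_remove`, and before each entry candidates whose variance
#' inflation factor against the current model exceeds `vif_limit` are
#' set aside (collinearity handling by omission).
#'
#' @inheritParams pearson_screen
#' @param k Number of top-ranked screened candidates considered.
#' @param p_enter,p_remove Entry and removal p-value thresholds.
#' @param vif_limit Largest tolerated variance inflation factor.
#' @return An object of class `stepwise_fit`: selected predictors (in
#'   entry order), partial coefficients, model R^2 and p-value,
#'   collinearity-dropped candidates, the screening table and the
#'   underlying `lm` fit. [tidy()] and [glance()] methods apply.
#' @export
stepwise_mlr <- function(data, response, candidates = NULL, k = 10,
                         p_enter = 0.05, p_remove = 0.10,
                         vif_limit = 10) {
  data <- tibble::as_tibble(data)
  screened <- pearson_screen(data, response, candidates)
  top <- screen_top(screened, k)
  data <- data[stats::complete.cases(data[c(response, top)]),
               c(response, top)]
  selected <- character(0)
  dropped <- character(0)
  term_p <- function(fit) {
    s <- suppressWarnings(summary(fit))$coefficients
    s[setdiff(rownames(s), "(Intercept)"), "Pr(>|t|)", drop = TRUE]
  }
  for (iter in 1:50) {
    pool <- setdiff(top, c(selected, dropped))
    # collinearity: omit candidates inflated against the current model
    if (length(selected) > 0L && length(pool) > 0L) {
      vifs <- vapply(pool, candidate_vif, 0, data = data,
                     selected = selected)
      dropped <- c(dropped, pool[vifs > vif_limit])
      pool <- pool[vifs <= vif_limit]
    }
    entered <- FALSE
    if (length(pool) > 0L) {
      pvals <- vapply(pool, function(cand) {
        f <- stats::reformulate(c(selected, cand), response = response)
        s <- suppressWarnings(
          summary(stats::lm(f, data = data)))$coefficients
        if (!cand %in% rownames(s)) return(NA_real_)
        s[cand, "Pr(>|t|)"]
      }, 0)
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) > 0L && min(pvals) < p_enter) {
        selected <- c(selected, names(pvals)[which.min(pvals)])
        entered <- TRUE
      }
    }
    # backward: peel off terms that lost significance
    repeat {
      if (length(selected) == 0L) break
      f <- stats::reformulate(selected, response = response)
      ps <- term_p(stats::lm(f, data = data))
      if (length(ps) == 0L || max(ps) <= p_remove) break
      selected <- setdiff(selected, names(ps)[which.max(ps)])
    }
    if (!entered) break
    if (length(selected) > 0L) {
      f <- stats::reformulate(selected, response = response)
      r2_now <- suppressWarnings(
        summary(stats::lm(f, data = data))$r.squared)
      if (r2_now > 1 - 1e-10) {
        break  # perfect fit; further terms are numerical noise
      }
    }
  }
  if (length(selected) == 0L) {
    fit <- stats::lm(stats::reformulate("1", response = response),
                     data = data)
    r2 <- 0
    p_model <- NA_real_
  } else {
    fit <- stats::lm(stats::reformulate(selected, response = response),
                     data = data)
    sm <- suppressWarnings(summary(fit))
    r2 <- sm$r.squared
    p_model <- stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                         sm$fstatistic[3L], lower.tail = FALSE)
  }
  structure(
    list(response = response, selected = selected,
         coefficients = stats::coef(fit), r_squared = r2,
         p_value = unname(p_model), dropped_collinear = dropped,
         screened = screened, n = nrow(data), model = fit),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise MLR for", x$response, "\n")
  cat("  selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "none", "\n")
  cat(sprintf("  R^2 = %.3f, p = %s, n = %d\n", x$r_squared,
              format.pval(x$p_value), x$n))
  if (length(x$dropped_collinear)) {
    cat("  dropped (collinear):",
        paste(x$dropped_collinear, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.stepwise_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"],
                 statistic = s[, "t value"],
                 p_value = s[, "Pr(>|t|)"])
}

#' @export
glance.stepwise_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value,
                 n = x$n, n_selected = length(x$selected))
}

#' Interannual trend of a yearly series
#'
#' Ordinary least squares of the value on calendar year: the fitted
#' slope is the phenological shift in units per year.
#'
#' @param data Data frame with a `year` column and the value column.
#' @param value Name of the value column.
#' @return One-row tibble: `series`, `slope`, `intercept`, `p`,
#'   `n_years`. A constant series yields slope 0 and p = 1.
#' @export
trend_fit <- function(data, value) {
  data <- tibble::as_tibble(data)
  stopifnot("year" %in% names(data), value %in% names(data))
  ok <- stats::complete.cases(data$year, data[[value]])
  y <- data[[value]][ok]
  yr <- data$year[ok]
  if (length(y) < 3L) {
    stop("trend_fit needs at least 3 non-missing years", call. = FALSE)
  }
  if (stats::sd(y) < 1e-12) {
    return(tibble::tibble(series = value, slope = 0,
                          intercept = mean(y), p = 1,
                          n_years = length(y)))
  }
  fit <- stats::lm(y ~ yr)
  s <- summary(fit)$coefficients
  tibble::tibble(series = value, slope = s["yr", "Estimate"],
                 intercept = s["(Intercept)", "Estimate"],
                 p = s["yr", "Pr(>|t|)"], n_years = length(y))
}
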