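# n-parameter logistic dose-response fitting and IC50 estimation.
#
# Model on x = log10(dose):
#   f(x) = B + (T - B) / (1 + 10^(b * (xmid - x)))^s
# with s fixed at 1 for the 4-parameter model. Fitting is bounded nonlinear
# least squares with multiple jittered starts; x is centred on the median
# log-dose internally, which makes the IC50's dose-scale equivariance exact.

#' Normalize treated responses to control wells
#'
#' @param treated numeric vector (densities or counts) of treated wells.
#' @param control numeric vector of control wells (medium only).
#' @return `treated / mean(control)`, replicates preserved.
#' @export
normalizeResponse <- function(treated, control) {
  m <- mean(control)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  treated / m
}

logistic5 <- function(xc, bottom, top, xmid, slope, asym) {
  bottom + (top - bottom) / (1 + 10^(slope * (xmid - xc)))^asym
}

# one bounded fit from a given start; returns NULL on failure
fitOnce <- function(xc, y, start, nParams, lower, upper) {
  form <- if (nParams == 5L) {
    y ~ bottom + (top - bottom) / (1 + 10^(slope * (xmid - xc)))^asym
  } else {
    y ~ bottom + (top - bottom) / (1 + 10^(slope * (xmid - xc)))
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(form,
      data = data.frame(xc = xc, y = y),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  fit
}

relativeIC50 <- function(p, center) {
  # dose where f reaches the midpoint between the fitted asymptotes
  xstar <- p["xmid"] - log10(2^(1 / p["asym"]) - 1) / p["slope"]
  unname(10^(xstar + center))
}

absoluteIC50 <- function(p, center) {
  # dose where the fitted curve crosses 0.5 (fraction of control)
  b <- p["bottom"]
  t <- p["top"]
  if ((0.5 - b) * (0.5 - t) >= 0) {
    return(NA_real_)
  }
  term <- ((t - b) / (0.5 - b))^(1 / p["asym"]) - 1
  if (term <= 0) {
    return(NA_real_)
  }
  xstar <- p["xmid"] - log10(term) / p["slope"]
  unname(10^(xstar + center))
}

fitCore <- function(xc, y, nParams, flatTol, startFrom = NULL) {
  if (diff(range(y)) < flatTol) {
    stop("no dose effect: response range below tolerance (", flatTol, ")")
  }
  rg <- diff(range(y))
  lower <- c(
    bottom = min(y) - 0.5 * rg, top = min(y), xmid = min(xc) - 2,
    slope = -20
  )
  upper <- c(
    bottom = max(y), top = max(y) + 0.5 * rg, xmid = max(xc) + 2,
    slope = 20
  )
  if (nParams == 5L) {
    lower <- c(lower, asym = 0.2)
    upper <- c(upper, asym = 5)
  }
  # heuristic initials: asymptotes from the data, midpoint swept over the
  # dose range, both slope signs and two magnitudes (fixed grid, no RNG)
  base <- list(
    bottom = min(y), top = max(y), xmid = stats::median(xc),
    slope = 1
  )
  if (nParams == 5L) base$asym <- 1
  starts <- list()
  xmids <- stats::quantile(xc, c(0.25, 0.5, 0.75), names = FALSE)
  for (sl in c(1, -1, 3, -3)) {
    for (xm in xmids) {
      s <- base
      s$slope <- sl
      s$xmid <- xm
      starts[[length(starts) + 1L]] <- s
    }
  }
  if (!is.null(startFrom)) {
    # warm start (bootstrap refits): try the full-fit solution first and
    # fall back to the multi-start sweep only if it fails
    s0 <- as.list(startFrom[seq_len(if (nParams == 5L) 5L else 4L)])
    s0 <- lapply(seq_along(s0), function(i) {
      min(max(s0[[i]], lower[i]), upper[i])
    })
    names(s0) <- names(lower)
    fit <- fitOnce(xc, y, s0, nParams, lower, upper)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      if (nParams == 4L) p <- c(p, asym = 1)
      return(list(par = p, rss = sum(stats::residuals(fit)^2)))
    }
  }
  best <- NULL
  bestRss <- Inf
  for (s in starts) {
    fit <- fitOnce(xc, y, s, nParams, lower, upper)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < bestRss - 1e-12) {
      bestRss <- rss
      best <- fit
    }
  }
  if (is.null(best)) {
    stop(
      "logistic fit failed to converge from all ", length(starts),
      " starts (n = ", length(y), ", response range = ",
      signif(rg, 3), ")"
    )
  }
  p <- stats::coef(best)
  if (nParams == 4L) p <- c(p, asym = 1)
  list(par = p, rss = bestRss)
}

#' Fit an n-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4- or 5-parameter logistic on log10(dose), with
#' a multi-start bounded optimizer and a nonparametric bootstrap confidence
#' interval for the IC50 obtained by resampling replicate wells within each
#' dose. The reported IC50 is the relative one (dose at the midpoint
#' between the fitted asymptotes); the absolute IC50 (curve = 0.5) is also
#' computed when the curve crosses it.
#'
#' @param doses dose per observation, uM (> 0; replicates repeat the dose).
#' @param responses fraction-of-control response per observation.
#' @param nParams 4 (default) or 5.
#' @param nBoot bootstrap resamples for the 95% CI (default 1000; 0 skips).
#' @param bootType "residual" (default) resamples pooled fit residuals onto
#'   the fitted curve; "case" resamples replicate wells within each dose.
#'   With few replicates per dose, case resampling underestimates the
#'   sampling variance and its intervals undercover; the residual scheme
#'   keeps the dose design fixed and is calibrated under homoscedastic
#'   noise.
#' @param seed RNG seed for the bootstrap.
#' @param flatTol minimum response range; below it the fit aborts with
#'   "no dose effect".
#' @return a \linkS4class{DoseResponseFit}.
#' @examples
#' d <- rep(2^(0:7) * 0.5, each = 3)
#' y <- 1 / (1 + (d / 2)) # ~ decreasing response, IC50 2
#' fit <- fitLogistic(d, y, nBoot = 50)
#' ic50(fit)
#' @export
fitLogistic <- function(doses, responses, nParams = 4L, nBoot = 1000L,
                        bootType = c("residual", "case"), seed = 1L,
                        flatTol = 0.05) {
  bootType <- match.arg(bootType)
  stopifnot(length(doses) == length(responses), all(doses > 0))
  nParams <- as.integer(nParams)
  if (!nParams %in% c(4L, 5L)) stop("nParams must be 4 or 5")
  if (length(unique(doses)) < nParams) {
    stop("need at least ", nParams, " distinct doses")
  }
  x <- log10(doses)
  center <- stats::median(x)
  xc <- x - center
  core <- fitCore(xc, responses, nParams, flatTol)
  ic <- relativeIC50(core$par, center)
  icAbs <- absoluteIC50(core$par, center)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    byDose <- split(seq_along(doses), doses)
    p <- core$par
    fitted <- logistic5(xc, p["bottom"], p["top"], p["xmid"], p["slope"],
      p["asym"])
    resid <- responses - fitted
    # inflate residuals for the d.f. lost to the fitted parameters
    # (modified residuals; keeps the resampling variance unbiased)
    resid <- resid * sqrt(length(resid) /
      max(1, length(resid) - length(stats::na.omit(p[1:nParams]))))
    set.seed(seed)
    boots <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
      if (bootType == "residual") {
        xb <- xc
        yb <- fitted + sample(resid, length(resid), replace = TRUE)
      } else {
        idx <- unlist(lapply(byDose, function(g) {
          g[sample.int(length(g), length(g), replace = TRUE)]
        }), use.names = FALSE)
        xb <- xc[idx]
        yb <- responses[idx]
      }
      bc <- tryCatch(
        fitCore(xb, yb, nParams, flatTol, startFrom = core$par),
        error = function(e) NULL
      )
      if (!is.null(bc)) boots[b] <- relativeIC50(bc$par, center)
    }
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 10) {
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
  }
  new("DoseResponseFit",
    parameters = core$par, nParams = nParams,
    ic50 = ic, ic50Absolute = icAbs, ic50CI95 = ci, rss = core$rss,
    data = data.frame(dose = doses, response = responses),
    extrapolated = !(ic >= min(doses) && ic <= max(doses))
  )
}

#' Predict from a fitted dose-response curve
#'
#' @param object a \linkS4class{DoseResponseFit}.
#' @param doses doses (uM) to evaluate.
#' @return fitted response values.
#' @export
predictResponse <- function(object, doses) {
  p <- object@parameters
  center <- stats::median(log10(object@data$dose))
  logistic5(
    log10(doses) - center, p["bottom"], p["top"], p["xmid"],
    p["slope"], p["asym"]
  )
}
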