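#' Three-parameter Hill fit
#'
#' Fits the concentration-response model
#' \deqn{R(c) = R_{max} \frac{c^h}{EC_{50}^h + c^h}}
#' (lower asymptote fixed at 0, appropriate for responses expressed as
#' dF/F0 over a ligand-free baseline) by nonlinear least squares on the
#' pooled replicates (default) or on per-concentration means.
#' Initialization: EC50 at the geometric mean of the tested concentrations,
#' Hill coefficient 1, \eqn{R_{max}} at the maximum observed response.
#'
#' @param table a \code{\link{dose_response_table}} (or data.frame with
#'   columns \code{concentration} in M and \code{response}).
#' @param pooled fit pooled replicates (TRUE) or per-concentration means.
#' @return list of class \code{hill_fit}: \code{r_max}, \code{ec50} (M),
#'   \code{hill}, \code{pec50}, \code{vcov}, \code{converged},
#'   \code{warning}.
#' @export
fit_hill3 <- function(table, pooled = TRUE) {
  conc <- table$concentration
  resp <- table$response
  stopifnot(all(conc > 0))
  uc <- sort(unique(conc))
  if (length(uc) < 3)
    stop("at least 3 distinct concentrations are required")
  if (log10(max(uc) / min(uc)) < 1)
    stop("tested concentrations must span at least one decade")
  if (!pooled) {
    resp <- as.numeric(tapply(resp, conc, mean))
    conc <- uc
  }
  # rescale concentrations to their geometric mean so all three parameters
  # are O(1) for the optimizer; exact unit invariance is preserved
  g <- exp(mean(log(uc)))
  df <- data.frame(conc = conc / g, resp = resp)
  # EC50 starting points: half-max crossing of the per-concentration means,
  # plus a spread over the tested range against bad local minima
  mu <- tapply(resp, conc, mean)
  half <- max(mu) / 2
  cross <- which(mu >= half)[1]
  ec50_starts <- unique(c(if (!is.na(cross)) uc[cross] / g,
                          1, min(uc) / g, max(uc) / g))
  best <- NULL
  for (e0 in ec50_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(resp ~ r_max * conc^hill / (ec50^hill + conc^hill),
                        data = df,
                        start = list(r_max = max(resp), ec50 = e0,
                                     hill = 1),
                        lower = c(1e-12, 1e-12, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 500,
                                                             ftol = 1e-12,
                                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (stats::coef(fit)[["hill"]] <= 2e-3) next # degenerate flat fit
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  fit <- best
  if (is.null(fit)) {
    return(structure(list(r_max = NA_real_, ec50 = NA_real_,
                          hill = NA_real_, pec50 = NA_real_, vcov = NULL,
                          converged = FALSE,
                          warning = "fit did not converge"),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  ec50 <- cf[["ec50"]] * g
  out_of_range <- ec50 > 10 * max(uc) || ec50 < min(uc) / 10
  structure(list(r_max = cf[["r_max"]], ec50 = ec50,
                 hill = cf[["hill"]],
                 pec50 = pec50_from_ec50(ec50),
                 vcov = tryCatch({
                   v <- stats::vcov(fit)
                   v[2, ] <- v[2, ] * g
                   v[, 2] <- v[, 2] * g
                   v
                 }, error = function(e) NULL),
                 converged = !out_of_range,
                 warning = if (out_of_range)
                   "fitted EC50 more than 10x outside the tested range"
                 else NULL),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: not converged", if (!is.null(x$warning))
      paste0("(", x$warning, ")"), "\n")
  } else {
    cat(sprintf("Three-parameter Hill fit:\n  R_max = %.3g  EC50 = %.3g M (%.4g nM)  h = %.3g  pEC50 = %.2f\n",
                x$r_max, x$ec50, 1e9 * x$ec50, x$hill, x$pec50))
  }
  invisible(x)
}

#' pEC50 from EC50
#'
#' \eqn{pEC_{50} = -\log_{10}(EC_{50} / 1 M)}; e.g. 28.65 nM gives 7.54.
#'
#' @param ec50 half-maximal effective concentration in molar, > 0.
#' @return pEC50 (dimensionless).
#' @export
pec50_from_ec50 <- function(ec50) {
  if (any(ec50 <= 0)) stop("EC50 must be positive")
  -log10(ec50)
}

#' Normalize dose-response values to the maximal response
#'
#' Divides responses by either the fitted Hill \eqn{R_{max}} (default) or by
#' the empirical maximum, so the plateau of the normalized curve is 1. EC50
#' and the Hill coefficient are unchanged by this rescaling.
#'
#' @param table a \code{\link{dose_response_table}}.
#' @param mode \code{"fitted"} or \code{"empirical"}.
#' @return normalized \code{dose_response_table} with the \code{normalized}
#'   attribute set.
#' @export
normalize_responses <- function(table, mode = c("fitted", "empirical")) {
  mode <- match.arg(mode)
  if (max(table$response) <= 0) stop("all responses are non-positive")
  denom <- if (mode == "fitted") {
    f <- fit_hill3(table)
    if (!f$converged) stop("Hill fit failed; use mode = \"empirical\"")
    f$r_max
  } else max(table$response)
  out <- dose_response_table(table$concentration, table$response / denom,
                             table$replicate_id, normalized = TRUE)
  attr(out, "norm_mode") <- mode
  attr(out, "norm_denominator") <- denom
  out
}
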