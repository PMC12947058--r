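#' Dose-response curve container
#'
#' @param doses Absorbed doses (Gy), non-negative and strictly increasing.
#' @param responses Measured responses (net OD, or normalized Raman
#'   intensity), same length.
#' @param uncertainties Optional 1-sigma uncertainties, same length.
#' @param modality `"OD"` or `"RS"`.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(doses, responses, uncertainties = NULL,
                                modality = c("OD", "RS")) {
  modality <- match.arg(modality)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length")
  }
  if (any(doses < 0)) stop("doses must be >= 0")
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing")
  }
  if (!is.null(uncertainties) && length(uncertainties) != length(doses)) {
    stop("uncertainties must match doses in length")
  }
  structure(list(doses = doses, responses = responses,
                 uncertainties = uncertainties, modality = modality),
            class = "dose_response_curve")
}

check_histogram <- function(hist) {
  if (!inherits(hist, "se_histogram")) stop("expected an se_histogram")
  if (abs(histogram_mass(hist) - 1) > 1e-6) {
    stop("histogram is not normalized: zero spike + integral must be 1")
  }
  invisible(hist)
}

#' One-hit detector response integrals
#'
#' `response_integral()` evaluates `integral exp(-alpha z) f(z; D) dz`
#' (including the z = 0 point mass) against a binned specific-energy
#' distribution using midpoint quadrature. `r_theory()` is the fraction of
#' affected sensitive volumes `1 - response_integral`, the Zaider one-hit
#' dose response: it vanishes at alpha = 0 and saturates at
#' `1 - f_{z=0}` for large alpha.
#'
#' @param hist A normalized [se_histogram()].
#' @param alpha Saturation parameter (Gy^-1), >= 0. Vectorized.
#' @return `response_integral`: values in `[zero_mass, 1]`;
#'   `r_theory`: values in `[0, 1 - zero_mass]`.
#' @export
response_integral <- function(hist, alpha) {
  check_histogram(hist)
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (length(hist$densities) == 0) return(rep(1, length(alpha)))
  mids <- (utils::head(hist$bin_edges, -1) +
           utils::tail(hist$bin_edges, -1)) / 2
  w <- hist$densities * diff(hist$bin_edges)
  vapply(alpha, function(a) hist$zero_mass + sum(exp(-a * mids) * w),
         numeric(1))
}

#' @rdname response_integral
#' @export
r_theory <- function(hist, alpha) {
  1 - response_integral(hist, alpha)
}

#' Modality response model
#'
#' Predicted detector response: a scaling factor m times the fraction of
#' affected sensitive volumes plus an offset signal c present even at 0 Gy
#' (initial polymerization). With the degenerate zero-dose distribution
#' (unit point mass at z = 0) the prediction is exactly `c`.
#'
#' @inheritParams response_integral
#' @param m Scaling factor, > 0.
#' @param c Offset signal (response units).
#' @return Predicted response `m * r_theory(hist, alpha) + c`.
#' @export
r_response <- function(hist, m, alpha, c) {
  if (!is.finite(m) || m <= 0) stop("m must be > 0")
  m * r_theory(hist, alpha) + c
}

#' Fit the one-hit response model to a dose-response curve
#'
#' Least-squares calibration of (m, alpha, c) by the Levenberg-Marquardt
#' algorithm (via [minpack.lm::nls.lm()]), using one specific-energy
#' histogram per dose to evaluate the model. Positivity of m and alpha is
#' enforced by fitting on the log scale; reported parameters are on the
#' natural scale. Unweighted by default; if the curve carries uncertainties,
#' `weighted = TRUE` applies 1/sigma^2 weights.
#'
#' @param curve A [dose_response_curve()] with at least 4 points.
#' @param hists List of normalized [se_histogram()]s, one per dose (use a
#'   unit zero spike, `se_histogram(1)`, for a 0 Gy point).
#' @param init Optional numeric `c(m, alpha, c)` starting values. Default:
#'   c0 = response at the lowest dose, m0 = max(response) - c0, alpha0 = 1.
#' @param weighted Use 1/sigma^2 weights when uncertainties are present.
#' @return An object of class `onehit_fit`: `m`, `alpha`, `c`, `fitted`,
#'   `residuals` (fitted - measured), `percent_differences`
#'   (100 |fitted - measured| / measured), `converged`, `info`, `message`,
#'   `modality`.
#' @export
#' @examples
#' eng <- calibrate_from_anchor(0.003, 0.35, 2.05)
#' doses <- delivered_doses()
#' hists <- lapply(doses, function(D)
#'   histogram_f(sample_field(eng, voxel_geometry_preset("vx-lg"), D,
#'                            c(100, 100, 10), seed = 7)))
#' resp <- mapply(r_response, hists, MoreArgs = list(m = 0.19, alpha = 1.2,
#'                c = 0.026))
#' fit_onehit(dose_response_curve(doses, resp, modality = "OD"), hists)
fit_onehit <- function(curve, hists, init = NULL, weighted = FALSE) {
  stopifnot(inherits(curve, "dose_response_curve"))
  y <- curve$responses
  if (length(y) < 4) stop("need at least 4 dose points to fit 3 parameters")
  if (length(hists) != length(y)) stop("one histogram per dose is required")
  lapply(hists, check_histogram)
  # precompute quadrature nodes once; alpha varies during optimization
  pre <- lapply(hists, function(h) {
    if (length(h$densities) == 0) {
      list(zm = h$zero_mass, mids = numeric(0), w = numeric(0))
    } else {
      list(zm = h$zero_mass,
           mids = (utils::head(h$bin_edges, -1) +
                   utils::tail(h$bin_edges, -1)) / 2,
           w = h$densities * diff(h$bin_edges))
    }
  })
  rtheo <- function(alpha) {
    vapply(pre, function(p) 1 - (p$zm + sum(exp(-alpha * p$mids) * p$w)),
           numeric(1))
  }
  if (is.null(init)) {
    c0 <- y[which.min(curve$doses)]
    m0 <- max(y) - c0
    if (!is.finite(m0) || m0 <= 0) m0 <- max(abs(y), 1e-3)
    init <- c(m0, 1, c0)
  }
  if (init[1] <= 0 || init[2] <= 0) stop("init m and alpha must be > 0")
  w <- rep(1, length(y))
  if (weighted) {
    if (is.null(curve$uncertainties)) {
      stop("weighted fit requested but the curve has no uncertainties")
    }
    w <- 1 / curve$uncertainties^2
  }
  fn <- function(par) {
    sqrt(w) * (exp(par[1]) * rtheo(exp(par[2])) + par[3] - y)
  }
  out <- minpack.lm::nls.lm(
    par = c(log(init[1]), log(init[2]), init[3]), fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  m <- exp(out$par[1])
  alpha <- exp(out$par[2])
  cc <- out$par[3]
  fitted <- m * rtheo(alpha) + cc
  converged <- out$info %in% 1:4
  if (!converged) {
    warning("Levenberg-Marquardt did not converge: ", out$message)
  }
  structure(list(
    m = m, alpha = alpha, c = cc,
    fitted = fitted,
    residuals = fitted - y,
    percent_differences = 100 * abs(fitted - y) / abs(y),
    converged = converged, info = out$info, message = out$message,
    niter = out$niter, modality = curve$modality
  ), class = "onehit_fit")
}

#' @export
print.onehit_fit <- function(x, ...) {
  cat(sprintf(
    "one-hit fit (%s): m = %.4g, alpha = %.4g Gy^-1, c = %.4g\n",
    x$modality, x$m, x$alpha, x$c
  ))
  cat(sprintf("  max |percent difference| = %.3g%%, converged: %s\n",
              max(x$percent_differences), x$converged))
  invisible(x)
}

#' Dose series of the irradiation study design
#'
#' `delivered_doses()` returns the 15 delivered doses of the film irradiations
#' (Gy); `tabulated_doses()` returns the dose grid of the tabulated Monte Carlo
#' summaries, which differs in three low-dose entries.
#'
#' @return Numeric vector of doses in Gy.
#' @export
delivered_doses <- function() {
  c(0.003, 0.005, 0.007, 0.01, 0.02, 0.03, 0.04, 0.05,
    0.07, 0.09, 0.1, 0.2, 0.3, 0.4, 0.5)
}

#' @rdname delivered_doses
#' @export
tabulated_doses <- function() {
  c(0.003, 0.006, 0.009, 0.011, 0.02, 0.03, 0.04, 0.05,
    0.07, 0.09, 0.1, 0.2, 0.3, 0.4, 0.5)
}
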