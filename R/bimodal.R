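# Two-Gaussian decomposition of the full-day activity profile and the
# afternoon break statistic T_break.

# Expected mass per 5-min bin under the two-Gaussian superposition
#   F(t) = a0 * dnorm(t, tM, sM) + aN * dnorm(t, tN, sN)
.two_gauss_mass <- function(par, centers, bin_width = .bin_width) {
  bin_width * (par[["a0"]] * dnorm(centers, par[["tM"]], par[["sM"]]) +
               par[["aN"]] * dnorm(centers, par[["tN"]], par[["sN"]]))
}

#' Fit a two-Gaussian superposition to a full-day activity profile
#'
#' Nonlinear least squares of the noon + evening Gaussian superposition
#' against the normalized full-day histogram over bin centres
#' (Levenberg-Marquardt, both amplitudes free). Initialization
#' `tM = 12, tN = 20, sM = sN = 2, a0 = aN = 0.5`; box constraints
#' `tM` in \[8, 16\], `tN` in \[17, 26\], `s` in \[0.25, 6\], amplitudes
#' nonnegative. Modes are relabeled if needed so the noon mode comes first.
#' A fit is flagged degenerate when one amplitude carries less than 5% of
#' the mass or the modes sit closer than 2 h.
#'
#' @param profile An `activity_profile` of the full-day window, or a bare
#'   numeric vector of 288 normalized bin masses.
#' @return A `bimodal_fit`: list with `a0`, `aN`, `tM`, `sM`, `tN`, `sN`,
#'   `residual` (sum of squared residuals), `converged`, `degenerate`.
#' @export
fit_two_gaussians <- function(profile) {
  if (inherits(profile, "activity_profile")) {
    if (profile$window != "full")
      stop("the two-Gaussian fit expects the full-day profile")
    y <- profile$density
    centers <- profile$centers
  } else {
    y <- as.numeric(profile)
    centers <- .window_spec("full")$centers
    if (length(y) != length(centers))
      stop("expected ", length(centers), " full-day bin masses")
    y <- y / sum(y)
  }
  start <- c(a0 = 0.5, aN = 0.5, tM = 12, sM = 2, tN = 20, sN = 2)
  lower <- c(a0 = 0, aN = 0, tM = 8, sM = 0.25, tN = 17, sN = 0.25)
  upper <- c(a0 = 5, aN = 5, tM = 16, sM = 6, tN = 26, sN = 6)
  resid_fun <- function(p) y - .two_gauss_mass(p, centers)
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- fit$par
  if (par[["tM"]] > par[["tN"]]) {  # relabel so the noon mode comes first
    par <- c(a0 = par[["aN"]], aN = par[["a0"]],
             tM = par[["tN"]], sM = par[["sN"]],
             tN = par[["tM"]], sN = par[["sM"]])
  }
  wts <- c(par[["a0"]], par[["aN"]]) / (par[["a0"]] + par[["aN"]])
  structure(
    list(a0 = par[["a0"]], aN = par[["aN"]],
         tM = par[["tM"]], sM = par[["sM"]],
         tN = par[["tN"]], sN = par[["sN"]],
         residual = sum(fit$fvec^2),
         converged = fit$info %in% 1:4,
         degenerate = any(wts < 0.05) ||
           (par[["tN"]] - par[["tM"]]) < 2),
    class = "bimodal_fit"
  )
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(paste0("<bimodal_fit> noon %.2f h (sd %.2f), evening %.2f h ",
                     "(sd %.2f), weights %.2f/%.2f%s%s\n"),
              x$tM, x$sM, x$tN, x$sN, x$a0, x$aN,
              if (!x$converged) " [not converged]" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Afternoon break duration T_break
#'
#' `T_break = (tN - sN) - (tM + sM)`: the gap between one standard
#' deviation above the noon mode and one below the evening mode. Negative
#' values (heavily overlapping modes) are returned as-is; a non-converged
#' or degenerate fit gives `NA`.
#'
#' @param fit A `bimodal_fit`.
#' @return Hours, or `NA_real_`.
#' @export
t_break <- function(fit) {
  stopifnot(inherits(fit, "bimodal_fit"))
  if (!fit$converged || fit$degenerate) return(NA_real_)
  (fit$tN - fit$sN) - (fit$tM + fit$sM)
}
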