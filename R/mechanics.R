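#' Surface tension from the diagonal pressure tensor
#'
#' For a planar membrane in an orthorhombic box the surface tension is the
#' imbalance between the normal and lateral pressure components integrated
#' over the box height,
#' \deqn{\gamma = L_z \left( P_{zz} - \tfrac{1}{2}(P_{xx} + P_{yy}) \right),}
#' evaluated here with pressures in bar and Lz in Angstrom; 1 bar.Angstrom =
#' 0.01 mN/m, so the result carries a 0.01 prefactor and is in mN/m.
#'
#' @param pressure numeric length-3 vector (Pxx, Pyy, Pzz) in bar, or an
#'   n-by-3 matrix / data frame with those columns for n frames.
#' @param Lz box height(s) in Angstrom (scalar or length n).
#' @return Surface tension(s) in mN/m.
#' @export
surface_tension <- function(pressure, Lz) {
  if (is.data.frame(pressure)) pressure <- as.matrix(pressure)
  if (is.null(dim(pressure))) pressure <- matrix(pressure, ncol = 3)
  if (any(Lz <= 0)) stop("Lz must be positive")
  g <- 0.01 * Lz * (pressure[, 3] - (pressure[, 1] + pressure[, 2]) / 2)
  unname(g)
}

#' Per-frame area per lipid
#'
#' Lateral box area divided by the number of lipids in one leaflet.
#'
#' @param frames list of [boxed_frame] objects (or a single frame).
#' @param lipids_per_leaflet positive lipid count in one leaflet.
#' @return Numeric vector of per-frame areas, Angstrom^2.
#' @export
area_per_lipid <- function(frames, lipids_per_leaflet) {
  if (inherits(frames, "boxed_frame")) frames <- list(frames)
  if (length(lipids_per_leaflet) != 1L || lipids_per_leaflet <= 0)
    stop("lipids_per_leaflet must be a single positive count")
  vapply(frames, function(fr) fr$box[1] * fr$box[2] / lipids_per_leaflet,
         numeric(1))
}

#' Autocorrelation-corrected mean and standard error of a time series
#'
#' Estimates the integrated autocorrelation time tau by summing the
#' normalized autocovariance function until its first non-positive value
#' (the initial-positive-sequence truncation), forms the statistical
#' inefficiency g = 1 + 2 tau, and reports
#' sem = sd(x) * sqrt(g / N).  For uncorrelated data g ~ 1 and the usual
#' sd/sqrt(N) is recovered; for an AR(1) process with coefficient phi the
#' true inefficiency is (1 + phi)/(1 - phi).  The autocovariance is
#' computed by FFT.
#'
#' @param series numeric vector, length >= 10.
#' @return A list with `mean`, `sem`, `tau` (frames), `g`, and `n`.
#' @export
autocorr_sem <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 10L) stop("autocorr_sem needs a series of length >= 10")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  mu <- mean(x)
  if (stats::sd(x) == 0)
    return(list(mean = mu, sem = 0, tau = 0, g = 1, n = n))
  xc <- x - mu
  m <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(xc, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / m
  acov <- ac[seq_len(n)] / n            # biased autocovariance
  rho <- acov / acov[1]
  if (n > 1L) {
    r <- rho[-1]
    cut <- which(r <= 0)[1]
    tau <- if (is.na(cut)) sum(r) else if (cut == 1L) 0 else sum(r[seq_len(cut - 1L)])
  } else tau <- 0
  tau <- max(tau, 0)
  g <- 1 + 2 * tau
  list(mean = mu, sem = stats::sd(x) * sqrt(g / n), tau = tau, g = g, n = n)
}

#' Bundle per-tension area-per-lipid series
#'
#' Attaches autocorrelation-corrected means and standard errors to each
#' imposed-tension series, ready for [fit_area_compressibility].
#'
#' @param gammas numeric vector of imposed surface tensions, mN/m.
#' @param series list of numeric area-per-lipid series (Angstrom^2), one per
#'   tension, each of length >= 2.
#' @param discard fraction of initial frames to drop from each series before
#'   computing statistics (equilibration discard; default 0).
#' @return An object of class `gamma_area_series`: a data frame with columns
#'   `gamma`, `mean_apl`, `sem_apl`, `tau`, `n`, carrying the raw series as
#'   an attribute.
#' @export
gamma_area_series <- function(gammas, series, discard = 0) {
  if (length(gammas) != length(series))
    stop("gammas and series must have the same length")
  if (discard < 0 || discard >= 1) stop("discard must be in [0, 1)")
  series <- lapply(series, function(s) {
    s <- as.numeric(s)
    if (length(s) < 2L) stop("every series must have length >= 2")
    if (discard > 0) s <- s[-seq_len(floor(discard * length(s)))]
    s
  })
  stats_list <- lapply(series, function(s) {
    if (length(s) >= 10L) {
      autocorr_sem(s)
    } else {
      list(mean = mean(s), sem = stats::sd(s) / sqrt(length(s)),
           tau = 0, g = 1, n = length(s))
    }
  })
  out <- data.frame(
    gamma = as.numeric(gammas),
    mean_apl = vapply(stats_list, `[[`, numeric(1), "mean"),
    sem_apl = vapply(stats_list, `[[`, numeric(1), "sem"),
    tau = vapply(stats_list, `[[`, numeric(1), "tau"),
    n = vapply(stats_list, `[[`, numeric(1), "n"))
  attr(out, "series") <- series
  class(out) <- c("gamma_area_series", "data.frame")
  out
}

#' Fit the area compressibility modulus K_A
#'
#' The bilayer is characterised by the linear response gamma = K_A * eps_A,
#' where the area strain eps_A = (<A> - <A>_0) / <A>_0 is measured relative
#' to the mean area per lipid at zero imposed tension.  K_A is the slope of
#' a regression of gamma on eps_A.  The imposed tensions are set exactly by
#' the barostat, so the statistical error lives in the strain: the fit is
#' weighted least squares with the strain uncertainties converted to
#' effective tension uncertainties through a preliminary slope estimate,
#' refined once.  The slope standard error is the analytic weighted
#' least-squares value using the per-point uncertainties as known variances.
#' If any strain uncertainty is zero (noiseless input) an unweighted fit
#' with residual-based errors is used instead.
#'
#' @param series_by_gamma a [gamma_area_series] with at least three distinct
#'   tensions, one of which must be gamma = 0 (the strain reference).
#' @return An object of class `ka_estimate`: list with `K_A` and `K_A_se`
#'   (mN/m), `A0` (Angstrom^2), `intercept` (mN/m), `r_squared`, and the
#'   per-tension diagnostics table `points`.
#' @export
fit_area_compressibility <- function(series_by_gamma) {
  df <- as.data.frame(series_by_gamma)
  if (length(unique(df$gamma)) < 3L)
    stop("need at least three distinct surface tensions")
  i0 <- which(df$gamma == 0)
  if (!length(i0))
    stop("a gamma = 0 series is required to define the reference area")
  A0 <- mean(df$mean_apl[i0])
  eps <- (df$mean_apl - A0) / A0
  sem_eps <- df$sem_apl / A0
  if (stats::sd(eps) == 0) stop("degenerate design: all strains identical")

  fit0 <- stats::lm(df$gamma ~ eps)
  slope <- unname(stats::coef(fit0)[2])
  weighted <- all(sem_eps > 0)
  if (weighted) {
    for (it in 1:2) {  # preliminary slope, one refinement
      w <- 1 / (slope^2 * sem_eps^2)
      fit <- stats::lm(df$gamma ~ eps, weights = w)
      slope <- unname(stats::coef(fit)[2])
    }
    # analytic slope variance with weights as known inverse variances
    xbar <- sum(w * eps) / sum(w)
    se <- sqrt(1 / sum(w * (eps - xbar)^2))
    res <- stats::residuals(fit)
    tss <- sum(w * (df$gamma - sum(w * df$gamma) / sum(w))^2)
    r2 <- if (tss > 0) max(0, min(1, 1 - sum(w * res^2) / tss)) else 1
  } else {
    fit <- fit0
    se <- summary(fit)$coefficients[2, 2]
    if (!is.finite(se)) se <- 0
    r2 <- summary(fit)$r.squared
  }
  structure(list(K_A = slope,
                 K_A_se = se,
                 A0 = A0,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 points = cbind(df, eps = eps, sem_eps = sem_eps)),
            class = "ka_estimate")
}

#' @export
print.ka_estimate <- function(x, ...) {
  cat(sprintf("K_A = %.2f +/- %.2f mN/m  (A0 = %.2f A^2, r^2 = %.4f)\n",
              x$K_A, x$K_A_se, x$A0, x$r_squared))
  invisible(x)
}
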