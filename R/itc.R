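#' Titration protocol
#'
#' Instrument protocol for a standard-volume ITC experiment. Defaults
#' follow the study design used throughout: 25 injections of 10 ul of
#' 700 uM ligand into a 1 ml cell of 70 uM macromolecule at 20 C.
#'
#' @param V0 Cell volume in litres.
#' @param Ls Syringe ligand concentration, mol/L.
#' @param M0 Initial cell macromolecule concentration, mol/L.
#' @param injections Vector of injection volumes in litres.
#' @param temperature Temperature in kelvin.
#' @return An object of class `titration_protocol`.
#' @export
titration_protocol <- function(V0 = 1.0e-3,
                               Ls = 700e-6,
                               M0 = 70e-6,
                               injections = rep(10e-6, 25),
                               temperature = 293.15) {
  stopifnot(V0 > 0, Ls >= 0, M0 >= 0, all(injections > 0), temperature > 0)
  if (sum(injections) > 0.5 * V0) {
    abort("total injected volume exceeds half the cell volume")
  }
  structure(list(V0 = V0, Ls = Ls, M0 = M0, injections = injections,
                 temperature = temperature),
            class = "titration_protocol")
}

#' One-site binding parameters
#'
#' @param Kd Dissociation constant, mol/L (> 0).
#' @param n Binding stoichiometry, sites per macromolecule (> 0).
#' @param dH Binding enthalpy, J per mole of complex.
#' @param q_offset Constant per-injection background heat, microjoules.
#' @return An object of class `one_site_params`.
#' @export
one_site_params <- function(Kd, n = 1, dH = -40e3, q_offset = 0) {
  stopifnot(Kd > 0, n > 0, is.finite(dH), is.finite(q_offset))
  structure(list(Kd = Kd, n = n, dH = dH, q_offset = q_offset),
            class = "one_site_params")
}

#' Equilibrium complex concentration for one-site binding
#'
#' Solves `PL` from total site concentration `n*M`, total ligand `L` and
#' `Kd` via the binding quadratic, using the numerically stable root form
#' `PL = 2ab / (S + sqrt(S^2 - 4ab))` with `a = n*M`, `b = L`,
#' `S = a + b + Kd` (avoids catastrophic cancellation at low occupancy).
#'
#' @param nM Total binding-site concentration, mol/L (vectorized).
#' @param L Total ligand concentration, mol/L.
#' @param Kd Dissociation constant, mol/L.
#' @return Complex concentration, mol/L.
#' @export
bound_complex <- function(nM, L, Kd) {
  a <- nM
  b <- L
  s <- a + b + Kd
  disc <- s * s - 4 * a * b
  stopifnot(all(disc >= 0))
  ifelse(a * b == 0, 0, 2 * a * b / (s + sqrt(disc)))
}

#' Simulate a one-site ITC titration
#'
#' Forward model of integrated per-injection heats. Concentrations follow
#' the displacement recursion: each injection of volume `v` displaces an
#' equal volume of cell contents, so
#' `M_i = M_{i-1} (1 - v_i/V0)` and
#' `L_i = L_{i-1} (1 - v_i/V0) + Ls v_i/V0`.
#' The complex concentration after each injection comes from
#' [bound_complex()], and the measured heat is
#' `q_i = dH * V0 * (PL_i - PL_{i-1} (1 - v_i/V0)) + q_offset + noise`
#' (in microjoules), i.e. the enthalpy of newly formed complex after
#' accounting for complex lost by displacement.
#'
#' @param protocol A [titration_protocol()].
#' @param params A [one_site_params()].
#' @param noise_sd Gaussian noise standard deviation, microjoules.
#' @param seed Integer seed (required when `noise_sd > 0` for
#'   reproducibility; ignored at zero noise).
#' @return A tibble with columns `injection`, `volume_L`, `M_total`,
#'   `L_total`, `PL`, `molar_ratio` and `heat_uJ`.
#' @export
simulate_titration <- function(protocol, params, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "titration_protocol"),
            inherits(params, "one_site_params"), noise_sd >= 0)
  if (noise_sd > 0 && is.null(seed)) abort("a seed is required when noise_sd > 0")
  q <- ideal_heats(protocol, params)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    q$heat_uJ <- q$heat_uJ + rnorm(nrow(q), 0, noise_sd)
  }
  q
}

## Noise-free forward model shared by simulation and fitting.
ideal_heats <- function(protocol, params) {
  v <- protocol$injections
  V0 <- protocol$V0
  ni <- length(v)
  M <- L <- PL <- q <- numeric(ni)
  m_prev <- protocol$M0
  l_prev <- 0
  pl_prev <- bound_complex(params$n * m_prev, l_prev, params$Kd)
  for (i in seq_len(ni)) {
    f <- 1 - v[i] / V0
    m <- m_prev * f
    l <- l_prev * f + protocol$Ls * v[i] / V0
    pl <- bound_complex(params$n * m, l, params$Kd)
    q[i] <- params$dH * V0 * (pl - pl_prev * f) * 1e6 + params$q_offset
    M[i] <- m; L[i] <- l; PL[i] <- pl
    m_prev <- m; l_prev <- l; pl_prev <- pl
  }
  tibble(injection = seq_len(ni), volume_L = v, M_total = M, L_total = L,
         PL = PL, molar_ratio = L / M, heat_uJ = q)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Heat-of-dilution correction
#'
#' Elementwise subtraction of a buffer-control titration from a sample
#' titration.
#'
#' @param heats Numeric vector (or thermogram tibble) of sample heats, uJ.
#' @param control Numeric vector (or thermogram tibble) of control heats,
#'   same length.
#' @return Corrected heats in the same shape as `heats`.
#' @export
subtract_dilution <- function(heats, control) {
  hv <- if (is.data.frame(heats)) heats$heat_uJ else heats
  cv <- if (is.data.frame(control)) control$heat_uJ else control
  if (length(hv) != length(cv)) {
    abort(sprintf("length mismatch: %d sample vs %d control injections",
                  length(hv), length(cv)))
  }
  out <- hv - cv
  if (is.data.frame(heats)) {
    heats$heat_uJ <- out
    heats
  } else {
    out
  }
}

#' Wiseman c parameter
#'
#' `c = n * M0 / Kd`, the dimensionless sigmoidality parameter of the
#' titration isotherm. Values below ~1 or above ~1000 give poorly
#' identifiable fits; a warning attribute flags those regimes.
#'
#' @param protocol A [titration_protocol()].
#' @param params A [one_site_params()] (or anything with `n` and `Kd`).
#' @return Numeric `c` with attribute `regime` one of `"ok"`, `"low"`,
#'   `"high"`.
#' @export
wiseman_c <- function(protocol, params) {
  c_val <- params$n * protocol$M0 / params$Kd
  structure(c_val,
            regime = if (c_val < 1) "low" else if (c_val > 1000) "high" else "ok")
}

#' Fit the one-site binding model to corrected heats
#'
#' Nonlinear least squares of the displacement forward model against
#' per-injection heats, with `Kd` log-parameterized and multi-start
#' Levenberg-Marquardt optimization (best residual sum of squares wins).
#' Non-convergence of all starts is flagged in the result rather than
#' raised.
#'
#' @param heats Numeric vector (or thermogram tibble) of dilution-corrected
#'   heats, microjoules.
#' @param protocol A [titration_protocol()].
#' @param fix_n Optional fixed stoichiometry (e.g. `1` in low-c regimes
#'   where `n` is not identifiable).
#' @param bounds Named list of `lower`/`upper` for `log10(Kd)` (mol/L);
#'   default `[-12, 0]`.
#' @param n_starts Number of optimization starts (default 8).
#' @param seed Integer seed controlling start-point jitter.
#' @param weights Per-injection weights for the least squares (default
#'   uniform).
#' @param discard_first Drop the first injection before fitting (vendor
#'   convention for syringe-diffusion artifacts; default `FALSE`).
#' @return An object of class `one_site_fit`: fields `params`
#'   ([one_site_params()]), `se` (named standard errors), `rss`, `c`
#'   (Wiseman c at the fit), `converged`, `n_fixed`, `fitted` tibble.
#' @export
fit_one_site <- function(heats, protocol, fix_n = NULL,
                         bounds = list(lower = -12, upper = 0),
                         n_starts = 8, seed = 1, weights = NULL,
                         discard_first = FALSE) {
  q <- if (is.data.frame(heats)) heats$heat_uJ else as.numeric(heats)
  stopifnot(length(q) == length(protocol$injections))
  use <- rep(TRUE, length(q))
  if (discard_first) use[1] <- FALSE
  if (sum(use) < 6) abort("at least 6 usable injections are required")
  w <- if (is.null(weights)) rep(1, length(q)) else weights
  n_free <- if (is.null(fix_n)) 4L else 3L
  if (sum(use) <= n_free) abort("fewer injections than free parameters")

  resid_fun <- function(theta) {
    p <- theta_to_params(theta, fix_n)
    pred <- ideal_heats(protocol, p)$heat_uJ
    sqrt(w[use]) * (pred[use] - q[use])
  }

  starts <- make_starts(q, protocol, fix_n, bounds, n_starts, seed)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun,
                         lower = start_bounds(s, bounds)$lower,
                         upper = start_bounds(s, bounds)$upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, se = NULL, rss = NA_real_,
                          c = NA_real_, converged = FALSE,
                          n_fixed = !is.null(fix_n), fitted = NULL),
                     class = "one_site_fit"))
  }
  fit <- best$fit
  pars <- theta_to_params(fit$par, fix_n)
  se <- tryCatch({
    covm <- tryCatch(vcov(fit), error = function(e) NULL)
    if (is.null(covm)) setNames(rep(NA_real_, length(fit$par)), names(fit$par))
    else setNames(sqrt(pmax(diag(covm), 0)), names(fit$par))
  }, error = function(e) setNames(rep(NA_real_, length(fit$par)), names(fit$par)))
  pred <- ideal_heats(protocol, pars)
  pred$observed_uJ <- q
  structure(list(
    params = pars,
    se = se,
    rss = best$rss,
    c = as.numeric(wiseman_c(protocol, pars)),
    converged = fit$info %in% 1:4,
    n_fixed = !is.null(fix_n),
    fitted = pred
  ), class = "one_site_fit")
}

theta_to_params <- function(theta, fix_n) {
  n <- if (is.null(fix_n)) theta[["n"]] else fix_n
  one_site_params(Kd = 10^theta[["logKd"]], n = n,
                  dH = theta[["dH"]], q_offset = theta[["q_offset"]])
}

make_starts <- function(q, protocol, fix_n, bounds, n_starts, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # crude scale cues: total heat fixes the sign/order of dH, Kd spans the
  # plausible window between 1 nM and the syringe concentration
  moles_lig <- protocol$Ls * sum(protocol$injections)
  dh0 <- sum(q) * 1e-6 / max(moles_lig, 1e-12)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1e4
  log_kd_grid <- seq(max(bounds$lower, -10), min(bounds$upper, log10(max(protocol$Ls, 1e-4))),
                     length.out = n_starts)
  lapply(seq_len(n_starts), function(i) {
    th <- c(logKd = log_kd_grid[i] + runif(1, -0.2, 0.2),
            dH = dh0 * runif(1, 0.5, 2))
    if (is.null(fix_n)) th <- c(th, n = runif(1, 0.6, 1.6))
    c(th, q_offset = 0)
  })
}

start_bounds <- function(start, bounds) {
  lo <- c(logKd = bounds$lower, dH = -Inf, n = 1e-3, q_offset = -Inf)
  hi <- c(logKd = bounds$upper, dH = Inf, n = 100, q_offset = Inf)
  list(lower = unname(lo[names(start)]), upper = unname(hi[names(start)]))
}

#' @export
print.one_site_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("<one_site_fit> not converged\n")
    return(invisible(x))
  }
  cat(sprintf("<one_site_fit> Kd = %.4g M, n = %.3g%s, dH = %.4g J/mol, c = %.3g\n",
              x$params$Kd, x$params$n, if (x$n_fixed) " (fixed)" else "",
              x$params$dH, x$c))
  invisible(x)
}
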