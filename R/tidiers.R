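#' Tidy a one-site ITC fit
#'
#' @param x A `one_site_fit` from [fit_one_site()].
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`. `Kd` is reported in mol/L (with the standard error
#'   propagated from the log10 scale), `dH` in J/mol, `q_offset` in uJ.
#' @method tidy one_site_fit
#' @export
tidy.one_site_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(), estimate = double(),
                  std.error = double()))
  }
  p <- x$params
  terms <- c("Kd", "n", "dH", "q_offset")
  est <- c(p$Kd, p$n, p$dH, p$q_offset)
  se <- c(
    if (!is.na(x$se[["logKd"]])) p$Kd * log(10) * x$se[["logKd"]] else NA_real_,
    if (x$n_fixed) 0 else x$se[["n"]],
    x$se[["dH"]],
    x$se[["q_offset"]]
  )
  tibble(term = terms, estimate = est, std.error = se)
}

#' Glance at a one-site ITC fit
#'
#' @param x A `one_site_fit`.
#' @param ... Unused.
#' @return One-row tibble: `rss`, `wiseman_c`, `converged`, `n_fixed`,
#'   `n_injections`.
#' @method glance one_site_fit
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble(rss = x$rss, wiseman_c = x$c, converged = x$converged,
         n_fixed = x$n_fixed,
         n_injections = if (is.null(x$fitted)) NA_integer_ else nrow(x$fitted))
}
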