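#' State-dependent gamma perch-height emission model
#'
#' Perch heights (cm above ground) are modelled as draws from a gamma
#' distribution whose parameters depend on the current activity state.
#' Actively foraging individuals are expected to perch lower than inactive,
#' sit-and-wait individuals; the constructor warns when the active mean
#' (`shape * scale`) is not below the inactive mean. The defaults (active
#' mean 30 cm, inactive mean 80 cm, both with shape 2) are plausible
#' reconstructions for trunk-ground anoles and are intended to be replaced
#' by values fitted from control observations with
#' [fit_emission_model()].
#'
#' @param active_shape,active_scale Gamma shape (dimensionless) and scale
#'   (cm) for the active state; both strictly positive.
#' @param inactive_shape,inactive_scale Gamma shape and scale for the
#'   inactive state.
#' @return An object of class `"emission_model"`.
#' @examples
#' em <- emission_model()
#' emission_means(em)
#' @export
emission_model <- function(active_shape = 2, active_scale = 15,
                           inactive_shape = 2, inactive_scale = 40) {
  pars <- c(active_shape = active_shape, active_scale = active_scale,
            inactive_shape = inactive_shape, inactive_scale = inactive_scale)
  if (!all(is.finite(pars)) || any(pars <= 0))
    stop("all emission parameters must be strictly positive and finite")
  em <- structure(as.list(pars), class = "emission_model")
  m <- emission_means(em)
  if (m[["active"]] >= m[["inactive"]])
    warning(sprintf(
      "active mean perch height (%.1f cm) is not below the inactive mean (%.1f cm); ",
      m[["active"]], m[["inactive"]]),
      "active foragers are expected to perch lower", call. = FALSE)
  em
}

#' Mean perch height per state of an emission model
#'
#' @param em An `"emission_model"`.
#' @return Named numeric vector `c(active = , inactive = )`, cm.
#' @export
emission_means <- function(em) {
  stopifnot(inherits(em, "emission_model"))
  c(active = em$active_shape * em$active_scale,
    inactive = em$inactive_shape * em$inactive_scale)
}

emission_vars <- function(em) {
  c(active = em$active_shape * em$active_scale^2,
    inactive = em$inactive_shape * em$inactive_scale^2)
}

#' @export
print.emission_model <- function(x, ...) {
  m <- emission_means(x)
  cat(sprintf("Gamma perch-height emissions:\n  active:   shape %.4g, scale %.4g cm (mean %.1f cm)\n  inactive: shape %.4g, scale %.4g cm (mean %.1f cm)\n",
              x$active_shape, x$active_scale, m[["active"]],
              x$inactive_shape, x$inactive_scale, m[["inactive"]]))
  n <- attr(x, "n")
  if (!is.null(n))
    cat(sprintf("  fitted from n = %d active, %d inactive observations\n",
                n[["active"]], n[["inactive"]]))
  invisible(x)
}

#' Expected population mean perch height for a state distribution
#'
#' The analytic mean perch height when a fraction `pi["active"]` of the
#' population is active: the mixture of the two state means.
#'
#' @param pi State distribution (active, inactive).
#' @param em An `"emission_model"`.
#' @return Expected mean perch height, cm.
#' @examples
#' expected_mean_perch(steady_state(baseline_matrix()), emission_model())
#' @export
expected_mean_perch <- function(pi, em) {
  pi <- as_state_distribution(pi)
  m <- emission_means(em)
  unname(pi[["active"]] * m[["active"]] + pi[["inactive"]] * m[["inactive"]])
}
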