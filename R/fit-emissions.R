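# Maximum-likelihood gamma fitting of the state-dependent perch-height
# emission distributions from classified control observations.

# Gamma MLE for (shape, scale): method-of-moments / Minka-style closed-form
# start, then Newton iterations on the profile log-likelihood score
# log(k) - digamma(k) = log(mean(x)) - mean(log(x)); scale = mean(x)/k.
fit_gamma_ml <- function(x, max_iter = 100, tol = 1e-10) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("insufficient data: need at least 3 positive observations")
  if (any(x <= 0)) stop("gamma fitting requires strictly positive values")
  m <- mean(x)
  if (stats::var(x) == 0 || m == 0)
    stop("degenerate data: zero variance, gamma parameters are unidentifiable")
  s <- log(m) - mean(log(x))
  # closed-form starting value; falls back to method of moments if s ~ 0
  k <- if (s > 1e-12) (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
       else m^2 / stats::var(x)
  for (i in seq_len(max_iter)) {
    f  <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2  # guard: stay in the positive domain
    if (abs(k_new - k) < tol * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  c(shape = k, scale = m / k, n = n)
}

#' Fit the perch-height emission model from classified observations
#'
#' Estimates the state-dependent gamma perch-height distributions from an
#' event-level bout table, the way control-plot field observations are
#' used to parameterize the foraging model: bouts are classified active or
#' inactive from their movement rates, and each state's gamma parameters
#' are fitted by maximum likelihood (method-of-moments initialization,
#' Newton refinement of the shape) to the perch-event heights of bouts in
#' that state. Ground observations (0 cm) are outside the gamma support
#' and are excluded; heights in (0, `floor_cm`\] are floored to `floor_cm`.
#'
#' @param bouts Event-level bout table ([validate_bout_table()] schema).
#' @param control_only Restrict to control-arm bouts (default `TRUE`).
#' @param floor_cm Heights in (0, `floor_cm`\] are set to `floor_cm`
#'   before fitting (default 0.5); heights of exactly 0 are dropped.
#' @param threshold Moves-per-minute activity threshold (default 0.8).
#' @param min_n Minimum positive observations required per state
#'   (default 3).
#' @return An `"emission_model"` with attribute `n`, the per-state sample
#'   sizes used.
#' @seealso [emission_model()], [classify_activity()]
#' @export
fit_emission_model <- function(bouts, control_only = TRUE, floor_cm = 0.5,
                               threshold = 0.8, min_n = 3) {
  validate_bout_table(bouts)
  if (control_only) bouts <- bouts[bouts$treatment == "control", , drop = FALSE]
  if (nrow(bouts) == 0) stop("no observations left after filtering to control bouts")
  activity <- classify_activity(bouts$n_moves, bouts$duration_min, threshold)
  fits <- lapply(c(active = "active", inactive = "inactive"), function(st) {
    h <- bouts$height_cm[activity == st]
    h <- h[h > 0]
    h[h <= floor_cm] <- floor_cm
    if (length(h) < min_n)
      stop("insufficient data: fewer than ", min_n,
           " positive perch heights in the ", st, " state (got ", length(h), ")")
    fit_gamma_ml(h)
  })
  em <- suppressWarnings(emission_model(
    active_shape = fits$active[["shape"]], active_scale = fits$active[["scale"]],
    inactive_shape = fits$inactive[["shape"]], inactive_scale = fits$inactive[["scale"]]))
  m <- emission_means(em)
  if (m[["active"]] >= m[["inactive"]])
    warning("fitted active mean perch height is not below the inactive mean; ",
            "check the activity classification or the data", call. = FALSE)
  attr(em, "n") <- c(active = unname(fits$active[["n"]]),
                     inactive = unname(fits$inactive[["n"]]))
  em
}
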