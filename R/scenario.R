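#' Resource-pulse perturbation specification
#'
#' Describes how a single resource-pulse event perturbs the population at
#' one time step. `synchrony_fraction` is the probability that each
#' individual independently initiates active foraging at the pulse;
#' `post_matrix` is the transition matrix in force after the pulse (e.g. a
#' reduced-foraging "satiation" matrix). Either may be omitted: a missing
#' fraction leaves states untouched at the pulse, a missing matrix keeps
#' the baseline dynamics.
#'
#' @param time_step 1-based index of the step at which the pulse acts.
#' @param synchrony_fraction Probability in \[0, 1\], or `NULL`.
#' @param post_matrix A `"transition_matrix"`, or `NULL`.
#' @return An object of class `"perturbation_spec"`.
#' @export
perturbation_spec <- function(time_step, synchrony_fraction = NULL,
                              post_matrix = NULL) {
  if (length(time_step) != 1 || !is.finite(time_step) ||
      time_step < 1 || time_step != round(time_step))
    stop("`time_step` must be a single positive integer (1-based step index)")
  if (!is.null(synchrony_fraction)) {
    if (length(synchrony_fraction) != 1 || !is.finite(synchrony_fraction) ||
        synchrony_fraction < 0 || synchrony_fraction > 1)
      stop("`synchrony_fraction` must lie in [0, 1]")
  }
  if (!is.null(post_matrix)) post_matrix <- as_transition_matrix(post_matrix)
  structure(list(time_step = as.integer(time_step),
                 synchrony_fraction = synchrony_fraction,
                 post_matrix = post_matrix),
            class = "perturbation_spec")
}

#' Full scenario specification for the two-state foraging model
#'
#' Bundles everything one model run needs: baseline transition matrix,
#' perch-height emission model, an optional pulse perturbation, population
#' size, horizon and RNG seed.
#'
#' @param baseline A `"transition_matrix"` in force before (and, absent a
#'   `post_matrix`, after) the perturbation.
#' @param emissions An `"emission_model"`.
#' @param perturbation A `"perturbation_spec"` or `NULL` (no pulse).
#' @param n_individuals Population size (>= 1).
#' @param n_steps Simulation horizon in steps (>= 1).
#' @param seed Integer RNG seed used by [simulate_scenario()].
#' @return An object of class `"scenario_spec"`.
#' @seealso [pulse_scenario()] for the four standard pulse scenarios.
#' @export
scenario_spec <- function(baseline = baseline_matrix(),
                          emissions = emission_model(),
                          perturbation = NULL,
                          n_individuals = 500, n_steps = 100, seed = 1L) {
  baseline <- as_transition_matrix(baseline)
  stopifnot(inherits(emissions, "emission_model"))
  if (!is.null(perturbation)) {
    if (!inherits(perturbation, "perturbation_spec"))
      stop("`perturbation` must be a perturbation_spec or NULL")
    if (perturbation$time_step >= n_steps)
      stop("`perturbation$time_step` must be < `n_steps` so that at least ",
           "one post-perturbation step exists")
  }
  if (n_individuals < 1 || n_individuals != round(n_individuals))
    stop("`n_individuals` must be a positive integer")
  if (n_steps < 1 || n_steps != round(n_steps))
    stop("`n_steps` must be a positive integer")
  structure(list(baseline = baseline, emissions = emissions,
                 perturbation = perturbation,
                 n_individuals = as.integer(n_individuals),
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "scenario_spec")
}

#' The four standard resource-pulse scenarios
#'
#' Convenience constructor for the four model variants used to explore
#' population perch-height responses to a pulsed subsidy:
#' \describe{
#'   \item{control}{baseline dynamics, no perturbation;}
#'   \item{synchrony}{a one-step pulse at which 90% of individuals
#'     initiate active foraging, baseline dynamics before and after;}
#'   \item{satiation}{no synchronized switch, but the transition matrix
#'     changes at the pulse to one whose stationary active fraction is 5%
#'     (fed animals forage less) for the rest of the run;}
#'   \item{combined}{both the synchronized switch and the satiation
#'     matrix.}
#' }
#'
#' @param name One of `"control"`, `"synchrony"`, `"satiation"`,
#'   `"combined"`.
#' @param emissions An `"emission_model"`.
#' @param n_individuals,n_steps,seed Passed to [scenario_spec()].
#' @param perturbation_step Step at which the pulse acts (default 50).
#' @param synchrony_fraction Fraction initiating active foraging at the
#'   pulse (default 0.9).
#' @param satiation_active Post-pulse stationary active fraction for the
#'   satiation matrix (default 0.05).
#' @param active_persistence Active-state persistence held fixed when
#'   constructing the satiation matrix (default 0.55, as in the baseline).
#' @return A `"scenario_spec"`.
#' @examples
#' sc <- pulse_scenario("synchrony", seed = 42)
#' traj <- analytic_trajectory(sc)
#' which.min(traj)  # the pulse step
#' @export
pulse_scenario <- function(name = c("control", "synchrony", "satiation", "combined"),
                           emissions = emission_model(),
                           n_individuals = 500, n_steps = 100, seed = 1L,
                           perturbation_step = 50, synchrony_fraction = 0.9,
                           satiation_active = 0.05, active_persistence = 0.55) {
  name <- match.arg(name)
  sat <- function() build_satiation_matrix(satiation_active, active_persistence)
  pert <- switch(name,
    control   = NULL,
    synchrony = perturbation_spec(perturbation_step, synchrony_fraction, NULL),
    satiation = perturbation_spec(perturbation_step, NULL, sat()),
    combined  = perturbation_spec(perturbation_step, synchrony_fraction, sat()))
  sc <- scenario_spec(baseline = baseline_matrix(), emissions = emissions,
                      perturbation = pert, n_individuals = n_individuals,
                      n_steps = n_steps, seed = seed)
  sc$name <- name
  sc
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario%s: %d individuals, %d steps, seed %d\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$n_individuals, x$n_steps, x$seed))
  if (is.null(x$perturbation)) {
    cat("  no perturbation\n")
  } else {
    p <- x$perturbation
    cat(sprintf("  pulse at step %d: synchrony fraction %s, post matrix %s\n",
                p$time_step,
                if (is.null(p$synchrony_fraction)) "none" else
                  format(p$synchrony_fraction),
                if (is.null(p$post_matrix)) "baseline" else "replaced"))
  }
  invisible(x)
}
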