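# Analytic and stochastic trajectories of the two-state pulse model, and
# the transient-duration statistic.

# Active-fraction trajectory implied by a scenario, computed exactly via
# the Chapman-Kolmogorov recursion. Step 1 holds the initial distribution
# (the baseline stationary state); the perturbation acts at step
# `time_step`: states are reset toward ACTIVE with the synchrony fraction,
# and the post matrix (if any) governs all transitions after that step.
analytic_active_fraction <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  P <- scenario$baseline
  pi_ss <- steady_state(P)
  n <- scenario$n_steps
  pert <- scenario$perturbation
  out <- numeric(n)
  pi <- pi_ss
  for (t in seq_len(n)) {
    if (t > 1) {
      Pt <- if (!is.null(pert) && !is.null(pert$post_matrix) && t > pert$time_step)
        pert$post_matrix else P
      pi <- drop(Pt %*% pi)
    }
    if (!is.null(pert) && t == pert$time_step && !is.null(pert$synchrony_fraction)) {
      f <- pert$synchrony_fraction
      pi <- c(f + (1 - f) * pi[1], (1 - f) * pi[2])
    }
    out[t] <- pi[1]
  }
  out
}

#' Analytic mean perch-height trajectory of a scenario
#'
#' Computes the expected population mean perch height at every time step
#' by propagating the activity-state distribution exactly (the
#' Chapman-Kolmogorov equation) and mixing the state-specific gamma means.
#' A control (unperturbed) scenario yields a constant trajectory at the
#' stationary mean.
#'
#' @param scenario A `"scenario_spec"`.
#' @return Numeric vector of expected mean perch heights (cm), length
#'   `scenario$n_steps`.
#' @examples
#' traj <- analytic_trajectory(pulse_scenario("combined"))
#' @export
analytic_trajectory <- function(scenario) {
  a <- analytic_active_fraction(scenario)
  m <- emission_means(scenario$emissions)
  a * m[["active"]] + (1 - a) * m[["inactive"]]
}

#' Stochastic population simulation of a scenario
#'
#' Simulates `n_individuals` independent two-state chains for `n_steps`
#' steps. Initial states are i.i.d. draws from the stationary distribution
#' of the baseline matrix; at the perturbation step each individual
#' independently initiates active foraging with probability
#' `synchrony_fraction` (all others transition under the matrix currently
#' in force), and the post matrix (if any) governs every later step. Each
#' individual's perch height is redrawn every step from its current
#' state's gamma distribution. Results are reproducible: the seed stored
#' in the scenario fully determines the output (R's default Mersenne
#' Twister generator; per step, transition draws are consumed before
#' height draws, individuals in index order).
#'
#' @param scenario A `"scenario_spec"`.
#' @param init Optional initial state distribution overriding the default
#'   stationary start (required when the baseline matrix has no unique
#'   stationary distribution, e.g. absorbing chains).
#' @return An object of class `"simulation_result"`: a list with
#'   `mean_perch_by_step` (cm), `active_fraction_by_step`, `states_final`
#'   (character), `seed`, and `scenario`.
#' @examples
#' res <- simulate_scenario(pulse_scenario("control", n_individuals = 100,
#'                                         n_steps = 20, seed = 7))
#' mean(res$active_fraction_by_step)
#' @export
simulate_scenario <- function(scenario, init = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  n <- scenario$n_individuals
  n_steps <- scenario$n_steps
  pert <- scenario$perturbation
  em <- scenario$emissions
  P <- scenario$baseline
  pi_ss <- if (is.null(init)) steady_state(P) else as_state_distribution(init)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(scenario$seed)

  # states: TRUE = active
  active <- stats::runif(n) < pi_ss[["active"]]
  mean_perch <- active_frac <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    if (t > 1) {
      Pt <- if (!is.null(pert) && !is.null(pert$post_matrix) && t > pert$time_step)
        pert$post_matrix else P
      p_active <- ifelse(active, Pt["active", "active"], Pt["active", "inactive"])
      active <- stats::runif(n) < p_active
    }
    if (!is.null(pert) && t == pert$time_step && !is.null(pert$synchrony_fraction)) {
      active <- active | (stats::runif(n) < pert$synchrony_fraction)
    }
    h <- numeric(n)
    n_a <- sum(active)
    if (n_a > 0)
      h[active] <- stats::rgamma(n_a, shape = em$active_shape, scale = em$active_scale)
    if (n_a < n)
      h[!active] <- stats::rgamma(n - n_a, shape = em$inactive_shape,
                                  scale = em$inactive_scale)
    mean_perch[t] <- mean(h)
    active_frac[t] <- n_a / n
  }
  structure(list(mean_perch_by_step = mean_perch,
                 active_fraction_by_step = active_frac,
                 states_final = ifelse(active, "active", "inactive"),
                 seed = scenario$seed,
                 rng_kind = RNGkind()[1],
                 scenario = scenario),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation: %d individuals x %d steps (seed %d, %s RNG)\n",
              x$scenario$n_individuals, x$scenario$n_steps, x$seed, x$rng_kind))
  cat(sprintf("  mean perch %.1f cm, mean active fraction %.3f\n",
              mean(x$mean_perch_by_step), mean(x$active_fraction_by_step)))
  invisible(x)
}

#' Duration of the post-pulse transient in a trajectory
#'
#' Counts how many steps a trajectory needs to relax back to its
#' post-perturbation asymptote: the smallest `k >= 0` such that the
#' deviation from the asymptote at step `perturbation_step + k` has shrunk
#' to at most `epsilon` times the deviation at the perturbation step
#' itself. Returns 0 when the perturbation produced no deviation (e.g. a
#' control trajectory).
#'
#' @param trajectory Numeric vector of mean perch heights by step.
#' @param perturbation_step 1-based index of the pulse step.
#' @param epsilon Fraction of the initial deviation regarded as "relaxed"
#'   (default 0.05, i.e. within 5%).
#' @param asymptote Post-perturbation asymptotic value. Defaults to the
#'   final trajectory value, appropriate for analytic trajectories run
#'   well past the transient and a pragmatic choice for stochastic ones;
#'   pass the exact analytic asymptote when known.
#' @return Integer number of steps.
#' @examples
#' traj <- analytic_trajectory(pulse_scenario("synchrony"))
#' transient_duration(traj, 50)  # 5 steps under the baseline matrix
#' @export
transient_duration <- function(trajectory, perturbation_step, epsilon = 0.05,
                               asymptote = NULL) {
  stopifnot(is.numeric(trajectory), length(trajectory) >= 2)
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon <= 0 || epsilon >= 1)
    stop("`epsilon` must lie strictly between 0 and 1")
  n <- length(trajectory)
  if (perturbation_step < 1 || perturbation_step >= n)
    stop("`perturbation_step` must leave at least one step after the pulse")
  if (is.null(asymptote)) asymptote <- trajectory[n]
  d0 <- abs(trajectory[perturbation_step] - asymptote)
  scale <- max(abs(asymptote), abs(trajectory[perturbation_step]), 1)
  if (d0 <= 1e-12 * scale) return(0L)
  dev <- abs(trajectory[perturbation_step:n] - asymptote)
  k <- which(dev <= epsilon * d0)
  if (length(k) == 0)
    stop("trajectory never relaxes to within `epsilon` of its initial deviation")
  as.integer(k[1] - 1L)
}
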