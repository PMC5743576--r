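#' @keywords internal
"_PACKAGE"

# Canonical state order used everywhere: row/column 1 = active, 2 = inactive.
fp_states <- function() c("active", "inactive")

#' Construct a two-state activity transition matrix
#'
#' Builds the column-stochastic 2x2 transition matrix of the two-state
#' (active / inactive) foraging model. Columns index the source state and
#' rows the destination state, so `P["active", "inactive"]` is the
#' probability that an inactive individual becomes active in one time step.
#' Time steps are unitless.
#'
#' @param active_persistence Probability an active individual remains active.
#' @param activation Probability an inactive individual becomes active.
#' @return A 2x2 matrix of class `"transition_matrix"` with `from`/`to`
#'   dimnames in the order active, inactive.
#' @seealso [baseline_matrix()], [build_satiation_matrix()], [steady_state()]
#' @examples
#' P <- transition_matrix(active_persistence = 0.55, activation = 0.05)
#' steady_state(P)
#' @export
transition_matrix <- function(active_persistence, activation) {
  stopifnot(is.numeric(active_persistence), length(active_persistence) == 1,
            is.numeric(activation), length(activation) == 1)
  P <- matrix(c(active_persistence, 1 - active_persistence,
                activation, 1 - activation),
              nrow = 2, ncol = 2,
              dimnames = list(to = fp_states(), from = fp_states()))
  as_transition_matrix(P)
}

#' Validate and classify a raw matrix as a transition matrix
#'
#' @param P A numeric 2x2 matrix; columns must sum to 1 and every entry lie
#'   in \[0, 1\].
#' @param tol Tolerance on the column-sum check.
#' @return `P` with class `"transition_matrix"` and canonical dimnames.
#' @export
as_transition_matrix <- function(P, tol = 1e-12) {
  if (!is.matrix(P) || !identical(dim(P), c(2L, 2L)) || !is.numeric(P))
    stop("`P` must be a numeric 2x2 matrix")
  if (any(P < -tol) || any(P > 1 + tol))
    stop("transition probabilities must lie in [0, 1]")
  cs <- colSums(P)
  if (any(abs(cs - 1) > tol))
    stop("each column of a transition matrix must sum to 1 (source states in columns); ",
         "got column sums ", paste(format(cs, digits = 15), collapse = ", "))
  P <- pmin(pmax(P, 0), 1)
  dim(P) <- c(2L, 2L)
  dimnames(P) <- list(to = fp_states(), from = fp_states())
  class(P) <- c("transition_matrix", "matrix", "array")
  P
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Two-state transition matrix (columns = source state):\n")
  print(unclass(x), ...)
  if (!both_absorbing(x)) {
    pi <- steady_state(x)
    cat(sprintf("Stationary distribution: active %.4f, inactive %.4f\n",
                pi[["active"]], pi[["inactive"]]))
  }
  invisible(x)
}

both_absorbing <- function(P) P[1, 1] == 1 && P[2, 2] == 1

#' Baseline activity transition matrix
#'
#' The reference parameterization of the two-state foraging model: active
#' individuals remain active with probability 0.55 (become inactive with
#' 0.45) and inactive individuals remain inactive with probability 0.95
#' (become active with 0.05). Its stationary distribution has individuals
#' actively foraging 10% of the time, consistent with field observations of
#' sit-and-wait Anolis lizards.
#'
#' @return A `"transition_matrix"`.
#' @examples
#' steady_state(baseline_matrix())  # (0.10, 0.90)
#' @export
baseline_matrix <- function() {
  transition_matrix(active_persistence = 0.55, activation = 0.05)
}

#' Stationary distribution of a two-state transition matrix
#'
#' Solves P pi = pi in closed form: the stationary active fraction equals
#' `activation / (activation + deactivation)` where `activation = P[A, I]`
#' and `deactivation = P[I, A]`.
#'
#' @param P A `"transition_matrix"`.
#' @return Named numeric vector `c(active = , inactive = )` summing to 1.
#' @examples
#' steady_state(baseline_matrix())
#' @export
steady_state <- function(P) {
  P <- as_transition_matrix(P)
  activation   <- P["active", "inactive"]
  deactivation <- P["inactive", "active"]
  if (activation == 0 && deactivation == 0)
    stop("no unique stationary distribution: both states are absorbing ",
         "(both diagonal entries equal 1)")
  a <- activation / (activation + deactivation)
  c(active = a, inactive = 1 - a)
}

#' Construct a transition matrix with a target stationary activity level
#'
#' Holds the active-state persistence fixed and solves the activation
#' probability so that the stationary active fraction equals
#' `target_active`:
#' `activation = (1 - active_persistence) * target_active / (1 - target_active)`.
#' With the default persistence this reproduces the post-subsidy
#' reduced-foraging ("satiation") matrix when `target_active = 0.05`, and
#' inverts to the baseline matrix when `target_active = 0.10`.
#'
#' @param target_active Desired stationary active fraction, in (0, 1).
#' @param active_persistence Probability an active individual remains
#'   active, in \[0, 1).
#' @return A `"transition_matrix"` whose [steady_state()] active component
#'   equals `target_active`.
#' @examples
#' sat <- build_satiation_matrix(0.05)
#' steady_state(sat)[["active"]]  # 0.05
#' @export
build_satiation_matrix <- function(target_active, active_persistence = 0.55) {
  stopifnot(length(target_active) == 1, length(active_persistence) == 1)
  if (!is.finite(target_active) || target_active <= 0 || target_active >= 1)
    stop("`target_active` must lie strictly between 0 and 1")
  if (!is.finite(active_persistence) || active_persistence < 0 || active_persistence >= 1)
    stop("`active_persistence` must lie in [0, 1)")
  activation <- (1 - active_persistence) * target_active / (1 - target_active)
  if (activation > 1)
    stop(sprintf(
      "infeasible parameters: required activation probability %.4f exceeds 1; ",
      activation), "lower `target_active` or raise `active_persistence`")
  transition_matrix(active_persistence, activation)
}

#' Propagate a state distribution forward in time
#'
#' Applies the Chapman-Kolmogorov recursion `pi_{t+1} = P pi_t` for `t`
#' steps under a fixed transition matrix.
#'
#' @param P A `"transition_matrix"`.
#' @param pi0 Initial state distribution: numeric length-2 vector
#'   (active, inactive) summing to 1.
#' @param t Number of steps (non-negative integer); `t = 0` returns `pi0`.
#' @return Named state distribution after `t` steps.
#' @examples
#' propagate(baseline_matrix(), c(1, 0), 1)  # (0.55, 0.45)
#' @export
propagate <- function(P, pi0, t) {
  P <- as_transition_matrix(P)
  pi0 <- as_state_distribution(pi0)
  if (length(t) != 1 || !is.finite(t) || t < 0 || t != round(t))
    stop("`t` must be a single non-negative integer")
  pi <- pi0
  for (i in seq_len(t)) pi <- drop(P %*% pi)
  stats::setNames(as.numeric(pi), fp_states())
}

as_state_distribution <- function(pi, tol = 1e-12) {
  if (!is.numeric(pi) || length(pi) != 2)
    stop("a state distribution must be a numeric length-2 vector (active, inactive)")
  if (any(pi < -tol)) stop("state probabilities must be non-negative")
  if (abs(sum(pi) - 1) > max(tol, 1e-9))
    stop("state probabilities must sum to 1; got ", format(sum(pi), digits = 15))
  stats::setNames(as.numeric(pi), fp_states())
}
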