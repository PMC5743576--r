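# Shared test helpers: independent oracles and hand-built fixtures.

# Power-iteration oracle for the stationary distribution: apply P^n to an
# arbitrary start vector. Independent of the closed form in steady_state().
power_iteration_pi <- function(P, n = 200, start = c(0.3, 0.7)) {
  v <- start
  for (i in seq_len(n)) v <- drop(unclass(P) %*% v)
  unname(v / sum(v))
}

# Random valid (column-stochastic, non-degenerate) two-state matrix.
random_transition_matrix <- function() {
  transition_matrix(active_persistence = stats::runif(1, 0.01, 0.99),
                    activation = stats::runif(1, 0.01, 0.99))
}

# Random emission model with active mean strictly below inactive mean.
random_emission_model <- function() {
  am <- stats::runif(1, 5, 60)
  im <- am + stats::runif(1, 10, 80)
  suppressWarnings(emission_model(
    active_shape = stats::runif(1, 0.5, 5), active_scale = 1,
    inactive_shape = stats::runif(1, 0.5, 5), inactive_scale = 1)) -> em
  em$active_scale <- am / em$active_shape
  em$inactive_scale <- im / em$inactive_shape
  em
}

# Hand-built event-level bout table. `events` is a list of data.frames
# with height_cm and dwell_min; bout-level fields are recycled.
make_bout_table <- function(events, plot_id = "B1P1", block_id = "B1",
                            treatment = "control", time_since_subsidy_min = -60,
                            duration_min = NULL, n_moves = 0, n_attacks = 0,
                            stage = "large", distance = NA_real_) {
  n_b <- length(events)
  rec <- function(x) rep_len(x, n_b)
  plot_id <- rec(plot_id); block_id <- rec(block_id)
  treatment <- rec(treatment); tss <- rec(time_since_subsidy_min)
  n_moves <- rec(n_moves); n_attacks <- rec(n_attacks); stage <- rec(stage)
  distance <- rec(distance)
  if (is.null(duration_min))
    duration_min <- vapply(events, function(e) sum(e$dwell_min), numeric(1))
  duration_min <- rec(duration_min)
  do.call(rbind, lapply(seq_len(n_b), function(i) {
    e <- events[[i]]
    data.frame(bout_id = sprintf("b%03d", i), plot_id = plot_id[i],
               block_id = block_id[i], treatment = treatment[i],
               time_since_subsidy_min = tss[i], duration_min = duration_min[i],
               event_index = seq_len(nrow(e)), height_cm = e$height_cm,
               dwell_min = e$dwell_min,
               distance_to_seaweed_cm = distance[i],
               n_moves = n_moves[i], n_attacks = n_attacks[i],
               stage = stage[i], marked_id = NA_character_,
               stringsAsFactors = FALSE)
  }))
}

ev <- function(height, dwell) data.frame(height_cm = height, dwell_min = dwell)

# Idealized classified control observations for emission-fitting checks:
# single-event bouts whose heights come from the true state's gamma and
# whose move counts place them unambiguously on the right side of the
# 0.8 moves/min threshold.
make_classified_bouts <- function(n_per_state, em, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h_a <- stats::rgamma(n_per_state, shape = em$active_shape, scale = em$active_scale)
  h_i <- stats::rgamma(n_per_state, shape = em$inactive_shape, scale = em$inactive_scale)
  events <- c(lapply(h_a, function(h) ev(h, 10)), lapply(h_i, function(h) ev(h, 10)))
  make_bout_table(events, duration_min = 10,
                  n_moves = rep(c(12L, 2L), each = n_per_state))
}
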