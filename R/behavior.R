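#' Behaviour repertoire
#'
#' Integer codes shared with the C++ engine. Affiliation comprises grooming,
#' affiliative signalling and approaching; submission comprises leaving,
#' submissive signalling and avoiding; aggression comprises attacking and
#' aggressive signalling. `flee` is the loser's response after aggression;
#' `rest` and `random_move` are the solitary fallbacks.
#'
#' @return Named integer vector mapping behaviour names to codes.
#' @export
behavior_codes <- function() {
  c(groom = 1L, affiliative_signal = 2L, approach = 3L, leave = 4L,
    submissive_signal = 5L, avoid = 6L, attack = 7L, aggressive_signal = 8L,
    flee = 9L, rest = 10L, random_move = 11L)
}

#' @rdname behavior_codes
#' @export
behavior_classes <- function() {
  list(affiliation = c("groom", "affiliative_signal", "approach"),
       submission = c("leave", "submissive_signal", "avoid"),
       aggression = c("attack", "aggressive_signal"))
}

#' Behaviour-selection parameters
#'
#' Baseline tendencies per behaviour and the coefficients with which the
#' emotional state and the FEAR/LIKE attitudes modulate them. The model
#' states directions, not magnitudes, so every coefficient here is a free,
#' documented parameter.
#'
#' The attitude modulations are: affiliative weight towards `j` is
#' multiplied by `m_j / mean(m)` with `m_j = (1 - lps) + lps * LIKE_ij`,
#' the mean running over the current candidate set -- selectivity
#' redistributes affiliative tendency among partners (relative weights
#' `m_j : m_k`) without damping how much the agent affiliates overall;
#' submissive weight by
#' `exp(fear_submission_gain * FEAR_ij)`; aggressive weight by
#' `exp(-fear_aggression_gain * FEAR_ij)`, additionally scaled down by
#' anxiety when `FEAR_ij > 0` (risk-sensitive aggression). Arousal scales
#' every active behaviour by `1 + arousal_gain * arousal`; anxiety scales
#' affiliation and submission by `1 + anxiety_gain * anxiety`; satisfaction
#' scales affiliation by `max(0, 1 - satiation_gain * satisfaction)`.
#'
#' @param b_groom,b_affil_signal,b_approach,b_leave,b_submis_signal,b_avoid,b_attack,b_aggr_signal,b_rest,b_random_move
#'   Baseline weights (nonnegative; rest must stay positive as fallback).
#' @param b_flee_resp,b_counter_resp Baseline weights of the two possible
#'   responses to a received attack.
#' @param fear_submission_gain,fear_aggression_gain Exponential FEAR gains.
#' @param arousal_gain,anxiety_gain,satiation_gain,risk_anxiety_gain
#'   Emotional-state modulation coefficients.
#' @param win_beta Steepness of the sigmoidal win-chance function; 8 gives
#'   near-even odds for adjacent ranks and >99% for the extreme rank gap.
#' @param move_speed Movement speed, m/min.
#' @param move_substep Movement activation interval, minutes (3 seconds).
#' @param move_stop_dist Distance at which flee/avoid/leave stop, meters.
#' @param bout_min,bout_max Uniform bounds of grooming/resting bout
#'   durations, minutes.
#' @param rwalk_minutes,rwalk_turn Random-walk bout length (minutes) and
#'   maximal per-substep turn (degrees).
#' @param winner_delay,bystander_delay,signal_delay Rescheduling delays
#'   (minutes) after a fight, for bystanders, and after receiving an
#'   aggressive signal.
#' @param observe_fight_dist Radius within which an escalated fight is
#'   perceived, meters.
#' @param act_mean,act_sd,act_floor Truncated-normal inter-activation
#'   interval, minutes.
#' @param max_move_bout Safety cap on directed movement bouts, minutes.
#' @return A named list of class `emo_behavior`.
#' @export
behavior_params <- function(b_groom = 1.2, b_affil_signal = 0.1,
                            b_approach = 0.15, b_leave = 0.1,
                            b_submis_signal = 0.05, b_avoid = 0.05,
                            b_attack = 0.1, b_aggr_signal = 0.05,
                            b_rest = 1.5, b_random_move = 0.3,
                            b_flee_resp = 1, b_counter_resp = 0.5,
                            fear_submission_gain = 4,
                            fear_aggression_gain = 4, arousal_gain = 1,
                            anxiety_gain = 1, satiation_gain = 1,
                            risk_anxiety_gain = 1, win_beta = 8,
                            move_speed = 10, move_substep = 0.05,
                            move_stop_dist = 5, bout_min = 2, bout_max = 10,
                            rwalk_minutes = 1, rwalk_turn = 30,
                            winner_delay = 0.25, bystander_delay = 0.1,
                            signal_delay = 0.05, observe_fight_dist = 20,
                            act_mean = 1, act_sd = 0.05, act_floor = 0.01,
                            max_move_bout = 5) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) >= 0), b_rest > 0, win_beta > 0, move_speed > 0,
            move_substep > 0, bout_min > 0, bout_max >= bout_min,
            act_floor > 0)
  class(p) <- "emo_behavior"
  p
}

#' Distance-gated eligible actions
#'
#' Which (behaviour, target) pairs are available given candidate distances:
#' contact behaviours (groom, leave, attack) within the interaction
#' distance; signals and avoidance within the personal distance; approach
#' for any perceivable candidate. Rest and random movement are always
#' eligible.
#'
#' @param distances Named or unnamed numeric vector of candidate distances
#'   (meters); names are taken as target ids.
#' @param world A [world_config()].
#' @return A data.frame with columns `behavior` and `target` (`NA` for the
#'   solitary behaviours).
#' @export
eligible_actions <- function(distances, world = world_config()) {
  ids <- if (is.null(names(distances))) seq_along(distances)
         else as.integer(names(distances))
  rows <- list()
  for (k in seq_along(distances)) {
    d <- distances[[k]]
    acts <- character(0)
    if (d <= world$interact_dist) acts <- c(acts, "groom", "leave", "attack")
    if (d <= world$pers_dist)
      acts <- c(acts, "affiliative_signal", "submissive_signal", "avoid",
                "aggressive_signal")
    if (d <= world$max_dist) acts <- c(acts, "approach")
    if (length(acts))
      rows[[length(rows) + 1L]] <- data.frame(behavior = acts,
                                              target = ids[k])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    behavior = c("rest", "random_move"), target = NA_integer_)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Action-selection probabilities
#'
#' Builds the weighted (behaviour, target) distribution an activated agent
#' samples from, implementing the selection contract: at `lps = 0`
#' affiliative weights ignore LIKE; affiliative weight towards `j` is
#' nondecreasing in `LIKE_ij` and concentrates on the most-LIKEd candidate
#' as `lps` grows; aggression decreases and submission increases in
#' `FEAR_ij`; arousal scales all active behaviours up, anxiety scales
#' affiliation/submission up and makes aggression risk-sensitive, and
#' satisfaction scales affiliation down. This calls the same C++ weight
#' builder the engine uses.
#'
#' @param distances Candidate distances in meters (candidates must already
#'   be within the perceivable distance; see [candidate_partners()]).
#' @param fear_row,like_row Ego's FEAR and LIKE attitudes towards the
#'   candidates, same order as `distances`.
#' @param state An [emotional_state()].
#' @param lps LIKE-partner selectivity in `[0, 1)`.
#' @param params A [behavior_params()].
#' @param world A [world_config()].
#' @param groom_blocked Logical vector: candidates currently unavailable for
#'   grooming (already being groomed, or moving).
#' @return A data.frame with columns `behavior`, `target` (index into the
#'   candidate vectors, `NA` for solitary), `weight` and normalized `prob`.
#' @export
action_probabilities <- function(distances, fear_row, like_row, state,
                                 lps = 0, params = behavior_params(),
                                 world = world_config(),
                                 groom_blocked = rep(FALSE,
                                                     length(distances))) {
  stopifnot(length(fear_row) == length(distances),
            length(like_row) == length(distances), lps >= 0, lps < 1)
  par <- flatten_params(run_config(lps = lps, world = world,
                                   behavior = params, validate = FALSE))
  df <- cpp_action_weights(as.numeric(distances), as.numeric(fear_row),
                           as.numeric(like_row), as.integer(groom_blocked),
                           state$arousal, state$anxiety, state$satisfaction,
                           par)
  codes <- behavior_codes()
  df$behavior <- names(codes)[df$behavior]
  df$prob <- if (sum(df$weight) > 0) df$weight / sum(df$weight) else
    rep(0, nrow(df))
  df
}

#' Grouping rule
#'
#' Grouping pre-empts ordinary action selection: it is needed when fewer
#' than `min_others` group members are within the neighbourhood radius
#' (full-circle view) or when any group member is farther than the
#' far-distance. The grouping response is approaching one uniformly random
#' group member.
#'
#' @param ego_id Agent id.
#' @param x,y Coordinates of all agents.
#' @param world A [world_config()].
#' @export
grouping_needed <- function(ego_id, x, y, world = world_config()) {
  cpp_grouping_needed(as.integer(ego_id), as.numeric(x), as.numeric(y),
                      world$near_dist, as.integer(world$min_others),
                      world$far_dist, world$width, world$height)
}

#' Sigmoidal win chance in an escalated fight
#'
#' `P(i wins) = 1 / (1 + exp(-beta * (dom_i - dom_j)))`; complementary
#' within the dyad and strictly increasing in the dominance difference.
#'
#' @inheritParams fear
#' @param beta Steepness (`> 0`).
#' @export
win_chance <- function(dom_i, dom_j, beta = 8) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (dom_i - dom_j)))
}
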