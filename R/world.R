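#' World geometry configuration
#'
#' Parameters of the continuous two-dimensional torus the group lives on and
#' of the agents' perception. Distances are in meters (one grid unit = 1 m),
#' angles in degrees. The bearing convention is 0 degrees = east,
#' counterclockwise positive; headings are normalized to `[0, 360)`.
#'
#' @param width,height Torus extent in meters.
#' @param interact_dist Maximum distance for contact behaviours
#'   (groom / leave / attack), meters.
#' @param pers_dist Personal distance: signals can be received and agents can
#'   be avoided within this radius; a dominant individual inside it elevates
#'   ego's arousal limit.
#' @param near_dist Neighbourhood radius used by the grouping rule
#'   (`GROUP_DIST`), meters.
#' @param max_dist Maximum perceivable distance, meters.
#' @param far_dist Distance beyond which a group member counts as lost,
#'   triggering grouping, meters.
#' @param min_others Minimum number of others required within `near_dist`
#'   before grouping is triggered.
#' @param view_angle Default view angle, degrees.
#' @param max_angle View angle while scanning, degrees (full circle).
#' @param max_partners Maximum number of candidate interaction partners
#'   considered per action-selection round.
#' @return A named list of class `emo_world`.
#' @export
world_config <- function(width = 300, height = 300, interact_dist = 1,
                         pers_dist = 5, near_dist = 20, max_dist = 50,
                         far_dist = 100, min_others = 3, view_angle = 120,
                         max_angle = 360, max_partners = 10) {
  w <- list(width = width, height = height, interact_dist = interact_dist,
            pers_dist = pers_dist, near_dist = near_dist, max_dist = max_dist,
            far_dist = far_dist, min_others = min_others,
            view_angle = view_angle, max_angle = max_angle,
            max_partners = max_partners)
  stopifnot(interact_dist > 0, interact_dist < pers_dist,
            pers_dist < near_dist, near_dist < max_dist, max_dist < far_dist,
            width > 0, height > 0, view_angle > 0, view_angle <= max_angle,
            max_angle == 360, max_partners >= 1, min_others >= 0)
  class(w) <- "emo_world"
  w
}

#' Shortest distance between two points on the torus
#'
#' @param ax,ay,bx,by Coordinates of the two points, meters.
#' @param world A [world_config()].
#' @return Distance in meters (at most half the torus diagonal).
#' @examples
#' torus_distance(1, 0, 299, 0)  # wraps: 2, not 298
#' @export
torus_distance <- function(ax, ay, bx, by, world = world_config()) {
  stopifnot(length(ax) == length(ay), length(bx) == length(by))
  mapply(cpp_torus_distance, ax, ay, bx, by,
         MoreArgs = list(w = world$width, h = world$height))
}

#' Bearing from one point to another on the torus
#'
#' 0 degrees = east, counterclockwise positive, result in `[0, 360)`.
#' @inheritParams torus_distance
#' @export
torus_bearing <- function(ax, ay, bx, by, world = world_config()) {
  mapply(cpp_torus_bearing, ax, ay, bx, by,
         MoreArgs = list(w = world$width, h = world$height))
}

#' Is a target inside ego's view cone?
#'
#' True when the torus-shortest bearing from ego to the target deviates from
#' ego's heading by at most half the view angle.
#'
#' @param ego Numeric vector `c(x, y, heading)`.
#' @param view_angle View angle in degrees, in `(0, 360]`.
#' @param target Numeric vector `c(x, y)`.
#' @inheritParams torus_distance
#' @export
in_view <- function(ego, view_angle, target, world = world_config()) {
  stopifnot(view_angle > 0, view_angle <= 360)
  cpp_in_view(ego[[1]], ego[[2]], ego[[3]], view_angle,
              target[[1]], target[[2]], world$width, world$height)
}

#' Candidate interaction partners
#'
#' The up-to-`max_partners` nearest recognizable individuals: within
#' `max_dist` and inside ego's current view cone, sorted by increasing
#' distance with ties broken by agent id. Ego itself is never a candidate.
#'
#' @param ego_id Agent id (1-based index into the coordinate vectors).
#' @param x,y Coordinates of all agents.
#' @param heading Ego's heading, degrees.
#' @param view_angle Current view angle, degrees (360 while scanning).
#' @inheritParams torus_distance
#' @return Integer vector of agent ids.
#' @export
candidate_partners <- function(ego_id, x, y, heading,
                               view_angle = world$view_angle,
                               world = world_config()) {
  stopifnot(length(x) == length(y), ego_id >= 1, ego_id <= length(x))
  cpp_candidate_partners(as.integer(ego_id), as.numeric(x), as.numeric(y),
                         heading, view_angle, world$width, world$height,
                         world$max_dist, as.integer(world$max_partners))
}

# ---------------------------------------------------------------------------
# activation scheduling
# ---------------------------------------------------------------------------

.kind_priority <- c("interrupt-attack" = 1L, "interrupt-signal" = 1L,
                    "interrupt-fight-nearby" = 1L, "proximity-notify" = 1L,
                    "movement-substep" = 2L, "scheduled" = 3L)

#' Draw an agent's next scheduled activation
#'
#' Inter-activation intervals are drawn from a normal distribution with mean
#' 1 minute and standard deviation 0.05 minutes, floored at 0.01 minutes.
#' The same distribution is used for the initial schedule and for every
#' subsequent non-bout activation.
#'
#' @param agent_id Agent id.
#' @param now Current time, minutes.
#' @param mean,sd,floor Parameters of the truncated normal interval.
#' @return A list `(time, agent_id, kind = "scheduled")`.
#' @export
schedule_next <- function(agent_id, now, mean = 1, sd = 0.05, floor = 0.01) {
  stopifnot(is.finite(now))
  delta <- max(rnorm(1L, mean, sd), floor)
  list(time = now + delta, agent_id = agent_id, kind = "scheduled")
}

#' Create an empty activation queue
#'
#' A small insertion-ordered priority queue used to express and test the
#' scheduling contract: events are delivered in nondecreasing time order;
#' ties are broken by kind (interrupts before movement substeps before
#' scheduled activations), then by agent id, then by insertion order.
#' The C++ engine uses the identical discipline internally.
#'
#' @return An environment of class `emo_queue`.
#' @export
event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$time <- numeric(0)
  q$agent <- integer(0)
  q$kind <- character(0)
  q$seq <- integer(0)
  q$counter <- 0L
  class(q) <- "emo_queue"
  q
}

#' @rdname event_queue
#' @param q An [event_queue()].
#' @param time Event time, minutes.
#' @param agent_id Agent id.
#' @param kind One of the activation kinds (see [event_queue()]).
#' @export
queue_push <- function(q, time, agent_id, kind = "scheduled") {
  stopifnot(inherits(q, "emo_queue"), kind %in% names(.kind_priority))
  q$counter <- q$counter + 1L
  q$time <- c(q$time, time)
  q$agent <- c(q$agent, as.integer(agent_id))
  q$kind <- c(q$kind, kind)
  q$seq <- c(q$seq, q$counter)
  invisible(q)
}

#' @rdname event_queue
#' @export
pop_next <- function(q) {
  stopifnot(inherits(q, "emo_queue"))
  if (length(q$time) == 0L)
    stop("empty activation queue: simulation end", call. = FALSE)
  ord <- order(q$time, .kind_priority[q$kind], q$agent, q$seq)
  i <- ord[1L]
  out <- list(time = q$time[i], agent_id = q$agent[i], kind = q$kind[i])
  q$time <- q$time[-i]
  q$agent <- q$agent[-i]
  q$kind <- q$kind[-i]
  q$seq <- q$seq[-i]
  out
}

#' @rdname event_queue
#' @export
queue_size <- function(q) length(q$time)
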