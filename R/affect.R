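#' Affect-dynamics parameters
#'
#' Rates and constants of the emotional state system. All state variables
#' (arousal, anxiety, satisfaction) live on `[0, 1]`; rates are per model
#' minute.
#'
#' @param sat_inc_groomer Satisfaction gain per minute while grooming
#'   another (0.05/min).
#' @param sat_inc_groomee Satisfaction gain per minute while being groomed
#'   (`GR_SAT_INC`, 0.1/min); the same rate drives the partner-specific
#'   satisfaction `PARTNER_SAT`.
#' @param sat_dec Linear satisfaction decay per minute outside grooming
#'   (0.02/min: a full level empties within one hour).
#' @param def_ar_limit Baseline arousal level (`DEF_AR_LIMIT`, 0.09), the
#'   limit arousal relaxes towards.
#' @param elev_ar_limit Elevated arousal limit while a FEARed (dominant)
#'   individual is within the personal distance.
#' @param lhw LIKE-history weight in minutes; 1 model DAY = 720 minutes.
#'   Larger values make earlier affiliation history weigh more.
#' @param relax_rate Exponential relaxation rate (per minute) with which
#'   arousal and anxiety approach their limit values.
#' @param scan_base,scan_gain Intercept and slope of the linear map from
#'   arousal to the scanning probability.
#' @param sat_limit,anx_limit Limit values for satisfaction and anxiety.
#' @param like_credit_given Also credit grooming *given* to the groomer's
#'   `PARTNER_SAT` (at the groomer rate), widening the bookkeeping beyond
#'   the operational received-grooming rule. Off by default; switching it
#'   on never changes the event stream at `lps = 0` (the bookkeeping
#'   consumes no random numbers).
#' @return A named list of class `emo_affect`.
#' @export
affect_params <- function(sat_inc_groomer = 0.05, sat_inc_groomee = 0.1,
                          sat_dec = 0.02, def_ar_limit = 0.09,
                          elev_ar_limit = 0.3, lhw = 720, relax_rate = 0.05,
                          scan_base = 0.1, scan_gain = 0.8, sat_limit = 0,
                          anx_limit = 0, like_credit_given = FALSE) {
  p <- list(sat_inc_groomer = sat_inc_groomer,
            sat_inc_groomee = sat_inc_groomee, sat_dec = sat_dec,
            def_ar_limit = def_ar_limit, elev_ar_limit = elev_ar_limit,
            lhw = lhw, relax_rate = relax_rate, scan_base = scan_base,
            scan_gain = scan_gain, sat_limit = sat_limit,
            anx_limit = anx_limit,
            like_credit_given = as.numeric(like_credit_given))
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, TRUE)),
            lhw > 0)
  class(p) <- "emo_affect"
  p
}

#' Emotional salience of social events
#'
#' Arousal and anxiety responses to discrete social events. Each row is an
#' event kind; the columns are the additive change applied to arousal and
#' anxiety (clamped afterwards to `[0, 1]`). The qualitative sign structure
#' is fixed by the model -- aggression received, given or observed and
#' losing a fight raise arousal and/or anxiety; winning, receiving
#' submission or affiliation, and grooming in either role lower anxiety;
#' receiving submission or affiliation and giving affiliation lower
#' arousal -- while the magnitudes are free parameters with the defaults
#' below. [validate_salience()] enforces the sign structure.
#'
#' @return A 13 x 2 numeric matrix with rownames naming the event kinds and
#'   columns `d_arousal`, `d_anxiety`.
#' @export
default_salience_table <- function() {
  tab <- rbind(
    receive_attack            = c( 0.40,  0.40),
    give_attack               = c( 0.20,  0.10),
    receive_aggressive_signal = c( 0.20,  0.20),
    give_aggressive_signal    = c( 0.10,  0.00),
    win_fight                 = c( 0.00, -0.20),
    lose_fight                = c( 0.20,  0.30),
    observe_fight             = c( 0.20,  0.20),
    receive_affiliative_signal = c(-0.10, -0.10),
    give_affiliative_signal   = c(-0.05, -0.05),
    receive_submissive_signal = c(-0.10, -0.10),
    give_submissive_signal    = c( 0.00, -0.10),
    receive_groom_start       = c(-0.10, -0.10),
    give_groom_start          = c(-0.05, -0.10))
  colnames(tab) <- c("d_arousal", "d_anxiety")
  tab
}

#' @rdname default_salience_table
#' @param table A salience matrix shaped like [default_salience_table()].
#' @export
validate_salience <- function(table) {
  ref <- default_salience_table()
  if (!is.matrix(table) || !identical(dim(table), dim(ref)) ||
      !identical(rownames(table), rownames(ref)))
    stop("salience table must have the same shape and rownames as ",
         "default_salience_table()", call. = FALSE)
  up_anx <- c("receive_attack", "give_attack", "receive_aggressive_signal",
              "lose_fight", "observe_fight")
  up_ar <- c("receive_attack", "give_attack", "receive_aggressive_signal",
             "give_aggressive_signal", "lose_fight", "observe_fight")
  dn_anx <- c("win_fight", "receive_submissive_signal",
              "receive_affiliative_signal", "receive_groom_start",
              "give_groom_start", "give_submissive_signal",
              "give_affiliative_signal")
  dn_ar <- c("receive_submissive_signal", "receive_affiliative_signal",
             "give_affiliative_signal", "receive_groom_start",
             "give_groom_start")
  if (any(table[up_anx, "d_anxiety"] <= 0))
    stop("aggression-related events must raise anxiety", call. = FALSE)
  if (any(table[up_ar, "d_arousal"] < 0))
    stop("aggression-related events must not lower arousal", call. = FALSE)
  if (any(table[dn_anx, "d_anxiety"] > 0))
    stop("affiliation/submission/winning must not raise anxiety",
         call. = FALSE)
  if (any(table[dn_ar, "d_arousal"] > 0))
    stop("received submission/affiliation and given affiliation must not ",
         "raise arousal", call. = FALSE)
  invisible(table)
}

#' FEAR attitude
#'
#' The fixed, antisymmetric valuation of aggression risk:
#' `FEAR_ij = myDOM_j - myDOM_i`. With dominance values on a 0.05..1.00
#' grid it spans -0.95 to +0.95.
#'
#' @param dom_i,dom_j Dominance strengths in `(0, 1]`.
#' @export
fear <- function(dom_i, dom_j) {
  stopifnot(all(dom_i > 0), all(dom_i <= 1), all(dom_j > 0), all(dom_j <= 1))
  dom_j - dom_i
}

#' @rdname fear
#' @param doms Vector of dominance strengths.
#' @return For `fear_matrix()`: the n x n antisymmetric matrix
#'   `FEAR[i, j] = doms[j] - doms[i]` with a zero diagonal.
#' @export
fear_matrix <- function(doms) {
  outer(doms, doms, function(di, dj) dj - di)
}

#' Fixed (control-model) LIKE attitude
#'
#' In the fixed-attitude control model the LIKE attitude is a symmetric,
#' decreasing function of absolute rank distance:
#' `LIKE_ij = max(0, L0 - LS * |myDOM_j - myDOM_i|)`, with conversion
#' parameters chosen so the distribution of values resembles the one
#' emerging in the dynamic model.
#'
#' @inheritParams fear
#' @param L0 Value at zero rank distance (0.243).
#' @param LS Decay slope per unit rank distance (0.36).
#' @export
fixed_like <- function(dom_i, dom_j, L0 = 0.243, LS = 0.36) {
  stopifnot(L0 >= 0, LS >= 0)
  pmax(0, L0 - LS * abs(dom_j - dom_i))
}

#' @rdname fixed_like
#' @param doms Vector of dominance strengths.
#' @export
fixed_like_matrix <- function(doms, L0 = 0.243, LS = 0.36) {
  m <- outer(doms, doms, fixed_like, L0 = L0, LS = LS)
  diag(m) <- 0
  m
}

#' Emotional-bookkeeping LIKE update
#'
#' Updates a LIKE attitude from the current partner-specific satisfaction:
#' `LIKE(t_n) = max((LHW * LIKE(t_{n-1}) + dt * PSAT(t_n)) / (LHW + dt),
#' PSAT(t_n))` with `dt = t_n - t_{n-1}`. The weighted mean makes LIKE decay
#' slowly (time constant `lhw`) when a partner stops grooming, while the
#' outer `max` lets current grooming raise LIKE immediately to the attained
#' `PARTNER_SAT` level.
#'
#' @param like_prev Previous LIKE value in `[0, 1]`.
#' @param psat_now Current `PARTNER_SAT` value in `[0, 1]`.
#' @param dt Minutes since the last update (`>= 0`).
#' @param lhw LIKE-history weight in minutes (1 DAY = 720).
#' @export
update_like <- function(like_prev, psat_now, dt, lhw = 720) {
  stopifnot(all(like_prev >= 0), all(like_prev <= 1),
            all(psat_now >= 0), all(psat_now <= 1), lhw > 0)
  if (any(dt < 0)) stop("negative dt: scheduling bug", call. = FALSE)
  mapply(cpp_update_like, like_prev, psat_now, dt, MoreArgs = list(lhw = lhw))
}

#' One emotional-state object
#'
#' @param arousal,anxiety,satisfaction Current levels in `[0, 1]`.
#' @param arousal_limit,anxiety_limit,satisfaction_limit Limit values the
#'   respective state relaxes towards.
#' @export
emotional_state <- function(arousal = 0.09, anxiety = 0, satisfaction = 0,
                            arousal_limit = 0.09, anxiety_limit = 0,
                            satisfaction_limit = 0) {
  s <- list(arousal = arousal, anxiety = anxiety, satisfaction = satisfaction,
            arousal_limit = arousal_limit, anxiety_limit = anxiety_limit,
            satisfaction_limit = satisfaction_limit)
  stopifnot(all(unlist(s) >= 0), all(unlist(s) <= 1))
  class(s) <- "emo_state"
  s
}

#' Linear satisfaction kinetics
#'
#' Satisfaction rises at 0.05/min for the groomer and 0.1/min for the
#' groomed individual, and decays at 0.02/min towards the satisfaction
#' limit otherwise; the result is clamped to `[0, 1]`.
#'
#' @param state An [emotional_state()].
#' @param role `"groomer"`, `"groomee"` or `"none"`.
#' @param dt Minutes elapsed.
#' @param params An [affect_params()].
#' @export
tick_satisfaction <- function(state, role = c("none", "groomer", "groomee"),
                              dt, params = affect_params()) {
  role <- match.arg(role)
  stopifnot(dt >= 0)
  s <- state$satisfaction
  s <- switch(role,
              groomer = s + params$sat_inc_groomer * dt,
              groomee = s + params$sat_inc_groomee * dt,
              none = max(state$satisfaction_limit, s - params$sat_dec * dt))
  state$satisfaction <- min(1, max(0, s))
  state
}

#' Partner-specific satisfaction kinetics
#'
#' `PARTNER_SAT[i, j]` tracks satisfaction attributable to grooming received
#' by `i` exclusively from `j`: the receiver's entry towards its current
#' groomer rises at the groomee rate (0.1/min) while every other entry of
#' the receiver's row decays at 0.02/min, clamped to `[0, 1]`.
#'
#' @param psat n x n `PARTNER_SAT` matrix (row = receiver).
#' @param receiver_id,groomer_id Agent ids; `groomer_id = NA` means the
#'   receiver is not being groomed and its whole row decays.
#' @inheritParams tick_satisfaction
#' @export
tick_partner_sat <- function(psat, receiver_id, groomer_id, dt,
                             params = affect_params()) {
  stopifnot(dt >= 0, is.na(groomer_id) || receiver_id != groomer_id)
  row <- pmax(0, psat[receiver_id, ] - params$sat_dec * dt)
  if (!is.na(groomer_id))
    row[groomer_id] <- min(1, psat[receiver_id, groomer_id] +
                                params$sat_inc_groomee * dt)
  psat[receiver_id, ] <- row
  psat[receiver_id, receiver_id] <- 0
  psat
}

#' Apply a discrete social event to the emotional state
#'
#' Adds the tabulated arousal and anxiety saliences and clamps to `[0, 1]`.
#' The proximity-of-a-dominant effect is not an event: it acts on the
#' arousal *limit* (see [affect_params()]'s `elev_ar_limit`) and is handled
#' by the movement proximity update.
#'
#' @inheritParams tick_satisfaction
#' @param event_kind A rowname of the salience table.
#' @param table Salience matrix, see [default_salience_table()].
#' @export
apply_event <- function(state, event_kind, table = default_salience_table()) {
  if (!event_kind %in% rownames(table))
    stop("unknown event kind: ", event_kind, call. = FALSE)
  state$arousal <- min(1, max(0, state$arousal + table[event_kind, 1]))
  state$anxiety <- min(1, max(0, state$anxiety + table[event_kind, 2]))
  state
}

#' Exponential relaxation towards a limit value
#'
#' `value' = limit + (value - limit) * exp(-rate * dt)`: monotone,
#' converges to the limit, and composes over subdivided intervals
#' (a semigroup), which makes lazy state updates exact.
#'
#' @param value Current level.
#' @param limit Limit value approached over time.
#' @param dt Minutes elapsed (`>= 0`).
#' @param rate Relaxation rate per minute.
#' @export
relax_toward_limit <- function(value, limit, dt, rate = 0.05) {
  stopifnot(all(dt >= 0), rate >= 0)
  limit + (value - limit) * exp(-rate * dt)
}

#' Scanning probability
#'
#' The probability of widening the view angle to the full circle before an
#' action-selection round; linear and nondecreasing in arousal, clamped to
#' `[0, 1]`.
#'
#' @param arousal Current arousal in `[0, 1]`.
#' @param params An [affect_params()].
#' @export
scan_probability <- function(arousal, params = affect_params()) {
  stopifnot(all(arousal >= 0), all(arousal <= 1))
  pmin(1, pmax(0, params$scan_base + params$scan_gain * arousal))
}
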