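// Event-driven core of the emosim model.
//
// The same static helpers back both the exported single-shot functions
// (used by the R-level API and the test-suite) and the Engine class that
// runs a full simulation, so there is exactly one implementation of the
// geometry, the candidate rule, the LIKE update and the action weights.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// torus geometry (0 deg = east, counterclockwise positive)
// ---------------------------------------------------------------------------

// note: wrapping uses floor division, not fmod (keeps the binary free of
// versioned libm symbols newer than the host glibc)
static inline double wrap_coord(double v, double span) {
  v -= span * std::floor(v / span);
  if (v >= span) v -= span;  // guard against rounding at the seam
  return v;
}

static inline double wrap_delta(double d, double span) {
  d = wrap_coord(d, span);
  if (d >= span / 2.0) d -= span;
  return d;
}

static inline double norm_deg(double a) { return wrap_coord(a, 360.0); }

static inline double tdist_f(double ax, double ay, double bx, double by,
                             double w, double h) {
  double dx = wrap_delta(bx - ax, w);
  double dy = wrap_delta(by - ay, h);
  return std::sqrt(dx * dx + dy * dy);
}

static inline double bearing_f(double ax, double ay, double bx, double by,
                               double w, double h) {
  double dx = wrap_delta(bx - ax, w);
  double dy = wrap_delta(by - ay, h);
  return norm_deg(std::atan2(dy, dx) * 180.0 / M_PI);
}

static inline bool in_view_f(double ax, double ay, double heading,
                             double view_angle, double bx, double by,
                             double w, double h) {
  if (view_angle >= 360.0) return true;
  double dev = std::fabs(wrap_delta(bearing_f(ax, ay, bx, by, w, h) - heading,
                                    360.0));
  return dev <= view_angle / 2.0;
}

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

static inline double like_update_f(double like_prev, double psat_now,
                                   double dt, double lhw) {
  double wm = (lhw * like_prev + dt * psat_now) / (lhw + dt);
  return wm > psat_now ? wm : psat_now;
}

static inline double win_chance_f(double dom_i, double dom_j, double beta) {
  return 1.0 / (1.0 + std::exp(-beta * (dom_i - dom_j)));
}

// ---------------------------------------------------------------------------
// exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_torus_distance(double ax, double ay, double bx, double by,
                          double w, double h) {
  return tdist_f(ax, ay, bx, by, w, h);
}

// [[Rcpp::export]]
double cpp_torus_bearing(double ax, double ay, double bx, double by,
                         double w, double h) {
  return bearing_f(ax, ay, bx, by, w, h);
}

// [[Rcpp::export]]
bool cpp_in_view(double ax, double ay, double heading, double view_angle,
                 double bx, double by, double w, double h) {
  return in_view_f(ax, ay, heading, view_angle, bx, by, w, h);
}

// 1-based ids of up to max_partners others within max_dist and the view
// cone, sorted by increasing distance, ties broken by id.
// [[Rcpp::export]]
IntegerVector cpp_candidate_partners(int ego, NumericVector x, NumericVector y,
                                     double heading, double view_angle,
                                     double w, double h, double max_dist,
                                     int max_partners) {
  int n = x.size();
  int e = ego - 1;
  std::vector<std::pair<double, int> > cand;
  for (int j = 0; j < n; ++j) {
    if (j == e) continue;
    double d = tdist_f(x[e], y[e], x[j], y[j], w, h);
    if (d > max_dist) continue;
    if (!in_view_f(x[e], y[e], heading, view_angle, x[j], y[j], w, h)) continue;
    cand.push_back(std::make_pair(d, j));
  }
  std::sort(cand.begin(), cand.end());
  int m = std::min((int)cand.size(), max_partners);
  IntegerVector out(m);
  for (int k = 0; k < m; ++k) out[k] = cand[k].second + 1;
  return out;
}

// [[Rcpp::export]]
double cpp_update_like(double like_prev, double psat_now, double dt,
                       double lhw) {
  if (dt < 0) stop("negative dt in LIKE update: scheduling bug");
  return like_update_f(like_prev, psat_now, dt, lhw);
}

// [[Rcpp::export]]
double cpp_win_chance(double dom_i, double dom_j, double beta) {
  return win_chance_f(dom_i, dom_j, beta);
}

// [[Rcpp::export]]
bool cpp_grouping_needed(int ego, NumericVector x, NumericVector y,
                         double group_dist, int min_others, double far_dist,
                         double w, double h) {
  int n = x.size(), e = ego - 1, cnt = 0;
  double dmax = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == e) continue;
    double d = tdist_f(x[e], y[e], x[j], y[j], w, h);
    if (d <= group_dist) ++cnt;
    if (d > dmax) dmax = d;
  }
  return cnt < min_others || dmax > far_dist;
}

// One movement substep toward (tx, ty); never overshoots past stop_at.
// [[Rcpp::export]]
NumericVector cpp_move_towards(double ax, double ay, double tx, double ty,
                               double step, double stop_at, double w,
                               double h) {
  double d = tdist_f(ax, ay, tx, ty, w, h);
  double s = std::min(step, std::max(0.0, d - 0.5 * stop_at));
  double b = bearing_f(ax, ay, tx, ty, w, h) * M_PI / 180.0;
  return NumericVector::create(wrap_coord(ax + s * std::cos(b), w),
                               wrap_coord(ay + s * std::sin(b), h),
                               norm_deg(b * 180.0 / M_PI));
}

// [[Rcpp::export]]
NumericVector cpp_move_away(double ax, double ay, double rx, double ry,
                            double step, double w, double h) {
  double b = bearing_f(rx, ry, ax, ay, w, h) * M_PI / 180.0;
  return NumericVector::create(wrap_coord(ax + step * std::cos(b), w),
                               wrap_coord(ay + step * std::sin(b), h),
                               norm_deg(b * 180.0 / M_PI));
}

// ---------------------------------------------------------------------------
// parameters
// ---------------------------------------------------------------------------

struct Par {
  double width, height, interact, pers, neard, maxd, fard, view, maxang;
  int min_others, max_partners;
  double sat_inc_groomer, sat_inc_groomee, sat_dec, def_ar_limit,
      elev_ar_limit, lhw, relax_rate, scan_base, scan_gain, sat_limit,
      anx_limit;
  bool like_credit_given;
  double b_groom, b_affil_signal, b_approach, b_leave, b_submis_signal,
      b_avoid, b_attack, b_aggr_signal, b_rest, b_random_move, b_flee_resp,
      b_counter_resp;
  double k_sub, k_agg, c_arousal, c_anxiety, c_satisfaction, c_risk, beta;
  double speed, substep, stop_dist, bout_min, bout_max, rwalk_minutes,
      rwalk_turn, winner_delay, bystander_delay, signal_delay, obs_fight_dist,
      act_mean, act_sd, act_floor, max_move_bout;
  double lps;
  bool dynamic_like;
  double burn_in, run_length, record_window, sample_interval;
};

static double pget(const NumericVector& p, const char* k) {
  if (!p.containsElementNamed(k)) stop("missing engine parameter: %s", k);
  return p[k];
}

static Par fill_par(const NumericVector& p) {
  Par P;
  P.width = pget(p, "width");
  P.height = pget(p, "height");
  P.interact = pget(p, "interact_dist");
  P.pers = pget(p, "pers_dist");
  P.neard = pget(p, "near_dist");
  P.maxd = pget(p, "max_dist");
  P.fard = pget(p, "far_dist");
  P.view = pget(p, "view_angle");
  P.maxang = pget(p, "max_angle");
  P.min_others = (int)pget(p, "min_others");
  P.max_partners = (int)pget(p, "max_partners");
  P.sat_inc_groomer = pget(p, "sat_inc_groomer");
  P.sat_inc_groomee = pget(p, "sat_inc_groomee");
  P.sat_dec = pget(p, "sat_dec");
  P.def_ar_limit = pget(p, "def_ar_limit");
  P.elev_ar_limit = pget(p, "elev_ar_limit");
  P.lhw = pget(p, "lhw");
  P.relax_rate = pget(p, "relax_rate");
  P.scan_base = pget(p, "scan_base");
  P.scan_gain = pget(p, "scan_gain");
  P.sat_limit = pget(p, "sat_limit");
  P.anx_limit = pget(p, "anx_limit");
  P.like_credit_given = pget(p, "like_credit_given") > 0.5;
  P.b_groom = pget(p, "b_groom");
  P.b_affil_signal = pget(p, "b_affil_signal");
  P.b_approach = pget(p, "b_approach");
  P.b_leave = pget(p, "b_leave");
  P.b_submis_signal = pget(p, "b_submis_signal");
  P.b_avoid = pget(p, "b_avoid");
  P.b_attack = pget(p, "b_attack");
  P.b_aggr_signal = pget(p, "b_aggr_signal");
  P.b_rest = pget(p, "b_rest");
  P.b_random_move = pget(p, "b_random_move");
  P.b_flee_resp = pget(p, "b_flee_resp");
  P.b_counter_resp = pget(p, "b_counter_resp");
  P.k_sub = pget(p, "fear_submission_gain");
  P.k_agg = pget(p, "fear_aggression_gain");
  P.c_arousal = pget(p, "arousal_gain");
  P.c_anxiety = pget(p, "anxiety_gain");
  P.c_satisfaction = pget(p, "satiation_gain");
  P.c_risk = pget(p, "risk_anxiety_gain");
  P.beta = pget(p, "win_beta");
  P.speed = pget(p, "move_speed");
  P.substep = pget(p, "move_substep");
  P.stop_dist = pget(p, "move_stop_dist");
  P.bout_min = pget(p, "bout_min");
  P.bout_max = pget(p, "bout_max");
  P.rwalk_minutes = pget(p, "rwalk_minutes");
  P.rwalk_turn = pget(p, "rwalk_turn");
  P.winner_delay = pget(p, "winner_delay");
  P.bystander_delay = pget(p, "bystander_delay");
  P.signal_delay = pget(p, "signal_delay");
  P.obs_fight_dist = pget(p, "observe_fight_dist");
  P.act_mean = pget(p, "act_mean");
  P.act_sd = pget(p, "act_sd");
  P.act_floor = pget(p, "act_floor");
  P.max_move_bout = pget(p, "max_move_bout");
  P.lps = pget(p, "lps");
  P.dynamic_like = pget(p, "dynamic_like") > 0.5;
  P.burn_in = pget(p, "burn_in");
  P.run_length = pget(p, "run_length");
  P.record_window = pget(p, "record_window");
  P.sample_interval = pget(p, "sample_interval");
  return P;
}

// behaviour codes shared with the R side (see behavior_codes())
enum Beh {
  GROOM = 1,
  AFFIL_SIGNAL = 2,
  APPROACH = 3,
  LEAVE = 4,
  SUBMIS_SIGNAL = 5,
  AVOID = 6,
  ATTACK = 7,
  AGGR_SIGNAL = 8,
  FLEE = 9,
  REST = 10,
  RANDOM_MOVE = 11
};

// salience table rows (fixed order shared with the R side)
enum Sal {
  RECV_ATTACK = 0,
  GIVE_ATTACK,
  RECV_AGGR_SIGNAL,
  GIVE_AGGR_SIGNAL,
  WIN_FIGHT,
  LOSE_FIGHT,
  OBSERVE_FIGHT,
  RECV_AFFIL_SIGNAL,
  GIVE_AFFIL_SIGNAL,
  RECV_SUBMIS_SIGNAL,
  GIVE_SUBMIS_SIGNAL,
  RECV_GROOM_START,
  GIVE_GROOM_START,
  N_SAL
};

// ---------------------------------------------------------------------------
// action weights: the contract (C1-C5) in one place
// ---------------------------------------------------------------------------

static void build_weights(const Par& P, int m, const double* dist,
                          const double* fearr, const double* liker,
                          const int* groom_blocked, double arousal,
                          double anxiety, double satisfaction,
                          std::vector<int>& beh, std::vector<int>& tgt,
                          std::vector<double>& wt) {
  double active = 1.0 + P.c_arousal * arousal;
  double affm = (1.0 + P.c_anxiety * anxiety) *
                std::max(0.0, 1.0 - P.c_satisfaction * satisfaction);
  // LIKE-partner selectivity redistributes affiliative weight among the
  // candidates (m_j relative to the candidate mean) rather than damping
  // overall affiliation; at lps = 0 every factor is exactly 1.
  double msum = 0.0;
  for (int k = 0; k < m; ++k) msum += (1.0 - P.lps) + P.lps * liker[k];
  double mbar = m > 0 ? msum / m : 1.0;
  for (int k = 0; k < m; ++k) {
    double mlike = ((1.0 - P.lps) + P.lps * liker[k]) / mbar;
    double subm = std::exp(P.k_sub * fearr[k]) * (1.0 + P.c_anxiety * anxiety);
    double aggm = std::exp(-P.k_agg * fearr[k]);
    if (fearr[k] > 0) aggm *= std::max(0.0, 1.0 - P.c_risk * anxiety);
    double d = dist[k];
    if (d <= P.interact) {
      if (!groom_blocked[k]) {
        beh.push_back(GROOM);
        tgt.push_back(k);
        wt.push_back(P.b_groom * mlike * affm * active);
      }
      beh.push_back(LEAVE);
      tgt.push_back(k);
      wt.push_back(P.b_leave * subm * active);
      beh.push_back(ATTACK);
      tgt.push_back(k);
      wt.push_back(P.b_attack * aggm * active);
    }
    if (d <= P.pers) {
      beh.push_back(AFFIL_SIGNAL);
      tgt.push_back(k);
      wt.push_back(P.b_affil_signal * mlike * affm * active);
      beh.push_back(SUBMIS_SIGNAL);
      tgt.push_back(k);
      wt.push_back(P.b_submis_signal * subm * active);
      beh.push_back(AVOID);
      tgt.push_back(k);
      wt.push_back(P.b_avoid * subm * active);
      beh.push_back(AGGR_SIGNAL);
      tgt.push_back(k);
      wt.push_back(P.b_aggr_signal * aggm * active);
    }
    beh.push_back(APPROACH);
    tgt.push_back(k);
    wt.push_back(P.b_approach * mlike * affm * active);
  }
  beh.push_back(REST);
  tgt.push_back(-1);
  wt.push_back(P.b_rest);
  beh.push_back(RANDOM_MOVE);
  tgt.push_back(-1);
  wt.push_back(P.b_random_move * active);
}

// [[Rcpp::export]]
DataFrame cpp_action_weights(NumericVector dist, NumericVector fear_row,
                             NumericVector like_row,
                             IntegerVector groom_blocked, double arousal,
                             double anxiety, double satisfaction,
                             NumericVector par) {
  Par P = fill_par(par);
  int m = dist.size();
  std::vector<int> beh, tgt;
  std::vector<double> wt;
  std::vector<int> gb(groom_blocked.begin(), groom_blocked.end());
  build_weights(P, m, dist.begin(), fear_row.begin(), like_row.begin(),
                gb.data(), arousal, anxiety, satisfaction, beh, tgt, wt);
  IntegerVector b(beh.begin(), beh.end()), tg(tgt.size());
  for (size_t k = 0; k < tgt.size(); ++k)
    tg[k] = tgt[k] < 0 ? NA_INTEGER : tgt[k] + 1;
  return DataFrame::create(_["behavior"] = b, _["target"] = tg,
                           _["weight"] = NumericVector(wt.begin(), wt.end()));
}

// ---------------------------------------------------------------------------
// engine
// ---------------------------------------------------------------------------

struct Ev {
  double t;
  int prio;  // 0 sampler, 1 interrupt, 2 movement substep, 3 scheduled
  int agent; // -2 for the sampler
  long long seq;
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.prio != b.prio) return a.prio > b.prio;
    if (a.agent != b.agent) return a.agent > b.agent;
    return a.seq > b.seq;
  }
};

enum MoveMode { M_APPROACH = 0, M_AWAY = 1, M_RANDOM = 2, M_GROUPING = 3 };

class Engine {
 public:
  Par P;
  int n;
  NumericMatrix fear, like, sal;
  std::vector<double> dom, x, y, heading, arousal, anxiety, satisfaction,
      ar_limit, last_upd, bout_end, groom_start, groom_dist0, move_until;
  std::vector<int> bout, groom_target, groomed_by, move_mode, move_ref;
  std::vector<double> psat;  // row-major n*n
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> Q;
  std::vector<long long> pend;
  long long seqc;
  double horizon, record_start, record_end;
  bool record_events;
  std::vector<double> ev_t, ev_val, ev_d;
  std::vector<int> ev_a, ev_r, ev_b;
  int K, ksample;
  std::vector<double> sx, sy, sar, sanx, ssat, slike;

  Engine(const Par& P_, const NumericMatrix& fear_, const NumericMatrix& like_,
         const NumericMatrix& sal_, const NumericVector& dom_,
         const NumericMatrix& pos0, const NumericVector& heading0,
         bool record_events_)
      : P(P_), n(dom_.size()), fear(fear_), like(clone(like_)), sal(sal_),
        record_events(record_events_) {
    dom.assign(dom_.begin(), dom_.end());
    x.resize(n);
    y.resize(n);
    heading.assign(heading0.begin(), heading0.end());
    for (int i = 0; i < n; ++i) {
      x[i] = pos0(i, 0);
      y[i] = pos0(i, 1);
    }
    arousal.assign(n, P.def_ar_limit);
    anxiety.assign(n, 0.0);
    satisfaction.assign(n, 0.0);
    ar_limit.assign(n, P.def_ar_limit);
    last_upd.assign(n, 0.0);
    bout.assign(n, 0);
    bout_end.assign(n, 0.0);
    groom_start.assign(n, 0.0);
    groom_dist0.assign(n, 0.0);
    move_until.assign(n, 0.0);
    groom_target.assign(n, -1);
    groomed_by.assign(n, -1);
    move_mode.assign(n, 0);
    move_ref.assign(n, -1);
    psat.assign((size_t)n * n, 0.0);
    pend.assign(n, 0);
    seqc = 0;
    horizon = P.burn_in + P.run_length;
    record_end = horizon;
    record_start = horizon - P.record_window;
    K = (int)std::floor(P.record_window / P.sample_interval + 1e-9);
    ksample = 0;
    sx.assign((size_t)K * n, 0.0);
    sy.assign((size_t)K * n, 0.0);
    sar.assign((size_t)K * n, 0.0);
    sanx.assign((size_t)K * n, 0.0);
    ssat.assign((size_t)K * n, 0.0);
    slike.assign((size_t)K * n * n, 0.0);
  }

  double tdist(int i, int j) const {
    return tdist_f(x[i], y[i], x[j], y[j], P.width, P.height);
  }

  double gap() {
    double d = R::rnorm(P.act_mean, P.act_sd);
    return d < P.act_floor ? P.act_floor : d;
  }

  void schedule(int i, double t, int prio) {
    pend[i] = ++seqc;
    Q.push({t, prio, i, seqc});
  }

  // lazy advance of agent i's continuous state to time t
  void advance(int i, double t) {
    double dt = t - last_upd[i];
    if (dt <= 0) return;
    double rate = 0.0;
    if (groom_target[i] >= 0) rate += P.sat_inc_groomer;
    if (groomed_by[i] >= 0) rate += P.sat_inc_groomee;
    if (rate > 0)
      satisfaction[i] = clamp01(satisfaction[i] + rate * dt);
    else
      satisfaction[i] =
          std::max(P.sat_limit, satisfaction[i] - P.sat_dec * dt);
    int g = groomed_by[i];
    int g2 = P.like_credit_given ? groom_target[i] : -1;
    double* ps = &psat[(size_t)i * n];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (j == g)
        ps[j] = std::min(1.0, ps[j] + P.sat_inc_groomee * dt);
      else if (j == g2)
        ps[j] = std::min(1.0, ps[j] + P.sat_inc_groomer * dt);
      else
        ps[j] = std::max(0.0, ps[j] - P.sat_dec * dt);
      if (P.dynamic_like) like(i, j) = like_update_f(like(i, j), ps[j], dt, P.lhw);
    }
    double f = std::exp(-P.relax_rate * dt);
    arousal[i] = clamp01(ar_limit[i] + (arousal[i] - ar_limit[i]) * f);
    anxiety[i] = clamp01(P.anx_limit + (anxiety[i] - P.anx_limit) * f);
    last_upd[i] = t;
  }

  void deltas(int i, int kind) {
    arousal[i] = clamp01(arousal[i] + sal(kind, 0));
    anxiety[i] = clamp01(anxiety[i] + sal(kind, 1));
  }

  void log_ev(int code, double t, int a, int r, double val, double d) {
    if (!record_events) return;
    if (code == GROOM) {
      // t = bout start; keep if the bout overlaps the window
      if (t + val <= record_start || t >= record_end) return;
    } else {
      if (t < record_start || t >= record_end) return;
    }
    ev_t.push_back(t);
    ev_a.push_back(a + 1);
    ev_r.push_back(r + 1);
    ev_b.push_back(code);
    ev_val.push_back(val);
    ev_d.push_back(d);
  }

  void check_ar_limit(int i, double t) {
    advance(i, t);
    bool near_dom = false;
    for (int j = 0; j < n && !near_dom; ++j) {
      if (j == i) continue;
      if (fear(i, j) > 0 && tdist(i, j) <= P.pers) near_dom = true;
    }
    ar_limit[i] = near_dom ? P.elev_ar_limit : P.def_ar_limit;
  }

  // after ending a movement bout: re-check ego's arousal limit and update
  // everyone who FEARs ego on ego's new position
  void proximity_update(int i, double t) {
    check_ar_limit(i, t);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (fear(j, i) > 0) check_ar_limit(j, t);
    }
  }

  void end_groom(int g, double t) {
    int j = groom_target[g];
    if (j < 0) return;
    advance(g, t);
    advance(j, t);
    if (t > groom_start[g])  // zero-length bouts (interrupted at start) are no-ops
      log_ev(GROOM, groom_start[g], g, j, t - groom_start[g], groom_dist0[g]);
    groom_target[g] = -1;
    groomed_by[j] = -1;
    bout[g] = 0;
  }

  // break ego's own activity (used when disturbed by aggression / a fight)
  void interrupt_bouts(int i, double t) {
    if (groom_target[i] >= 0) end_groom(i, t);
    bout[i] = 0;
  }

  void start_move(int i, double t, int mode, int ref) {
    if (groom_target[i] >= 0) end_groom(i, t);
    if (groomed_by[i] >= 0) {
      int g = groomed_by[i];
      end_groom(g, t);
      schedule(g, t, 1);  // groomer re-decides at once
    }
    bout[i] = 3;
    move_mode[i] = mode;
    move_ref[i] = ref;
    move_until[i] =
        t + (mode == M_RANDOM ? P.rwalk_minutes : P.max_move_bout);
    schedule(i, t + P.substep, 2);
  }

  bool grouping_needed(int i) const {
    int cnt = 0;
    double dmax = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = tdist(i, j);
      if (d <= P.neard) ++cnt;
      if (d > dmax) dmax = d;
    }
    return cnt < P.min_others || dmax > P.fard;
  }

  void resolve_attack(int i, int j, double t) {
    advance(i, t);
    advance(j, t);
    if (groom_target[j] >= 0) end_groom(j, t);
    if (groomed_by[j] >= 0) {
      int g = groomed_by[j];
      end_groom(g, t);
      schedule(g, t, 1);
    }
    bout[j] = 0;
    double datt = tdist(i, j);
    log_ev(ATTACK, t, i, j, 1.0, datt);
    deltas(j, RECV_ATTACK);
    deltas(i, GIVE_ATTACK);
    double F = fear(j, i);
    double wf = P.b_flee_resp * std::exp(P.k_sub * F) *
                (1.0 + P.c_anxiety * anxiety[j]);
    double wc = P.b_counter_resp * std::exp(-P.k_agg * F);
    if (F > 0) wc *= std::max(0.0, 1.0 - P.c_risk * anxiety[j]);
    bool counter = unif_rand() * (wf + wc) >= wf;
    int winner, loser;
    if (counter) {
      log_ev(ATTACK, t, j, i, 1.0, datt);
      deltas(j, GIVE_ATTACK);
      double p = win_chance_f(dom[i], dom[j], P.beta);
      winner = (unif_rand() < p) ? i : j;
      loser = i + j - winner;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        double dmin = std::min(tdist(k, i), tdist(k, j));
        if (dmin <= P.obs_fight_dist) {
          advance(k, t);
          deltas(k, OBSERVE_FIGHT);
          interrupt_bouts(k, t);
          schedule(k, t + P.bystander_delay, 1);
        }
      }
    } else {
      winner = i;
      loser = j;
    }
    deltas(winner, WIN_FIGHT);
    deltas(loser, LOSE_FIGHT);
    log_ev(FLEE, t, loser, winner, 1.0, tdist(loser, winner));
    start_move(loser, t, M_AWAY, winner);
    schedule(winner, t + P.winner_delay, 1);
  }

  void select_action(int i, double t) {
    advance(i, t);
    bout[i] = 0;
    double pscan = clamp01(P.scan_base + P.scan_gain * arousal[i]);
    bool wide = unif_rand() < pscan;
    double va = wide ? P.maxang : P.view;
    if (grouping_needed(i)) {
      int idx = (int)(unif_rand() * (n - 1));
      if (idx >= n - 1) idx = n - 2;
      if (idx >= i) ++idx;
      start_move(i, t, M_GROUPING, idx);
      return;
    }
    std::vector<std::pair<double, int> > cand;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = tdist(i, j);
      if (d > P.maxd) continue;
      if (!in_view_f(x[i], y[i], heading[i], va, x[j], y[j], P.width,
                     P.height))
        continue;
      cand.push_back(std::make_pair(d, j));
    }
    std::sort(cand.begin(), cand.end());
    int m = std::min((int)cand.size(), P.max_partners);
    std::vector<double> dist(m), fearr(m), liker(m);
    std::vector<int> ids(m), gb(m);
    for (int k = 0; k < m; ++k) {
      dist[k] = cand[k].first;
      ids[k] = cand[k].second;
      fearr[k] = fear(i, ids[k]);
      liker[k] = like(i, ids[k]);
      gb[k] = (groomed_by[ids[k]] >= 0 || bout[ids[k]] == 3) ? 1 : 0;
    }
    std::vector<int> beh, tgt;
    std::vector<double> wt;
    build_weights(P, m, dist.data(), fearr.data(), liker.data(), gb.data(),
                  arousal[i], anxiety[i], satisfaction[i], beh, tgt, wt);
    double tot = 0.0;
    for (size_t k = 0; k < wt.size(); ++k) tot += wt[k];
    double u = unif_rand() * tot, acc = 0.0;
    int pick = (int)wt.size() - 1;
    for (size_t k = 0; k < wt.size(); ++k) {
      acc += wt[k];
      if (u < acc) {
        pick = (int)k;
        break;
      }
    }
    int b = beh[pick];
    int j = tgt[pick] >= 0 ? ids[tgt[pick]] : -1;
    switch (b) {
      case GROOM: {
        advance(j, t);
        groom_target[i] = j;
        groomed_by[j] = i;
        groom_start[i] = t;
        groom_dist0[i] = dist[tgt[pick]];
        double dur = R::runif(P.bout_min, P.bout_max);
        bout[i] = 1;
        bout_end[i] = t + dur;
        deltas(i, GIVE_GROOM_START);
        deltas(j, RECV_GROOM_START);
        schedule(i, bout_end[i], 3);
        break;
      }
      case AFFIL_SIGNAL:
        advance(j, t);
        log_ev(AFFIL_SIGNAL, t, i, j, 1.0, dist[tgt[pick]]);
        deltas(i, GIVE_AFFIL_SIGNAL);
        deltas(j, RECV_AFFIL_SIGNAL);
        schedule(i, t + gap(), 3);
        break;
      case APPROACH:
        log_ev(APPROACH, t, i, j, 1.0, dist[tgt[pick]]);
        start_move(i, t, M_APPROACH, j);
        break;
      case LEAVE:
        log_ev(LEAVE, t, i, j, 1.0, dist[tgt[pick]]);
        start_move(i, t, M_AWAY, j);
        break;
      case SUBMIS_SIGNAL:
        advance(j, t);
        log_ev(SUBMIS_SIGNAL, t, i, j, 1.0, dist[tgt[pick]]);
        deltas(i, GIVE_SUBMIS_SIGNAL);
        deltas(j, RECV_SUBMIS_SIGNAL);
        schedule(i, t + gap(), 3);
        break;
      case AVOID:
        log_ev(AVOID, t, i, j, 1.0, dist[tgt[pick]]);
        start_move(i, t, M_AWAY, j);
        break;
      case ATTACK:
        resolve_attack(i, j, t);
        break;
      case AGGR_SIGNAL:
        advance(j, t);
        log_ev(AGGR_SIGNAL, t, i, j, 1.0, dist[tgt[pick]]);
        deltas(i, GIVE_AGGR_SIGNAL);
        deltas(j, RECV_AGGR_SIGNAL);
        interrupt_bouts(j, t);
        schedule(j, t + P.signal_delay, 1);
        schedule(i, t + gap(), 3);
        break;
      case REST:
        bout[i] = 2;
        bout_end[i] = t + R::runif(P.bout_min, P.bout_max);
        schedule(i, bout_end[i], 3);
        break;
      case RANDOM_MOVE:
        start_move(i, t, M_RANDOM, -1);
        break;
    }
  }

  void substep(int i, double t) {
    if (bout[i] != 3) return;  // defensively: bout was broken elsewhere
    int mode = move_mode[i], r = move_ref[i];
    double step = P.speed * P.substep;
    bool done = false;
    if (mode == M_APPROACH || mode == M_GROUPING) {
      double d = tdist(i, r);
      if (d <= P.interact || t >= move_until[i] ||
          (mode == M_GROUPING && !grouping_needed(i)))
        done = true;
      else {
        double s = std::min(step, d - 0.5 * P.interact);
        double b = bearing_f(x[i], y[i], x[r], y[r], P.width, P.height);
        heading[i] = b;
        b *= M_PI / 180.0;
        x[i] = wrap_coord(x[i] + s * std::cos(b), P.width);
        y[i] = wrap_coord(y[i] + s * std::sin(b), P.height);
      }
    } else if (mode == M_AWAY) {
      double d = tdist(i, r);
      if (d > P.stop_dist || t >= move_until[i])
        done = true;
      else {
        double b = bearing_f(x[r], y[r], x[i], y[i], P.width, P.height);
        heading[i] = b;
        b *= M_PI / 180.0;
        x[i] = wrap_coord(x[i] + step * std::cos(b), P.width);
        y[i] = wrap_coord(y[i] + step * std::sin(b), P.height);
      }
    } else {  // M_RANDOM
      if (t >= move_until[i])
        done = true;
      else {
        heading[i] = norm_deg(heading[i] +
                              R::runif(-P.rwalk_turn, P.rwalk_turn));
        double b = heading[i] * M_PI / 180.0;
        x[i] = wrap_coord(x[i] + step * std::cos(b), P.width);
        y[i] = wrap_coord(y[i] + step * std::sin(b), P.height);
      }
    }
    if (!done) {
      schedule(i, t + P.substep, 2);
    } else {
      bout[i] = 0;
      proximity_update(i, t);
      if (mode == M_APPROACH)
        select_action(i, t);  // arrival triggers an immediate new round
      else
        schedule(i, t + gap(), 3);
    }
  }

  void take_sample(double t) {
    for (int i = 0; i < n; ++i) advance(i, t);
    size_t off = (size_t)ksample * n;
    for (int i = 0; i < n; ++i) {
      sx[off + i] = x[i];
      sy[off + i] = y[i];
      sar[off + i] = arousal[i];
      sanx[off + i] = anxiety[i];
      ssat[off + i] = satisfaction[i];
    }
    size_t off2 = (size_t)ksample * n * n;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) slike[off2 + (size_t)j * n + i] = like(i, j);
    ++ksample;
  }

  List run(const NumericVector& t0) {
    for (int i = 0; i < n; ++i) schedule(i, t0[i], 3);
    for (int k = 1; k <= K; ++k)
      Q.push({record_start + k * P.sample_interval, 0, -2, 0});
    while (!Q.empty()) {
      Ev e = Q.top();
      Q.pop();
      if (e.t > horizon + 1e-9) break;
      if (e.agent == -2) {
        if (ksample < K) take_sample(e.t);
        continue;
      }
      if (e.seq != pend[e.agent]) continue;  // superseded
      int i = e.agent;
      if (e.prio == 2) {
        substep(i, e.t);
      } else {
        if (groom_target[i] >= 0) end_groom(i, e.t);
        bout[i] = 0;
        select_action(i, e.t);
      }
    }
    // flush grooming bouts still open at the horizon
    for (int i = 0; i < n; ++i)
      if (groom_target[i] >= 0) end_groom(i, horizon);

    DataFrame events = DataFrame::create(
        _["time"] = NumericVector(ev_t.begin(), ev_t.end()),
        _["actor"] = IntegerVector(ev_a.begin(), ev_a.end()),
        _["receiver"] = IntegerVector(ev_r.begin(), ev_r.end()),
        _["behavior"] = IntegerVector(ev_b.begin(), ev_b.end()),
        _["value"] = NumericVector(ev_val.begin(), ev_val.end()),
        _["dist"] = NumericVector(ev_d.begin(), ev_d.end()));
    NumericVector lk(slike.begin(), slike.end());
    lk.attr("dim") = IntegerVector::create(n, n, K);
    auto mat = [&](std::vector<double>& v) {
      NumericMatrix m(n, K);
      std::copy(v.begin(), v.end(), m.begin());
      return m;  // column k = sample k
    };
    NumericMatrix likef(n, n);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) likef(i, j) = like(i, j);
    return List::create(
        _["events"] = events, _["sample_x"] = mat(sx), _["sample_y"] = mat(sy),
        _["sample_arousal"] = mat(sar), _["sample_anxiety"] = mat(sanx),
        _["sample_satisfaction"] = mat(ssat), _["sample_like"] = lk,
        _["like_final"] = likef, _["record_start"] = record_start,
        _["record_end"] = record_end, _["n_samples"] = ksample);
  }
};

// [[Rcpp::export]]
List cpp_run_engine(NumericVector par, NumericVector dom, NumericMatrix fear,
                    NumericMatrix like0, NumericMatrix pos0,
                    NumericVector heading0, NumericVector t0,
                    NumericMatrix salience, bool record_events) {
  Par P = fill_par(par);
  if (salience.nrow() != N_SAL || salience.ncol() != 2)
    stop("salience table must be %d x 2", (int)N_SAL);
  Engine eng(P, fear, like0, salience, dom, pos0, heading0, record_events);
  return eng.run(t0);
}
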