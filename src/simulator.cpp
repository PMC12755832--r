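// Event-driven core of the mixed-acuity ED simulator.
//
// The dispatch logic lives here in one place: the same selection routine is
// used inside the event loop and exposed to R (cpp_select_next) so that the
// policy surface tested from R is byte-for-byte the one the simulator runs.
//
// Conventions: time in minutes from the start of the run; physician ids are
// 0-based internally and exposed 0-based to R as well; ESI levels are 1..5.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// base rules
enum BaseRule { BASE_FCFS = 0, BASE_ACUITY_FCFS = 1, BASE_APQ = 2, BASE_AAPQ = 3 };
// add-ons
enum Addon { ADDON_PFT = 0, ADDON_LWP = 1 };

struct Policy {
  int base;
  std::vector<int> addons;
  double w[6];       // acuity weight indexed by ESI level (1..5)
  double epsilon;    // AAPQ elapsed-time scale (per minute)
  double lwp_delta;  // load-imbalance trigger (patients)
  int pft_physician; // designated fast-track physician (0-based)
};

static Policy parse_policy(const List& pol) {
  Policy p;
  p.base = as<int>(pol["base_code"]);
  IntegerVector ad = pol["addon_codes"];
  p.addons.assign(ad.begin(), ad.end());
  NumericVector w = pol["weights"]; // length 5, index esi-1
  for (int i = 0; i < 6; ++i) p.w[i] = 0.0;
  for (int i = 0; i < 5; ++i) p.w[i + 1] = w[i];
  p.epsilon = as<double>(pol["aapq_epsilon"]);
  p.lwp_delta = as<double>(pol["lwp_delta"]);
  p.pft_physician = as<int>(pol["pft_physician"]);
  return p;
}

struct Waiting {
  int pid;
  int esi;
  double arrival;
};

// ties everywhere: earlier arrival, then lower patient id
static bool earlier(const Waiting& a, const Waiting& b) {
  if (a.arrival != b.arrival) return a.arrival < b.arrival;
  return a.pid < b.pid;
}

// index of the patient the base rule would pick; -1 if queue empty
static int base_pick(const Policy& p, const std::vector<Waiting>& q, double now) {
  if (q.empty()) return -1;
  int best = 0;
  for (size_t i = 1; i < q.size(); ++i) {
    const Waiting& a = q[i];
    const Waiting& b = q[best];
    bool take = false;
    switch (p.base) {
    case BASE_FCFS:
      take = earlier(a, b);
      break;
    case BASE_ACUITY_FCFS:
      if (a.esi != b.esi) take = a.esi < b.esi; else take = earlier(a, b);
      break;
    case BASE_APQ: {
      double sa = p.w[a.esi] * (now - a.arrival);
      double sb = p.w[b.esi] * (now - b.arrival);
      if (sa != sb) take = sa > sb; else take = earlier(a, b);
      break;
    }
    case BASE_AAPQ: {
      double sa = p.w[a.esi] + p.epsilon * (now - a.arrival);
      double sb = p.w[b.esi] + p.epsilon * (now - b.arrival);
      if (sa != sb) take = sa > sb; else take = earlier(a, b);
      break;
    }
    }
    if (take) best = (int)i;
  }
  return best;
}

// Rotational default assignment: scan cyclically from (patient_id mod n)
// for a physician with spare capacity; -1 if none. Balanced in expectation
// (like a charge nurse rotating assignments) but drifts under heterogeneous
// service times — the imbalance the LWP add-on exists to correct. Stateless,
// so the dispatch decision is a pure function of the queue snapshot.
static int default_physician(const std::vector<int>& loads, int capacity,
                             int pid) {
  int n = (int)loads.size();
  if (n == 0) return -1;
  int start = ((pid % n) + n) % n;
  for (int k = 0; k < n; ++k) {
    int j = (start + k) % n;
    if (loads[j] < capacity) return j;
  }
  return -1;
}

// Full dispatch decision. Returns true and fills (qi, phys) when a patient
// can start service now; order of checks: ESI-1 override, add-ons in their
// configured order, then the base rule.
static bool select_next(const Policy& p, const std::vector<Waiting>& q,
                        double now, const std::vector<int>& loads,
                        int capacity, int free_beds,
                        int& qi, int& phys) {
  if (free_beds <= 0 || q.empty()) return false;
  bool any_free = false;
  for (size_t j = 0; j < loads.size(); ++j)
    if (loads[j] < capacity) { any_free = true; break; }
  if (!any_free) return false;

  // resuscitation-level arrivals jump every queue
  int esi1 = -1;
  for (size_t i = 0; i < q.size(); ++i) {
    if (q[i].esi == 1 && (esi1 < 0 || earlier(q[i], q[esi1]))) esi1 = (int)i;
  }
  if (esi1 >= 0) {
    qi = esi1;
    phys = default_physician(loads, capacity, q[esi1].pid);
    return true;
  }

  for (size_t k = 0; k < p.addons.size(); ++k) {
    if (p.addons[k] == ADDON_PFT) {
      // negative id = designate the last physician on the roster
      int d = p.pft_physician >= 0 ? p.pft_physician : (int)loads.size() - 1;
      if (d >= 0 && d < (int)loads.size() && loads[d] < capacity) {
        int low = -1;
        for (size_t i = 0; i < q.size(); ++i) {
          if (q[i].esi >= 4 && (low < 0 || earlier(q[i], q[low]))) low = (int)i;
        }
        if (low >= 0) { qi = low; phys = d; return true; }
      }
    } else if (p.addons[k] == ADDON_LWP) {
      int n = (int)loads.size();
      if (n >= 2) {
        int pmin = 0;
        for (int j = 1; j < n; ++j) if (loads[j] < loads[pmin]) pmin = j;
        double sum = 0; for (int j = 0; j < n; ++j) sum += loads[j];
        double mean_others = (sum - loads[pmin]) / (n - 1);
        if (mean_others - loads[pmin] >= p.lwp_delta && loads[pmin] < capacity) {
          int pick = base_pick(p, q, now);
          if (pick >= 0) { qi = pick; phys = pmin; return true; }
        }
      }
    }
  }

  int pick = base_pick(p, q, now);
  if (pick < 0) return false;
  qi = pick;
  phys = default_physician(loads, capacity, q[pick].pid);
  return true;
}

// [[Rcpp::export]]
SEXP cpp_select_next(List policy, IntegerVector patient_id, IntegerVector esi,
                     NumericVector arrival_time, double now,
                     IntegerVector physician_loads, int capacity, int free_beds) {
  Policy p = parse_policy(policy);
  std::vector<Waiting> q(patient_id.size());
  for (int i = 0; i < patient_id.size(); ++i) {
    q[i].pid = patient_id[i];
    q[i].esi = esi[i];
    q[i].arrival = arrival_time[i];
  }
  std::vector<int> loads(physician_loads.begin(), physician_loads.end());
  int qi = -1, phys = -1;
  if (!select_next(p, q, now, loads, capacity, free_beds, qi, phys))
    return R_NilValue;
  return List::create(_["patient_id"] = q[qi].pid, _["physician_id"] = phys);
}

// ---- service-time sampling ------------------------------------------------

enum ServiceFamily { SVC_LOGNORMAL = 0, SVC_EXPONENTIAL = 1, SVC_FIXED = 2 };

static double draw_service(int family, double p1, double p2, double floor_min) {
  double x;
  switch (family) {
  case SVC_LOGNORMAL:   x = R::rlnorm(p1, p2); break; // p1 meanlog, p2 sdlog
  case SVC_EXPONENTIAL: x = R::rexp(p1);       break; // p1 = mean (scale)
  case SVC_FIXED:       x = p1;                break;
  default: stop("unknown service family code");
  }
  return x < floor_min ? floor_min : x;
}

// [[Rcpp::export]]
NumericVector cpp_sample_service(int n, int family, double p1, double p2,
                                 double floor_min) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_service(family, p1, p2, floor_min);
  return out;
}

// ---- arrival process ------------------------------------------------------

// Stationary Poisson, or piecewise-constant daily profile via thinning.
struct ArrivalGen {
  double rate;               // per minute (stationary)
  std::vector<double> prof;  // per-minute rate by hour of day (size 24) or empty
  double rmax;
  ArrivalGen(double r, const std::vector<double>& profile)
    : rate(r), prof(profile) {
    rmax = rate;
    for (size_t i = 0; i < prof.size(); ++i) if (prof[i] > rmax) rmax = prof[i];
  }
  double rate_at(double t) const {
    if (prof.empty()) return rate;
    int hour = (int)(((long long)std::floor(t / 60.0)) % 24);
    return prof[hour];
  }
  double next(double now) const {
    double t = now;
    for (;;) {
      t += R::rexp(1.0 / rmax);
      if (prof.empty()) return t;
      if (R::unif_rand() < rate_at(t) / rmax) return t;
    }
  }
};

static int draw_esi(const NumericVector& mix) {
  double u = R::unif_rand(), c = 0.0;
  for (int i = 0; i < 5; ++i) { c += mix[i]; if (u < c) return i + 1; }
  return 5;
}

// [[Rcpp::export]]
DataFrame cpp_generate_arrivals(double rate_per_min, NumericVector rate_profile,
                                NumericVector esi_mix, double horizon) {
  std::vector<double> prof(rate_profile.begin(), rate_profile.end());
  ArrivalGen gen(rate_per_min, prof);
  std::vector<double> times;
  std::vector<int> esis;
  double t = gen.next(0.0);
  while (t <= horizon) {
    times.push_back(t);
    esis.push_back(draw_esi(esi_mix));
    t = gen.next(t);
  }
  return DataFrame::create(_["time"] = times, _["esi"] = esis);
}

// ---- event loop -----------------------------------------------------------

struct Event {
  double t;
  int type; // 0 departure, 1 arrival (departures first on ties)
  int pid;
};
struct EventLater {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.type != b.type) return a.type > b.type;
    return a.pid > b.pid;
  }
};

// [[Rcpp::export]]
List cpp_simulate(List config, List policy) {
  Policy pol = parse_policy(policy);
  int n_beds = as<int>(config["n_beds"]);
  int n_phys = as<int>(config["n_physicians"]);
  int capacity = as<int>(config["physician_capacity"]);
  double rate = as<double>(config["arrival_rate_per_min"]);
  NumericVector rate_profile = config["rate_profile_per_min"]; // len 0 or 24
  NumericVector esi_mix = config["esi_mix"];
  IntegerVector svc_family = config["service_family"]; // length 5
  NumericVector svc_p1 = config["service_p1"];
  NumericVector svc_p2 = config["service_p2"];
  double floor_min = as<double>(config["service_floor"]);
  double kappa = as<double>(config["workload_sensitivity"]);
  double horizon = as<double>(config["horizon"]);

  std::vector<double> prof(rate_profile.begin(), rate_profile.end());
  ArrivalGen gen(rate, prof);

  std::priority_queue<Event, std::vector<Event>, EventLater> ev;
  std::vector<Waiting> q;
  std::vector<int> loads(n_phys, 0);
  int free_beds = n_beds;

  std::vector<int> p_esi;
  std::vector<double> p_arr, p_start, p_dep;
  std::vector<int> p_phys;

  double t0 = gen.next(0.0);
  if (t0 <= horizon) {
    Event e; e.t = t0; e.type = 1; e.pid = -1;
    ev.push(e);
  }

  while (!ev.empty()) {
    Event e = ev.top(); ev.pop();
    if (e.t > horizon) break; // clock stops: still-in-system patients are censored
    double now = e.t;
    if (e.type == 1) { // arrival
      int pid = (int)p_esi.size();
      int esi = draw_esi(esi_mix);
      p_esi.push_back(esi);
      p_arr.push_back(now);
      p_start.push_back(NA_REAL);
      p_dep.push_back(NA_REAL);
      p_phys.push_back(NA_INTEGER);
      Waiting w; w.pid = pid; w.esi = esi; w.arrival = now;
      q.push_back(w);
      double tn = gen.next(now);
      if (tn <= horizon) { Event a; a.t = tn; a.type = 1; a.pid = -1; ev.push(a); }
    } else { // departure
      int pid = e.pid;
      loads[p_phys[pid]] -= 1;
      free_beds += 1;
      p_dep[pid] = now;
    }
    // dispatch everyone who can start service at this epoch
    int qi, phys;
    while (select_next(pol, q, now, loads, capacity, free_beds, qi, phys)) {
      int pid = q[qi].pid;
      int fam = svc_family[p_esi[pid] - 1];
      double svc = draw_service(fam, svc_p1[p_esi[pid] - 1],
                                svc_p2[p_esi[pid] - 1], floor_min);
      // a physician's attention is shared across concurrent patients:
      // service slows with the load found at service start
      if (capacity > 1 && kappa > 0.0)
        svc *= 1.0 + kappa * (double)loads[phys] / (double)(capacity - 1);
      p_start[pid] = now;
      p_phys[pid] = phys;
      loads[phys] += 1;
      free_beds -= 1;
      q.erase(q.begin() + qi);
      Event d; d.t = now + svc; d.type = 0; d.pid = pid;
      ev.push(d);
    }
  }

  int n = (int)p_esi.size();
  IntegerVector out_pid(n), out_esi(n), out_phys(n);
  NumericVector out_arr(n), out_start(n), out_dep(n);
  for (int i = 0; i < n; ++i) {
    out_pid[i] = i + 1;
    out_esi[i] = p_esi[i];
    out_arr[i] = p_arr[i];
    out_start[i] = p_start[i];
    out_dep[i] = p_dep[i];
    out_phys[i] = p_phys[i];
  }
  return List::create(
    _["patient_id"] = out_pid, _["esi"] = out_esi,
    _["arrival_time"] = out_arr, _["service_start"] = out_start,
    _["departure_time"] = out_dep, _["physician_id"] = out_phys,
    _["n_arrivals"] = n);
}
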