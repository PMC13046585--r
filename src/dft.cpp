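// Decision Field Theory-Planning simulator core.
//
// A tree is passed as flat arrays (see encode_tree() on the R side):
//   type:  0 = outcome node (ON), 1 = chance node (CN), 2 = decision node
//   value: outcome value (ONs only)
//   ks/kn: child-offset and child-count into kids/probs
// Children are in the order stored on the R object; choice indices refer
// to that order.  Uses R's RNG so seeding from R controls all draws.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct TreeView {
  const int *type;
  const double *value;
  const int *ks;
  const int *kn;
  const int *kids;
  const double *probs;
};

struct Params {
  double theta_plan;
  double theta_final;
  double phi;
  double delta;
  double dd_lo, dd_hi;
  int max_steps;
};

struct Counters {
  long steps = 0;
  long forced = 0;
};

int sim_decision(const TreeView &tr, int dn, bool planning, bool plan_dn2,
                 const Params &p, Counters &ct, int *steps_out);

// One mental simulation of `node`'s eventual outcome.  `entry` marks the
// start of an alternative's simulation within a deliberation step; only
// there can a daydream replace the whole draw.
double sim_outcome(const TreeView &tr, int node, bool planning, bool plan_dn2,
                   bool entry, const Params &p, Counters &ct) {
  if (entry && p.delta > 0 && unif_rand() < p.delta)
    return p.dd_lo + unif_rand() * (p.dd_hi - p.dd_lo);
  int t = tr.type[node];
  if (t == 0) return tr.value[node];
  int off = tr.ks[node], n = tr.kn[node];
  if (t == 1) {  // chance node
    // magnitude-biased sampling: planning mode, two-outcome terminal CN
    if (planning && n == 2 && tr.type[tr.kids[off]] == 0 &&
        tr.type[tr.kids[off + 1]] == 0) {
      double v0 = std::fabs(tr.value[tr.kids[off]]);
      double v1 = std::fabs(tr.value[tr.kids[off + 1]]);
      int hi = (v1 > v0) ? 1 : 0;
      int pick = (unif_rand() < p.phi) ? hi : 1 - hi;
      return tr.value[tr.kids[off + pick]];
    }
    double u = unif_rand(), acc = 0;
    int pick = n - 1;
    for (int k = 0; k < n; ++k) {
      acc += tr.probs[off + k];
      if (u < acc) { pick = k; break; }
    }
    return sim_outcome(tr, tr.kids[off + pick], planning, plan_dn2, false, p,
                       ct);
  }
  // decision node encountered mid-simulation (a future DN2)
  int choice;
  if (plan_dn2) {
    int st = 0;
    choice = sim_decision(tr, node, true, plan_dn2, p, ct, &st);
  } else {
    choice = (unif_rand() < 0.5) ? 0 : 1;  // rho2 = .50: flip a coin
  }
  return sim_outcome(tr, tr.kids[off + choice], planning, plan_dn2, false, p,
                     ct);
}

// Accumulate valences V = nu_i - nu_j until |P| reaches the mode's
// threshold.  Returns 0 (first-listed child) or 1.
int sim_decision(const TreeView &tr, int dn, bool planning, bool plan_dn2,
                 const Params &p, Counters &ct, int *steps_out) {
  int off = tr.ks[dn];
  double theta = planning ? p.theta_plan : p.theta_final;
  double P = 0;
  for (int step = 1; step <= p.max_steps; ++step) {
    double a = sim_outcome(tr, tr.kids[off], planning, plan_dn2, true, p, ct);
    double b =
        sim_outcome(tr, tr.kids[off + 1], planning, plan_dn2, true, p, ct);
    P += a - b;
    ct.steps += 1;
    if (P >= theta || P <= -theta) {
      *steps_out = step;
      return (P > 0) ? 0 : 1;
    }
  }
  ct.forced += 1;
  *steps_out = p.max_steps;
  if (P > 0) return 0;
  if (P < 0) return 1;
  return (unif_rand() < 0.5) ? 0 : 1;
}

TreeView view(const IntegerVector &type, const NumericVector &value,
              const IntegerVector &ks, const IntegerVector &kn,
              const IntegerVector &kids, const NumericVector &probs) {
  TreeView tr;
  tr.type = type.begin();
  tr.value = value.begin();
  tr.ks = ks.begin();
  tr.kn = kn.begin();
  tr.kids = kids.begin();
  tr.probs = probs.begin();
  return tr;
}

Params params_of(const List &par) {
  Params p;
  p.theta_plan = as<double>(par["theta_plan"]);
  p.theta_final = as<double>(par["theta_final"]);
  p.phi = as<double>(par["phi"]);
  p.delta = as<double>(par["delta"]);
  NumericVector r = par["daydream_range"];
  p.dd_lo = r[0];
  p.dd_hi = r[1];
  p.max_steps = as<int>(par["max_steps"]);
  return p;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_sim_outcomes(IntegerVector type, NumericVector value,
                               IntegerVector ks, IntegerVector kn,
                               IntegerVector kids, NumericVector probs,
                               int node, bool planning, bool plan_dn2,
                               List par, int n) {
  TreeView tr = view(type, value, ks, kn, kids, probs);
  Params p = params_of(par);
  Counters ct;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = sim_outcome(tr, node, planning, plan_dn2, true, p, ct);
  return out;
}

// [[Rcpp::export]]
List cpp_sim_decisions(IntegerVector type, NumericVector value,
                       IntegerVector ks, IntegerVector kn, IntegerVector kids,
                       NumericVector probs, int dn, bool planning,
                       bool plan_dn2, List par, int n) {
  TreeView tr = view(type, value, ks, kn, kids, probs);
  Params p = params_of(par);
  Counters ct;
  IntegerVector choice(n), steps(n);
  for (int i = 0; i < n; ++i) {
    int st = 0;
    choice[i] = sim_decision(tr, dn, planning, plan_dn2, p, ct, &st);
    steps[i] = st;
  }
  return List::create(_["choice"] = choice, _["steps"] = steps,
                      _["forced"] = (double)ct.forced);
}

// Per-step trace of a single deliberation (debugging interface):
// columns nu_i, nu_j, V, P.
// [[Rcpp::export]]
List cpp_sim_decision_trace(IntegerVector type, NumericVector value,
                            IntegerVector ks, IntegerVector kn,
                            IntegerVector kids, NumericVector probs, int dn,
                            bool planning, bool plan_dn2, List par) {
  TreeView tr = view(type, value, ks, kn, kids, probs);
  Params p = params_of(par);
  Counters ct;
  int off = tr.ks[dn];
  double theta = planning ? p.theta_plan : p.theta_final;
  std::vector<double> ni, nj, vv, pp;
  double P = 0;
  int choice = -1;
  for (int step = 1; step <= p.max_steps; ++step) {
    double a = sim_outcome(tr, tr.kids[off], planning, plan_dn2, true, p, ct);
    double b =
        sim_outcome(tr, tr.kids[off + 1], planning, plan_dn2, true, p, ct);
    P += a - b;
    ni.push_back(a);
    nj.push_back(b);
    vv.push_back(a - b);
    pp.push_back(P);
    if (P >= theta || P <= -theta) {
      choice = (P > 0) ? 0 : 1;
      break;
    }
  }
  if (choice < 0)
    choice = (P > 0) ? 0 : (P < 0 ? 1 : (unif_rand() < 0.5 ? 0 : 1));
  return List::create(_["choice"] = choice, _["nu_i"] = wrap(ni),
                      _["nu_j"] = wrap(nj), _["V"] = wrap(vv),
                      _["P"] = wrap(pp));
}
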