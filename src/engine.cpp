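// Agent-based population engine for single-cell CRISPR-Cas kinetics.
//
// Constant-size population of exponentially growing cells advanced by a
// first-division scheduling loop; per-cell reaction kinetics sampled
// exactly by thinning against a propensity upper bound (the propensities
// of this network are state-only, so the bound B = headroom * a0 is
// always valid and thinning is exact). Uses R's RNG throughout so runs
// are bit-reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// species indices
enum { iP = 0, iC, iR, iRs, iE, iEs, iEP, iEsP, iF, iY, NSPEC };
// reaction channels
enum { rBurst = 0, rCrR, rCrRs, rAsmE, rAsmEs, rBindE, rBindEs,
       rDegEP, rDegEsP, rDecR, rDecRs, rDecF, rInt, rRep, rRep2_unused,
       NREACT_ };
static const int NREACT = 15;  // 0..13 used + reporter at 14
static const int rRepo = 14;

struct Kin {
  double k1, b_c, a, k_r, d_r, k_a, k_on, fold, k_deg, d_f, k_int,
         k_rep, p_s, k_y;
  int n_f;
};

struct Cell {
  int gid;
  long st[NSPEC];
  int astar;
  double mu, vb, vd, t_birth, t_div;  // absolute times
  double t_adapt;                     // -1 if no integration in lineage
  bool lost;
  double t_loss;
};

static inline long targets_total(const Cell& c) {
  return c.st[iP] + c.st[iEP] + c.st[iEsP];
}

static inline void propensities(const Cell& c, const Kin& k, double* a) {
  a[rBurst]  = k.k1 / k.a;
  a[rCrR]    = k.k_r;
  a[rCrRs]   = k.k_r * c.astar;
  a[rAsmE]   = k.k_a * c.st[iC] * c.st[iR];
  a[rAsmEs]  = k.k_a * c.st[iC] * c.st[iRs];
  a[rBindE]  = k.k_on * c.st[iE] * c.st[iP];
  a[rBindEs] = k.fold * k.k_on * c.st[iEs] * c.st[iP];
  a[rDegEP]  = k.k_deg * c.st[iEP];
  a[rDegEsP] = k.k_deg * c.st[iEsP];
  a[rDecR]   = k.d_r * c.st[iR];
  a[rDecRs]  = k.d_r * c.st[iRs];
  a[rDecF]   = k.d_f * c.st[iF];
  a[rInt]    = k.k_int * c.st[iF] * (1 - c.astar);
  double T   = (double) targets_total(c);
  double rep = k.k_rep * T * (1.0 - T / k.p_s);
  a[rRep]    = rep > 0 ? rep : 0.0;
  a[rRepo]   = k.k_y * c.st[iP];
}

struct EventRec { int kind; int gid; double time; };
struct LossRec { int gid; double time; double t_adapt; };

struct Archive {
  std::vector<int> parent;
  std::vector<double> t_birth, mu, vb, vd, t_end;
  std::vector<int> fate;  // 0 alive, 1 divided, 2 culled
  std::vector<std::vector<long> > rcount;
  int add(int par, double tb, double mu_, double vb_, double vd_) {
    parent.push_back(par); t_birth.push_back(tb); mu.push_back(mu_);
    vb.push_back(vb_); vd.push_back(vd_); t_end.push_back(NA_REAL);
    fate.push_back(0);
    rcount.push_back(std::vector<long>(NREACT, 0));
    return (int) parent.size() - 1;
  }
};

// advance one cell's chemistry over dt minutes by thinning; fires
// integration/loss bookkeeping; returns number of accepted events
static long advance_cell(Cell& c, double t0, double dt, const Kin& k,
                         double headroom, Archive& arch,
                         std::vector<EventRec>& events,
                         std::vector<LossRec>& losses,
                         bool log_events, long max_events) {
  double a[NREACT];
  double tau = 0.0;
  long n_acc = 0, n_iter = 0;
  for (;;) {
    propensities(c, k, a);
    double a0 = 0.0;
    for (int i = 0; i < NREACT; ++i) a0 += a[i];
    if (a0 <= 0.0) break;
    double B = headroom * a0;
    for (;;) {
      if (++n_iter > max_events)
        stop("runaway event rate: more than %ld candidate events in one "
             "advance step (cell gid %d, a0 = %g); check rate parameters",
             max_events, c.gid, a0);
      tau += R::rexp(1.0 / B);
      if (tau >= dt) return n_acc;
      double u = R::runif(0.0, B);
      if (u <= a0) {
        // select channel
        double cum = 0.0;
        int ch = NREACT - 1;
        for (int i = 0; i < NREACT; ++i) {
          cum += a[i];
          if (u <= cum) { ch = i; break; }
        }
        double tnow = t0 + tau;
        switch (ch) {
        case rBurst: {
          double m = k.a * k.b_c;
          long sz = 1 + (m > 1.0 ? (long) R::rgeom(1.0 / m) : 0);
          c.st[iC] += sz;
          break; }
        case rCrR:    c.st[iR] += 1; break;
        case rCrRs:   c.st[iRs] += 1; break;
        case rAsmE:   c.st[iC] -= 1; c.st[iR] -= 1; c.st[iE] += 1; break;
        case rAsmEs:  c.st[iC] -= 1; c.st[iRs] -= 1; c.st[iEs] += 1; break;
        case rBindE:  c.st[iE] -= 1; c.st[iP] -= 1; c.st[iEP] += 1; break;
        case rBindEs: c.st[iEs] -= 1; c.st[iP] -= 1; c.st[iEsP] += 1; break;
        case rDegEP:  c.st[iEP] -= 1; c.st[iE] += 1; c.st[iF] += k.n_f; break;
        case rDegEsP: c.st[iEsP] -= 1; c.st[iEs] += 1; c.st[iF] += k.n_f; break;
        case rDecR:   c.st[iR] -= 1; break;
        case rDecRs:  c.st[iRs] -= 1; break;
        case rDecF:   c.st[iF] -= 1; break;
        case rInt:
          c.st[iF] -= 1; c.astar = 1;
          if (c.t_adapt < 0) c.t_adapt = tnow;
          events.push_back(EventRec{3, c.gid, tnow});
          break;
        case rRep:    c.st[iP] += 1; break;
        case rRepo:   c.st[iY] += 1; break;
        }
        arch.rcount[c.gid][ch] += 1;
        ++n_acc;
        if (!c.lost && targets_total(c) == 0) {
          c.lost = true; c.t_loss = tnow;
          losses.push_back(LossRec{c.gid, tnow, c.t_adapt});
          events.push_back(EventRec{4, c.gid, tnow});
        }
        break;  // propensities changed; recompute
      }
      // thinned: state unchanged, bound still valid, keep drawing
    }
  }
  return n_acc;
}

static double draw_ratio(double vr_mean, double vr_sd) {
  for (int i = 0; i < 1000; ++i) {
    double r = R::rnorm(vr_mean, vr_sd);
    if (r > 0.1 && r < 0.9) return r;
  }
  return vr_mean;
}

static void assign_growth(Cell& c, double mu_ml, double mu_sl,
                          double vd_ml, double vd_sl) {
  c.mu = R::rlnorm(mu_ml, mu_sl);
  c.vd = R::rlnorm(vd_ml, vd_sl);
  int guard = 0;
  while (c.vd <= c.vb * 1.05 && ++guard < 100)
    c.vd = R::rlnorm(vd_ml, vd_sl);
  if (c.vd <= c.vb * 1.05) c.vd = c.vb * 2.0;
}

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix init_state, IntegerVector init_astar,
                  NumericVector init_mu, NumericVector init_vb,
                  NumericVector init_vd, NumericVector init_age,
                  List kin_in, List growth_in, double t_final,
                  double record_interval, bool stop_when_cleared,
                  bool freeze_cleared, double headroom,
                  double max_events_per_step) {
  const int N = init_state.nrow();
  if (init_state.ncol() != NSPEC) stop("state matrix must have %d columns", NSPEC);

  Kin k;
  k.k1 = as<double>(kin_in["k1"]);     k.b_c = as<double>(kin_in["b_c"]);
  k.a = as<double>(kin_in["a"]);       k.k_r = as<double>(kin_in["k_r"]);
  k.d_r = as<double>(kin_in["d_r"]);   k.k_a = as<double>(kin_in["k_a"]);
  k.k_on = as<double>(kin_in["k_on_low"]);
  k.fold = as<double>(kin_in["fold_consensus"]);
  k.k_deg = as<double>(kin_in["k_deg"]); k.n_f = as<int>(kin_in["n_f"]);
  k.d_f = as<double>(kin_in["d_f"]);   k.k_int = as<double>(kin_in["k_int"]);
  k.k_rep = as<double>(kin_in["k_rep"]); k.p_s = as<double>(kin_in["p_s"]);
  k.k_y = as<double>(kin_in["k_y"]);

  double mu_ml = as<double>(growth_in["mu_meanlog"]);
  double mu_sl = as<double>(growth_in["mu_sdlog"]);
  double vd_ml = as<double>(growth_in["vd_meanlog"]);
  double vd_sl = as<double>(growth_in["vd_sdlog"]);
  double vr_mean = as<double>(growth_in["mu_vr"]);
  double vr_sd = as<double>(growth_in["sigma_vr"]);

  Archive arch;
  std::vector<EventRec> events;
  std::vector<LossRec> losses;
  std::vector<Cell> pop(N);

  for (int i = 0; i < N; ++i) {
    Cell& c = pop[i];
    for (int s = 0; s < NSPEC; ++s) c.st[s] = (long) init_state(i, s);
    c.astar = init_astar[i];
    c.mu = init_mu[i]; c.vb = init_vb[i]; c.vd = init_vd[i];
    double tgen = std::log(c.vd / c.vb) / c.mu;
    c.t_birth = -init_age[i];
    c.t_div = c.t_birth + tgen;
    c.t_adapt = -1.0;
    c.lost = targets_total(c) == 0;
    c.t_loss = c.lost ? 0.0 : -1.0;
    c.gid = arch.add(-1, c.t_birth, c.mu, c.vb, c.vd);
    if (c.lost) losses.push_back(LossRec{c.gid, 0.0, -1.0});
  }

  // series buffers
  std::vector<double> ser_time, ser_size;
  std::vector<int> ser_gid;
  std::vector<std::vector<long> > ser_st(NSPEC);
  bool record = record_interval > 0;
  double next_rec = 0.0;

  double t = 0.0;
  long max_ev = (long) max_events_per_step;

  auto snapshot = [&](double tt) {
    for (int i = 0; i < N; ++i) {
      const Cell& c = pop[i];
      ser_time.push_back(tt);
      ser_gid.push_back(c.gid + 1);  // 1-based, matching the cells table
      ser_size.push_back(c.vb * std::exp(c.mu * (tt - c.t_birth)));
      for (int s = 0; s < NSPEC; ++s) ser_st[s].push_back(c.st[s]);
    }
  };

  if (record) { snapshot(0.0); next_rec = record_interval; }

  while (t < t_final) {
    // next dividing cell
    int j = 0;
    for (int i = 1; i < N; ++i) if (pop[i].t_div < pop[j].t_div) j = i;
    double t_next = std::min(pop[j].t_div, t_final);
    bool rec_stop = false;
    if (record && next_rec < t_next) { t_next = next_rec; rec_stop = true; }
    double dt = t_next - t;

    if (dt > 0) {
      for (int i = 0; i < N; ++i) {
        if (freeze_cleared && pop[i].lost) continue;
        advance_cell(pop[i], t, dt, k, headroom, arch, events, losses,
                     false, max_ev);
      }
      t = t_next;
    } else {
      t = t_next;
    }

    if (rec_stop) { snapshot(t); next_rec += record_interval; continue; }
    if (t >= t_final) break;

    // division of cell j at time t
    Cell mother = pop[j];
    arch.fate[mother.gid] = 1;
    arch.t_end[mother.gid] = t;
    events.push_back(EventRec{1, mother.gid, t});

    double r1 = draw_ratio(vr_mean, vr_sd);
    Cell d1, d2;
    d1.vb = r1 * mother.vd; d2.vb = mother.vd - d1.vb;
    d1.t_birth = d2.t_birth = t;
    d1.astar = d2.astar = mother.astar;
    d1.t_adapt = d2.t_adapt = mother.t_adapt;
    // proteins: binomial with probability = daughter-1 size fraction
    for (int s = 0; s < NSPEC; ++s) { d1.st[s] = 0; d2.st[s] = 0; }
    int prot[] = { iC, iR, iRs, iE, iEs, iF, iY };
    for (int pi = 0; pi < 7; ++pi) {
      int s = prot[pi];
      long n = mother.st[s];
      long x1 = n > 0 ? (long) R::rbinom((double) n, r1) : 0;
      d1.st[s] = x1; d2.st[s] = n - x1;
    }
    // targets and target-containing complexes: daughter 1 receives
    // K = round-stochastic(n_tot * r1) entities, species assigned by a
    // multivariate hypergeometric draw
    {
      long P = mother.st[iP], EP = mother.st[iEP], EsP = mother.st[iEsP];
      long ntot = P + EP + EsP;
      double kf = ntot * r1;
      long K = (long) std::floor(kf);
      if (R::unif_rand() < kf - std::floor(kf)) K += 1;
      if (K > ntot) K = ntot;
      long kP = 0, kEP = 0;
      if (K > 0) {
        kP = (long) R::rhyper((double) P, (double) (ntot - P), (double) K);
        if (K - kP > 0)
          kEP = (long) R::rhyper((double) EP, (double) EsP, (double) (K - kP));
      }
      long kEsP = K - kP - kEP;
      d1.st[iP] = kP; d1.st[iEP] = kEP; d1.st[iEsP] = kEsP;
      d2.st[iP] = P - kP; d2.st[iEP] = EP - kEP; d2.st[iEsP] = EsP - kEsP;
    }
    assign_growth(d1, mu_ml, mu_sl, vd_ml, vd_sl);
    assign_growth(d2, mu_ml, mu_sl, vd_ml, vd_sl);
    d1.t_div = t + std::log(d1.vd / d1.vb) / d1.mu;
    d2.t_div = t + std::log(d2.vd / d2.vb) / d2.mu;
    d1.gid = arch.add(mother.gid, t, d1.mu, d1.vb, d1.vd);
    d2.gid = arch.add(mother.gid, t, d2.mu, d2.vb, d2.vd);
    // a daughter can inherit zero targets even though the mother still
    // had targets: clearance by unequal partitioning
    for (Cell* d : { &d1, &d2 }) {
      d->lost = mother.lost;
      d->t_loss = mother.t_loss;
      if (!mother.lost && targets_total(*d) == 0) {
        d->lost = true; d->t_loss = t;
        losses.push_back(LossRec{d->gid, t, d->t_adapt});
        events.push_back(EventRec{4, d->gid, t});
      }
    }

    // replace mother by daughter 1, append daughter 2, cull one of N+1
    pop[j] = d1;
    pop.push_back(d2);
    int cull = (int) std::floor(R::unif_rand() * (N + 1));
    if (cull > N) cull = N;
    arch.fate[pop[cull].gid] = 2;
    arch.t_end[pop[cull].gid] = t;
    events.push_back(EventRec{2, pop[cull].gid, t});
    pop[cull] = pop[N];
    pop.pop_back();

    if (stop_when_cleared) {
      bool all_lost = true;
      for (int i = 0; i < N; ++i)
        if (!pop[i].lost) { all_lost = false; break; }
      if (all_lost) break;
    }
  }

  // mark survivors alive
  int ncell = (int) arch.parent.size();
  IntegerVector a_parent(ncell), a_fate(ncell);
  NumericVector a_tb(ncell), a_mu(ncell), a_vb(ncell), a_vd(ncell),
                a_tend(ncell);
  for (int i = 0; i < ncell; ++i) {
    a_parent[i] = arch.parent[i] < 0 ? NA_INTEGER : arch.parent[i] + 1;
    a_tb[i] = arch.t_birth[i]; a_mu[i] = arch.mu[i];
    a_vb[i] = arch.vb[i]; a_vd[i] = arch.vd[i];
    a_fate[i] = arch.fate[i]; a_tend[i] = arch.t_end[i];
  }
  DataFrame cells = DataFrame::create(
    _["cell"] = seq_len(ncell), _["parent"] = a_parent,
    _["t_birth"] = a_tb, _["t_end"] = a_tend, _["mu"] = a_mu,
    _["v_birth"] = a_vb, _["v_div"] = a_vd, _["fate"] = a_fate);

  int nl = (int) losses.size();
  IntegerVector l_gid(nl); NumericVector l_t(nl), l_ta(nl);
  for (int i = 0; i < nl; ++i) {
    l_gid[i] = losses[i].gid + 1; l_t[i] = losses[i].time;
    l_ta[i] = losses[i].t_adapt < 0 ? NA_REAL : losses[i].t_adapt;
  }
  DataFrame lossdf = DataFrame::create(
    _["cell"] = l_gid, _["t_loss"] = l_t, _["t_adapt"] = l_ta);

  int ne = (int) events.size();
  IntegerVector e_kind(ne), e_gid(ne); NumericVector e_t(ne);
  for (int i = 0; i < ne; ++i) {
    e_kind[i] = events[i].kind; e_gid[i] = events[i].gid + 1;
    e_t[i] = events[i].time;
  }
  DataFrame eventdf = DataFrame::create(
    _["cell"] = e_gid, _["time"] = e_t, _["kind"] = e_kind);

  IntegerMatrix counts(ncell, NREACT);
  for (int i = 0; i < ncell; ++i)
    for (int rch = 0; rch < NREACT; ++rch)
      counts(i, rch) = (int) arch.rcount[i][rch];

  // final population state
  NumericMatrix fin(N, NSPEC);
  IntegerVector fin_gid(N), fin_astar(N);
  NumericVector fin_age(N);
  for (int i = 0; i < N; ++i) {
    for (int s = 0; s < NSPEC; ++s) fin(i, s) = (double) pop[i].st[s];
    fin_gid[i] = pop[i].gid + 1;
    fin_astar[i] = pop[i].astar;
    fin_age[i] = t - pop[i].t_birth;
  }

  List series;
  if (record) {
    int nr = (int) ser_time.size();
    List cols;
    cols["time"] = wrap(ser_time);
    cols["cell"] = wrap(ser_gid);
    cols["size"] = wrap(ser_size);
    const char* nm[] = { "P", "C", "R", "Rs", "E", "Es", "EP", "EsP",
                         "F", "Y" };
    for (int s = 0; s < NSPEC; ++s) {
      IntegerVector v(nr);
      for (int i = 0; i < nr; ++i) v[i] = (int) ser_st[s][i];
      cols[nm[s]] = v;
    }
    series = List::create(_["data"] = cols);
  }

  return List::create(
    _["cells"] = cells, _["losses"] = lossdf, _["events"] = eventdf,
    _["counts"] = counts, _["series"] = series,
    _["final_state"] = fin, _["final_cell"] = fin_gid,
    _["final_astar"] = fin_astar, _["final_age"] = fin_age,
    _["t_end"] = t);
}

// single-cell advance used by the R-level extrande_advance wrapper for
// the CRISPR network (state-only propensities)
// [[Rcpp::export]]
List cpp_advance_cell(NumericVector state, int astar, double t0, double dt,
                      List kin_in, double headroom,
                      double max_events_per_step) {
  Kin k;
  k.k1 = as<double>(kin_in["k1"]);     k.b_c = as<double>(kin_in["b_c"]);
  k.a = as<double>(kin_in["a"]);       k.k_r = as<double>(kin_in["k_r"]);
  k.d_r = as<double>(kin_in["d_r"]);   k.k_a = as<double>(kin_in["k_a"]);
  k.k_on = as<double>(kin_in["k_on_low"]);
  k.fold = as<double>(kin_in["fold_consensus"]);
  k.k_deg = as<double>(kin_in["k_deg"]); k.n_f = as<int>(kin_in["n_f"]);
  k.d_f = as<double>(kin_in["d_f"]);   k.k_int = as<double>(kin_in["k_int"]);
  k.k_rep = as<double>(kin_in["k_rep"]); k.p_s = as<double>(kin_in["p_s"]);
  k.k_y = as<double>(kin_in["k_y"]);

  Archive arch;
  std::vector<EventRec> events;
  std::vector<LossRec> losses;
  Cell c;
  for (int s = 0; s < NSPEC; ++s) c.st[s] = (long) state[s];
  c.astar = astar; c.t_adapt = -1.0;
  c.lost = targets_total(c) == 0; c.t_loss = -1.0;
  c.mu = 0; c.vb = 1; c.vd = 2; c.t_birth = t0; c.t_div = R_PosInf;
  c.gid = arch.add(-1, t0, 0, 1, 2);
  long nacc = advance_cell(c, t0, dt, k, headroom, arch, events, losses,
                           false, (long) max_events_per_step);
  NumericVector out(NSPEC);
  for (int s = 0; s < NSPEC; ++s) out[s] = (double) c.st[s];
  IntegerVector cnt(NREACT);
  for (int rch = 0; rch < NREACT; ++rch) cnt[rch] = (int) arch.rcount[0][rch];
  return List::create(_["state"] = out, _["astar"] = c.astar,
                      _["n_events"] = (double) nacc, _["counts"] = cnt,
                      _["t_adapt"] = c.t_adapt < 0 ? NA_REAL : c.t_adapt,
                      _["t_loss"] = c.t_loss < 0 ? NA_REAL : c.t_loss);
}
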