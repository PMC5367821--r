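// Exact solvers for the farm planning MILP under one resource constraint.
//
// Core: a multiple-choice knapsack (one option per cell, sum of usages
// bounded) solved by depth-first branch and bound. Node bounds are the
// exact LP value of the remaining subproblem, computed greedily over the
// cells' dominance-reduced concave (usage, profit) frontiers; cells with
// identical option lists are grouped and their assignments forced to
// follow a fixed preference ranking (symmetry breaking).
//
// Two-sided: independent per-block frequency (irrigation) and seed
// decisions. The search branches over per-irrigation-block frequencies;
// node bounds are the cell-level MCKP LP with decided blocks held to
// their frequency and all consistency constraints relaxed (a valid upper
// bound); every complete frequency assignment leaves an exact MCKP over
// seed blocks, solved by the core.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

struct CellOptions {
  std::vector<double> w, p;
};

struct Frontier {
  std::vector<double> sky_w, sky_p; // dominance-reduced, usage ascending
  std::vector<int> sky_opt;         // original option index
  std::vector<double> hull_w, hull_p;
  std::vector<int> hull_t; // skyline index of each hull point
};

Frontier build_frontier(const std::vector<double>& w,
                        const std::vector<double>& p) {
  const int I = (int)w.size();
  std::vector<int> ord(I);
  for (int i = 0; i < I; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int z) {
    if (w[a] != w[z]) return w[a] < w[z];
    if (p[a] != p[z]) return p[a] > p[z];
    return a < z;
  });
  Frontier f;
  double bestp = -HUGE_VAL;
  for (int i : ord) {
    if (p[i] > bestp + 1e-12) {
      bestp = p[i];
      f.sky_w.push_back(w[i]);
      f.sky_p.push_back(p[i]);
      f.sky_opt.push_back(i);
    }
  }
  std::vector<int> hull;
  const int n = (int)f.sky_w.size();
  for (int t = 0; t < n; ++t) {
    while ((int)hull.size() >= 2) {
      const int a = hull[hull.size() - 2], z = hull[hull.size() - 1];
      const double s1 = (f.sky_p[z] - f.sky_p[a]) / (f.sky_w[z] - f.sky_w[a]);
      const double s2 = (f.sky_p[t] - f.sky_p[z]) / (f.sky_w[t] - f.sky_w[z]);
      if (s2 >= s1 - 1e-15) hull.pop_back(); else break;
    }
    hull.push_back(t);
  }
  for (int t : hull) {
    f.hull_w.push_back(f.sky_w[t]);
    f.hull_p.push_back(f.sky_p[t]);
    f.hull_t.push_back(t);
  }
  return f;
}

// hash a cell's option list so duplicate cells can be grouped in O(C I)
std::uint64_t hash_options(const CellOptions& c) {
  std::uint64_t h = 1469598103934665603ull;
  auto mix = [&](double x) {
    std::uint64_t v;
    std::memcpy(&v, &x, sizeof v);
    h ^= v;
    h *= 1099511628211ull;
  };
  for (double x : c.w) mix(x);
  for (double x : c.p) mix(x);
  return h;
}

struct MckpResult {
  bool feasible = false, optimal = false, capped = false;
  std::vector<int> choice; // option index per cell
  double value = -HUGE_VAL, bound = NA_REAL;
};

struct Inc {
  int g;
  int from_t = -1, to_t = -1; // skyline endpoints of the hull step
  double dw, slope;
};

// Exact MCKP over cells with arbitrary (usage >= 0, profit) option lists.
// `warm` may hold a feasible option index per cell (or be empty).
MckpResult mckp_solve(const std::vector<CellOptions>& cells, double b,
                      double tol, double feas_tol_rel, double& nodes,
                      double node_cap, const std::vector<int>& warm,
                      bool polish_pairs = true) {
  const int C = (int)cells.size();
  const double feas_tol = feas_tol_rel * std::max(1.0, b);
  MckpResult res;
  res.choice.assign(C, -1);

  // duplicate-cell groups via hashing
  std::vector<int> group(C, -1), rep;
  {
    std::unordered_map<std::uint64_t, std::vector<int>> buckets;
    for (int c = 0; c < C; ++c) {
      auto& bucket = buckets[hash_options(cells[c])];
      for (int g : bucket) {
        if (cells[rep[g]].w == cells[c].w && cells[rep[g]].p == cells[c].p) {
          group[c] = g;
          break;
        }
      }
      if (group[c] < 0) {
        rep.push_back(c);
        group[c] = (int)rep.size() - 1;
        bucket.push_back(group[c]);
      }
    }
  }
  const int G = (int)rep.size();

  std::vector<Frontier> fr(G);
  for (int g = 0; g < G; ++g) fr[g] = build_frontier(cells[rep[g]].w, cells[rep[g]].p);

  std::vector<Inc> inc;
  for (int g = 0; g < G; ++g)
    for (size_t t = 1; t < fr[g].hull_w.size(); ++t) {
      const double dw = fr[g].hull_w[t] - fr[g].hull_w[t - 1];
      inc.push_back({g, fr[g].hull_t[t - 1], fr[g].hull_t[t], dw,
                     (fr[g].hull_p[t] - fr[g].hull_p[t - 1]) / dw});
    }
  std::sort(inc.begin(), inc.end(),
            [](const Inc& a, const Inc& z) { return a.slope > z.slope; });
  std::vector<double> w0(G), p0(G);
  for (int g = 0; g < G; ++g) { w0[g] = fr[g].hull_w[0]; p0[g] = fr[g].hull_p[0]; }

  auto lp_rem = [&](const int* cnt, double rcap, double* lam_out) -> double {
    double wmin = 0, val = 0;
    for (int g = 0; g < G; ++g) {
      wmin += cnt[g] * w0[g];
      val += cnt[g] * p0[g];
    }
    if (wmin > rcap + feas_tol) return -HUGE_VAL;
    double slack = rcap - wmin;
    if (lam_out) *lam_out = 0;
    for (const Inc& e : inc) {
      if (cnt[e.g] == 0) continue;
      const double take = std::min(cnt[e.g] * e.dw, slack);
      val += take * e.slope;
      slack -= take;
      if (slack <= 1e-12) {
        if (lam_out) *lam_out = e.slope;
        break;
      }
    }
    return val;
  };

  std::vector<int> full_cnt(G, 0);
  for (int c = 0; c < C; ++c) full_cnt[group[c]]++;
  double lambda = 0;
  nodes += 1;
  const double ub_root = lp_rem(full_cnt.data(), b, &lambda);
  if (ub_root == -HUGE_VAL) return res; // infeasible
  res.bound = ub_root;
  const double tie_tol = tol * std::max(1.0, std::fabs(ub_root));

  // dive order: skyline ranked by reduced profit at the root dual price
  struct Rank {
    std::vector<double> w, p;
    std::vector<int> opt;
  };
  std::vector<Rank> rank(G);
  std::vector<double> regret(G);
  for (int g = 0; g < G; ++g) {
    const int n = (int)fr[g].sky_w.size();
    std::vector<int> o(n);
    for (int t = 0; t < n; ++t) o[t] = t;
    std::sort(o.begin(), o.end(), [&](int a, int z) {
      const double ra = fr[g].sky_p[a] - lambda * fr[g].sky_w[a];
      const double rz = fr[g].sky_p[z] - lambda * fr[g].sky_w[z];
      if (ra != rz) return ra > rz;
      return a < z;
    });
    for (int t : o) {
      rank[g].w.push_back(fr[g].sky_w[t]);
      rank[g].p.push_back(fr[g].sky_p[t]);
      rank[g].opt.push_back(fr[g].sky_opt[t]);
    }
    const double top = rank[g].p[0] - lambda * rank[g].w[0];
    const double sec = n > 1 ? rank[g].p[1] - lambda * rank[g].w[1] : -HUGE_VAL;
    regret[g] = top - sec;
  }
  std::vector<int> gord(G);
  for (int g = 0; g < G; ++g) gord[g] = g;
  std::sort(gord.begin(), gord.end(), [&](int a, int z) {
    if (regret[a] != regret[z]) return regret[a] > regret[z];
    return a < z;
  });
  std::vector<int> ord;
  ord.reserve(C);
  {
    std::vector<std::vector<int>> members(G);
    for (int c = 0; c < C; ++c) members[group[c]].push_back(c);
    for (int g : gord)
      for (int c : members[g]) ord.push_back(c);
  }

  std::vector<int> cnt_suf((C + 1) * G, 0);
  for (int d = C - 1; d >= 0; --d) {
    for (int g = 0; g < G; ++g) cnt_suf[d * G + g] = cnt_suf[(d + 1) * G + g];
    cnt_suf[d * G + group[ord[d]]]++;
  }

  double best_val = -HUGE_VAL;
  std::vector<int> best_choice(C, -1), choice(C, -1);
  if ((int)warm.size() == C) {
    double v = 0, u = 0;
    for (int c = 0; c < C; ++c) {
      v += cells[c].p[warm[c]];
      u += cells[c].w[warm[c]];
    }
    if (u <= b + feas_tol) {
      best_val = v;
      best_choice = warm;
    }
  }

  // --- incumbent construction in count space ------------------------------
  // A solution is summarized by, per group, the number of cells at each
  // skyline option. Two candidates are built (the caller's warm start
  // lifted onto the skyline, and the LP greedy rounded down cell-wise and
  // continued through cheaper increments), the better one is polished by
  // single and pairwise group-level exchange moves, and the result seeds
  // the search. Pair moves matter: distinct groups often carry exactly
  // identical frontier increments, and the optimum trades them one-off.
  {
    std::vector<std::vector<int>> ncnt(G);
    for (int g = 0; g < G; ++g) ncnt[g].assign(fr[g].sky_w.size(), 0);
    auto counts_value = [&](const std::vector<std::vector<int>>& nc,
                            double* usage_out) {
      double v = 0, u = 0;
      for (int g = 0; g < G; ++g)
        for (size_t t = 0; t < nc[g].size(); ++t) {
          v += nc[g][t] * fr[g].sky_p[t];
          u += nc[g][t] * fr[g].sky_w[t];
        }
      if (usage_out) *usage_out = u;
      return v;
    };

    // candidate 1: warm start, each option lifted to its dominating
    // skyline point (no worse in profit, no heavier in usage)
    double warm_val = -HUGE_VAL;
    std::vector<std::vector<int>> warm_cnt;
    if ((int)warm.size() == C) {
      warm_cnt = ncnt;
      for (int c = 0; c < C; ++c) {
        const int g = group[c];
        const double wo = cells[c].w[warm[c]];
        const double po = cells[c].p[warm[c]];
        int t_dom = 0;
        for (size_t t = 0; t < fr[g].sky_w.size(); ++t)
          if (fr[g].sky_w[t] <= wo + 1e-12) t_dom = (int)t; else break;
        if (fr[g].sky_p[t_dom] < po - 1e-9) t_dom = 0; // defensive
        warm_cnt[g][t_dom]++;
      }
      double u;
      const double v = counts_value(warm_cnt, &u);
      if (u <= b + feas_tol) warm_val = v;
    }

    // candidate 2: LP greedy rounded down, continued through the
    // remaining (cheaper) increments with whatever slack is left
    std::vector<std::vector<int>> lp_cnt = ncnt;
    for (int g = 0; g < G; ++g) lp_cnt[g][fr[g].hull_t[0]] = full_cnt[g];
    double lp_val = -HUGE_VAL;
    {
      double slack = b;
      for (int g = 0; g < G; ++g) slack -= full_cnt[g] * w0[g];
      if (slack >= -feas_tol) {
        for (const Inc& e : inc) {
          const int avail = lp_cnt[e.g][e.from_t];
          if (avail == 0) continue;
          const int k = std::min(avail,
            (int)std::floor(slack / e.dw + 1e-12));
          if (k <= 0) continue;
          lp_cnt[e.g][e.from_t] -= k;
          lp_cnt[e.g][e.to_t] += k;
          slack -= k * e.dw;
        }
        lp_val = counts_value(lp_cnt, nullptr);
      }
    }

    std::vector<std::vector<int>> cur =
      warm_val >= lp_val ? warm_cnt : lp_cnt;
    double cur_val = std::max(warm_val, lp_val);

    if (cur_val > -HUGE_VAL) {
      // polish: single moves, then pairwise exchanges across groups
      struct Move { int g, from, to; double dw, dp; };
      double usage;
      counts_value(cur, &usage);
      int n_moves_cap = 0;
      for (int g = 0; g < G; ++g)
        n_moves_cap += (int)fr[g].sky_w.size() * (int)fr[g].sky_w.size();
      const bool do_pairs = polish_pairs && n_moves_cap <= 2500;
      for (int iter = 0; iter < 400; ++iter) {
        double slack = b - usage;
        std::vector<Move> mv;
        for (int g = 0; g < G; ++g) {
          const int n = (int)fr[g].sky_w.size();
          for (int t = 0; t < n; ++t) {
            if (cur[g][t] == 0) continue;
            for (int t2 = 0; t2 < n; ++t2) {
              if (t2 == t) continue;
              mv.push_back({g, t, t2,
                fr[g].sky_w[t2] - fr[g].sky_w[t],
                fr[g].sky_p[t2] - fr[g].sky_p[t]});
            }
          }
        }
        int bi = -1;
        double bdp = 1e-12;
        for (size_t i = 0; i < mv.size(); ++i)
          if (mv[i].dp > bdp && mv[i].dw <= slack + 1e-12) {
            bdp = mv[i].dp;
            bi = (int)i;
          }
        if (bi >= 0) {
          cur[mv[bi].g][mv[bi].from]--;
          cur[mv[bi].g][mv[bi].to]++;
          usage += mv[bi].dw;
          cur_val += mv[bi].dp;
          continue;
        }
        if (!do_pairs) break;
        int pi = -1, pj = -1;
        double pdp = 1e-12;
        for (size_t i = 0; i < mv.size(); ++i)
          for (size_t j = i; j < mv.size(); ++j) {
            if (mv[i].dw + mv[j].dw > slack + 1e-12) continue;
            const double dp = mv[i].dp + mv[j].dp;
            if (dp <= pdp) continue;
            if (i == j || (mv[i].g == mv[j].g && mv[i].from == mv[j].from)) {
              if (cur[mv[i].g][mv[i].from] < 2) continue;
            }
            pdp = dp;
            pi = (int)i;
            pj = (int)j;
          }
        if (pi < 0) break;
        for (int k : {pi, pj}) {
          cur[mv[k].g][mv[k].from]--;
          cur[mv[k].g][mv[k].to]++;
          usage += mv[k].dw;
          cur_val += mv[k].dp;
        }
      }

      if (cur_val > best_val) {
        // expand counts to per-cell choices
        std::vector<std::vector<int>> members(G);
        for (int c = 0; c < C; ++c) members[group[c]].push_back(c);
        std::vector<int> gc(C, -1);
        bool ok = true;
        for (int g = 0; g < G && ok; ++g) {
          size_t at = 0;
          for (size_t t = 0; t < cur[g].size(); ++t)
            for (int k = 0; k < cur[g][t]; ++k) {
              if (at >= members[g].size()) { ok = false; break; }
              gc[members[g][at++]] = fr[g].sky_opt[t];
            }
          if (at != members[g].size()) ok = false;
        }
        if (ok) {
          best_val = cur_val;
          best_choice = gc;
        }
      }
    }
  }

  // Lagrangian reduced-cost fixing at the root dual price: an option can
  // be dropped when forcing it already pushes the bound below the
  // incumbent. The Lagrangian bound g(lambda) >= LP bound, so this is a
  // valid (conservative) filter.
  if (best_val > -HUGE_VAL) {
    double g_lam = lambda * b;
    std::vector<double> redmax(G, -HUGE_VAL);
    for (int g = 0; g < G; ++g)
      for (size_t t = 0; t < rank[g].w.size(); ++t)
        redmax[g] = std::max(redmax[g], rank[g].p[t] - lambda * rank[g].w[t]);
    for (int c = 0; c < C; ++c) g_lam += redmax[group[c]];
    for (int g = 0; g < G; ++g) {
      Rank kept;
      for (size_t t = 0; t < rank[g].w.size(); ++t) {
        const double red_t = rank[g].p[t] - lambda * rank[g].w[t];
        if (t == 0 || g_lam - (redmax[g] - red_t) > best_val + tie_tol) {
          kept.w.push_back(rank[g].w[t]);
          kept.p.push_back(rank[g].p[t]);
          kept.opt.push_back(rank[g].opt[t]);
        }
      }
      rank[g] = kept;
    }
  }

  struct Node {
    int depth, pos;
    double used, acc;
  };
  std::vector<Node> stack;
  stack.reserve(C + 1);
  stack.push_back({0, 0, 0.0, 0.0});
  while (!stack.empty()) {
    Node& nd = stack.back();
    if (nd.depth == C) {
      if (nd.acc > best_val + tie_tol) {
        best_val = nd.acc;
        best_choice = choice;
      }
      stack.pop_back();
      continue;
    }
    const int cc = ord[nd.depth];
    const Rank& sr = rank[group[cc]];
    const int n = (int)sr.opt.size();
    bool descended = false;
    while (nd.pos < n) {
      const int pos = nd.pos++;
      const double used2 = nd.used + sr.w[pos];
      const double acc2 = nd.acc + sr.p[pos];
      nodes += 1;
      if (nodes > node_cap) { res.capped = true; break; }
      const double lp = lp_rem(&cnt_suf[(nd.depth + 1) * G], b - used2, nullptr);
      if (lp == -HUGE_VAL || acc2 + lp <= best_val + tie_tol) continue;
      choice[cc] = sr.opt[pos];
      const int nxt = nd.depth + 1;
      // symmetry: within a duplicate-group run, positions never decrease
      const int nxt_min = (nxt < C && group[ord[nxt]] == group[cc]) ? pos : 0;
      stack.push_back({nxt, nxt_min, used2, acc2});
      descended = true;
      break;
    }
    if (res.capped) return res;
    if (!descended && nd.pos >= n) stack.pop_back();
  }

  if (best_val == -HUGE_VAL) return res; // infeasible
  res.feasible = res.optimal = true;
  res.value = best_val;
  res.choice = best_choice;
  return res;
}

} // namespace

// [[Rcpp::export(name = ".mckp_single_cpp")]]
List mckp_single_cpp(NumericMatrix prof, NumericMatrix U, double b,
                     double tol, double feas_tol_rel, double node_cap,
                     IntegerVector warm_choice) {
  const int C = prof.nrow(), I = prof.ncol();
  std::vector<CellOptions> cells(C);
  for (int c = 0; c < C; ++c) {
    cells[c].w.resize(I);
    cells[c].p.resize(I);
    for (int i = 0; i < I; ++i) {
      cells[c].w[i] = U(c, i);
      cells[c].p[i] = prof(c, i);
    }
  }
  std::vector<int> warm;
  if (warm_choice.size() == C) {
    warm.resize(C);
    for (int c = 0; c < C; ++c) warm[c] = warm_choice[c] - 1;
  }
  double nodes = 0;
  MckpResult r = mckp_solve(cells, b, tol, feas_tol_rel, nodes, node_cap, warm);
  if (r.capped)
    stop("branch-and-bound node cap exceeded (%.0f nodes)", node_cap);
  if (!r.feasible) {
    return List::create(
      _["status"] = "infeasible", _["choice"] = R_NilValue,
      _["value"] = NA_REAL, _["bound"] = r.bound, _["nodes"] = nodes);
  }
  IntegerVector out(C);
  for (int c = 0; c < C; ++c) out[c] = r.choice[c] + 1;
  return List::create(
    _["status"] = "optimal", _["choice"] = out, _["value"] = r.value,
    _["bound"] = r.bound, _["nodes"] = nodes);
}

// [[Rcpp::export(name = ".two_sided_cpp")]]
List two_sided_cpp(NumericVector P3, NumericVector U3, double b,
                   IntegerVector irr_block, IntegerVector seed_block,
                   int R, int S, double tol, double feas_tol_rel,
                   double node_cap, IntegerVector warm_r,
                   IntegerVector warm_s) {
  const int C = irr_block.size();
  int Q = 0, Pn = 0;
  for (int c = 0; c < C; ++c) {
    Q = std::max(Q, irr_block[c]);
    Pn = std::max(Pn, seed_block[c]);
  }
  const double feas_tol = feas_tol_rel * std::max(1.0, b);
  auto at = [&](const NumericVector& A, int c, int r, int s) {
    return A[c + C * (r + R * s)]; // dims C x R x S, column-major
  };

  // per cell: frontier over all R*S options (block undecided) and over
  // the S seed options at each fixed frequency (block decided)
  std::vector<Frontier> f_full(C);
  std::vector<std::vector<Frontier>> f_fix(C, std::vector<Frontier>(R));
  for (int c = 0; c < C; ++c) {
    std::vector<double> w, p;
    for (int r = 0; r < R; ++r)
      for (int s = 0; s < S; ++s) {
        w.push_back(at(U3, c, r, s));
        p.push_back(at(P3, c, r, s));
      }
    f_full[c] = build_frontier(w, p);
    for (int r = 0; r < R; ++r) {
      std::vector<double> wr(S), pr(S);
      for (int s = 0; s < S; ++s) {
        wr[s] = at(U3, c, r, s);
        pr[s] = at(P3, c, r, s);
      }
      f_fix[c][r] = build_frontier(wr, pr);
    }
  }

  std::vector<std::vector<int>> block_cells(Q);
  for (int c = 0; c < C; ++c) block_cells[irr_block[c] - 1].push_back(c);
  std::vector<int> assigned(Q, -1);

  // LP bound of the current node: every cell contributes its current
  // frontier (frequency-fixed when its block is decided), consistency
  // relaxed, capacity exact.
  std::vector<Inc> scratch_inc;
  auto node_bound = [&](double* lam_out) -> double {
    double wmin = 0, val = 0;
    scratch_inc.clear();
    for (int c = 0; c < C; ++c) {
      const int a = assigned[irr_block[c] - 1];
      const Frontier& f = a < 0 ? f_full[c] : f_fix[c][a];
      wmin += f.hull_w[0];
      val += f.hull_p[0];
      for (size_t t = 1; t < f.hull_w.size(); ++t) {
        const double dw = f.hull_w[t] - f.hull_w[t - 1];
        scratch_inc.push_back({0, dw, (f.hull_p[t] - f.hull_p[t - 1]) / dw});
      }
    }
    if (wmin > b + feas_tol) return -HUGE_VAL;
    std::sort(scratch_inc.begin(), scratch_inc.end(),
              [](const Inc& a, const Inc& z) { return a.slope > z.slope; });
    double slack = b - wmin;
    if (lam_out) *lam_out = 0;
    for (const Inc& e : scratch_inc) {
      const double take = std::min(e.dw, slack);
      val += take * e.slope;
      slack -= take;
      if (slack <= 1e-12) {
        if (lam_out) *lam_out = e.slope;
        break;
      }
    }
    return val;
  };

  double nodes = 1;
  double lambda = 0;
  const double ub_root = node_bound(&lambda);
  if (ub_root == -HUGE_VAL) {
    return List::create(
      _["status"] = "infeasible", _["r_choice"] = R_NilValue,
      _["s_choice"] = R_NilValue, _["value"] = NA_REAL,
      _["bound"] = NA_REAL, _["nodes"] = nodes);
  }
  const double tie_tol = tol * std::max(1.0, std::fabs(ub_root));

  // branch order: larger blocks first
  std::vector<int> bord(Q);
  for (int q = 0; q < Q; ++q) bord[q] = q;
  std::sort(bord.begin(), bord.end(), [&](int a, int z) {
    if (block_cells[a].size() != block_cells[z].size())
      return block_cells[a].size() > block_cells[z].size();
    return a < z;
  });

  double best_val = -HUGE_VAL;
  std::vector<int> best_r(Q, -1), best_s(Pn, -1);

  // build and solve the seed-block MCKP left by a complete frequency
  // assignment; `warm_leaf` may carry a seed choice per seed block
  auto leaf_solve = [&](const std::vector<int>& warm_leaf, bool pairs) {
    std::vector<CellOptions> agg(Pn);
    for (int p = 0; p < Pn; ++p) {
      agg[p].w.assign(S, 0.0);
      agg[p].p.assign(S, 0.0);
    }
    for (int c = 0; c < C; ++c) {
      const int r = assigned[irr_block[c] - 1];
      const int p = seed_block[c] - 1;
      for (int s = 0; s < S; ++s) {
        agg[p].w[s] += at(U3, c, r, s);
        agg[p].p[s] += at(P3, c, r, s);
      }
    }
    MckpResult lr = mckp_solve(agg, b, tol, feas_tol_rel, nodes, node_cap,
                               warm_leaf, pairs);
    if (lr.capped)
      stop("branch-and-bound node cap exceeded (%.0f nodes)", node_cap);
    if (lr.feasible && lr.value > best_val + tie_tol) {
      best_val = lr.value;
      for (int q = 0; q < Q; ++q) best_r[q] = assigned[q];
      best_s = lr.choice;
    }
  };

  // warm start from the caller (e.g. the common-coarsening solution)
  if (warm_r.size() == Q && warm_s.size() == Pn) {
    for (int q = 0; q < Q; ++q) assigned[q] = warm_r[q] - 1;
    std::vector<int> wl(Pn);
    for (int p = 0; p < Pn; ++p) wl[p] = warm_s[p] - 1;
    leaf_solve(wl, true);
    for (int q = 0; q < Q; ++q) assigned[q] = -1;
  }

  struct Node {
    int depth, pos;
    std::vector<int> child; // candidate frequencies, bound-ranked
  };
  std::vector<Node> stack;
  stack.reserve(Q + 1);

  auto make_node = [&](int depth) {
    Node nd;
    nd.depth = depth;
    nd.pos = 0;
    if (depth < Q) {
      const int q = bord[depth];
      std::vector<double> score(R, 0.0);
      for (int r = 0; r < R; ++r)
        for (int c : block_cells[q]) {
          const Frontier& f = f_fix[c][r];
          double m = -HUGE_VAL; // best reduced profit on this frontier
          for (size_t t = 0; t < f.sky_w.size(); ++t)
            m = std::max(m, f.sky_p[t] - lambda * f.sky_w[t]);
          score[r] += m;
        }
      nd.child.resize(R);
      for (int r = 0; r < R; ++r) nd.child[r] = r;
      std::sort(nd.child.begin(), nd.child.end(), [&](int a, int z) {
        if (score[a] != score[z]) return score[a] > score[z];
        return a < z;
      });
    }
    return nd;
  };

  stack.push_back(make_node(0));
  while (!stack.empty()) {
    Node& nd = stack.back();
    if (nd.depth == Q) {
      // seed the leaf with the best seed assignment found so far (it is
      // simply ignored when infeasible under this frequency assignment)
      leaf_solve(best_s[0] >= 0 ? best_s : std::vector<int>(), false);
      stack.pop_back();
      continue;
    }
    const int q = bord[nd.depth];
    bool descended = false;
    while (nd.pos < (int)nd.child.size()) {
      const int r = nd.child[nd.pos++];
      nodes += 1;
      if (nodes > node_cap)
        stop("branch-and-bound node cap exceeded (%.0f nodes)", node_cap);
      assigned[q] = r;
      const double ub = node_bound(nullptr);
      if (ub == -HUGE_VAL || ub <= best_val + tie_tol) {
        assigned[q] = -1;
        continue;
      }
      stack.push_back(make_node(nd.depth + 1));
      descended = true;
      break;
    }
    if (!descended) {
      assigned[q] = -1;
      stack.pop_back();
    }
  }

  if (best_val == -HUGE_VAL) {
    return List::create(
      _["status"] = "infeasible", _["r_choice"] = R_NilValue,
      _["s_choice"] = R_NilValue, _["value"] = NA_REAL,
      _["bound"] = ub_root, _["nodes"] = nodes);
  }
  IntegerVector rc(Q), sc(Pn);
  for (int q = 0; q < Q; ++q) rc[q] = best_r[q] + 1;
  for (int p = 0; p < Pn; ++p) sc[p] = best_s[p] + 1;
  return List::create(
    _["status"] = "optimal", _["r_choice"] = rc, _["s_choice"] = sc,
    _["value"] = best_val, _["bound"] = ub_root, _["nodes"] = nodes);
}
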