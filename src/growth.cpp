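#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// One growth cone: the motile tip agent that elongates, turns and branches.
struct Cone {
  int node;          // index of the node currently being extended
  double dir[3];     // unit outgrowth direction
  double rate;       // elongation rate, um/s, fixed until the cone branches
  int gamma;         // centrifugal order of the terminal segment
  double since_turn; // length grown since the last direction evaluation, um
};

static void normalize3(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (n > 0) { v[0] /= n; v[1] /= n; v[2] /= n; }
}

// Truncated-normal elongation rate: redraw negative Gaussian samples.
static double draw_rate(double mn, double sd) {
  if (sd <= 0) return mn;
  double r;
  int guard = 0;
  do {
    r = R::rnorm(mn, sd);
  } while (r < 0 && ++guard < 10000);
  return r < 0 ? 0.0 : r;
}

// Random unit vector orthogonal to d.
static void rand_perp(const double *d, double *u) {
  for (int tries = 0; tries < 100; ++tries) {
    double v[3] = { norm_rand(), norm_rand(), norm_rand() };
    double dot = v[0] * d[0] + v[1] * d[1] + v[2] * d[2];
    u[0] = v[0] - dot * d[0];
    u[1] = v[1] - dot * d[1];
    u[2] = v[2] - dot * d[2];
    double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    if (n > 1e-8) { u[0] /= n; u[1] /= n; u[2] /= n; return; }
  }
  u[0] = 1; u[1] = 0; u[2] = 0; // unreachable in practice
}

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericVector root, NumericVector dir0,
                   double B_inf, double E, double S, double tau,
                   double eri_mn, double eri_sd,
                   double dt, double total_time,
                   double turn_step, double turn_sd,
                   double branch_angle_mean, double branch_angle_sd,
                   int tip_cap) {
  if (tau <= 0) stop("tau must be > 0");
  if (dt <= 0) stop("dt must be > 0");
  if (B_inf < 0) stop("B_inf must be >= 0");
  if (eri_mn < 0) stop("eri_mn must be >= 0");
  int n_steps = (int)std::floor(total_time / dt);

  std::vector<double> px, py, pz;
  std::vector<int> parent; // 0-based, -1 for root
  px.push_back(root[0]); py.push_back(root[1]); pz.push_back(root[2]);
  parent.push_back(-1);

  std::vector<Cone> cones;
  {
    Cone c;
    px.push_back(root[0]); py.push_back(root[1]); pz.push_back(root[2]);
    parent.push_back(0);
    c.node = 1;
    c.dir[0] = dir0[0]; c.dir[1] = dir0[1]; c.dir[2] = dir0[2];
    normalize3(c.dir);
    c.rate = draw_rate(eri_mn, eri_sd);
    c.gamma = 0;
    c.since_turn = 0;
    cones.push_back(c);
  }

  std::vector<double> prob;
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    // --- elongation (and turning at fixed grown-length intervals) ---
    for (size_t i = 0; i < cones.size(); ++i) {
      Cone &c = cones[i];
      double adv = c.rate * dt;
      if (adv > 0) {
        px[c.node] += adv * c.dir[0];
        py[c.node] += adv * c.dir[1];
        pz[c.node] += adv * c.dir[2];
        c.since_turn += adv;
        if (c.since_turn >= turn_step) {
          // freeze the current line piece, perturb the direction
          int nn = (int)px.size();
          px.push_back(px[c.node]); py.push_back(py[c.node]); pz.push_back(pz[c.node]);
          parent.push_back(c.node);
          c.node = nn;
          if (turn_sd > 0) {
            c.dir[0] += turn_sd * norm_rand();
            c.dir[1] += turn_sd * norm_rand();
            c.dir[2] += turn_sd * norm_rand();
            normalize3(c.dir);
          }
          c.since_turn = 0;
        }
      }
    }
    // --- branching: probabilities from the tip population before any event ---
    size_t n = cones.size();
    double sumw = 0;
    for (size_t i = 0; i < n; ++i) sumw += std::pow(2.0, -S * cones[i].gamma);
    double D = B_inf * (std::exp(-t / tau) - std::exp(-(t + dt) / tau));
    double base = std::pow((double)n, -E) * ((double)n / sumw) * D;
    prob.resize(n);
    for (size_t i = 0; i < n; ++i) {
      double p = base * std::pow(2.0, -S * cones[i].gamma);
      prob[i] = p > 1.0 ? 1.0 : p;
    }
    for (size_t i = 0; i < n; ++i) {
      if (unif_rand() >= prob[i]) continue;
      Cone c = cones[i]; // branch point = current tip node (frozen)
      double A = branch_angle_sd > 0
        ? R::rnorm(branch_angle_mean, branch_angle_sd) : branch_angle_mean;
      if (A < 0) A = 0;
      if (A > M_PI) A = M_PI;
      double u[3];
      rand_perp(c.dir, u);
      double ca = std::cos(A / 2), sa = std::sin(A / 2);
      for (int d = 0; d < 2; ++d) {
        Cone nc;
        int nn = (int)px.size();
        px.push_back(px[c.node]); py.push_back(py[c.node]); pz.push_back(pz[c.node]);
        parent.push_back(c.node);
        nc.node = nn;
        double sgn = d == 0 ? 1.0 : -1.0;
        nc.dir[0] = ca * c.dir[0] + sgn * sa * u[0];
        nc.dir[1] = ca * c.dir[1] + sgn * sa * u[1];
        nc.dir[2] = ca * c.dir[2] + sgn * sa * u[2];
        normalize3(nc.dir);
        nc.rate = draw_rate(eri_mn, eri_sd);
        nc.gamma = c.gamma + 1;
        nc.since_turn = 0;
        if (d == 0) cones[i] = nc; else cones.push_back(nc);
      }
      if ((int)cones.size() > tip_cap)
        stop("runaway growth: tip count exceeded cap (%d); check parameters", tip_cap);
    }
  }

  int N = (int)px.size();
  NumericMatrix pos(N, 3);
  IntegerVector par(N);
  for (int i = 0; i < N; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i]; pos(i, 2) = pz[i];
    par[i] = parent[i] + 1; // 1-based; root gets 0
  }
  IntegerVector tips(cones.size());
  IntegerVector tip_gamma(cones.size());
  NumericVector tip_rate(cones.size());
  for (size_t i = 0; i < cones.size(); ++i) {
    tips[i] = cones[i].node + 1;
    tip_gamma[i] = cones[i].gamma;
    tip_rate[i] = cones[i].rate;
  }
  return List::create(_["pos"] = pos, _["parent"] = par,
                      _["tips"] = tips, _["tip_gamma"] = tip_gamma,
                      _["tip_rate"] = tip_rate);
}

// Cumulative path length from the root for every node.
// [[Rcpp::export(name = ".cum_path_cpp")]]
NumericVector cum_path_cpp(NumericMatrix pos, IntegerVector parent) {
  int N = pos.nrow();
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    int p = parent[i];
    if (p == 0) { out[i] = 0; continue; }
    double dx = pos(i, 0) - pos(p - 1, 0);
    double dy = pos(i, 1) - pos(p - 1, 1);
    double dz = pos(i, 2) - pos(p - 1, 2);
    out[i] = out[p - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return out;
}
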