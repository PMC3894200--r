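#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// Closest approach of two line segments a1-a2 and d1-d2.
// "Crossing" demands the common perpendicular of the carrier lines to touch
// both segments strictly in their interiors; parallel pairs never cross.
struct Cross {
  bool crossing;
  double dist;
  double s, t;       // parameters on the axonal / dendritic segment
  double mid[3];     // midpoint of the orthogonal connector
};

static Cross seg_cross(const double *a1, const double *a2,
                       const double *d1, const double *d2) {
  Cross res; res.crossing = false; res.dist = NA_REAL;
  res.s = NA_REAL; res.t = NA_REAL;
  res.mid[0] = res.mid[1] = res.mid[2] = NA_REAL;
  double u[3] = { a2[0] - a1[0], a2[1] - a1[1], a2[2] - a1[2] };
  double v[3] = { d2[0] - d1[0], d2[1] - d1[1], d2[2] - d1[2] };
  double w[3] = { a1[0] - d1[0], a1[1] - d1[1], a1[2] - d1[2] };
  double a = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  double b = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double c = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
  double d = u[0] * w[0] + u[1] * w[1] + u[2] * w[2];
  double e = v[0] * w[0] + v[1] * w[1] + v[2] * w[2];
  double denom = a * c - b * b;
  if (a <= 0 || c <= 0) return res;           // degenerate zero-length piece
  if (denom <= 1e-12 * a * c) return res;     // parallel lines: no crossing
  double s = (b * e - c * d) / denom;
  double t = (a * e - b * d) / denom;
  if (s <= 0 || s >= 1 || t <= 0 || t >= 1) return res;
  double P[3] = { a1[0] + s * u[0], a1[1] + s * u[1], a1[2] + s * u[2] };
  double Q[3] = { d1[0] + t * v[0], d1[1] + t * v[1], d1[2] + t * v[2] };
  double dx = P[0] - Q[0], dy = P[1] - Q[1], dz = P[2] - Q[2];
  res.crossing = true;
  res.dist = std::sqrt(dx * dx + dy * dy + dz * dz);
  res.s = s; res.t = t;
  res.mid[0] = (P[0] + Q[0]) / 2;
  res.mid[1] = (P[1] + Q[1]) / 2;
  res.mid[2] = (P[2] + Q[2]) / 2;
  return res;
}

// [[Rcpp::export(name = ".segment_pair_crossing_cpp")]]
List segment_pair_crossing_cpp(NumericVector a1, NumericVector a2,
                               NumericVector d1, NumericVector d2) {
  Cross r = seg_cross(&a1[0], &a2[0], &d1[0], &d2[0]);
  return List::create(_["crossing"] = r.crossing, _["distance"] = r.dist,
                      _["midpoint"] = NumericVector::create(r.mid[0], r.mid[1], r.mid[2]),
                      _["s"] = r.s, _["t"] = r.t);
}

static inline long long cell_key(int ix, int iy, int iz) {
  return ((long long)(ix + 1048576) << 42) |
         ((long long)(iy + 1048576) << 21) |
         (long long)(iz + 1048576);
}

// Candidate-synapse detection over axonal vs dendritic line-piece sets using
// a uniform spatial grid on piece midpoints. Cell size >= max piece length +
// threshold guarantees any qualifying pair sits in adjacent cells.
// ax, de: columns x1 y1 z1 x2 y2 z2; ids are per-piece metadata.
// [[Rcpp::export(name = ".detect_synapses_cpp")]]
DataFrame detect_synapses_cpp(NumericMatrix ax, IntegerVector ax_neuron,
                              NumericVector ax_path0, IntegerVector ax_id,
                              NumericMatrix de, IntegerVector de_neuron,
                              NumericVector de_path0, IntegerVector de_id,
                              IntegerVector de_kind, double threshold) {
  int na = ax.nrow(), nd = de.nrow();
  double maxlen = 0;
  for (int i = 0; i < na; ++i) {
    double dx = ax(i, 3) - ax(i, 0), dy = ax(i, 4) - ax(i, 1), dz = ax(i, 5) - ax(i, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (l > maxlen) maxlen = l;
  }
  for (int i = 0; i < nd; ++i) {
    double dx = de(i, 3) - de(i, 0), dy = de(i, 4) - de(i, 1), dz = de(i, 5) - de(i, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (l > maxlen) maxlen = l;
  }
  double cell = maxlen + threshold;
  if (cell <= 0) cell = 1;

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(nd * 2);
  std::vector<double> dmx(nd), dmy(nd), dmz(nd);
  for (int i = 0; i < nd; ++i) {
    dmx[i] = (de(i, 0) + de(i, 3)) / 2;
    dmy[i] = (de(i, 1) + de(i, 4)) / 2;
    dmz[i] = (de(i, 2) + de(i, 5)) / 2;
    int ix = (int)std::floor(dmx[i] / cell);
    int iy = (int)std::floor(dmy[i] / cell);
    int iz = (int)std::floor(dmz[i] / cell);
    grid[cell_key(ix, iy, iz)].push_back(i);
  }

  std::vector<int> o_pre, o_post, o_axid, o_deid, o_kind;
  std::vector<double> o_x, o_y, o_z, o_dist, o_prepath, o_postpath;
  double a1[3], a2[3], d1[3], d2[3];
  for (int i = 0; i < na; ++i) {
    a1[0] = ax(i, 0); a1[1] = ax(i, 1); a1[2] = ax(i, 2);
    a2[0] = ax(i, 3); a2[1] = ax(i, 4); a2[2] = ax(i, 5);
    double la = std::sqrt((a2[0]-a1[0])*(a2[0]-a1[0]) + (a2[1]-a1[1])*(a2[1]-a1[1]) +
                          (a2[2]-a1[2])*(a2[2]-a1[2]));
    if (la < 1e-9) continue;
    double mx = (a1[0] + a2[0]) / 2, my = (a1[1] + a2[1]) / 2, mz = (a1[2] + a2[2]) / 2;
    int cx = (int)std::floor(mx / cell);
    int cy = (int)std::floor(my / cell);
    int cz = (int)std::floor(mz / cell);
    for (int ix = cx - 1; ix <= cx + 1; ++ix)
      for (int iy = cy - 1; iy <= cy + 1; ++iy)
        for (int iz = cz - 1; iz <= cz + 1; ++iz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            grid.find(cell_key(ix, iy, iz));
          if (it == grid.end()) continue;
          const std::vector<int> &bucket = it->second;
          for (size_t bi = 0; bi < bucket.size(); ++bi) {
            int j = bucket[bi];
            if (de_neuron[j] == ax_neuron[i]) continue; // no autapses
            d1[0] = de(j, 0); d1[1] = de(j, 1); d1[2] = de(j, 2);
            d2[0] = de(j, 3); d2[1] = de(j, 4); d2[2] = de(j, 5);
            double ld = std::sqrt((d2[0]-d1[0])*(d2[0]-d1[0]) + (d2[1]-d1[1])*(d2[1]-d1[1]) +
                                  (d2[2]-d1[2])*(d2[2]-d1[2]));
            if (ld < 1e-9) continue;
            Cross r = seg_cross(a1, a2, d1, d2);
            if (!r.crossing || r.dist >= threshold) continue;
            o_pre.push_back(ax_neuron[i]);
            o_post.push_back(de_neuron[j]);
            o_axid.push_back(ax_id[i]);
            o_deid.push_back(de_id[j]);
            o_kind.push_back(de_kind[j]);
            o_x.push_back(r.mid[0]); o_y.push_back(r.mid[1]); o_z.push_back(r.mid[2]);
            o_dist.push_back(r.dist);
            o_prepath.push_back(ax_path0[i] + r.s * la);
            o_postpath.push_back(de_path0[j] + r.t * ld);
          }
        }
  }
  return DataFrame::create(
    _["pre"] = o_pre, _["post"] = o_post,
    _["axonal_piece"] = o_axid, _["dendritic_piece"] = o_deid,
    _["x"] = o_x, _["y"] = o_y, _["z"] = o_z,
    _["orth_dist"] = o_dist, _["kind"] = o_kind,
    _["pre_path_dist"] = o_prepath, _["post_path_dist"] = o_postpath);
}
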