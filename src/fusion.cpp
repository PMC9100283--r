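#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// DBSCAN (density-based clustering) on small 3D candidate sets.
//
// Labels: 0 = NOISE, 1..k = cluster ids (contiguous). The neighbor test is a
// closed Euclidean inequality (distance <= eps) and a point's neighborhood
// includes the point itself, so with min_neighbors = 1 every point is a core
// point and no point is labeled NOISE. Expansion claims only still-unassigned
// points (a point labeled NOISE earlier in the scan order is not reclaimed as
// a border point).
// ---------------------------------------------------------------------------

static inline double dist2(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// pts: n x 3 row-major flat vector
static std::vector<int> dbscan_core(const std::vector<double> &pts, int n,
                                    double eps, int min_neighbors) {
  const double eps2 = eps * eps;
  std::vector<int> labels(n, -2); // -2 UNASSIGNED, -1 NOISE, >=1 cluster id
  std::vector<int> queue;
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != -2) continue;
    // SCAN(i)
    queue.clear();
    for (int z = 0; z < n; ++z)
      if (dist2(&pts[3 * i], &pts[3 * z]) <= eps2) queue.push_back(z);
    if ((int)queue.size() < min_neighbors) {
      labels[i] = -1;
      continue;
    }
    ++k;
    labels[i] = k;
    for (size_t pos = 0; pos < queue.size(); ++pos) {
      int z = queue[pos];
      if (labels[z] != -2) continue;
      labels[z] = k;
      std::vector<int> nz;
      for (int w = 0; w < n; ++w)
        if (dist2(&pts[3 * z], &pts[3 * w]) <= eps2) nz.push_back(w);
      if ((int)nz.size() >= min_neighbors)
        queue.insert(queue.end(), nz.begin(), nz.end());
    }
  }
  for (int i = 0; i < n; ++i)
    if (labels[i] == -1) labels[i] = 0;
  return labels;
}

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericMatrix pts, double eps, int min_neighbors) {
  int n = pts.nrow();
  std::vector<double> flat(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) flat[3 * i + j] = pts(i, j);
  std::vector<int> lab = dbscan_core(flat, n, eps, min_neighbors);
  return IntegerVector(lab.begin(), lab.end());
}

// ---------------------------------------------------------------------------
// Single-joint merge: cluster sensor candidates plus auxiliary candidates
// (cross-sensor reference position, previous merged position), pick the
// largest cluster, and return the centroid of the winning cluster's *sensor*
// members. Auxiliary candidates count toward cluster size but never toward
// the centroid.
//
// Tie rule for equally large clusters: prefer the cluster containing the
// reference candidate, then the one containing the previous position, then
// the one whose centroid is nearest the previous position, then the lowest
// cluster id.
//
// status: 0 = missing, 1 = merged, 2 = predicted_only
// ---------------------------------------------------------------------------

struct MergeOut {
  double pos[3];
  int n_contributing;
  int status;
};

static MergeOut merge_one(const std::vector<double> &sensor_pts,
                          bool has_ref, const double *refp,
                          bool has_prev, const double *prevp,
                          double eps, int min_neighbors) {
  MergeOut out;
  out.pos[0] = out.pos[1] = out.pos[2] = NA_REAL;
  out.n_contributing = 0;
  int ns = (int)sensor_pts.size() / 3;
  if (ns == 0) {
    if (has_prev) {
      out.status = 2;
      for (int d = 0; d < 3; ++d) out.pos[d] = prevp[d];
    } else {
      out.status = 0;
    }
    return out;
  }
  std::vector<double> pts(sensor_pts);
  int ref_idx = -1, prev_idx = -1;
  if (has_ref) {
    ref_idx = (int)pts.size() / 3;
    pts.insert(pts.end(), refp, refp + 3);
  }
  if (has_prev) {
    prev_idx = (int)pts.size() / 3;
    pts.insert(pts.end(), prevp, prevp + 3);
  }
  int n = (int)pts.size() / 3;
  std::vector<int> lab = dbscan_core(pts, n, eps, min_neighbors);
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, lab[i]);
  if (k == 0) { // everything NOISE (possible only when min_neighbors > n)
    if (has_prev) {
      out.status = 2;
      for (int d = 0; d < 3; ++d) out.pos[d] = prevp[d];
    } else out.status = 0;
    return out;
  }
  std::vector<int> size(k + 1, 0), nsen(k + 1, 0);
  std::vector<bool> hasref(k + 1, false), hasprev(k + 1, false);
  std::vector<double> cent(3 * (k + 1), 0.0), scent(3 * (k + 1), 0.0);
  for (int i = 0; i < n; ++i) {
    int c = lab[i];
    if (c == 0) continue;
    size[c]++;
    for (int d = 0; d < 3; ++d) cent[3 * c + d] += pts[3 * i + d];
    if (i == ref_idx) hasref[c] = true;
    else if (i == prev_idx) hasprev[c] = true;
    else {
      nsen[c]++;
      for (int d = 0; d < 3; ++d) scent[3 * c + d] += pts[3 * i + d];
    }
  }
  // choose winner among clusters with >= 1 sensor member preferred when the
  // overall winner would otherwise leave no fallback position
  auto better = [&](int a, int b) { // is a better than b?
    if (size[a] != size[b]) return size[a] > size[b];
    if (hasref[a] != hasref[b]) return (bool)hasref[a];
    if (hasprev[a] != hasprev[b]) return (bool)hasprev[a];
    if (has_prev) {
      double ca[3], cb[3];
      for (int d = 0; d < 3; ++d) {
        ca[d] = cent[3 * a + d] / size[a];
        cb[d] = cent[3 * b + d] / size[b];
      }
      double da = dist2(ca, prevp), db = dist2(cb, prevp);
      if (da != db) return da < db;
    }
    return a < b;
  };
  int win = 1;
  for (int c = 2; c <= k; ++c)
    if (better(c, win)) win = c;
  if (nsen[win] == 0) {
    if (has_prev) {
      out.status = 2;
      for (int d = 0; d < 3; ++d) out.pos[d] = prevp[d];
      return out;
    }
    // no previous position to fall back on: take the best sensor-containing
    // cluster instead
    int alt = -1;
    for (int c = 1; c <= k; ++c)
      if (nsen[c] > 0 && (alt < 0 || better(c, alt))) alt = c;
    if (alt < 0) { out.status = 0; return out; }
    win = alt;
  }
  out.status = 1;
  out.n_contributing = nsen[win];
  for (int d = 0; d < 3; ++d) out.pos[d] = scent[3 * win + d] / nsen[win];
  return out;
}

// [[Rcpp::export]]
List cpp_merge_joint(NumericMatrix candidates, NumericVector reference,
                     NumericVector previous, double eps, int min_neighbors) {
  std::vector<double> pts;
  for (int i = 0; i < candidates.nrow(); ++i)
    for (int d = 0; d < 3; ++d) pts.push_back(candidates(i, d));
  bool has_ref = reference.size() == 3;
  bool has_prev = previous.size() == 3;
  MergeOut m = merge_one(pts, has_ref, has_ref ? &reference[0] : NULL,
                         has_prev, has_prev ? &previous[0] : NULL,
                         eps, min_neighbors);
  return List::create(
      _["position"] = NumericVector::create(m.pos[0], m.pos[1], m.pos[2]),
      _["n_contributing"] = m.n_contributing, _["status"] = m.status);
}

// ---------------------------------------------------------------------------
// Streaming fusion engine.
//
// Inputs are flat per-observation vectors sorted by frame_index; joints and
// sensors are 0-based integer codes. conf: 2 = medium, 1 = low (confidence
// "none" rows are dropped upstream). mirror[j] is the contralateral joint
// index or -1 for midline joints.
//
// Per frame: (optional) left/right arrangement against cross-sensor
// reference positions; per-joint merge (plain averaging or DBSCAN with
// auxiliary candidates); (optional) per-joint constant-position Kalman
// tracking with isotropic covariance (the tracked output is the one-step
// prediction; the first tracked position equals the first measurement).
// ---------------------------------------------------------------------------

// reference position of one joint: mean of medium-confidence candidates,
// else mean of low-confidence candidates; false when no candidate
static bool reference_of(const std::vector<double> &pos,
                         const std::vector<int> &conf, int S, int j, int J,
                         double *out) {
  for (int level = 2; level >= 1; --level) {
    double acc[3] = {0, 0, 0};
    int cnt = 0;
    for (int s = 0; s < S; ++s) {
      int idx = s * J + j;
      if (conf[idx] == level) {
        for (int d = 0; d < 3; ++d) acc[d] += pos[3 * idx + d];
        ++cnt;
      }
    }
    if (cnt > 0) {
      for (int d = 0; d < 3; ++d) out[d] = acc[d] / cnt;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_fuse_stream(IntegerVector frame, IntegerVector sensor,
                     IntegerVector joint, NumericMatrix pos,
                     IntegerVector conf, int n_sensors, int n_joints,
                     IntegerVector mirror, IntegerVector is_right,
                     List config, List state) {
  const bool arrange = as<bool>(config["arrange"]);
  const bool use_dbscan = as<bool>(config["use_dbscan"]);
  const bool use_reference = as<bool>(config["use_reference"]);
  const bool use_previous = as<bool>(config["use_previous"]);
  const bool use_kalman = as<bool>(config["use_kalman"]);
  const double eps = as<double>(config["eps_mm"]);
  const int min_neighbors = as<int>(config["min_neighbors"]);
  const double q = as<double>(config["q"]);
  const double r = as<double>(config["r"]);
  const int max_predict = as<int>(config["max_predict"]);

  const int S = n_sensors, J = n_joints;
  const int nobs = frame.size();

  // persistent per-joint state (continued from `state` when provided)
  NumericMatrix prev_pos(J, 3);
  LogicalVector prev_valid(J);
  IntegerVector consec(J);
  LogicalVector k_init(J);
  NumericMatrix k_x(J, 3);
  NumericVector k_p(J);
  if (state.size() > 0) {
    prev_pos = clone(as<NumericMatrix>(state["prev_pos"]));
    prev_valid = clone(as<LogicalVector>(state["prev_valid"]));
    consec = clone(as<IntegerVector>(state["consec_predicted"]));
    k_init = clone(as<LogicalVector>(state["kalman_initialized"]));
    k_x = clone(as<NumericMatrix>(state["kalman_x"]));
    k_p = clone(as<NumericVector>(state["kalman_p"]));
  } else {
    for (int j = 0; j < J; ++j) {
      prev_valid[j] = false; consec[j] = 0; k_init[j] = false; k_p[j] = 1.0;
    }
  }

  int fmin = 0, fmax = -1;
  if (nobs > 0) {
    fmin = frame[0];
    fmax = frame[nobs - 1];
    for (int i = 1; i < nobs; ++i)
      if (frame[i] < frame[i - 1])
        stop("stream-order error: frame indices are not non-decreasing");
  }
  const int nframes = (nobs > 0) ? (fmax - fmin + 1) : 0;

  IntegerVector out_frame(nframes * J), out_joint(nframes * J),
      out_status(nframes * J), out_ncon(nframes * J);
  NumericMatrix out_pos(nframes * J, 3);
  std::fill(out_pos.begin(), out_pos.end(), NA_REAL);

  // per-frame working arrays
  std::vector<double> fpos(3 * S * J);
  std::vector<int> fconf(S * J);

  int row = 0;
  for (int f = fmin; f <= fmax; ++f) {
    std::fill(fconf.begin(), fconf.end(), 0);
    while (row < nobs && frame[row] == f) {
      int idx = sensor[row] * J + joint[row];
      fconf[idx] = conf[row];
      for (int d = 0; d < 3; ++d) fpos[3 * idx + d] = pos(row, d);
      ++row;
    }

    if (arrange) {
      for (int jr = 0; jr < J; ++jr) {
        if (!is_right[jr]) continue; // the checking rule uses the right-side
        int jl = mirror[jr];         // joint's reference position
        if (jl < 0) continue;
        double ref_r[3];
        if (!reference_of(fpos, fconf, S, jr, J, ref_r)) continue;
        for (int s = 0; s < S; ++s) {
          int ir = s * J + jr, il = s * J + jl;
          if (fconf[ir] == 0 || fconf[il] == 0) continue;
          double d_correct = dist2(ref_r, &fpos[3 * ir]);
          double d_wrong = dist2(ref_r, &fpos[3 * il]);
          if (d_correct > d_wrong) {
            for (int d = 0; d < 3; ++d)
              std::swap(fpos[3 * ir + d], fpos[3 * il + d]);
            std::swap(fconf[ir], fconf[il]);
          }
        }
      }
    }

    for (int j = 0; j < J; ++j) {
      MergeOut m;
      if (!use_dbscan) { // plain averaging (variants A1/A2)
        double acc[3] = {0, 0, 0};
        int cnt = 0;
        for (int s = 0; s < S; ++s) {
          int idx = s * J + j;
          if (fconf[idx] >= 1) {
            for (int d = 0; d < 3; ++d) acc[d] += fpos[3 * idx + d];
            ++cnt;
          }
        }
        if (cnt > 0) {
          m.status = 1;
          m.n_contributing = cnt;
          for (int d = 0; d < 3; ++d) m.pos[d] = acc[d] / cnt;
        } else {
          m.status = 0;
          m.n_contributing = 0;
          m.pos[0] = m.pos[1] = m.pos[2] = NA_REAL;
        }
      } else {
        std::vector<double> cands;
        for (int s = 0; s < S; ++s) {
          int idx = s * J + j;
          if (fconf[idx] >= 1)
            cands.insert(cands.end(), &fpos[3 * idx], &fpos[3 * idx] + 3);
        }
        double refp[3];
        bool has_ref = use_reference &&
                       reference_of(fpos, fconf, S, j, J, refp);
        bool has_prev = use_previous && prev_valid[j];
        double prevp[3];
        if (has_prev)
          for (int d = 0; d < 3; ++d) prevp[d] = prev_pos(j, d);
        m = merge_one(cands, has_ref, refp, has_prev, prevp, eps,
                      min_neighbors);
      }

      // previous-position bookkeeping and sustained-dropout cutoff
      if (m.status == 1) {
        consec[j] = 0;
        prev_valid[j] = true;
        for (int d = 0; d < 3; ++d) prev_pos(j, d) = m.pos[d];
      } else if (m.status == 2) {
        consec[j] += 1;
        if (consec[j] > max_predict) {
          m.status = 0;
          m.pos[0] = m.pos[1] = m.pos[2] = NA_REAL;
          prev_valid[j] = false;
          k_init[j] = false;
        }
      }

      double out_xyz[3] = {m.pos[0], m.pos[1], m.pos[2]};
      if (use_kalman) {
        if (m.status == 1) {
          if (!k_init[j]) {
            k_init[j] = true;
            k_p[j] = 1.0;
            for (int d = 0; d < 3; ++d) k_x(j, d) = m.pos[d];
            // first tracked position equals the first measurement
          } else {
            double p_pred = k_p[j] + q;
            double K = p_pred / (p_pred + r);
            for (int d = 0; d < 3; ++d) {
              double x_pred = k_x(j, d);
              out_xyz[d] = x_pred; // tracked output = prediction
              k_x(j, d) = x_pred + K * (m.pos[d] - x_pred);
            }
            k_p[j] = (1.0 - K) * p_pred;
          }
        } else if (m.status == 2 && k_init[j]) {
          k_p[j] += q; // predict without correction
          for (int d = 0; d < 3; ++d) out_xyz[d] = k_x(j, d);
        }
      }

      int o = (f - fmin) * J + j;
      out_frame[o] = f;
      out_joint[o] = j;
      out_status[o] = m.status;
      out_ncon[o] = m.n_contributing;
      if (m.status != 0)
        for (int d = 0; d < 3; ++d) out_pos(o, d) = out_xyz[d];
    }
  }

  List out_state = List::create(
      _["prev_pos"] = prev_pos, _["prev_valid"] = prev_valid,
      _["consec_predicted"] = consec, _["kalman_initialized"] = k_init,
      _["kalman_x"] = k_x, _["kalman_p"] = k_p);
  return List::create(
      _["frame_index"] = out_frame, _["joint"] = out_joint,
      _["pos"] = out_pos, _["status"] = out_status,
      _["n_contributing"] = out_ncon, _["state"] = out_state);
}

// ---------------------------------------------------------------------------
// Arrangement only: corrects left/right labels per sensor against the
// cross-sensor reference and reports which observations were swapped.
// Input rows must be sorted by frame_index.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_arrange_stream(IntegerVector frame, IntegerVector sensor,
                        IntegerVector joint, NumericMatrix pos,
                        IntegerVector conf, int n_sensors, int n_joints,
                        IntegerVector mirror, IntegerVector is_right) {
  const int S = n_sensors, J = n_joints;
  const int nobs = frame.size();
  NumericMatrix out_pos = clone(pos);
  IntegerVector out_conf = clone(conf);
  LogicalVector swapped(nobs);

  std::vector<double> fpos(3 * S * J);
  std::vector<int> fconf(S * J), frow(S * J);

  int row = 0;
  while (row < nobs) {
    int f = frame[row];
    std::fill(fconf.begin(), fconf.end(), 0);
    std::fill(frow.begin(), frow.end(), -1);
    int start = row;
    while (row < nobs && frame[row] == f) {
      if (frame[row] < f)
        stop("stream-order error: frame indices are not non-decreasing");
      int idx = sensor[row] * J + joint[row];
      fconf[idx] = conf[row];
      frow[idx] = row;
      for (int d = 0; d < 3; ++d) fpos[3 * idx + d] = pos(row, d);
      ++row;
    }
    (void)start;
    for (int jr = 0; jr < J; ++jr) {
      if (!is_right[jr]) continue;
      int jl = mirror[jr];
      if (jl < 0) continue;
      double ref_r[3];
      if (!reference_of(fpos, fconf, S, jr, J, ref_r)) continue;
      for (int s = 0; s < S; ++s) {
        int ir = s * J + jr, il = s * J + jl;
        if (fconf[ir] == 0 || fconf[il] == 0) continue;
        double d_correct = dist2(ref_r, &fpos[3 * ir]);
        double d_wrong = dist2(ref_r, &fpos[3 * il]);
        if (d_correct > d_wrong) {
          int rr = frow[ir], rl = frow[il];
          for (int d = 0; d < 3; ++d) {
            out_pos(rr, d) = pos(rl, d);
            out_pos(rl, d) = pos(rr, d);
          }
          out_conf[rr] = conf[rl];
          out_conf[rl] = conf[rr];
          swapped[rr] = true;
          swapped[rl] = true;
        }
      }
    }
  }
  return List::create(_["pos"] = out_pos, _["conf"] = out_conf,
                      _["swapped"] = swapped);
}
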