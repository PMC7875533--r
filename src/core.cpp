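// Langevin dynamics core for a semiflexible bead-spring DNA chain with
// diffusing multivalent bridge particles (bridging-induced phase separation).
//
// Reduced units: bead diameter sigma = 1, k_B T = 1, bead mass m = 1.
// Integration: BAOAB Langevin splitting (one force evaluation per step).
// Binding: Metropolis bond moves with a hard valence cap and proposal-count
// correction so detailed balance holds for frozen configurations.
//
// Deterministic for a given seed: single-threaded, fixed iteration order,
// own Box-Muller normals on top of mt19937_64 (std distributions are
// implementation-defined and would not be portable).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {  // (0,1)
    const uint64_t x = eng() >> 11;
    return (static_cast<double>(x) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    const double u1 = unif(), u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  int below(int n) {  // uniform integer in [0, n)
    return std::min(n - 1, static_cast<int>(unif() * n));
  }
};

inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

inline double mind1(double d, double L) {
  if (L > 0.0) d -= L * std::nearbyint(d / L);
  return d;
}

struct CellList {
  int nc = 0;          // cells per dimension (0 => brute force)
  double L = 0.0, cw = 0.0;
  std::vector<int> head, nxt;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double box, double cutoff) {
    L = box;
    const int n = static_cast<int>(x.size());
    nc = (box > 0.0) ? static_cast<int>(std::floor(box / cutoff)) : 0;
    if (nc < 4) { nc = 0; return; }  // brute force for tiny boxes
    cw = box / nc;
    head.assign(static_cast<size_t>(nc) * nc * nc, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      const int cx = static_cast<int>(wrap1(x[i], L) / cw) % nc;
      const int cy = static_cast<int>(wrap1(y[i], L) / cw) % nc;
      const int cz = static_cast<int>(wrap1(z[i], L) / cw) % nc;
      const int c = (cz * nc + cy) * nc + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

struct Sys {
  int n_beads = 0, n_bridges = 0, n = 0;
  double L = 0.0;                      // box side; <= 0 means open boundaries
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<char> bindable;          // per chain bead
  std::vector<std::vector<int>> bonds; // per bridge: bound bead indices
  std::vector<int> bead_links;         // bridges bound per bead (bookkeeping)
  // force field
  double fene_k = 30.0, fene_r0 = 1.5, kappa = 0.0;
  bool wca = true;
  double wca_eps = 1.0;
  // binding
  double eps_bind = 4.0, r_capture = 1.5, k_bond = 40.0, r0_bond = 1.12246204830937;
  int valence = 2, seg_excl = 2;
  double wca_cut = 1.12246204830937, wca_cut2 = wca_cut * wca_cut;
  CellList cl;
  // Verlet neighbour list for the nonbonded WCA loop
  double skin = 0.4;
  bool nl_dirty = true;
  std::vector<int> nl_i, nl_j;
  std::vector<double> x0, y0, z0;

  bool nl_stale() const {
    const double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      const double a = mind1(x[i] - x0[i], L), b = mind1(y[i] - y0[i], L),
                   c = mind1(z[i] - z0[i], L);
      if (a * a + b * b + c * c > lim) return true;
    }
    return false;
  }

  void build_nlist() {
    const double rl = wca_cut + skin;
    const double rl2 = rl * rl;
    nl_i.clear(); nl_j.clear();
    cl.build(x, y, z, L, rl);
    auto consider = [&](int i, int j) {
      if (j < n_beads && i < n_beads && std::abs(i - j) == 1) return;
      if (dist2(i, j) <= rl2) { nl_i.push_back(i); nl_j.push_back(j); }
    };
    if (cl.nc == 0) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) consider(i, j);
    } else {
      const int nc = cl.nc;
      for (int i = 0; i < n; ++i) {
        const int cx = static_cast<int>(wrap1(x[i], L) / cl.cw) % nc;
        const int cy = static_cast<int>(wrap1(y[i], L) / cl.cw) % nc;
        const int cz = static_cast<int>(wrap1(z[i], L) / cl.cw) % nc;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              const int ccx = (cx + ox + nc) % nc;
              const int ccy = (cy + oy + nc) % nc;
              const int ccz = (cz + oz + nc) % nc;
              for (int j = cl.head[(static_cast<size_t>(ccz) * nc + ccy) * nc + ccx];
                   j >= 0; j = cl.nxt[j])
                if (j > i) consider(i, j);
            }
      }
    }
    x0 = x; y0 = y; z0 = z;
    nl_dirty = false;
  }

  double dx(int i, int j) const { return mind1(x[i] - x[j], L); }
  double dy(int i, int j) const { return mind1(y[i] - y[j], L); }
  double dz(int i, int j) const { return mind1(z[i] - z[j], L); }
  double dist2(int i, int j) const {
    const double a = dx(i, j), b = dy(i, j), c = dz(i, j);
    return a * a + b * b + c * c;
  }

  void add_wca(int i, int j) {
    const double a = dx(i, j), b = dy(i, j), c = dz(i, j);
    const double r2 = a * a + b * b + c * c;
    if (r2 >= wca_cut2 || r2 <= 1e-12) return;
    const double ir2 = 1.0 / r2;
    const double ir6 = ir2 * ir2 * ir2;
    const double fmag = 24.0 * wca_eps * ir6 * (2.0 * ir6 - 1.0) * ir2;  // F/r
    fx[i] += fmag * a; fy[i] += fmag * b; fz[i] += fmag * c;
    fx[j] -= fmag * a; fy[j] -= fmag * b; fz[j] -= fmag * c;
  }

  void forces() {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    const double r02 = fene_r0 * fene_r0;
    // FENE backbone (+ WCA between bonded neighbours)
    for (int i = 0; i + 1 < n_beads; ++i) {
      const int j = i + 1;
      const double a = dx(j, i), b = dy(j, i), c = dz(j, i);
      const double r2 = a * a + b * b + c * c;
      if (r2 >= r02)
        stop("FENE bond %d-%d reached maximum extension (r=%.3f): timestep too large",
             i + 1, j + 1, std::sqrt(r2));
      const double fmag = -fene_k / (1.0 - r2 / r02);  // F/r on j along (j-i)
      fx[j] += fmag * a; fy[j] += fmag * b; fz[j] += fmag * c;
      fx[i] -= fmag * a; fy[i] -= fmag * b; fz[i] -= fmag * c;
      add_wca(i, j);  // bonded-pair repulsion is part of the bond potential
                      // (keeps the rest length ~0.97 sigma even for phantom
                      // chains, where only nonbonded WCA is switched off)
    }
    // Kratky-Porod bending: U = kappa (1 - cos theta)
    if (kappa > 0.0) {
      for (int i = 1; i + 1 < n_beads; ++i) {
        const double b1x = dx(i, i - 1), b1y = dy(i, i - 1), b1z = dz(i, i - 1);
        const double b2x = dx(i + 1, i), b2y = dy(i + 1, i), b2z = dz(i + 1, i);
        const double n1 = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
        const double n2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
        const double ux = b1x / n1, uy = b1y / n1, uz = b1z / n1;
        const double vx_ = b2x / n2, vy_ = b2y / n2, vz_ = b2z / n2;
        const double cth = ux * vx_ + uy * vy_ + uz * vz_;
        // F_{i-1} = -kappa (v - c u)/|b1| ; F_{i+1} = kappa (u - c v)/|b2|
        const double f0x = -kappa * (vx_ - cth * ux) / n1;
        const double f0y = -kappa * (vy_ - cth * uy) / n1;
        const double f0z = -kappa * (vz_ - cth * uz) / n1;
        const double f2x = kappa * (ux - cth * vx_) / n2;
        const double f2y = kappa * (uy - cth * vy_) / n2;
        const double f2z = kappa * (uz - cth * vz_) / n2;
        fx[i - 1] += f0x; fy[i - 1] += f0y; fz[i - 1] += f0z;
        fx[i + 1] += f2x; fy[i + 1] += f2y; fz[i + 1] += f2z;
        fx[i] -= f0x + f2x; fy[i] -= f0y + f2y; fz[i] -= f0z + f2z;
      }
    }
    // nonbonded WCA via the Verlet neighbour list
    if (wca && n > 1) {
      if (nl_dirty || nl_stale()) build_nlist();
      for (size_t k = 0; k < nl_i.size(); ++k) add_wca(nl_i[k], nl_j[k]);
    }
    // bridge-bead harmonic bonds
    for (int b = 0; b < n_bridges; ++b) {
      const int ib = n_beads + b;
      for (int bead : bonds[b]) {
        const double a = dx(ib, bead), bb = dy(ib, bead), c = dz(ib, bead);
        const double r = std::sqrt(a * a + bb * bb + c * c);
        if (r < 1e-9) continue;
        const double fmag = -k_bond * (r - r0_bond) / r;
        fx[ib] += fmag * a; fy[ib] += fmag * bb; fz[ib] += fmag * c;
        fx[bead] -= fmag * a; fy[bead] -= fmag * bb; fz[bead] -= fmag * c;
      }
    }
  }

  double bond_energy(int bridge, int bead) const {
    const int ib = n_beads + bridge;
    const double r = std::sqrt(dist2(ib, bead));
    const double d = r - r0_bond;
    return 0.5 * k_bond * d * d - eps_bind;
  }

  // One Metropolis sweep over bridges: each bridge proposes (with prob 1/2)
  // a bond creation to a random in-range bindable bead, else a deletion of a
  // random existing bond. Proposal-count ratios keep detailed balance.
  void binding_sweep(Rng& rng, std::vector<int>& scratch) {
    if (n_bridges == 0) return;
    cl.build(x, y, z, L, std::max(wca_cut, r_capture));
    const double rc2 = r_capture * r_capture;
    for (int b = 0; b < n_bridges; ++b) {
      const int ib = n_beads + b;
      // candidates: bindable beads within capture radius, not bonded to b
      scratch.clear();
      if (cl.nc == 0) {
        for (int j = 0; j < n_beads; ++j)
          if (bindable[j] && dist2(ib, j) <= rc2) scratch.push_back(j);
      } else {
        const int nc = cl.nc;
        const int cx = static_cast<int>(wrap1(x[ib], L) / cl.cw) % nc;
        const int cy = static_cast<int>(wrap1(y[ib], L) / cl.cw) % nc;
        const int cz = static_cast<int>(wrap1(z[ib], L) / cl.cw) % nc;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              const int ccx = (cx + ox + nc) % nc;
              const int ccy = (cy + oy + nc) % nc;
              const int ccz = (cz + oz + nc) % nc;
              for (int j = cl.head[(static_cast<size_t>(ccz) * nc + ccy) * nc + ccx];
                   j >= 0; j = cl.nxt[j])
                if (j < n_beads && bindable[j] && dist2(ib, j) <= rc2)
                  scratch.push_back(j);
            }
        std::sort(scratch.begin(), scratch.end());
      }
      // `scratch` now holds every in-range bindable bead. Candidates for
      // bond creation additionally exclude beads this bridge already holds
      // and -- because a bridge's binding sites sit on distinct faces and
      // engage distinct DNA segments -- beads within seg_excl of one it
      // holds. The same count in the post-move state enters the reverse-move
      // proposal probability, so detailed balance holds exactly.
      auto n_candidates = [&](int skip_bead) {
        int cnt = 0;
        for (int j : scratch) {
          bool blocked = false;
          for (int bead : bonds[b]) {
            if (bead == skip_bead) continue;
            if (std::abs(j - bead) <= seg_excl) { blocked = true; break; }
          }
          if (!blocked) ++cnt;
        }
        return cnt;
      };
      const int nb = static_cast<int>(bonds[b].size());
      if (rng.unif() < 0.5) {  // creation
        if (nb >= valence) continue;
        // filtered candidate list for the forward proposal
        std::vector<int> cand;
        for (int j : scratch) {
          bool blocked = false;
          for (int bead : bonds[b])
            if (std::abs(j - bead) <= seg_excl) { blocked = true; break; }
          if (!blocked) cand.push_back(j);
        }
        const int ncand = static_cast<int>(cand.size());
        if (ncand == 0) continue;
        const int bead = cand[rng.below(ncand)];
        const double dE = bond_energy(b, bead);
        const double acc = (static_cast<double>(ncand) / (nb + 1)) * std::exp(-dE);
        if (rng.unif() < acc) {
          bonds[b].push_back(bead);
          ++bead_links[bead];
        }
      } else {  // deletion
        if (nb == 0) continue;
        const int k = rng.below(nb);
        const int bead = bonds[b][k];
        const double Eb = bond_energy(b, bead);
        const double r2 = dist2(ib, bead);
        double acc;
        if (r2 > rc2) {
          acc = 1.0;  // stretched beyond capture: always release
        } else {
          const int ncand_after = n_candidates(bead);  // includes `bead`
          acc = (static_cast<double>(nb) / ncand_after) * std::exp(Eb);
        }
        if (rng.unif() < acc) {
          bonds[b][k] = bonds[b].back();
          bonds[b].pop_back();
          --bead_links[bead];
        }
      }
    }
  }
};

Sys make_sys(NumericMatrix pos, NumericMatrix vel, IntegerMatrix bond_mat,
             int n_beads, LogicalVector bindable, double box, List ff) {
  Sys s;
  s.n = pos.nrow();
  s.n_beads = n_beads;
  s.n_bridges = s.n - n_beads;
  s.L = box;
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.vx.resize(s.n); s.vy.resize(s.n); s.vz.resize(s.n);
  s.fx.resize(s.n); s.fy.resize(s.n); s.fz.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
  }
  s.bindable.resize(n_beads);
  for (int i = 0; i < n_beads; ++i) s.bindable[i] = bindable[i] ? 1 : 0;
  s.bonds.assign(std::max(s.n_bridges, 0), {});
  s.bead_links.assign(n_beads, 0);
  for (int k = 0; k < bond_mat.nrow(); ++k) {
    const int b = bond_mat(k, 0) - 1;  // 1-based from R
    const int bead = bond_mat(k, 1) - 1;
    s.bonds[b].push_back(bead);
    ++s.bead_links[bead];
  }
  s.fene_k = ff["fene_k"]; s.fene_r0 = ff["fene_r0"];
  s.kappa = ff["kappa"];
  s.wca = ff["wca"]; s.wca_eps = ff["wca_eps"];
  s.eps_bind = ff["eps_bind"]; s.r_capture = ff["r_capture"];
  s.k_bond = ff["k_bond"]; s.r0_bond = ff["r0_bond"];
  s.valence = ff["valence"];
  s.seg_excl = ff["seg_excl"];
  return s;
}

IntegerMatrix bonds_out(const Sys& s) {
  int m = 0;
  for (const auto& v : s.bonds) m += static_cast<int>(v.size());
  IntegerMatrix out(m, 2);
  int k = 0;
  for (int b = 0; b < s.n_bridges; ++b)
    for (int bead : s.bonds[b]) {
      out(k, 0) = b + 1;
      out(k, 1) = bead + 1;
      ++k;
    }
  return out;
}

NumericMatrix pos_out(const Sys& s) {
  NumericMatrix out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i];
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerMatrix bond_mat,
             int n_beads, LogicalVector bindable, double box, List ff,
             double dt, double friction, int n_steps, int bind_every,
             int snap_stride, double seed) {
  Sys s = make_sys(pos, vel, bond_mat, n_beads, bindable, box, ff);
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> scratch;

  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);  // kT = m = 1
  List snaps;
  std::vector<NumericMatrix> snap_pos;
  std::vector<IntegerMatrix> snap_bonds;
  s.forces();
  for (int step = 1; step <= n_steps; ++step) {
    // BAOAB
    for (int i = 0; i < s.n; ++i) {
      s.vx[i] += 0.5 * dt * s.fx[i];
      s.vy[i] += 0.5 * dt * s.fy[i];
      s.vz[i] += 0.5 * dt * s.fz[i];
      s.x[i] += 0.5 * dt * s.vx[i];
      s.y[i] += 0.5 * dt * s.vy[i];
      s.z[i] += 0.5 * dt * s.vz[i];
      s.vx[i] = c1 * s.vx[i] + c2 * rng.norm();
      s.vy[i] = c1 * s.vy[i] + c2 * rng.norm();
      s.vz[i] = c1 * s.vz[i] + c2 * rng.norm();
      s.x[i] += 0.5 * dt * s.vx[i];
      s.y[i] += 0.5 * dt * s.vy[i];
      s.z[i] += 0.5 * dt * s.vz[i];
    }
    if (s.L > 0.0) {
      for (int i = 0; i < s.n; ++i) {
        s.x[i] = wrap1(s.x[i], s.L);
        s.y[i] = wrap1(s.y[i], s.L);
        s.z[i] = wrap1(s.z[i], s.L);
      }
    }
    if (bind_every > 0 && s.n_bridges > 0 && step % bind_every == 0)
      s.binding_sweep(rng, scratch);
    s.forces();
    for (int i = 0; i < s.n; ++i) {
      s.vx[i] += 0.5 * dt * s.fx[i];
      s.vy[i] += 0.5 * dt * s.fy[i];
      s.vz[i] += 0.5 * dt * s.fz[i];
    }
    if (snap_stride > 0 && step % snap_stride == 0) {
      snap_pos.push_back(pos_out(s));
      snap_bonds.push_back(bonds_out(s));
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  List sp(snap_pos.size()), sb(snap_bonds.size());
  for (size_t i = 0; i < snap_pos.size(); ++i) { sp[i] = snap_pos[i]; sb[i] = snap_bonds[i]; }
  return List::create(_["pos"] = pos_out(s), _["vel"] = [&] {
                        NumericMatrix v(s.n, 3);
                        for (int i = 0; i < s.n; ++i) {
                          v(i, 0) = s.vx[i]; v(i, 1) = s.vy[i]; v(i, 2) = s.vz[i];
                        }
                        return v;
                      }(),
                      _["bonds"] = bonds_out(s), _["snap_pos"] = sp,
                      _["snap_bonds"] = sb);
}

// Binding sweeps with frozen particle positions (Monte Carlo only); used for
// equilibrium-occupancy checks and as the update_binding primitive.
// [[Rcpp::export]]
List cpp_binding_sweeps(NumericMatrix pos, IntegerMatrix bond_mat, int n_beads,
                        LogicalVector bindable, double box, List ff,
                        int n_sweeps, double seed, int record_every = 0) {
  NumericMatrix vel(pos.nrow(), 3);
  Sys s = make_sys(pos, vel, bond_mat, n_beads, bindable, box, ff);
  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> scratch;
  std::vector<double> occupancy;
  for (int k = 0; k < n_sweeps; ++k) {
    s.binding_sweep(rng, scratch);
    if (record_every > 0 && (k + 1) % record_every == 0) {
      int m = 0;
      for (const auto& v : s.bonds) m += static_cast<int>(v.size());
      occupancy.push_back(m);
    }
  }
  return List::create(_["bonds"] = bonds_out(s), _["n_bonds_trace"] = wrap(occupancy));
}

// All particle pairs closer than `cutoff` (minimum image if box > 0).
// Returns an m x 2 matrix of 1-based index pairs (i < j).
// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pos, double box, double cutoff) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  const double c2 = cutoff * cutoff;
  std::vector<std::pair<int, int>> out;
  CellList cl;
  cl.build(x, y, z, box, cutoff);
  auto check = [&](int i, int j) {
    const double a = mind1(x[i] - x[j], box), b = mind1(y[i] - y[j], box),
                 c = mind1(z[i] - z[j], box);
    if (a * a + b * b + c * c <= c2) out.emplace_back(i, j);
  };
  if (cl.nc == 0) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) check(i, j);
  } else {
    const int nc = cl.nc;
    for (int i = 0; i < n; ++i) {
      const int cx = static_cast<int>(wrap1(x[i], box) / cl.cw) % nc;
      const int cy = static_cast<int>(wrap1(y[i], box) / cl.cw) % nc;
      const int cz = static_cast<int>(wrap1(z[i], box) / cl.cw) % nc;
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            const int ccx = (cx + ox + nc) % nc;
            const int ccy = (cy + oy + nc) % nc;
            const int ccz = (cz + oz + nc) % nc;
            for (int j = cl.head[(static_cast<size_t>(ccz) * nc + ccy) * nc + ccx];
                 j >= 0; j = cl.nxt[j])
              if (j > i) check(i, j);
          }
    }
  }
  std::sort(out.begin(), out.end());
  IntegerMatrix res(static_cast<int>(out.size()), 2);
  for (size_t k = 0; k < out.size(); ++k) {
    res(k, 0) = out[k].first + 1;
    res(k, 1) = out[k].second + 1;
  }
  return res;
}
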