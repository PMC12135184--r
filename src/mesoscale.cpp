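// Coarse-grained chromatin-fiber model and Metropolis Monte Carlo sampler.
//
// Sites (all coordinates nm, energies kBT):
//   CENTER  rigid nucleosome-core centroid (core-core soft excluded volume)
//   CHARGE  12 rigid surface pseudo-charges per core (8 rim + 4 face
//           patches; default rim -7.5 e, faces 0: sum -60 e)
//   ANCHOR  rigid DNA exit/entry points on the core superhelix
//   PHANTOM rigid tangent-direction markers for entry/exit bend joints
//   LH      rigid linker-histone beads: two 3-bead rows flanking the
//           dyad axis (stem zipper)
//   TAILA   rigid histone-tail anchor points
//   TAIL    mobile histone-tail beads (8 chains x 3 beads)
//   LINK    mobile linker-DNA beads (3 nm = 8.8235 bp each, -4.2 e)
//
// Energy: harmonic stretch about 3 nm (zero-linker spring included),
// discrete worm-like-chain bending (modulus Lp/l0 per joint, including the
// entry/exit joints fixed in the core frame), screened Coulomb over charged
// non-bonded pairs (DNA-DNA pairs may use a separate screening length for
// implicit Mg2+), purely repulsive truncated-shifted 12-6 excluded volume,
// and a capped core-core soft term allowing nucleosome overlap.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

enum SiteType { CENTER = 0, CHARGE = 1, ANCHOR = 2, PHANTOM = 3,
                LH = 4, TAILA = 5, TAIL = 6, LINK = 7 };

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  Vec3 unit() const { double n = norm(); return Vec3(x / n, y / n, z / n); }
};

struct Mat3 {
  double m[9]; // row-major
  Mat3() { std::memset(m, 0, sizeof(m)); m[0] = m[4] = m[8] = 1.0; }
  Vec3 apply(const Vec3& v) const {
    return Vec3(m[0] * v.x + m[1] * v.y + m[2] * v.z,
                m[3] * v.x + m[4] * v.y + m[5] * v.z,
                m[6] * v.x + m[7] * v.y + m[8] * v.z);
  }
  Mat3 mul(const Mat3& o) const {
    Mat3 r;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += m[3 * i + k] * o.m[3 * k + j];
        r.m[3 * i + j] = s;
      }
    return r;
  }
};

static Mat3 axis_angle(const Vec3& axis, double angle) {
  Vec3 u = axis.unit();
  double c = std::cos(angle), s = std::sin(angle), t = 1 - c;
  Mat3 R;
  R.m[0] = c + u.x * u.x * t;     R.m[1] = u.x * u.y * t - u.z * s; R.m[2] = u.x * u.z * t + u.y * s;
  R.m[3] = u.y * u.x * t + u.z * s; R.m[4] = c + u.y * u.y * t;     R.m[5] = u.y * u.z * t - u.x * s;
  R.m[6] = u.z * u.x * t - u.y * s; R.m[7] = u.z * u.y * t + u.x * s; R.m[8] = c + u.z * u.z * t;
  return R;
}

struct Bond { int i, j; double r0, k; };
struct Bend { int a, b, c; double g; };   // g*(1-cos theta) at vertex b

struct Params {
  double l0, k_dna, k_zero, k_tail, tail_l0;
  double lp;                 // nm -> bend modulus lp/l0 per DNA joint
  double lB;                 // Bjerrum length, kBT units
  double lambda_gen, lambda_dna;
  double q_link, q_charge, q_face, q_tail, q_lh;
  double sig_link, sig_charge, sig_face, sig_tail, sig_lh;
  double eps_ev, ev_cap;
  double sig_cc, cap_cc;     // core-core soft excluded volume
  double elec_cutoff_factor; // skip pairs beyond factor*lambda
  bool charges_on;
  double cut2;               // global squared interaction range
  double cut2_nb;            // squared range for non-center pairs
};

static Params read_params(const List& p) {
  Params q;
  q.l0 = p["l0"]; q.k_dna = p["k_dna"]; q.k_zero = p["k_zero"];
  q.k_tail = p["k_tail"]; q.tail_l0 = p["tail_l0"];
  q.lp = p["lp"]; q.lB = p["lB"];
  q.lambda_gen = p["lambda_gen"]; q.lambda_dna = p["lambda_dna"];
  q.q_link = p["q_link"]; q.q_charge = p["q_charge"];
  q.q_face = p["q_face"];
  q.q_tail = p["q_tail"]; q.q_lh = p["q_lh"];
  q.sig_link = p["sig_link"]; q.sig_charge = p["sig_charge"];
  q.sig_face = p["sig_face"];
  q.sig_tail = p["sig_tail"]; q.sig_lh = p["sig_lh"];
  q.eps_ev = p["eps_ev"]; q.ev_cap = p["ev_cap"];
  q.sig_cc = p["sig_cc"]; q.cap_cc = p["cap_cc"];
  q.elec_cutoff_factor = p["elec_cutoff_factor"];
  q.charges_on = as<bool>(p["charges_on"]);
  double maxsig = std::max(std::max(q.sig_link, q.sig_charge),
                           std::max(q.sig_tail, q.sig_lh));
  double rng_nb = std::max(q.elec_cutoff_factor *
                               std::max(q.lambda_gen, q.lambda_dna),
                           1.122462 * maxsig);
  q.cut2_nb = rng_nb * rng_nb;
  double rng = std::max(rng_nb, 1.122462 * q.sig_cc);
  q.cut2 = rng * rng;
  return q;
}

// ---------------------------------------------------------------------------

class Fiber {
public:
  int n_cores;
  std::vector<int> nbeads;        // per linker
  std::vector<double> linker_bp;
  std::vector<int> lh_on;
  Params par;

  // site arrays
  std::vector<Vec3> pos;
  std::vector<int> type, core_of, linker_of, rank, tail_chain;
  std::vector<double> chainpos;   // position along the fiber chain
  std::vector<double> charge, sigma;
  std::vector<Vec3> local;        // rigid-site coords in the core frame
  std::vector<int> center_site, anchor_exit, anchor_entry,
      phantom_exit, phantom_entry;
  std::vector<std::vector<int> > core_sites;   // rigid sites + tail beads
  std::vector<Vec3> core_pos;
  std::vector<Mat3> core_R;
  std::vector<int> mobile;        // LINK + TAIL site indices
  std::vector<int> inter;         // sites with nonbonded interactions
  std::vector<std::vector<int> > linker_sites; // per linker bead indices
  std::vector<Bond> bonds;
  std::vector<Bend> bends;
  std::vector<std::vector<int> > bonds_of, bends_of; // per-site membership

  // core geometry constants (nm): effective LH-closed wrap, dyad on +x;
  // the flattened pitch lets entry/exit linkers appose into stems
  static constexpr double SH_R = 4.18, SH_PITCH = 0.7, SH_TURNS = 1.58;

  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;
  std::uniform_real_distribution<double> unif;

  Fiber(const IntegerVector& nb, const NumericVector& lbp,
        const IntegerVector& lh, const List& parlist, uint64_t seed)
      : gauss(0.0, 1.0), unif(0.0, 1.0) {
    n_cores = nb.size() + 1;
    nbeads.assign(nb.begin(), nb.end());
    linker_bp.assign(lbp.begin(), lbp.end());
    lh_on.assign(lh.begin(), lh.end());
    par = read_params(parlist);
    rng.seed(seed);
    build_topology();
    init_configuration();
  }

  int add_site(int t, int core, int link, int rk, int chain, double cp) {
    pos.push_back(Vec3());
    type.push_back(t); core_of.push_back(core); linker_of.push_back(link);
    rank.push_back(rk); tail_chain.push_back(chain); chainpos.push_back(cp);
    double q = 0, s = 0;
    switch (t) {
      case CHARGE: q = par.q_charge; s = par.sig_charge; break;
      case LH:     q = par.q_lh;     s = par.sig_lh; break;
      case TAIL:   q = par.q_tail;   s = par.sig_tail; break;
      case LINK:   q = par.q_link;   s = par.sig_link; break;
      default: break;
    }
    charge.push_back(q); sigma.push_back(s);
    local.push_back(Vec3());
    return (int)pos.size() - 1;
  }

  // superhelix point and tangent at angle theta (theta=0 at the dyad, +x)
  Vec3 sh_point(double th) const {
    return Vec3(SH_R * std::cos(th), SH_R * std::sin(th),
                SH_PITCH * th / (2 * M_PI));
  }
  Vec3 sh_tangent(double th) const {
    return Vec3(-SH_R * std::sin(th), SH_R * std::cos(th),
                SH_PITCH / (2 * M_PI)).unit();
  }

  void build_topology() {
    double g = par.lp / par.l0;
    double the = SH_TURNS * M_PI;   // entry at +1.7*pi, exit at -1.7*pi
    Vec3 a_entry = sh_point(the), a_exit = sh_point(-the);
    Vec3 t_in = sh_tangent(the) * (-1.0);  // DNA runs toward decreasing theta
    Vec3 t_out = sh_tangent(-the) * (-1.0);
    center_site.resize(n_cores); anchor_exit.resize(n_cores);
    anchor_entry.resize(n_cores); phantom_exit.resize(n_cores);
    phantom_entry.resize(n_cores);
    core_sites.resize(n_cores);
    core_pos.resize(n_cores); core_R.resize(n_cores);
    linker_sites.resize(std::max(0, n_cores - 1));

    for (int c = 0; c < n_cores; ++c) {
      double cp = (double)c;
      int s;
      s = add_site(CENTER, c, -1, 0, -1, cp); local[s] = Vec3();
      center_site[c] = s; core_sites[c].push_back(s);
      // 12 surface pseudo-charges totalling q_charge_total: 8 negative rim
      // sites (wrapped DNA) and 4 positive face patches (histone surface),
      // giving nucleosomes the face-face stacking propensity of the real
      // charge anisotropy
      for (int k = 0; k < 8; ++k) {
        double th = 2 * M_PI * k / 8.0;
        s = add_site(CHARGE, c, -1, k, -1, cp);
        local[s] = Vec3(5.0 * std::cos(th), 5.0 * std::sin(th),
                        (k % 2 == 0) ? 0.8 : -0.8);
        core_sites[c].push_back(s);
      }
      for (int k = 0; k < 4; ++k) {
        s = add_site(CHARGE, c, -1, 8 + k, -1, cp);
        charge.back() = par.q_face;
        sigma.back() = par.sig_face;
        local[s] = Vec3((k % 2 == 0) ? 2.5 : -2.5, 0,
                        (k < 2) ? 2.9 : -2.9);
        core_sites[c].push_back(s);
      }
      s = add_site(ANCHOR, c, -1, 0, -1, cp); local[s] = a_exit;
      anchor_exit[c] = s; core_sites[c].push_back(s);
      s = add_site(ANCHOR, c, -1, 1, -1, cp); local[s] = a_entry;
      anchor_entry[c] = s; core_sites[c].push_back(s);
      s = add_site(PHANTOM, c, -1, 0, -1, cp);
      local[s] = a_exit - t_out * par.l0;       // segment phantom->anchor = t_out
      phantom_exit[c] = s; core_sites[c].push_back(s);
      s = add_site(PHANTOM, c, -1, 1, -1, cp);
      local[s] = a_entry + t_in * par.l0;       // segment anchor->phantom = t_in
      phantom_entry[c] = s; core_sites[c].push_back(s);
      if (lh_on[c]) {
        // LH as a two-row zipper along the dyad axis, displaced off the
        // linker plane: each row binds one of the two linkers so the pair
        // can appose at DNA-DNA contact distance (stem geometry)
        for (int k = 0; k < 6; ++k) {
          s = add_site(LH, c, -1, k, -1, cp);
          local[s] = Vec3(5.8 + 1.8 * (k % 3), (k < 3) ? 2.4 : -2.4, 0.0);
          core_sites[c].push_back(s);
        }
      }
      for (int tc = 0; tc < 8; ++tc) {          // tail anchors + beads
        double th = 2 * M_PI * (tc % 4) / 4.0 + ((tc < 4) ? M_PI / 4 : 0.0);
        double zz = (tc < 4) ? 2.4 : -2.4;
        int ta = add_site(TAILA, c, -1, tc, tc, cp);
        local[ta] = Vec3(3.2 * std::cos(th), 3.2 * std::sin(th), zz);
        core_sites[c].push_back(ta);
        int prev = ta;
        for (int b = 0; b < 3; ++b) {
          int tb = add_site(TAIL, c, -1, b, tc, cp);
          core_sites[c].push_back(tb); mobile.push_back(tb);
          bonds.push_back({prev, tb, par.tail_l0, par.k_tail});
          prev = tb;
        }
      }
    }
    for (int l = 0; l < n_cores - 1; ++l) {
      int k = nbeads[l];
      std::vector<int> path;
      path.push_back(phantom_exit[l]); path.push_back(anchor_exit[l]);
      int prev = anchor_exit[l];
      for (int b = 0; b < k; ++b) {
        int s = add_site(LINK, -1, l, b, -1,
                         l + (b + 1.0) / (k + 1.0));
        linker_sites[l].push_back(s); mobile.push_back(s);
        bonds.push_back({prev, s, par.l0, par.k_dna});
        path.push_back(s);
        prev = s;
      }
      bonds.push_back({prev, anchor_entry[l + 1], par.l0,
                       (k == 0) ? par.k_zero : par.k_dna});
      path.push_back(anchor_entry[l + 1]);
      path.push_back(phantom_entry[l + 1]);
      for (size_t i = 1; i + 1 < path.size(); ++i)
        bends.push_back({path[i - 1], path[i], path[i + 1], g});
    }
    bonds_of.assign(pos.size(), std::vector<int>());
    bends_of.assign(pos.size(), std::vector<int>());
    for (size_t b = 0; b < bonds.size(); ++b) {
      bonds_of[bonds[b].i].push_back((int)b);
      bonds_of[bonds[b].j].push_back((int)b);
    }
    for (size_t b = 0; b < bends.size(); ++b) {
      bends_of[bends[b].a].push_back((int)b);
      bends_of[bends[b].b].push_back((int)b);
      bends_of[bends[b].c].push_back((int)b);
    }
    for (size_t s = 0; s < pos.size(); ++s)
      if (active(type[s]) || type[s] == CENTER) inter.push_back((int)s);
  }

  void place_core(int c, const Vec3& p, const Mat3& R) {
    core_pos[c] = p; core_R[c] = R;
    for (int s : core_sites[c])
      if (type[s] != TAIL) pos[s] = p + R.apply(local[s]);
  }

  // initial configuration: irregular zigzag -- straight linkers along the
  // exit tangent, downstream frame pre-rotated by the helical register
  // 2*pi*(L mod 10.5)/10.5 about the linker axis (kinematic twist)
  void init_configuration() {
    double the = SH_TURNS * M_PI;
    Vec3 t_in_l = sh_tangent(the) * (-1.0);
    Vec3 t_out_l = sh_tangent(-the) * (-1.0);
    place_core(0, Vec3(), Mat3());
    for (int c = 0; c < n_cores; ++c) {
      // tails: extend outward from their anchors along the anchor offset
      for (int s : core_sites[c]) {
        if (type[s] != TAIL) continue;
        int ch = tail_chain[s]; int rk = rank[s];
        // find this chain's anchor local coords
        Vec3 aloc;
        for (int s2 : core_sites[c])
          if (type[s2] == TAILA && tail_chain[s2] == ch) aloc = local[s2];
        Vec3 dir = Vec3(aloc.x, aloc.y, aloc.z * 2.0).unit();
        pos[s] = core_pos[c] +
          core_R[c].apply(aloc + dir * (par.tail_l0 * (rk + 1)));
      }
      if (c == n_cores - 1) break;
      // linker beads along the world exit tangent
      Vec3 u = core_R[c].apply(t_out_l).unit();
      Vec3 a = pos[anchor_exit[c]];
      int k = nbeads[c];
      for (int b = 0; b < k; ++b)
        pos[linker_sites[c][b]] = a + u * (par.l0 * (b + 1));
      Vec3 q = a + u * (par.l0 * (k + 1));
      // frame for core c+1: map local entry tangent onto u, then spin by
      // the helical register about the linker axis
      Vec3 t_in_w_target = u;
      Vec3 axis = t_in_l.cross(t_in_w_target);
      double cosang = std::max(-1.0, std::min(1.0, t_in_l.dot(t_in_w_target)));
      Mat3 R0;
      if (axis.norm() > 1e-9) R0 = axis_angle(axis, std::acos(cosang));
      else if (cosang < 0) {
        Vec3 perp = std::fabs(t_in_l.x) < 0.9 ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
        R0 = axis_angle(t_in_l.cross(perp), M_PI);
      }
      double Lbp = linker_bp[c] < 0 ? 0 : linker_bp[c];
      double reg = 2 * M_PI * std::fmod(Lbp, 10.5) / 10.5;
      Mat3 R = axis_angle(u, reg).mul(R0);
      Vec3 p = q - R.apply(local[anchor_entry[c + 1]]);
      place_core(c + 1, p, R);
    }
  }

  // ------------------------------------------------------------------ energy
  bool excluded(int i, int j) const {
    int ci = core_of[i], cj = core_of[j];
    if (ci >= 0 && ci == cj) {
      bool ti = type[i] == TAIL, tj = type[j] == TAIL;
      if (!ti || !tj) return true;              // rigid-rigid or tail-rigid
      if (tail_chain[i] == tail_chain[j] &&
          std::abs(rank[i] - rank[j]) <= 1) return true;
      return false;                             // tails of one core interact
    }
    if (type[i] == LINK && type[j] == LINK &&
        linker_of[i] == linker_of[j] &&
        std::abs(rank[i] - rank[j]) <= 1) return true;
    return false;
  }

  inline bool active(int t) const {
    return t == CHARGE || t == LH || t == TAIL || t == LINK;
  }

  // nonbonded pair energy given explicit positions; every excluded-volume
  // term is capped (soft overlap) so energies stay finite even for fully
  // overlapping nucleosomes / zero-length linkers
  double pair_energy(int i, int j, const Vec3& pi, const Vec3& pj,
                     double* elec = 0, double* elec_lh = 0,
                     double* ev = 0, double* ev_core = 0) const {
    double dx = pi.x - pj.x, dy = pi.y - pj.y, dz = pi.z - pj.z;
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > par.cut2) return 0;
    int ti = type[i], tj = type[j];
    double e = 0;
    if (ti == CENTER || tj == CENTER) {
      if (ti != CENTER || tj != CENTER) return 0;
      double rc = par.sig_cc * 1.122462048309373;
      if (r2 >= rc * rc) return 0;
      double s2 = par.sig_cc * par.sig_cc / std::max(r2, 1e-12);
      double s6 = s2 * s2 * s2;
      double w = std::min(4 * par.eps_ev * (s6 * s6 - s6) + par.eps_ev,
                          par.cap_cc);
      if (ev_core) *ev_core += w;
      return w;
    }
    if (r2 > par.cut2_nb) return 0;
    double r = std::sqrt(r2);
    double sg = 0.5 * (sigma[i] + sigma[j]);
    if (par.charges_on && charge[i] != 0 && charge[j] != 0) {
      double lam = (ti == LINK && tj == LINK) ? par.lambda_dna : par.lambda_gen;
      if (r < lam * par.elec_cutoff_factor) {
        // charges are smeared over the bead: floor r at the contact scale
        // so capped excluded volume cannot be beaten by point-Coulomb
        double re = std::max(r, 0.9 * sg);
        double ee = par.lB * charge[i] * charge[j] *
          std::exp(-re / lam) / std::max(re, 1e-6);
        e += ee;
        if (ti == LH || tj == LH) { if (elec_lh) *elec_lh += ee; }
        else if (elec) *elec += ee;
      }
    }
    double rc = sg * 1.122462048309373;
    if (r < rc) {
      double s2 = sg * sg / std::max(r2, 1e-12);
      double s6 = s2 * s2 * s2;
      double w = std::min(4 * par.eps_ev * (s6 * s6 - s6) + par.eps_ev,
                          par.ev_cap);
      e += w;
      if (ev) *ev += w;
    }
    return e;
  }

  double bond_energy(const Bond& b, const Vec3& pi, const Vec3& pj) const {
    double d = (pi - pj).norm() - b.r0;
    return 0.5 * b.k * d * d;
  }

  double bend_energy(const Bend& t, const Vec3& pa, const Vec3& pb,
                     const Vec3& pc) const {
    Vec3 u = pb - pa, v = pc - pb;
    double nu = u.norm(), nv = v.norm();
    if (nu < 1e-9 || nv < 1e-9) return 0;
    return t.g * (1.0 - u.dot(v) / (nu * nv));
  }

  List full_energy() const {
    double estr = 0, ebend = 0, eel = 0, eel_lh = 0, eev = 0, eevc = 0;
    for (const Bond& b : bonds) estr += bond_energy(b, pos[b.i], pos[b.j]);
    for (const Bend& t : bends)
      ebend += bend_energy(t, pos[t.a], pos[t.b], pos[t.c]);
    for (size_t a = 0; a < inter.size(); ++a)
      for (size_t b = a + 1; b < inter.size(); ++b) {
        int i = inter[a], j = inter[b];
        if (excluded(i, j)) continue;
        pair_energy(i, j, pos[i], pos[j], &eel, &eel_lh, &eev, &eevc);
      }
    double tot = estr + ebend + eel + eel_lh + eev + eevc;
    if (!std::isfinite(tot)) stop("non-finite total energy");
    return List::create(_["stretch"] = estr, _["bend"] = ebend,
                        _["elec"] = eel, _["elec_lh"] = eel_lh,
                        _["ev"] = eev, _["ev_core"] = eevc,
                        _["total"] = tot);
  }

  double total_energy_value() const {
    List e = full_energy();
    return as<double>(e["total"]);
  }

  // ---------------------------------------------------------------- sampling
  // delta energy for moving the set M (newpos parallel to M)
  double delta_energy(const std::vector<int>& M,
                      const std::vector<Vec3>& newpos,
                      std::vector<char>& moved) const {
    for (int s : M) moved[s] = 1;
    double dE = 0;
    for (size_t a = 0; a < M.size(); ++a) {
      int i = M[a];
      if (!active(type[i]) && type[i] != CENTER) continue;
      for (int j : inter) {
        if (moved[j]) continue;
        if (excluded(i, j)) continue;
        dE += pair_energy(i, j, newpos[a], pos[j]) -
              pair_energy(i, j, pos[i], pos[j]);
      }
    }
    // bonded terms crossing the cut (collect uniquely)
    std::vector<int> bl, tl;
    for (int s : M) {
      for (int b : bonds_of[s]) bl.push_back(b);
      for (int t : bends_of[s]) tl.push_back(t);
    }
    std::sort(bl.begin(), bl.end()); bl.erase(std::unique(bl.begin(), bl.end()), bl.end());
    std::sort(tl.begin(), tl.end()); tl.erase(std::unique(tl.begin(), tl.end()), tl.end());
    auto np = [&](int s) -> const Vec3& {
      if (moved[s]) {
        for (size_t a = 0; a < M.size(); ++a) if (M[a] == s) return newpos[a];
      }
      return pos[s];
    };
    for (int bi : bl) {
      const Bond& b = bonds[bi];
      if (moved[b.i] && moved[b.j]) continue;   // rigid within the moved set
      dE += bond_energy(b, np(b.i), np(b.j)) -
            bond_energy(b, pos[b.i], pos[b.j]);
    }
    for (int ti : tl) {
      const Bend& t = bends[ti];
      if (moved[t.a] && moved[t.b] && moved[t.c]) continue;
      dE += bend_energy(t, np(t.a), np(t.b), np(t.c)) -
            bend_energy(t, pos[t.a], pos[t.b], pos[t.c]);
    }
    for (int s : M) moved[s] = 0;
    return dE;
  }

  Vec3 rand_unit() {
    while (true) {
      Vec3 v(gauss(rng), gauss(rng), gauss(rng));
      if (v.norm() > 1e-8) return v.unit();
    }
  }

  // Run MC. Returns frames + acceptance statistics + energy bookkeeping.
  List run(int n_sweeps_burnin, int n_frames, int sweep_interval,
           NumericVector amps, bool autotune, bool freeze_cores,
           double prob_bead, double prob_core, double prob_pivot,
           double prob_tail, double prob_crank) {
    std::vector<char> moved(pos.size(), 0);
    double E = total_energy_value();
    double amp_bead = amps[0], amp_core_t = amps[1], amp_core_r = amps[2],
           amp_pivot = amps[3], amp_tail = amps[4];
    double amp_crank = amps.size() > 5 ? amps[5] : 1.0;
    long att[5] = {0, 0, 0, 0, 0}, acc[5] = {0, 0, 0, 0, 0};
    long att_tune[5] = {0, 0, 0, 0, 0}, acc_tune[5] = {0, 0, 0, 0, 0};
    std::vector<int> cranks;        // linkers with >= 1 bead
    for (int l = 0; l + 1 < n_cores; ++l)
      if (nbeads[l] > 0) cranks.push_back(l);
    int n_mobile = std::max((size_t)1, mobile.size());
    int moves_per_sweep = n_mobile + n_cores;
    int total_sweeps = n_sweeps_burnin + n_frames * sweep_interval;

    // collect tail-chain list and pivot candidates once
    std::vector<std::pair<int, int> > tails; // (core, chain)
    for (int c = 0; c < n_cores; ++c)
      for (int tc = 0; tc < 8; ++tc) tails.push_back({c, tc});
    std::vector<int> pivot_nodes;            // linker beads + core centers
    for (auto& ls : linker_sites) for (int s : ls) pivot_nodes.push_back(s);
    for (int c = 0; c + 1 < n_cores; ++c) pivot_nodes.push_back(center_site[c]);

    List frames(n_frames), core_frames(n_frames);
    NumericVector frame_E(n_frames);
    int frame_i = 0;

    std::vector<int> M; std::vector<Vec3> NP;
    for (int sweep = 0; sweep < total_sweeps; ++sweep) {
      for (int mv = 0; mv < moves_per_sweep; ++mv) {
        double u = unif(rng);
        int kind;
        if (u < prob_bead) kind = 0;
        else if (u < prob_bead + prob_core) kind = 1;
        else if (u < prob_bead + prob_core + prob_pivot) kind = 2;
        else if (u < prob_bead + prob_core + prob_pivot + prob_crank &&
                 !cranks.empty()) kind = 4;
        else kind = 3;
        if (freeze_cores && (kind == 1 || kind == 2)) kind = 0;
        M.clear(); NP.clear();
        Mat3 R; Vec3 origin, trans;
        bool rigid_core_move = false; int cmove = -1;

        if (kind == 0) {
          if (mobile.empty()) continue;
          int s = mobile[(size_t)(unif(rng) * mobile.size())];
          M.push_back(s);
          NP.push_back(pos[s] + Vec3(gauss(rng), gauss(rng), gauss(rng)) *
                       amp_bead);
        } else if (kind == 1) {
          cmove = (int)(unif(rng) * n_cores);
          origin = core_pos[cmove];
          R = axis_angle(rand_unit(), gauss(rng) * amp_core_r);
          trans = Vec3(gauss(rng), gauss(rng), gauss(rng)) * amp_core_t;
          for (int s : core_sites[cmove]) {
            M.push_back(s);
            NP.push_back(origin + trans + R.apply(pos[s] - origin));
          }
          rigid_core_move = true;
        } else if (kind == 2) {
          if (pivot_nodes.empty()) continue;
          int s = pivot_nodes[(size_t)(unif(rng) * pivot_nodes.size())];
          double cp = chainpos[s];
          origin = pos[s];
          R = axis_angle(rand_unit(), gauss(rng) * amp_pivot);
          for (size_t q = 0; q < pos.size(); ++q)
            if (chainpos[q] > cp + 1e-9) {
              M.push_back((int)q);
              NP.push_back(origin + R.apply(pos[q] - origin));
            }
          if (M.empty()) continue;
        } else if (kind == 4) {
          // crankshaft: rotate a whole linker about its anchor-anchor axis
          int l = cranks[(size_t)(unif(rng) * cranks.size())];
          Vec3 a = pos[anchor_exit[l]], b = pos[anchor_entry[l + 1]];
          Vec3 ax = b - a;
          if (ax.norm() < 1e-6) continue;
          R = axis_angle(ax, gauss(rng) * amp_crank);
          origin = a;
          for (int s : linker_sites[l]) {
            M.push_back(s);
            NP.push_back(a + R.apply(pos[s] - a));
          }
        } else {
          auto& tc = tails[(size_t)(unif(rng) * tails.size())];
          // anchor position of that chain
          Vec3 ap;
          for (int s : core_sites[tc.first])
            if (type[s] == TAILA && tail_chain[s] == tc.second) ap = pos[s];
          R = axis_angle(rand_unit(), gauss(rng) * amp_tail);
          for (int s : core_sites[tc.first])
            if (type[s] == TAIL && tail_chain[s] == tc.second) {
              M.push_back(s);
              NP.push_back(ap + R.apply(pos[s] - ap));
            }
        }

        double dE = delta_energy(M, NP, moved);
        ++att[kind]; ++att_tune[kind];
        if (dE <= 0 || unif(rng) < std::exp(-dE)) {
          for (size_t a = 0; a < M.size(); ++a) pos[M[a]] = NP[a];
          if (rigid_core_move) {
            core_pos[cmove] = origin + trans + R.apply(core_pos[cmove] - origin);
            core_R[cmove] = R.mul(core_R[cmove]);
          } else if (kind == 2) {
            // pivot also rotates downstream core frames
            for (int c = 0; c < n_cores; ++c)
              if (moved_core_in(M, c)) {
                core_pos[c] = origin + R.apply(core_pos[c] - origin);
                core_R[c] = R.mul(core_R[c]);
              }
          }
          E += dE;
          ++acc[kind]; ++acc_tune[kind];
        }
      }
      if (autotune && sweep < n_sweeps_burnin && (sweep + 1) % 200 == 0) {
        double r0a = att_tune[0] ? (double)acc_tune[0] / att_tune[0] : 0.4;
        double r1 = att_tune[1] ? (double)acc_tune[1] / att_tune[1] : 0.4;
        double r2 = att_tune[2] ? (double)acc_tune[2] / att_tune[2] : 0.4;
        double r3 = att_tune[3] ? (double)acc_tune[3] / att_tune[3] : 0.4;
        double r4 = att_tune[4] ? (double)acc_tune[4] / att_tune[4] : 0.4;
        auto adj = [](double& a, double r, double lo, double hi) {
          if (r > 0.5) a *= 1.2; else if (r < 0.3) a *= 0.8;
          a = std::max(lo, std::min(hi, a));
        };
        adj(amp_bead, r0a, 0.02, 2.0);
        adj(amp_core_t, r1, 0.02, 3.0); adj(amp_core_r, r1, 0.01, 1.0);
        adj(amp_pivot, r2, 0.005, 1.0); adj(amp_tail, r3, 0.01, 1.5);
        adj(amp_crank, r4, 0.05, 3.14);
        for (int k = 0; k < 5; ++k) { att_tune[k] = 0; acc_tune[k] = 0; }
      }
      if (sweep >= n_sweeps_burnin &&
          (sweep - n_sweeps_burnin + 1) % sweep_interval == 0 &&
          frame_i < n_frames) {
        NumericMatrix fr((int)pos.size(), 3);
        for (size_t s = 0; s < pos.size(); ++s) {
          fr(s, 0) = pos[s].x; fr(s, 1) = pos[s].y; fr(s, 2) = pos[s].z;
        }
        NumericMatrix cf(n_cores, 12);
        for (int c = 0; c < n_cores; ++c) {
          cf(c, 0) = core_pos[c].x; cf(c, 1) = core_pos[c].y;
          cf(c, 2) = core_pos[c].z;
          for (int k = 0; k < 9; ++k) cf(c, 3 + k) = core_R[c].m[k];
        }
        frames[frame_i] = fr; core_frames[frame_i] = cf;
        frame_E[frame_i] = E;
        ++frame_i;
      }
    }
    NumericVector acc_rates(5);
    for (int k = 0; k < 5; ++k)
      acc_rates[k] = att[k] ? (double)acc[k] / att[k] : NA_REAL;
    acc_rates.names() = CharacterVector::create("bead", "core", "pivot",
                                                "tail", "crank");
    return List::create(_["frames"] = frames, _["core_frames"] = core_frames,
                        _["frame_energy"] = frame_E,
                        _["acceptance"] = acc_rates,
                        _["energy_incremental"] = E,
                        _["energy_full"] = total_energy_value(),
                        _["amps_final"] = NumericVector::create(
                            amp_bead, amp_core_t, amp_core_r, amp_pivot,
                            amp_tail));
  }

  bool moved_core_in(const std::vector<int>& M, int c) const {
    int cs = center_site[c];
    for (int s : M) if (s == cs) return true;
    return false;
  }

  DataFrame sites_table() const {
    int n = (int)pos.size();
    CharacterVector tn(n);
    const char* names[] = {"core_center", "core_charge", "anchor", "phantom",
                           "lh", "tail_anchor", "tail", "linker"};
    IntegerVector co(n), lo(n), rk(n), ch(n);
    NumericVector q(n), sg(n);
    for (int i = 0; i < n; ++i) {
      tn[i] = names[type[i]];
      co[i] = core_of[i] + 1; lo[i] = linker_of[i] + 1;
      rk[i] = rank[i] + 1; ch[i] = tail_chain[i] + 1;
      q[i] = charge[i]; sg[i] = sigma[i];
    }
    return DataFrame::create(_["type"] = tn, _["core"] = co,
                             _["linker"] = lo, _["rank"] = rk,
                             _["tail_chain"] = ch, _["charge"] = q,
                             _["sigma"] = sg,
                             _["stringsAsFactors"] = false);
  }

  NumericMatrix positions() const {
    NumericMatrix m((int)pos.size(), 3);
    for (size_t s = 0; s < pos.size(); ++s) {
      m(s, 0) = pos[s].x; m(s, 1) = pos[s].y; m(s, 2) = pos[s].z;
    }
    return m;
  }

  void set_positions(const NumericMatrix& m) {
    if ((size_t)m.nrow() != pos.size())
      stop("position matrix has wrong number of sites");
    for (size_t s = 0; s < pos.size(); ++s)
      pos[s] = Vec3(m(s, 0), m(s, 1), m(s, 2));
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fiber_sites")]]
List cpp_fiber_sites(IntegerVector nbeads, NumericVector linker_bp,
                     IntegerVector lh_on, List params) {
  Fiber f(nbeads, linker_bp, lh_on, params, 1);
  return List::create(_["sites"] = f.sites_table(),
                      _["positions"] = f.positions(),
                      _["energy"] = f.full_energy());
}

// [[Rcpp::export(name = ".cpp_fiber_energy")]]
List cpp_fiber_energy(IntegerVector nbeads, NumericVector linker_bp,
                      IntegerVector lh_on, List params,
                      NumericMatrix positions) {
  Fiber f(nbeads, linker_bp, lh_on, params, 1);
  f.set_positions(positions);
  return f.full_energy();
}

// [[Rcpp::export(name = ".cpp_run_mc")]]
List cpp_run_mc(IntegerVector nbeads, NumericVector linker_bp,
                IntegerVector lh_on, List params, List settings,
                double seed) {
  Fiber f(nbeads, linker_bp, lh_on, params, (uint64_t)seed);
  NumericVector amps = settings["amps"];
  List out = f.run(as<int>(settings["burnin_sweeps"]),
                   as<int>(settings["n_frames"]),
                   as<int>(settings["sweep_interval"]),
                   amps,
                   as<bool>(settings["autotune"]),
                   as<bool>(settings["freeze_cores"]),
                   as<double>(settings["prob_bead"]),
                   as<double>(settings["prob_core"]),
                   as<double>(settings["prob_pivot"]),
                   as<double>(settings["prob_tail"]),
                   as<double>(settings["prob_crank"]));
  out["sites"] = f.sites_table();
  return out;
}

// ---------------------------------------------------------------------------
// Free-chain / tethered-bead validation sampler: a plain bead-spring chain
// (harmonic bonds, discrete WLC bending, optional isotropic tether on bead
// 1) used as the analytically solvable oracle for the Metropolis machinery.

// [[Rcpp::export(name = ".cpp_free_chain_mc")]]
List cpp_free_chain_mc(int n_beads, double l0, double k_stretch,
                       double lp, double tether_k,
                       int burnin_sweeps, int n_frames, int sweep_interval,
                       double amp, double seed) {
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<Vec3> x(n_beads);
  for (int i = 0; i < n_beads; ++i) x[i] = Vec3(l0 * i, 0, 0);
  double g = (n_beads > 2 && lp > 0) ? lp / l0 : 0.0;

  auto site_energy = [&](int i, const Vec3& p) {
    double e = 0;
    if (i == 0 && tether_k > 0) e += 0.5 * tether_k * p.dot(p);
    for (int j = std::max(0, i - 1); j <= std::min(n_beads - 2, i); ++j) {
      const Vec3& a = (j == i) ? p : x[j];
      const Vec3& b = (j + 1 == i) ? p : x[j + 1];
      double d = (a - b).norm() - l0;
      e += 0.5 * k_stretch * d * d;
    }
    if (g > 0)
      for (int j = std::max(1, i - 1); j <= std::min(n_beads - 2, i + 1); ++j) {
        const Vec3& a = (j - 1 == i) ? p : x[j - 1];
        const Vec3& b = (j == i) ? p : x[j];
        const Vec3& c = (j + 1 == i) ? p : x[j + 1];
        Vec3 u = b - a, v = c - b;
        double nu = u.norm(), nv = v.norm();
        if (nu > 1e-9 && nv > 1e-9) e += g * (1.0 - u.dot(v) / (nu * nv));
      }
    return e;
  };

  long att = 0, acc = 0;
  int total = burnin_sweeps + n_frames * sweep_interval;
  List frames(n_frames); int fi = 0;
  for (int sweep = 0; sweep < total; ++sweep) {
    for (int mv = 0; mv < n_beads; ++mv) {
      int i = (int)(unif(rng) * n_beads);
      Vec3 p = x[i] + Vec3(gauss(rng), gauss(rng), gauss(rng)) * amp;
      double dE = site_energy(i, p) - site_energy(i, x[i]);
      ++att;
      if (dE <= 0 || unif(rng) < std::exp(-dE)) { x[i] = p; ++acc; }
    }
    // pivot move for chains (decorrelates tangents quickly)
    if (n_beads > 2) {
      int i = 1 + (int)(unif(rng) * (n_beads - 2));
      Vec3 axis(gauss(rng), gauss(rng), gauss(rng));
      if (axis.norm() > 1e-8) {
        Mat3 R = axis_angle(axis, gauss(rng) * 0.6);
        double e0 = 0, e1 = 0;
        // only the joint at i changes under a rigid downstream rotation
        Vec3 u = x[i] - x[i - 1], v = x[i + 1] - x[i];
        Vec3 vn = R.apply(v);
        if (g > 0) {
          e0 = g * (1.0 - u.dot(v) / (u.norm() * v.norm()));
          e1 = g * (1.0 - u.dot(vn) / (u.norm() * vn.norm()));
        }
        if (e1 - e0 <= 0 || unif(rng) < std::exp(-(e1 - e0)))
          for (int j = i + 1; j < n_beads; ++j)
            x[j] = x[i] + R.apply(x[j] - x[i]);
      }
    }
    if (sweep >= burnin_sweeps &&
        (sweep - burnin_sweeps + 1) % sweep_interval == 0 && fi < n_frames) {
      NumericMatrix fr(n_beads, 3);
      for (int i = 0; i < n_beads; ++i) {
        fr(i, 0) = x[i].x; fr(i, 1) = x[i].y; fr(i, 2) = x[i].z;
      }
      frames[fi++] = fr;
    }
  }
  return List::create(_["frames"] = frames,
                      _["acceptance"] = att ? (double)acc / att : NA_REAL);
}
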