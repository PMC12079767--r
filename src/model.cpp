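#pragma GCC optimize("O3")
// Two-stage conditional-template network: Stage-1 conditional velocity
// generator (covariate -> latent -> transpose-conv decoder -> velocity field)
// and Stage-2 U-Net registration network, with hand-written backpropagation.
//
// Feature maps are stored as (npix x C) matrices, pixels column-major
// (i1 fastest), matching the R array convention. Velocity fields are predicted
// at half the image resolution and integrated there; deformations are
// bilinearly upsampled (and scaled) to the full grid before warping.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;

// from geometry.cpp
void integrate2_tape(const vec& v, int n1, int n2, int steps, std::vector<vec>& tape);
vec integrate2_bwd(const std::vector<vec>& tape, int n1, int n2, const vec& g_final);
void warp2_img(const double* f, const double* u, int n1, int n2, double* out);
void warp2_img_bwd(const double* f, const double* u, int n1, int n2,
                   const double* gout, double* gimg, double* gu);
double bending2(const double* u, int n1, int n2);
void bending2_grad(const double* u, int n1, int n2, double w, double* gu);

// ---------------------------------------------------------------------------
// layers

// im2col for 3x3 kernels, stride 1, zero padding 1.
static mat im2col3(const mat& in, int n1, int n2) {
  int C = in.n_cols;
  mat cols(in.n_rows, (std::size_t)C * 9, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int k2 = -1; k2 <= 1; ++k2)
      for (int k1 = -1; k1 <= 1; ++k1) {
        int q = c * 9 + (k2 + 1) * 3 + (k1 + 1);
        double* dst = cols.colptr(q);
        const double* src = in.colptr(c);
        for (int i2 = 0; i2 < n2; ++i2) {
          int j2 = i2 + k2;
          if (j2 < 0 || j2 >= n2) continue;
          int lo = std::max(0, -k1), hi = std::min(n1, n1 - k1); // i1 in [lo, hi)
          if (hi > lo)
            std::memcpy(dst + i2 * n1 + lo, src + j2 * n1 + lo + k1,
                        (hi - lo) * sizeof(double));
        }
      }
  return cols;
}

// adjoint scatter of im2col3
static mat col2im3(const mat& gcols, int n1, int n2, int C) {
  mat gin((std::size_t)n1 * n2, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int k2 = -1; k2 <= 1; ++k2)
      for (int k1 = -1; k1 <= 1; ++k1) {
        int q = c * 9 + (k2 + 1) * 3 + (k1 + 1);
        const double* src = gcols.colptr(q);
        double* dst = gin.colptr(c);
        for (int i2 = 0; i2 < n2; ++i2) {
          int j2 = i2 + k2;
          if (j2 < 0 || j2 >= n2) continue;
          int lo = std::max(0, -k1), hi = std::min(n1, n1 - k1);
          for (int i1 = lo; i1 < hi; ++i1)
            dst[j2 * n1 + i1 + k1] += src[i2 * n1 + i1];
        }
      }
  return gin;
}

static mat pool2(const mat& in, int n1, int n2) {
  int m1 = n1 / 2, m2 = n2 / 2, C = in.n_cols;
  mat out((std::size_t)m1 * m2, C);
  for (int c = 0; c < C; ++c) {
    const double* s = in.colptr(c);
    double* d = out.colptr(c);
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i)
        d[i + m1 * j] = 0.25 * (s[2*i + n1*2*j] + s[2*i+1 + n1*2*j] +
                                s[2*i + n1*(2*j+1)] + s[2*i+1 + n1*(2*j+1)]);
  }
  return out;
}

static mat pool2_bwd(const mat& g, int n1, int n2) {
  int m1 = n1 / 2, m2 = n2 / 2, C = g.n_cols;
  mat gin((std::size_t)n1 * n2, C);
  for (int c = 0; c < C; ++c) {
    const double* s = g.colptr(c);
    double* d = gin.colptr(c);
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i) {
        double v = 0.25 * s[i + m1 * j];
        d[2*i + n1*2*j] = v; d[2*i+1 + n1*2*j] = v;
        d[2*i + n1*(2*j+1)] = v; d[2*i+1 + n1*(2*j+1)] = v;
      }
  }
  return gin;
}

// nearest-neighbour 2x upsampling (U-Net decoder path)
static mat upnn2(const mat& in, int n1, int n2) {
  int m1 = n1 * 2, m2 = n2 * 2, C = in.n_cols;
  mat out((std::size_t)m1 * m2, C);
  for (int c = 0; c < C; ++c) {
    const double* s = in.colptr(c);
    double* d = out.colptr(c);
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i)
        d[i + m1 * j] = s[i / 2 + n1 * (j / 2)];
  }
  return out;
}

static mat upnn2_bwd(const mat& g, int n1, int n2) {
  int m1 = n1 * 2, m2 = n2 * 2, C = g.n_cols;
  mat gin((std::size_t)n1 * n2, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* s = g.colptr(c);
    double* d = gin.colptr(c);
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i)
        d[i / 2 + n1 * (j / 2)] += s[i + m1 * j];
  }
  return gin;
}

// Bilinear upsampling of a half-resolution field to the full grid with value
// scaling (displacements in voxel units double when the grid doubles).
// Half-grid pixel i covers full pixels 2i, 2i+1; full pixel I maps to
// half coordinate (I - 0.5) / 2, clamped.
struct UpTap { int i0; double f; bool edge; };
static inline UpTap uptap(int I, int n) {
  double p = (I - 0.5) / 2.0;
  UpTap t; t.edge = false;
  if (p <= 0) { p = 0; t.edge = true; }
  if (p >= n - 1) { p = n - 1; t.edge = true; }
  t.i0 = (int)std::floor(p); if (t.i0 > n - 2) t.i0 = n - 2;
  t.f = p - t.i0;
  return t;
}

static mat up2_scale(const mat& in, int n1, int n2, double scale) {
  int m1 = n1 * 2, m2 = n2 * 2, C = in.n_cols;
  mat out((std::size_t)m1 * m2, C);
  std::vector<UpTap> t1(m1), t2(m2);
  for (int i = 0; i < m1; ++i) t1[i] = uptap(i, n1);
  for (int j = 0; j < m2; ++j) t2[j] = uptap(j, n2);
  for (int c = 0; c < C; ++c) {
    const double* s = in.colptr(c);
    double* d = out.colptr(c);
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i) {
        const UpTap &a = t1[i], &b = t2[j];
        d[i + m1 * j] = scale * (
          (1 - a.f) * (1 - b.f) * s[a.i0 + n1 * b.i0] +
          a.f * (1 - b.f) * s[a.i0 + 1 + n1 * b.i0] +
          (1 - a.f) * b.f * s[a.i0 + n1 * (b.i0 + 1)] +
          a.f * b.f * s[a.i0 + 1 + n1 * (b.i0 + 1)]);
      }
  }
  return out;
}

static mat up2_scale_bwd(const mat& g, int n1, int n2, double scale) {
  int m1 = n1 * 2, m2 = n2 * 2, C = g.n_cols;
  mat gin((std::size_t)n1 * n2, C, arma::fill::zeros);
  std::vector<UpTap> t1(m1), t2(m2);
  for (int i = 0; i < m1; ++i) t1[i] = uptap(i, n1);
  for (int j = 0; j < m2; ++j) t2[j] = uptap(j, n2);
  for (int c = 0; c < C; ++c) {
    const double* s = g.colptr(c);
    double* d = gin.colptr(c);
    for (int j = 0; j < m2; ++j)
      for (int i = 0; i < m1; ++i) {
        const UpTap &a = t1[i], &b = t2[j];
        double v = scale * s[i + m1 * j];
        d[a.i0 + n1 * b.i0]         += (1 - a.f) * (1 - b.f) * v;
        d[a.i0 + 1 + n1 * b.i0]     += a.f * (1 - b.f) * v;
        d[a.i0 + n1 * (b.i0 + 1)]   += (1 - a.f) * b.f * v;
        d[a.i0 + 1 + n1 * (b.i0 + 1)] += a.f * b.f * v;
      }
  }
  return gin;
}

// Transpose convolution, kernel 4, stride 2, padding 1 (doubles the grid).
// Weight layout: w[ci + Cin*(co + Cout*(k1 + 4*k2))].
static mat tconv4(const mat& in, int n1, int n2, const double* w, const double* b,
                  int Cin, int Cout) {
  int m1 = n1 * 2, m2 = n2 * 2;
  mat out((std::size_t)m1 * m2, Cout);
  for (int co = 0; co < Cout; ++co) out.col(co).fill(b[co]);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      std::size_t pin = i + (std::size_t)n1 * j;
      for (int k2 = 0; k2 < 4; ++k2) {
        int o2 = 2 * j + k2 - 1;
        if (o2 < 0 || o2 >= m2) continue;
        for (int k1 = 0; k1 < 4; ++k1) {
          int o1 = 2 * i + k1 - 1;
          if (o1 < 0 || o1 >= m1) continue;
          std::size_t pout = o1 + (std::size_t)m1 * o2;
          const double* wk = w + (std::size_t)Cin * Cout * (k1 + 4 * k2);
          for (int co = 0; co < Cout; ++co) {
            double acc = 0;
            const double* wc = wk + (std::size_t)Cin * co;
            for (int ci = 0; ci < Cin; ++ci) acc += in(pin, ci) * wc[ci];
            out(pout, co) += acc;
          }
        }
      }
    }
  return out;
}

static void tconv4_bwd(const mat& in, int n1, int n2, const double* w,
                       int Cin, int Cout, const mat& gout,
                       mat& gin, double* gw, double* gb) {
  int m1 = n1 * 2, m2 = n2 * 2;
  gin.zeros((std::size_t)n1 * n2, Cin);
  for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(gout.col(co));
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      std::size_t pin = i + (std::size_t)n1 * j;
      for (int k2 = 0; k2 < 4; ++k2) {
        int o2 = 2 * j + k2 - 1;
        if (o2 < 0 || o2 >= m2) continue;
        for (int k1 = 0; k1 < 4; ++k1) {
          int o1 = 2 * i + k1 - 1;
          if (o1 < 0 || o1 >= m1) continue;
          std::size_t pout = o1 + (std::size_t)m1 * o2;
          std::size_t wo = (std::size_t)Cin * Cout * (k1 + 4 * k2);
          for (int co = 0; co < Cout; ++co) {
            double g = gout(pout, co);
            const double* wc = w + wo + (std::size_t)Cin * co;
            double* gwc = gw + wo + (std::size_t)Cin * co;
            for (int ci = 0; ci < Cin; ++ci) {
              gin(pin, ci) += g * wc[ci];
              gwc[ci] += g * in(pin, ci);
            }
          }
        }
      }
    }
}

static inline mat relu(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }
static inline mat relu_bwd(const mat& g, const mat& y) {
  mat r(g.n_rows, g.n_cols);
  const double* gp = g.memptr();
  const double* yp = y.memptr();
  double* rp = r.memptr();
  for (std::size_t i = 0; i < g.n_elem; ++i) rp[i] = yp[i] > 0 ? gp[i] : 0.0;
  return r;
}

// ---------------------------------------------------------------------------
// configuration and parameter layout

struct Cfg {
  int H, W, h, w, cov, lat, hid, ch0, g0, steps;
  std::vector<int> up_ch; // stage-1 decoder channels after each transpose conv
  std::vector<int> s2;    // stage-2 encoder widths (4 levels)
};

static Cfg parse_cfg(List cfg) {
  Cfg c;
  IntegerVector grid = cfg["grid"];
  c.H = grid[0]; c.W = grid[1];
  c.h = c.H / 2; c.w = c.W / 2;
  c.cov = as<int>(cfg["cov_dim"]);
  c.lat = as<int>(cfg["latent"]);
  c.hid = as<int>(cfg["s1_hidden"]);
  c.ch0 = as<int>(cfg["s1_ch0"]);
  c.g0  = as<int>(cfg["s1_g0"]);
  c.steps = as<int>(cfg["steps"]);
  IntegerVector up = cfg["s1_up_ch"];
  c.up_ch.assign(up.begin(), up.end());
  IntegerVector s2 = cfg["s2_ch"];
  c.s2.assign(s2.begin(), s2.end());
  if (c.H % 8 != 0 || c.W % 8 != 0) stop("grid must be divisible by 8");
  if (c.H != c.W) stop("the network engine assumes a square grid");
  int g = c.g0;
  for (std::size_t i = 0; i < c.up_ch.size(); ++i) g *= 2;
  if (g != c.h) stop("s1_g0 * 2^length(s1_up_ch) must equal grid[1]/2");
  if (c.s2.size() != 4) stop("s2_ch must have 4 entries");
  return c;
}

struct PSpec { std::string name; int r, c, offset; };

static std::vector<PSpec> build_layout(const Cfg& c) {
  std::vector<PSpec> L;
  int off = 0;
  auto add = [&](std::string n, int r, int cc) {
    L.push_back({ n, r, cc, off });
    off += r * cc;
  };
  add("s1.fc1.W", c.hid, c.cov);   add("s1.fc1.b", c.hid, 1);
  add("s1.mu.W", c.lat, c.hid);    add("s1.mu.b", c.lat, 1);
  add("s1.lv.W", c.lat, c.hid);    add("s1.lv.b", c.lat, 1);
  add("s1.fc2.W", c.ch0 * c.g0 * c.g0, c.lat); add("s1.fc2.b", c.ch0 * c.g0 * c.g0, 1);
  int cin = c.ch0;
  for (std::size_t i = 0; i < c.up_ch.size(); ++i) {
    add("s1.up" + std::to_string(i + 1) + ".W", cin * c.up_ch[i], 16);
    add("s1.up" + std::to_string(i + 1) + ".b", c.up_ch[i], 1);
    cin = c.up_ch[i];
  }
  add("s1.head.W", cin * 9, 2); add("s1.head.b", 2, 1);
  int c1 = c.s2[0], c2 = c.s2[1], c3 = c.s2[2], c4 = c.s2[3];
  add("s2.enc1.W", 2 * 9, c1);  add("s2.enc1.b", c1, 1);
  add("s2.enc2.W", c1 * 9, c2); add("s2.enc2.b", c2, 1);
  add("s2.enc3.W", c2 * 9, c3); add("s2.enc3.b", c3, 1);
  add("s2.enc4.W", c3 * 9, c4); add("s2.enc4.b", c4, 1);
  add("s2.dec3.W", (c4 + c3) * 9, c3); add("s2.dec3.b", c3, 1);
  add("s2.dec2.W", (c3 + c2) * 9, c2); add("s2.dec2.b", c2, 1);
  add("s2.head.W", c2 * 9, 2); add("s2.head.b", 2, 1);
  return L;
}

// [[Rcpp::export]]
List ca_param_layout_cpp(List cfg) {
  Cfg c = parse_cfg(cfg);
  std::vector<PSpec> L = build_layout(c);
  CharacterVector names(L.size());
  IntegerVector rows(L.size()), cols(L.size()), offs(L.size());
  int total = 0;
  for (std::size_t i = 0; i < L.size(); ++i) {
    names[i] = L[i].name; rows[i] = L[i].r; cols[i] = L[i].c; offs[i] = L[i].offset;
    total = L[i].offset + L[i].r * L[i].c;
  }
  return List::create(_["names"] = names, _["rows"] = rows, _["cols"] = cols,
                      _["offsets"] = offs, _["total"] = total);
}

// Parameter accessor: zero-copy views into the flat vector.
struct Params {
  std::map<std::string, PSpec> idx;
  double* base;
  Params(const std::vector<PSpec>& L, double* b) : base(b) {
    for (auto& p : L) idx[p.name] = p;
  }
  mat M(const std::string& n) const {
    const PSpec& p = idx.at(n);
    return mat(base + p.offset, p.r, p.c, false, true);
  }
  vec V(const std::string& n) const {
    const PSpec& p = idx.at(n);
    return vec(base + p.offset, (std::size_t)p.r * p.c, false, true);
  }
  double* ptr(const std::string& n) const { return base + idx.at(n).offset; }
};

// ---------------------------------------------------------------------------
// stage forwards/backwards

struct S1Tape {
  vec h1, mu, lv, z, h2;
  std::vector<mat> F;   // decoder activations (post-relu), F[0] at g0
  mat cols_head;        // im2col of last activation for the head conv
  mat v;                // (h*w x 2)
};

static void stage1_fwd(const Cfg& c, const Params& P, const vec& cov,
                       const vec& eps, bool sample, S1Tape& t) {
  t.h1 = relu(P.M("s1.fc1.W") * cov + P.V("s1.fc1.b"));
  t.mu = P.M("s1.mu.W") * t.h1 + P.V("s1.mu.b");
  t.lv = P.M("s1.lv.W") * t.h1 + P.V("s1.lv.b");
  t.z = sample ? vec(t.mu + arma::exp(0.5 * t.lv) % eps) : t.mu;
  t.h2 = relu(P.M("s1.fc2.W") * t.z + P.V("s1.fc2.b"));
  int g = c.g0, npix = c.g0 * c.g0;
  mat F0(const_cast<double*>(t.h2.memptr()), npix, c.ch0, true, true);
  t.F.clear(); t.F.push_back(F0);
  int cin = c.ch0;
  for (std::size_t i = 0; i < c.up_ch.size(); ++i) {
    std::string nm = "s1.up" + std::to_string(i + 1);
    mat o = tconv4(t.F.back(), g, g, P.ptr(nm + ".W"), P.ptr(nm + ".b"),
                   cin, c.up_ch[i]);
    t.F.push_back(relu(o));
    g *= 2; cin = c.up_ch[i];
  }
  t.cols_head = im2col3(t.F.back(), g, g);
  t.v = t.cols_head * P.M("s1.head.W");
  t.v.each_row() += P.V("s1.head.b").t();
}

static void stage1_bwd(const Cfg& c, const Params& P, const vec& cov,
                       const vec& eps, bool sample, const S1Tape& t,
                       const mat& gv, Params& G) {
  int g = c.h; // last decoder grid
  G.M("s1.head.W") += t.cols_head.t() * gv;
  G.V("s1.head.b") += arma::sum(gv, 0).t();
  mat gF = col2im3(gv * P.M("s1.head.W").t(), g, g, t.F.back().n_cols);
  for (int i = (int)c.up_ch.size() - 1; i >= 0; --i) {
    gF = relu_bwd(gF, t.F[i + 1]);
    g /= 2;
    std::string nm = "s1.up" + std::to_string(i + 1);
    int cin = (i == 0) ? c.ch0 : c.up_ch[i - 1];
    mat gin;
    tconv4_bwd(t.F[i], g, g, P.ptr(nm + ".W"), cin, c.up_ch[i], gF,
               gin, G.ptr(nm + ".W"), G.ptr(nm + ".b"));
    gF = gin;
  }
  vec gh2 = arma::vectorise(gF);
  gh2 = arma::vectorise(relu_bwd(mat(gh2), mat(t.h2)));
  G.M("s1.fc2.W") += gh2 * t.z.t();
  G.V("s1.fc2.b") += gh2;
  vec gz = P.M("s1.fc2.W").t() * gh2;
  vec gmu = gz;
  vec glv = sample ? vec(0.5 * gz % arma::exp(0.5 * t.lv) % eps)
                   : vec(arma::zeros(c.lat));
  G.M("s1.mu.W") += gmu * t.h1.t();
  G.V("s1.mu.b") += gmu;
  G.M("s1.lv.W") += glv * t.h1.t();
  G.V("s1.lv.b") += glv;
  vec gh1 = P.M("s1.mu.W").t() * gmu + P.M("s1.lv.W").t() * glv;
  gh1 = arma::vectorise(relu_bwd(mat(gh1), mat(t.h1)));
  G.M("s1.fc1.W") += gh1 * cov.t();
  G.V("s1.fc1.b") += gh1;
}

struct S2Tape {
  mat in2, e1, e2, e3, e4, d3in, d3, d2in, d2;
  mat cols1, cols2, cols3, cols4, colsd3, colsd2, colsh;
  mat v; // (h*w x 2)
};

static void stage2_fwd(const Cfg& c, const Params& P, const mat& in2, S2Tape& t) {
  int H = c.H, W = c.W;
  t.in2 = in2;
  t.cols1 = im2col3(t.in2, H, W);
  t.e1 = t.cols1 * P.M("s2.enc1.W");
  t.e1.each_row() += P.V("s2.enc1.b").t();
  t.e1 = relu(t.e1);
  mat p1 = pool2(t.e1, H, W);
  t.cols2 = im2col3(p1, H / 2, W / 2);
  t.e2 = t.cols2 * P.M("s2.enc2.W");
  t.e2.each_row() += P.V("s2.enc2.b").t();
  t.e2 = relu(t.e2);
  mat p2 = pool2(t.e2, H / 2, W / 2);
  t.cols3 = im2col3(p2, H / 4, W / 4);
  t.e3 = t.cols3 * P.M("s2.enc3.W");
  t.e3.each_row() += P.V("s2.enc3.b").t();
  t.e3 = relu(t.e3);
  mat p3 = pool2(t.e3, H / 4, W / 4);
  t.cols4 = im2col3(p3, H / 8, W / 8);
  t.e4 = t.cols4 * P.M("s2.enc4.W");
  t.e4.each_row() += P.V("s2.enc4.b").t();
  t.e4 = relu(t.e4);
  t.d3in = arma::join_rows(upnn2(t.e4, H / 8, W / 8), t.e3);
  t.colsd3 = im2col3(t.d3in, H / 4, W / 4);
  t.d3 = t.colsd3 * P.M("s2.dec3.W");
  t.d3.each_row() += P.V("s2.dec3.b").t();
  t.d3 = relu(t.d3);
  t.d2in = arma::join_rows(upnn2(t.d3, H / 4, W / 4), t.e2);
  t.colsd2 = im2col3(t.d2in, H / 2, W / 2);
  t.d2 = t.colsd2 * P.M("s2.dec2.W");
  t.d2.each_row() += P.V("s2.dec2.b").t();
  t.d2 = relu(t.d2);
  t.colsh = im2col3(t.d2, H / 2, W / 2);
  t.v = t.colsh * P.M("s2.head.W");
  t.v.each_row() += P.V("s2.head.b").t();
}

// returns grad wrt the 2-channel input
static mat stage2_bwd(const Cfg& c, const Params& P, const S2Tape& t,
                      const mat& gv, Params& G) {
  int H = c.H, W = c.W;
  G.M("s2.head.W") += t.colsh.t() * gv;
  G.V("s2.head.b") += arma::sum(gv, 0).t();
  mat gd2 = col2im3(gv * P.M("s2.head.W").t(), H / 2, W / 2, t.d2.n_cols);
  gd2 = relu_bwd(gd2, t.d2);
  G.M("s2.dec2.W") += t.colsd2.t() * gd2;
  G.V("s2.dec2.b") += arma::sum(gd2, 0).t();
  mat gd2in = col2im3(gd2 * P.M("s2.dec2.W").t(), H / 2, W / 2, t.d2in.n_cols);
  int c3 = t.d3.n_cols;
  mat gd3 = upnn2_bwd(gd2in.cols(0, c3 - 1), H / 4, W / 4);
  mat ge2 = gd2in.cols(c3, gd2in.n_cols - 1);
  gd3 = relu_bwd(gd3, t.d3);
  G.M("s2.dec3.W") += t.colsd3.t() * gd3;
  G.V("s2.dec3.b") += arma::sum(gd3, 0).t();
  mat gd3in = col2im3(gd3 * P.M("s2.dec3.W").t(), H / 4, W / 4, t.d3in.n_cols);
  int c4 = t.e4.n_cols;
  mat ge4 = upnn2_bwd(gd3in.cols(0, c4 - 1), H / 8, W / 8);
  mat ge3 = gd3in.cols(c4, gd3in.n_cols - 1);
  ge4 = relu_bwd(ge4, t.e4);
  G.M("s2.enc4.W") += t.cols4.t() * ge4;
  G.V("s2.enc4.b") += arma::sum(ge4, 0).t();
  mat gp3 = col2im3(ge4 * P.M("s2.enc4.W").t(), H / 8, W / 8, t.e3.n_cols);
  ge3 += pool2_bwd(gp3, H / 4, W / 4);
  ge3 = relu_bwd(ge3, t.e3);
  G.M("s2.enc3.W") += t.cols3.t() * ge3;
  G.V("s2.enc3.b") += arma::sum(ge3, 0).t();
  mat gp2 = col2im3(ge3 * P.M("s2.enc3.W").t(), H / 4, W / 4, t.e2.n_cols);
  ge2 += pool2_bwd(gp2, H / 2, W / 2);
  ge2 = relu_bwd(ge2, t.e2);
  G.M("s2.enc2.W") += t.cols2.t() * ge2;
  G.V("s2.enc2.b") += arma::sum(ge2, 0).t();
  mat gp1 = col2im3(ge2 * P.M("s2.enc2.W").t(), H / 2, W / 2, t.e1.n_cols);
  mat ge1 = pool2_bwd(gp1, H, W);
  ge1 = relu_bwd(ge1, t.e1);
  G.M("s2.enc1.W") += t.cols1.t() * ge1;
  G.V("s2.enc1.b") += arma::sum(ge1, 0).t();
  return col2im3(ge1 * P.M("s2.enc1.W").t(), H, W, 2);
}

// ---------------------------------------------------------------------------
// full per-sample forward (+ optional backward)

// [[Rcpp::export]]
List ca_model_run_cpp(List cfg, NumericVector params, NumericVector grad_out,
                      NumericMatrix Tmpl, Nullable<NumericMatrix> X_,
                      NumericVector cov, NumericVector eps, bool sample,
                      NumericVector m0, NumericVector m1, double z0, double z1,
                      double lambda, bool do_update, bool mean_grad,
                      NumericVector gammas, bool mean_l1, bool want_grad,
                      bool light) {
  Cfg c = parse_cfg(cfg);
  std::vector<PSpec> L = build_layout(c);
  Params P(L, params.begin());
  int H = c.H, W = c.W, h = c.h, w = c.w;
  std::size_t nv = (std::size_t)H * W, nvh = (std::size_t)h * w;
  double Nv = (double)nv;

  // --- Stage 1
  S1Tape s1;
  stage1_fwd(c, P, vec(cov.begin(), cov.size()), vec(eps.begin(), eps.size()),
             sample, s1);
  vec v1h = arma::vectorise(s1.v);                  // (2*h*w)
  std::vector<vec> tape1;
  integrate2_tape(v1h, h, w, c.steps, tape1);
  mat u1h(tape1.back().memptr(), nvh, 2, false, true);
  mat u1f = up2_scale(u1h, h, w, 2.0);              // (H*W x 2)
  NumericVector Talpha(nv);
  warp2_img(REAL(Tmpl), u1f.memptr(), H, W, REAL(Talpha));

  bool have_X = X_.isNotNull();

  // tracked-mean combination (state update optional)
  vec vm0(m0.begin(), m0.size()), vm1(m1.begin(), m1.size());
  double gam[6];
  for (int i = 0; i < 6; ++i) gam[i] = gammas[i];

  if (!have_X) {
    // template-building / export mode: no Stage 2, no losses
    vec vhat = v1h + z0 * vm0 + z1 * vm1;
    std::vector<vec> tapeh;
    integrate2_tape(vhat, h, w, c.steps, tapeh);
    mat uhh(tapeh.back().memptr(), nvh, 2, false, true);
    mat uhf = up2_scale(uhh, h, w, 2.0);
    NumericVector That(nv);
    warp2_img(REAL(Tmpl), uhf.memptr(), H, W, REAL(That));
    return List::create(
      _["Talpha"] = Talpha, _["That"] = That,
      _["v1h"] = NumericVector(v1h.begin(), v1h.end()),
      _["vhath"] = NumericVector(vhat.begin(), vhat.end()),
      _["u1f"] = NumericVector(u1f.memptr(), u1f.memptr() + 2 * nv),
      _["uhatf"] = NumericVector(uhf.memptr(), uhf.memptr() + 2 * nv));
  }

  NumericMatrix X(X_);

  // --- Stage 2
  mat in2((std::size_t)nv, 2);
  std::memcpy(in2.colptr(0), REAL(Talpha), nv * sizeof(double));
  std::memcpy(in2.colptr(1), REAL(X), nv * sizeof(double));
  S2Tape s2;
  stage2_fwd(c, P, in2, s2);
  vec v2h = arma::vectorise(s2.v);
  std::vector<vec> tape2;
  integrate2_tape(v2h, h, w, c.steps, tape2);
  mat u2h(tape2.back().memptr(), nvh, 2, false, true);
  mat u2f = up2_scale(u2h, h, w, 2.0);
  NumericVector Xhat(nv);
  warp2_img(REAL(Talpha), u2f.memptr(), H, W, REAL(Xhat));

  // --- tracker update (EMA, stored state detached) then combination
  double q0 = lambda * z0, q1 = lambda * z1;
  vec nm0 = vm0, nm1 = vm1;
  if (do_update) {
    nm0 = (1 - q0) * vm0 + q0 * v2h;
    nm1 = (1 - q1) * vm1 + q1 * v2h;
  }
  // gradient coefficient of v2h inside vhat (current-sample update term)
  double cv2 = (do_update && mean_grad) ? (z0 * q0 + z1 * q1) : 0.0;
  vec vhat = v1h + z0 * nm0 + z1 * nm1;
  std::vector<vec> tapeh;
  integrate2_tape(vhat, h, w, c.steps, tapeh);
  mat uhh(tapeh.back().memptr(), nvh, 2, false, true);
  mat uhf = up2_scale(uhh, h, w, 2.0);
  NumericVector That(nv);
  warp2_img(REAL(Tmpl), uhf.memptr(), H, W, REAL(That));

  // --- losses
  double Lr = 0, Lm = 0;
  for (std::size_t i = 0; i < nv; ++i) {
    double d = Xhat[i] - X[i];
    Lr += d * d;
  }
  Lr /= Nv;
  for (std::size_t i = 0; i < nv; ++i) {
    double d = Talpha[i] - That[i];
    Lm += mean_l1 ? std::fabs(d) : d * d;
  }
  Lm /= Nv;
  double Lb1 = bending2(u1f.memptr(), H, W);
  double Lb2 = bending2(u2f.memptr(), H, W);
  double Ld1 = arma::accu(arma::square(u1f)) / Nv;
  double Ld2 = arma::accu(arma::square(u2f)) / Nv;
  double Ltot = gam[0] * Lr + gam[1] * Lb1 + gam[2] * Lb2 +
                gam[3] * Ld1 + gam[4] * Ld2 + gam[5] * Lm;

  List out = List::create(
    _["recon"] = Lr, _["bend1"] = Lb1, _["bend2"] = Lb2,
    _["disp1"] = Ld1, _["disp2"] = Ld2, _["mean"] = Lm, _["total"] = Ltot,
    _["newm0"] = NumericVector(nm0.begin(), nm0.end()),
    _["newm1"] = NumericVector(nm1.begin(), nm1.end()));
  if (!light) {
    out["Talpha"] = Talpha; out["That"] = That; out["Xhat"] = Xhat;
    out["v1h"] = NumericVector(v1h.begin(), v1h.end());
    out["v2h"] = NumericVector(v2h.begin(), v2h.end());
    out["u1f"] = NumericVector(u1f.memptr(), u1f.memptr() + 2 * nv);
    out["u2f"] = NumericVector(u2f.memptr(), u2f.memptr() + 2 * nv);
    out["uhatf"] = NumericVector(uhf.memptr(), uhf.memptr() + 2 * nv);
  }
  if (!want_grad) return out;

  // --- backward
  if ((std::size_t)grad_out.size() != (std::size_t)params.size())
    stop("grad buffer size mismatch");
  Params G(L, grad_out.begin());

  // recon -> Xhat
  std::vector<double> gXhat(nv);
  for (std::size_t i = 0; i < nv; ++i)
    gXhat[i] = gam[0] * 2.0 * (Xhat[i] - X[i]) / Nv;

  // Xhat = warp(Talpha, u2f)
  std::vector<double> gTalpha(nv, 0.0);
  mat gu2f(nv, 2, arma::fill::zeros);
  warp2_img_bwd(REAL(Talpha), u2f.memptr(), H, W, gXhat.data(),
                gTalpha.data(), gu2f.memptr());
  bending2_grad(u2f.memptr(), H, W, gam[2], gu2f.memptr());
  gu2f += (gam[4] * 2.0 / Nv) * u2f;
  mat gu2h = up2_scale_bwd(gu2f, h, w, 2.0);
  vec gv2h = integrate2_bwd(tape2, h, w, arma::vectorise(gu2h));

  // mean loss -> That and Talpha
  std::vector<double> gThat(nv);
  for (std::size_t i = 0; i < nv; ++i) {
    double d = Talpha[i] - That[i];
    double g = mean_l1 ? (d > 0 ? 1.0 : (d < 0 ? -1.0 : 0.0)) / Nv
                       : 2.0 * d / Nv;
    gThat[i] = -gam[5] * g;
    gTalpha[i] += gam[5] * g;
  }
  // That = warp(T, uhatf); grad wrt T discarded (template fixed)
  mat guhf(nv, 2, arma::fill::zeros);
  warp2_img_bwd(REAL(Tmpl), uhf.memptr(), H, W, gThat.data(), nullptr,
                guhf.memptr());
  mat guhh = up2_scale_bwd(guhf, h, w, 2.0);
  vec gvhat = integrate2_bwd(tapeh, h, w, arma::vectorise(guhh));
  // vhat = v1h + const + cv2 * v2h (gradient view)
  vec gv1h = gvhat;
  gv2h += cv2 * gvhat;

  // Stage-2 backward; input channel 0 is Talpha
  mat gv2m(gv2h.memptr(), nvh, 2, false, true);
  mat gin2 = stage2_bwd(c, P, s2, gv2m, G);
  for (std::size_t i = 0; i < nv; ++i) gTalpha[i] += gin2(i, 0);

  // Talpha = warp(T, u1f)
  mat gu1f(nv, 2, arma::fill::zeros);
  warp2_img_bwd(REAL(Tmpl), u1f.memptr(), H, W, gTalpha.data(), nullptr,
                gu1f.memptr());
  bending2_grad(u1f.memptr(), H, W, gam[1], gu1f.memptr());
  gu1f += (gam[3] * 2.0 / Nv) * u1f;
  mat gu1h = up2_scale_bwd(gu1f, h, w, 2.0);
  gv1h += integrate2_bwd(tape1, h, w, arma::vectorise(gu1h));

  // Stage-1 backward
  mat gv1m(gv1h.memptr(), nvh, 2, false, true);
  stage1_bwd(c, P, vec(cov.begin(), cov.size()), vec(eps.begin(), eps.size()),
             sample, s1, gv1m, G);
  return out;
}

// ---------------------------------------------------------------------------
// internal small-deformation SVF registration (evaluation utility)

// Gradient descent (Adam) on 0.5-resolution? No: full-resolution velocity,
// objective MSE(warp(moving, u), fixed) + lambda_bend * bending(u).
// [[Rcpp::export]]
List ca_register_cpp(NumericMatrix fixed, NumericMatrix moving, int iters,
                     double lr, double lambda_bend, int steps) {
  int H = fixed.nrow(), W = fixed.ncol();
  std::size_t nv = (std::size_t)H * W;
  double Nv = (double)nv;
  vec v(2 * nv, arma::fill::zeros);
  vec madam(2 * nv, arma::fill::zeros), vadam(2 * nv, arma::fill::zeros);
  NumericVector warped(nv);
  NumericVector trace(iters);
  std::vector<vec> tape;
  double b1 = 0.9, b2 = 0.999, epsn = 1e-8;
  for (int it = 0; it < iters; ++it) {
    integrate2_tape(v, H, W, steps, tape);
    const vec& u = tape.back();
    warp2_img(REAL(moving), u.memptr(), H, W, REAL(warped));
    double loss = 0;
    std::vector<double> gw(nv);
    for (std::size_t i = 0; i < nv; ++i) {
      double d = warped[i] - fixed[i];
      loss += d * d;
      gw[i] = 2.0 * d / Nv;
    }
    loss /= Nv;
    loss += lambda_bend * bending2(u.memptr(), H, W);
    trace[it] = loss;
    mat gu(nv, 2, arma::fill::zeros);
    warp2_img_bwd(REAL(moving), u.memptr(), H, W, gw.data(), nullptr, gu.memptr());
    bending2_grad(u.memptr(), H, W, lambda_bend, gu.memptr());
    vec g = integrate2_bwd(tape, H, W, arma::vectorise(gu));
    madam = b1 * madam + (1 - b1) * g;
    vadam = b2 * vadam + (1 - b2) * arma::square(g);
    double bc1 = 1 - std::pow(b1, it + 1), bc2 = 1 - std::pow(b2, it + 1);
    v -= lr * (madam / bc1) / (arma::sqrt(vadam / bc2) + epsn);
  }
  integrate2_tape(v, H, W, steps, tape);
  const vec& u = tape.back();
  warp2_img(REAL(moving), u.memptr(), H, W, REAL(warped));
  return List::create(
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["warped"] = warped, _["trace"] = trace);
}
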