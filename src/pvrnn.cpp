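// PV-RNN engine: hierarchical multiple-timescale recurrent network with
// per-step Gaussian latent variables, conditional prior, adaptive posterior,
// normalized variational free energy, and backpropagation through time.
//
// Layer index l = 0 is the layer closest to the output. Layer l receives
// deterministic context from layers l-1 and l+1 (when they exist). Time
// constants tau give leaky-integrator dynamics:
//   h_t = (1 - 1/tau) h_{t-1} + (1/tau)(Wdd d~_{t-1} + Wzd z_t + cross + bh)
//   d~_t = tanh(h_t)
// Prior (t>1):      mu_p = tanh(Wmu_p d~_{t-1} + bmu_p), sig_p = exp(...)
// Posterior:        mu_q = tanh(Wmu_q d~_{t-1} + Amu_t + bmu_q), ...
// At absolute t = 1 the prior is the unit Gaussian and d~_0 = 0.
//
// Free energy (normalized):
//   F = sum_t sum_l w(l,t) * mean_r delta(l,r,t)
//     + (1/R_X) sum_t || mask .* (X_t - Xbar_t) ||^2
// with delta the elementwise Gaussian KL(q || p).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

namespace {

struct Net {
  int L;
  arma::ivec dd, zz;
  vec alpha;                       // 1 / tau
  std::vector<mat> Wdd, Wdu, Wdl;  // self, from l+1, from l-1
  std::vector<mat> Wzd;
  std::vector<vec> bh;
  std::vector<mat> Wmu_q, Wsig_q;  // posterior head weights
  std::vector<mat> Wmu_p, Wsig_p;  // prior head weights (== posterior if shared)
  std::vector<vec> bmu_p, bsig_p, bmu_q, bsig_q;
  mat Wout;
  vec bout;
  bool shared;
};

mat as_mat(SEXP s) { return as<mat>(s); }
vec as_vec(SEXP s) { return as<vec>(s); }

Net parse_net(const List& params, const List& specs) {
  Net n;
  arma::ivec d = as<arma::ivec>(specs["d"]);
  arma::ivec z = as<arma::ivec>(specs["z"]);
  vec tau = as<vec>(specs["tau"]);
  n.L = d.n_elem;
  n.dd = d; n.zz = z;
  n.alpha = 1.0 / tau;
  n.shared = as<bool>(params["share_heads"]);
  List layers = params["layers"];
  for (int l = 0; l < n.L; ++l) {
    List ly = layers[l];
    n.Wdd.push_back(as_mat(ly["Wdd"]));
    n.Wdu.push_back(l + 1 < n.L ? as_mat(ly["Wdu"]) : mat());
    n.Wdl.push_back(l > 0 ? as_mat(ly["Wdl"]) : mat());
    n.Wzd.push_back(as_mat(ly["Wzd"]));
    n.bh.push_back(as_vec(ly["bh"]));
    n.Wmu_q.push_back(as_mat(ly["Wmu_q"]));
    n.Wsig_q.push_back(as_mat(ly["Wsig_q"]));
    if (n.shared) {
      n.Wmu_p.push_back(as_mat(ly["Wmu_q"]));
      n.Wsig_p.push_back(as_mat(ly["Wsig_q"]));
    } else {
      n.Wmu_p.push_back(as_mat(ly["Wmu_p"]));
      n.Wsig_p.push_back(as_mat(ly["Wsig_p"]));
    }
    n.bmu_p.push_back(as_vec(ly["bmu_p"]));
    n.bsig_p.push_back(as_vec(ly["bsig_p"]));
    n.bmu_q.push_back(as_vec(ly["bmu_q"]));
    n.bsig_q.push_back(as_vec(ly["bsig_q"]));
  }
  n.Wout = as_mat(params["Wout"]);
  n.bout = as_vec(params["bout"]);
  return n;
}

// zero-valued gradient container mirroring Net
struct NetGrad {
  std::vector<mat> Wdd, Wdu, Wdl, Wzd;
  std::vector<vec> bh;
  std::vector<mat> Wmu_q, Wsig_q, Wmu_p, Wsig_p;
  std::vector<vec> bmu_p, bsig_p, bmu_q, bsig_q;
  mat Wout;
  vec bout;
  NetGrad(const Net& n) {
    for (int l = 0; l < n.L; ++l) {
      Wdd.push_back(arma::zeros<mat>(arma::size(n.Wdd[l])));
      Wdu.push_back(l + 1 < n.L ? arma::zeros<mat>(arma::size(n.Wdu[l])) : mat());
      Wdl.push_back(l > 0 ? arma::zeros<mat>(arma::size(n.Wdl[l])) : mat());
      Wzd.push_back(arma::zeros<mat>(arma::size(n.Wzd[l])));
      bh.push_back(arma::zeros<vec>(n.dd[l]));
      Wmu_q.push_back(arma::zeros<mat>(arma::size(n.Wmu_q[l])));
      Wsig_q.push_back(arma::zeros<mat>(arma::size(n.Wsig_q[l])));
      Wmu_p.push_back(arma::zeros<mat>(arma::size(n.Wmu_p[l])));
      Wsig_p.push_back(arma::zeros<mat>(arma::size(n.Wsig_p[l])));
      bmu_p.push_back(arma::zeros<vec>(n.zz[l]));
      bsig_p.push_back(arma::zeros<vec>(n.zz[l]));
      bmu_q.push_back(arma::zeros<vec>(n.zz[l]));
      bsig_q.push_back(arma::zeros<vec>(n.zz[l]));
    }
    Wout = arma::zeros<mat>(arma::size(n.Wout));
    bout = arma::zeros<vec>(n.bout.n_elem);
  }
  List to_list(const Net& n) const {
    List layers(n.L);
    for (int l = 0; l < n.L; ++l) {
      List ly = List::create(
        _["Wdd"] = Wdd[l], _["Wzd"] = Wzd[l], _["bh"] = bh[l],
        _["Wmu_q"] = n.shared ? mat(Wmu_q[l] + Wmu_p[l]) : Wmu_q[l],
        _["Wsig_q"] = n.shared ? mat(Wsig_q[l] + Wsig_p[l]) : Wsig_q[l],
        _["bmu_p"] = bmu_p[l], _["bsig_p"] = bsig_p[l],
        _["bmu_q"] = bmu_q[l], _["bsig_q"] = bsig_q[l]);
      if (!n.shared) {
        ly["Wmu_p"] = Wmu_p[l];
        ly["Wsig_p"] = Wsig_p[l];
      }
      if (l + 1 < n.L) ly["Wdu"] = Wdu[l];
      if (l > 0) ly["Wdl"] = Wdl[l];
      layers[l] = ly;
    }
    return List::create(_["layers"] = layers, _["Wout"] = Wout,
                        _["bout"] = bout);
  }
};

mat rnorm_mat(int r, int c) {
  mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = R::norm_rand();
  return m;
}

struct FwdState {
  // [t][l], t = 0..T with t = 0 the pre-window state
  std::vector<std::vector<mat>> d, h;
  // [t-1][l], t = 1..T
  std::vector<std::vector<mat>> z, eps, muq, sigq, mup, sigp;
  cube xbar;      // RX x B x T
  mat kl;         // L x T, per-dim mean of delta summed over batch
  double comp, err;
};

// Forward pass over a window/sequence of length T for a batch of B series.
// unit_start: the first step of this window is absolute time 1.
void forward(const Net& n, const cube& X, const std::vector<cube>& Amu,
             const std::vector<cube>& Asig, const mat& w, const vec& mask,
             const std::vector<mat>& h0, const std::vector<mat>& d0,
             bool unit_start, bool deterministic,
             const std::vector<cube>* eps_in, FwdState& st) {
  const int T = X.n_slices, B = X.n_cols, L = n.L;
  const double RX = arma::accu(mask);
  st.d.assign(T + 1, std::vector<mat>(L));
  st.h.assign(T + 1, std::vector<mat>(L));
  st.z.assign(T, std::vector<mat>(L));
  st.eps.assign(T, std::vector<mat>(L));
  st.muq.assign(T, std::vector<mat>(L));
  st.sigq.assign(T, std::vector<mat>(L));
  st.mup.assign(T, std::vector<mat>(L));
  st.sigp.assign(T, std::vector<mat>(L));
  st.xbar.set_size(n.Wout.n_rows, B, T);
  st.kl.zeros(L, T);
  st.comp = 0.0;
  st.err = 0.0;
  for (int l = 0; l < L; ++l) {
    st.h[0][l] = h0[l];
    st.d[0][l] = d0[l];
  }
  for (int t = 1; t <= T; ++t) {
    for (int l = 0; l < L; ++l) {
      const mat& dprev = st.d[t - 1][l];
      // posterior
      mat amu = n.Wmu_q[l] * dprev + Amu[l].slice(t - 1);
      amu.each_col() += n.bmu_q[l];
      mat muq = arma::tanh(amu);
      mat asq = n.Wsig_q[l] * dprev + Asig[l].slice(t - 1);
      asq.each_col() += n.bsig_q[l];
      mat sigq = arma::exp(asq);
      // prior
      mat mup, sigp;
      if (t == 1 && unit_start) {
        mup.zeros(n.zz[l], B);
        sigp.ones(n.zz[l], B);
      } else {
        mat amup = n.Wmu_p[l] * dprev;
        amup.each_col() += n.bmu_p[l];
        mup = arma::tanh(amup);
        mat asp = n.Wsig_p[l] * dprev;
        asp.each_col() += n.bsig_p[l];
        sigp = arma::exp(asp);
      }
      mat eps;
      if (deterministic) eps = arma::zeros<mat>(n.zz[l], B);
      else if (eps_in) eps = (*eps_in)[l].slice(t - 1);
      else eps = rnorm_mat(n.zz[l], B);
      mat z = muq + sigq % eps;
      // KL(q || p), per-dim mean, summed over batch
      mat delta = arma::log(sigp / sigq) +
        (arma::square(muq - mup) + arma::square(sigq)) /
        (2.0 * arma::square(sigp)) - 0.5;
      double klv = arma::accu(delta) / n.zz[l];
      st.kl(l, t - 1) = klv;
      st.comp += w(l, t - 1) * klv;
      // deterministic update
      mat u = n.Wdd[l] * st.d[t - 1][l] + n.Wzd[l] * z;
      u.each_col() += n.bh[l];
      if (l + 1 < L) u += n.Wdu[l] * st.d[t - 1][l + 1];
      if (l > 0) u += n.Wdl[l] * st.d[t - 1][l - 1];
      mat h = (1.0 - n.alpha[l]) * st.h[t - 1][l] + n.alpha[l] * u;
      st.h[t][l] = h;
      st.d[t][l] = arma::tanh(h);
      st.z[t - 1][l] = z;
      st.eps[t - 1][l] = eps;
      st.muq[t - 1][l] = muq;
      st.sigq[t - 1][l] = sigq;
      st.mup[t - 1][l] = mup;
      st.sigp[t - 1][l] = sigp;
    }
    mat o = n.Wout * st.d[t][0];
    o.each_col() += n.bout;
    mat xb = arma::tanh(o);
    st.xbar.slice(t - 1) = xb;
    mat e = xb - X.slice(t - 1);
    e.each_col() %= mask;
    st.err += arma::accu(arma::square(e)) / RX;
  }
}

// Backward pass; fills parameter gradients (if pg) and A gradients (if ga).
void backward(const Net& n, const cube& X, const mat& w, const vec& mask,
              bool unit_start, const FwdState& st, NetGrad* pg,
              std::vector<cube>* gAmu, std::vector<cube>* gAsig) {
  const int T = X.n_slices, B = X.n_cols, L = n.L;
  const double RX = arma::accu(mask);
  std::vector<mat> gd(L), ghnext(L);
  for (int l = 0; l < L; ++l) {
    gd[l] = arma::zeros<mat>(n.dd[l], B);
    ghnext[l] = arma::zeros<mat>(n.dd[l], B);
  }
  for (int t = T; t >= 1; --t) {
    // output contribution at t
    {
      const mat& xb = st.xbar.slice(t - 1);
      mat e = xb - X.slice(t - 1);
      e.each_col() %= mask;
      mat go = (2.0 / RX) * e % (1.0 - arma::square(xb));
      gd[0] += n.Wout.t() * go;
      if (pg) {
        pg->Wout += go * st.d[t][0].t();
        pg->bout += arma::sum(go, 1);
      }
    }
    std::vector<mat> gdprev(L);
    for (int l = 0; l < L; ++l) gdprev[l] = arma::zeros<mat>(n.dd[l], B);
    for (int l = 0; l < L; ++l) {
      mat gh = gd[l] % (1.0 - arma::square(st.d[t][l])) +
        (1.0 - n.alpha[l]) * ghnext[l];
      ghnext[l] = gh;
      mat gu = n.alpha[l] * gh;
      const mat& dprev = st.d[t - 1][l];
      if (pg) {
        pg->Wdd[l] += gu * dprev.t();
        pg->Wzd[l] += gu * st.z[t - 1][l].t();
        pg->bh[l] += arma::sum(gu, 1);
        if (l + 1 < L) pg->Wdu[l] += gu * st.d[t - 1][l + 1].t();
        if (l > 0) pg->Wdl[l] += gu * st.d[t - 1][l - 1].t();
      }
      gdprev[l] += n.Wdd[l].t() * gu;
      if (l + 1 < L) gdprev[l + 1] += n.Wdu[l].t() * gu;
      if (l > 0) gdprev[l - 1] += n.Wdl[l].t() * gu;
      // latent path
      const mat& muq = st.muq[t - 1][l];
      const mat& sigq = st.sigq[t - 1][l];
      const mat& mup = st.mup[t - 1][l];
      const mat& sigp = st.sigp[t - 1][l];
      const mat& eps = st.eps[t - 1][l];
      const double c = w(l, t - 1) / n.zz[l];
      mat sigp2 = arma::square(sigp);
      mat gz = n.Wzd[l].t() * gu;
      mat gmuq = gz + c * (muq - mup) / sigp2;
      mat gasq = gz % sigq % eps +
        c * (arma::square(sigq) / sigp2 - 1.0);
      mat gamu = gmuq % (1.0 - arma::square(muq));
      if (gAmu) {
        (*gAmu)[l].slice(t - 1) = gamu;
        (*gAsig)[l].slice(t - 1) = gasq;
      }
      if (pg) {
        pg->Wmu_q[l] += gamu * dprev.t();
        pg->Wsig_q[l] += gasq * dprev.t();
        pg->bmu_q[l] += arma::sum(gamu, 1);
        pg->bsig_q[l] += arma::sum(gasq, 1);
      }
      gdprev[l] += n.Wmu_q[l].t() * gamu + n.Wsig_q[l].t() * gasq;
      if (!(t == 1 && unit_start)) {
        mat gmup = -c * (muq - mup) / sigp2;
        mat gasp = c * (1.0 - (arma::square(muq - mup) +
                               arma::square(sigq)) / sigp2);
        mat gamup = gmup % (1.0 - arma::square(mup));
        if (pg) {
          pg->Wmu_p[l] += gamup * dprev.t();
          pg->Wsig_p[l] += gasp * dprev.t();
          pg->bmu_p[l] += arma::sum(gamup, 1);
          pg->bsig_p[l] += arma::sum(gasp, 1);
        }
        gdprev[l] += n.Wmu_p[l].t() * gamup + n.Wsig_p[l].t() * gasp;
      }
    }
    gd = gdprev;
  }
}

std::vector<cube> parse_cubes(const List& a) {
  std::vector<cube> out;
  for (int i = 0; i < a.size(); ++i) out.push_back(as<cube>(a[i]));
  return out;
}

std::vector<mat> parse_mats(const List& a) {
  std::vector<mat> out;
  for (int i = 0; i < a.size(); ++i) out.push_back(as<mat>(a[i]));
  return out;
}

std::vector<mat> zero_states(const Net& n, int B) {
  std::vector<mat> out;
  for (int l = 0; l < n.L; ++l) out.push_back(arma::zeros<mat>(n.dd[l], B));
  return out;
}

List cubes_to_list(const std::vector<cube>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

List states_to_list(const std::vector<mat>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_free_energy(List params, List specs, arma::cube X, List Amu,
                     List Asig, arma::mat w, arma::vec mask,
                     bool unit_start, bool deterministic,
                     Nullable<List> eps = R_NilValue,
                     Nullable<List> h0 = R_NilValue,
                     Nullable<List> d0 = R_NilValue,
                     bool want_param_grads = true,
                     bool want_A_grads = true,
                     bool want_states = false) {
  Net n = parse_net(params, specs);
  const int B = X.n_cols;
  std::vector<cube> amu = parse_cubes(Amu), asig = parse_cubes(Asig);
  std::vector<cube> epsv;
  std::vector<cube>* epsp = nullptr;
  if (eps.isNotNull()) {
    epsv = parse_cubes(List(eps));
    epsp = &epsv;
  }
  std::vector<mat> h0v = h0.isNotNull() ? parse_mats(List(h0)) : zero_states(n, B);
  std::vector<mat> d0v = d0.isNotNull() ? parse_mats(List(d0)) : zero_states(n, B);
  FwdState st;
  forward(n, X, amu, asig, w, mask, h0v, d0v, unit_start, deterministic,
          epsp, st);
  List out = List::create(
    _["F"] = st.comp + st.err, _["complexity"] = st.comp,
    _["error"] = st.err, _["kl"] = st.kl, _["xbar"] = st.xbar);
  if (want_param_grads || want_A_grads) {
    NetGrad pg(n);
    std::vector<cube> gAmu, gAsig;
    for (int l = 0; l < n.L; ++l) {
      gAmu.push_back(arma::zeros<cube>(arma::size(amu[l])));
      gAsig.push_back(arma::zeros<cube>(arma::size(asig[l])));
    }
    backward(n, X, w, mask, unit_start, st,
             want_param_grads ? &pg : nullptr, &gAmu, &gAsig);
    if (want_param_grads) out["grads"] = pg.to_list(n);
    if (want_A_grads) {
      out["gAmu"] = cubes_to_list(gAmu);
      out["gAsig"] = cubes_to_list(gAsig);
    }
  }
  if (want_states) {
    const int T = X.n_slices;
    List hT(n.L), dT(n.L), h1(n.L), d1(n.L);
    for (int l = 0; l < n.L; ++l) {
      hT[l] = st.h[T][l]; dT[l] = st.d[T][l];
      h1[l] = st.h[1][l]; d1[l] = st.d[1][l];
    }
    out["h_last"] = hT; out["d_last"] = dT;
    out["h_first"] = h1; out["d_first"] = d1;
    // posterior/prior traces of layer 1 and per-layer KL at last step
    List muq(n.L), mup(n.L), sigq(n.L), sigp(n.L);
    for (int l = 0; l < n.L; ++l) {
      mat mq(n.zz[l], T), mp(n.zz[l], T), sq(n.zz[l], T), sp(n.zz[l], T);
      for (int t = 0; t < T; ++t) {
        mq.col(t) = st.muq[t][l].col(0);
        mp.col(t) = st.mup[t][l].col(0);
        sq.col(t) = st.sigq[t][l].col(0);
        sp.col(t) = st.sigp[t][l].col(0);
      }
      muq[l] = mq; mup[l] = mp; sigq[l] = sq; sigp[l] = sp;
    }
    out["muq"] = muq; out["mup"] = mup;
    out["sigq"] = sigq; out["sigp"] = sigp;
  }
  return out;
}

// Closed-loop generation sampling z from the prior at every step.
// [[Rcpp::export]]
List cpp_prior_generate(List params, List specs, int T, bool unit_start,
                        bool deterministic,
                        Nullable<List> h0 = R_NilValue,
                        Nullable<List> d0 = R_NilValue) {
  Net n = parse_net(params, specs);
  std::vector<mat> h = h0.isNotNull() ? parse_mats(List(h0)) : zero_states(n, 1);
  std::vector<mat> d = d0.isNotNull() ? parse_mats(List(d0)) : zero_states(n, 1);
  mat xbar(n.Wout.n_rows, T);
  List mup_tr(n.L), sigp_tr(n.L);
  std::vector<mat> mupm(n.L), sigpm(n.L);
  for (int l = 0; l < n.L; ++l) {
    mupm[l].set_size(n.zz[l], T);
    sigpm[l].set_size(n.zz[l], T);
  }
  for (int t = 1; t <= T; ++t) {
    std::vector<mat> dnew(n.L), hnew(n.L);
    for (int l = 0; l < n.L; ++l) {
      mat mup, sigp;
      if (t == 1 && unit_start) {
        mup.zeros(n.zz[l], 1);
        sigp.ones(n.zz[l], 1);
      } else {
        mat amup = n.Wmu_p[l] * d[l];
        amup.each_col() += n.bmu_p[l];
        mup = arma::tanh(amup);
        mat asp = n.Wsig_p[l] * d[l];
        asp.each_col() += n.bsig_p[l];
        sigp = arma::exp(asp);
      }
      mat eps = deterministic ? arma::zeros<mat>(n.zz[l], 1)
                              : rnorm_mat(n.zz[l], 1);
      mat z = mup + sigp % eps;
      mat u = n.Wdd[l] * d[l] + n.Wzd[l] * z;
      u.each_col() += n.bh[l];
      if (l + 1 < n.L) u += n.Wdu[l] * d[l + 1];
      if (l > 0) u += n.Wdl[l] * d[l - 1];
      hnew[l] = (1.0 - n.alpha[l]) * h[l] + n.alpha[l] * u;
      dnew[l] = arma::tanh(hnew[l]);
      mupm[l].col(t - 1) = mup.col(0);
      sigpm[l].col(t - 1) = sigp.col(0);
    }
    h = hnew; d = dnew;
    mat o = n.Wout * d[0];
    o.each_col() += n.bout;
    mat xb = arma::tanh(o);
    xbar.col(t - 1) = xb.col(0);
  }
  for (int l = 0; l < n.L; ++l) {
    mup_tr[l] = mupm[l];
    sigp_tr[l] = sigpm[l];
  }
  return List::create(_["xbar"] = xbar.t(), _["mup"] = mup_tr,
                      _["sigp"] = sigp_tr,
                      _["h_last"] = states_to_list(h),
                      _["d_last"] = states_to_list(d));
}

// Sliding-window error regression: `iterations` Adam steps on the adaptive
// posterior variables A of the current window (network weights frozen),
// followed by a final forward pass and a one-step generative prediction from
// the prior. Returns updated A, the free-energy trace, window diagnostics and
// the states after the first window step (used when the window slides).
// [[Rcpp::export]]
List cpp_infer_window(List params, List specs, arma::mat Xwin, List Amu,
                      List Asig, arma::vec w_layers, arma::vec mask,
                      int iterations, double lr, bool unit_start,
                      bool resample_noise, bool deterministic,
                      List h0, List d0, bool predict_deterministic) {
  Net n = parse_net(params, specs);
  const int V = Xwin.n_rows;
  cube X(Xwin.n_cols, 1, V);
  for (int t = 0; t < V; ++t) X.slice(t) = Xwin.row(t).t();
  std::vector<cube> amu = parse_cubes(Amu), asig = parse_cubes(Asig);
  std::vector<mat> h0v = parse_mats(h0), d0v = parse_mats(d0);
  mat w(n.L, V);
  for (int l = 0; l < n.L; ++l) w.row(l).fill(w_layers[l]);
  // Adam state for A (fresh each call)
  std::vector<cube> mAmu, vAmu, mAsig, vAsig;
  for (int l = 0; l < n.L; ++l) {
    mAmu.push_back(arma::zeros<cube>(arma::size(amu[l])));
    vAmu.push_back(arma::zeros<cube>(arma::size(amu[l])));
    mAsig.push_back(arma::zeros<cube>(arma::size(asig[l])));
    vAsig.push_back(arma::zeros<cube>(arma::size(asig[l])));
  }
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  vec ftrace(iterations);
  FwdState st;
  std::vector<cube>* epsp = nullptr;
  std::vector<cube> eps_fixed;
  if (!resample_noise && !deterministic) {
    for (int l = 0; l < n.L; ++l) {
      cube e(n.zz[l], 1, V);
      for (arma::uword i = 0; i < e.n_elem; ++i) e(i) = R::norm_rand();
      eps_fixed.push_back(e);
    }
    epsp = &eps_fixed;
  }
  for (int it = 1; it <= iterations; ++it) {
    forward(n, X, amu, asig, w, mask, h0v, d0v, unit_start, deterministic,
            epsp, st);
    ftrace[it - 1] = st.comp + st.err;
    std::vector<cube> gAmu, gAsig;
    for (int l = 0; l < n.L; ++l) {
      gAmu.push_back(arma::zeros<cube>(arma::size(amu[l])));
      gAsig.push_back(arma::zeros<cube>(arma::size(asig[l])));
    }
    backward(n, X, w, mask, unit_start, st, nullptr, &gAmu, &gAsig);
    const double bc1 = 1.0 - std::pow(b1, it);
    const double bc2 = 1.0 - std::pow(b2, it);
    for (int l = 0; l < n.L; ++l) {
      mAmu[l] = b1 * mAmu[l] + (1 - b1) * gAmu[l];
      vAmu[l] = b2 * vAmu[l] + (1 - b2) * arma::square(gAmu[l]);
      amu[l] -= lr * (mAmu[l] / bc1) / (arma::sqrt(vAmu[l] / bc2) + adam_eps);
      mAsig[l] = b1 * mAsig[l] + (1 - b1) * gAsig[l];
      vAsig[l] = b2 * vAsig[l] + (1 - b2) * arma::square(gAsig[l]);
      asig[l] -= lr * (mAsig[l] / bc1) / (arma::sqrt(vAsig[l] / bc2) + adam_eps);
    }
  }
  // final pass with optimized A
  forward(n, X, amu, asig, w, mask, h0v, d0v, unit_start, deterministic,
          epsp, st);
  double f_final = st.comp + st.err;
  // one generative step beyond the window from the prior
  std::vector<mat> dT(n.L), hT(n.L);
  for (int l = 0; l < n.L; ++l) { dT[l] = st.d[V][l]; hT[l] = st.h[V][l]; }
  std::vector<mat> dnew(n.L), hnew(n.L);
  for (int l = 0; l < n.L; ++l) {
    mat amup = n.Wmu_p[l] * dT[l];
    amup.each_col() += n.bmu_p[l];
    mat mup = arma::tanh(amup);
    mat asp = n.Wsig_p[l] * dT[l];
    asp.each_col() += n.bsig_p[l];
    mat sigp = arma::exp(asp);
    mat eps = predict_deterministic ? arma::zeros<mat>(n.zz[l], 1)
                                    : rnorm_mat(n.zz[l], 1);
    mat z = mup + sigp % eps;
    mat u = n.Wdd[l] * dT[l] + n.Wzd[l] * z;
    u.each_col() += n.bh[l];
    if (l + 1 < n.L) u += n.Wdu[l] * dT[l + 1];
    if (l > 0) u += n.Wdl[l] * dT[l - 1];
    hnew[l] = (1.0 - n.alpha[l]) * hT[l] + n.alpha[l] * u;
    dnew[l] = arma::tanh(hnew[l]);
  }
  mat o = n.Wout * dnew[0];
  o.each_col() += n.bout;
  mat predm = arma::tanh(o);
  vec pred = predm.col(0);
  // diagnostics at the last window step and averaged over the window
  vec klT(n.L), klW(n.L);
  for (int l = 0; l < n.L; ++l) {
    klT[l] = st.kl(l, V - 1);
    klW[l] = arma::mean(st.kl.row(l));
  }
  List muq1(n.L), mup1(n.L), muqF(n.L), sigqF(n.L);
  for (int l = 0; l < n.L; ++l) {
    muq1[l] = vec(st.muq[V - 1][l].col(0));
    mup1[l] = vec(st.mup[V - 1][l].col(0));
    muqF[l] = vec(st.muq[0][l].col(0));
    sigqF[l] = vec(st.sigq[0][l].col(0));
  }
  List h1(n.L), d1(n.L);
  for (int l = 0; l < n.L; ++l) { h1[l] = st.h[1][l]; d1[l] = st.d[1][l]; }
  return List::create(
    _["Amu"] = cubes_to_list(amu), _["Asig"] = cubes_to_list(asig),
    _["ftrace"] = ftrace, _["F"] = f_final,
    _["complexity"] = st.comp, _["error"] = st.err,
    _["kl_last"] = klT, _["kl_window"] = klW,
    _["muq_last"] = muq1, _["mup_last"] = mup1,
    _["muq_first"] = muqF, _["sigq_first"] = sigqF,
    _["pred_next"] = pred,
    _["xbar"] = [&]() {
      mat xw(V, (int)n.Wout.n_rows);
      for (int t = 0; t < V; ++t) xw.row(t) = st.xbar.slice(t).col(0).t();
      return xw;
    }(),
    _["h_first"] = h1, _["d_first"] = d1,
    _["h_last"] = states_to_list(hT), _["d_last"] = states_to_list(dT));
}
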