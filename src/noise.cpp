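// Log-normal measurement-noise kernel: numerical evaluation of the
// conditional density p(yhat | y) for the noise model
//   yhat_k = eta_x * y_k + eta_a,   eta_x ~ LogN(mu_x, sig_x),
//                                   eta_a ~ LogN(mu_a, sig_a),
// independent across output dimensions.  The one-dimensional set of
// noise realizations compatible with (yhat, y) is parameterized by the
// additive component s = eta_a, giving the convolution integral
//   p(yhat|y) = \int_0^{yhat} f_a(s) f_x((yhat - s)/y) / y ds,
// which by construction integrates to one in yhat, so that the product
// over dimensions is a proper conditional density.  The integral has no
// closed form and is evaluated by adaptive Simpson quadrature.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014327;

// log-normal pdf, zero on the closed negative half-line
static inline double lnpdf(double v, double mu, double sig) {
    if (v <= 0.0) return 0.0;
    double z = (std::log(v) - mu) / sig;
    return INV_SQRT_2PI * std::exp(-0.5 * z * z) / (v * sig);
}

struct NoiseDim {
    double mu_x, sig_x, mu_a, sig_a;
};

// integrand in the additive variable s (eta_a): good when the
// multiplicative factor is the wider of the two
// integrand in the multiplicative variable v (eta_x): good when
// y is small and the s-parameterization would be a near-delta spike
struct Integrand {
    double yhat, y;
    NoiseDim nd;
    bool over_v;
    double operator()(double t) const {
        if (over_v)   // t = v, s = yhat - v*y, ds = y dv
            return lnpdf(t, nd.mu_x, nd.sig_x) *
                   lnpdf(yhat - t * y, nd.mu_a, nd.sig_a);
        return lnpdf(t, nd.mu_a, nd.sig_a) *
               lnpdf((yhat - t) / y, nd.mu_x, nd.sig_x) / y;
    }
};

// classic adaptive Simpson with absolute tolerance and depth cap
static double simpson_rec(const Integrand &f, double a, double b,
                          double fa, double fm, double fb, double whole,
                          double tol, int depth) {
    double m  = 0.5 * (a + b);
    double lm = 0.5 * (a + m), rm = 0.5 * (m + b);
    double flm = f(lm), frm = f(rm);
    double left  = (m - a) / 6.0 * (fa + 4.0 * flm + fm);
    double right = (b - m) / 6.0 * (fm + 4.0 * frm + fb);
    double delta = left + right - whole;
    if (depth <= 0 || std::fabs(delta) <= 15.0 * tol)
        return left + right + delta / 15.0;
    return simpson_rec(f, a, m, fa, flm, fm, left,  0.5 * tol, depth - 1) +
           simpson_rec(f, m, b, fm, frm, fb, right, 0.5 * tol, depth - 1);
}

static double simpson_adaptive(const Integrand &f, double a, double b,
                               double tol) {
    if (b <= a) return 0.0;
    double m = 0.5 * (a + b);
    double fa = f(a), fm = f(m), fb = f(b);
    double whole = (b - a) / 6.0 * (fa + 4.0 * fm + fb);
    return simpson_rec(f, a, b, fa, fm, fb, whole, tol, 48);
}

// one-dimensional conditional density p(yhat | y)
static double cond1(double yhat, double y, const NoiseDim &nd, double tol) {
    if (yhat <= 0.0) return 0.0;
    if (y <= 0.0)                       // multiplicative term vanishes
        return lnpdf(yhat, nd.mu_a, nd.sig_a);

    // effective support: both log-normal factors within ~1e-16 of peak
    const double K = 8.7;
    double a_lo = std::exp(nd.mu_a - K * nd.sig_a);
    double a_hi = std::exp(nd.mu_a + K * nd.sig_a);
    double v_lo = std::exp(nd.mu_x - K * nd.sig_x);
    double v_hi = std::exp(nd.mu_x + K * nd.sig_x);

    // multiplicative contribution negligible against the additive
    // scale: additive-only limit (avoids a near-delta integrand)
    if (y * v_hi < 1e-5 * std::exp(nd.mu_a))
        return lnpdf(yhat, nd.mu_a, nd.sig_a);

    // pick the integration variable in which neither factor is a
    // narrow spike: additive variable s when the multiplicative part
    // is wide (y of order 1), multiplicative variable v otherwise
    bool over_v = y * std::exp(nd.mu_x) < std::exp(nd.mu_a);
    Integrand f{yhat, y, nd, over_v};

    double lo, hi, m1, m2;
    if (over_v) {
        lo = std::max(std::max(0.0, v_lo), (yhat - a_hi) / y);
        hi = std::min(v_hi, (yhat - a_lo) / y);
        m1 = std::exp(nd.mu_x - nd.sig_x * nd.sig_x);
        m2 = (yhat - std::exp(nd.mu_a - nd.sig_a * nd.sig_a)) / y;
    } else {
        lo = std::max(std::max(0.0, a_lo), yhat - y * v_hi);
        hi = std::min(std::min(yhat, a_hi), yhat - y * v_lo);
        m1 = std::exp(nd.mu_a - nd.sig_a * nd.sig_a);
        m2 = yhat - y * std::exp(nd.mu_x - nd.sig_x * nd.sig_x);
    }
    if (hi <= lo) return 0.0;

    // split at the two interior peak candidates so the initial Simpson
    // probe cannot step over a narrow mode
    double brk[4];
    int nb = 0;
    brk[nb++] = lo;
    if (m1 > lo && m1 < hi) brk[nb++] = m1;
    if (m2 > lo && m2 < hi) brk[nb++] = m2;
    brk[nb++] = hi;
    std::sort(brk, brk + nb);

    double total = 0.0;
    for (int i = 0; i + 1 < nb; ++i)
        total += simpson_adaptive(f, brk[i], brk[i + 1], tol / (nb - 1));
    return total;
}

// vectorized conditional density over (yhat, y) pairs, one dimension
RcppExport SEXP c_cond_density(SEXP yhatS, SEXP yS, SEXP noiseS, SEXP tolS) {
    NumericVector yhat(yhatS), y(yS), noise(noiseS);
    double tol = as<double>(tolS);
    NoiseDim nd{noise[0], noise[1], noise[2], noise[3]};
    R_xlen_t n = yhat.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = cond1(yhat[i], y[i], nd, tol);
    return out;
}

// bilinear interpolation table of p(yhat|y) on a log-log grid,
// used as a fast path inside large conditional-matrix computations
struct DensTable {
    std::vector<double> lyh, ly, val;  // val[iy * nyh + iyh]
    int nyh, ny;
    double y_floor;                    // below this, additive-only limit
    NoiseDim nd;

    void build(double yh_min, double yh_max, double y_min, double y_max,
               int nyh_, int ny_, const NoiseDim &nd_, double tol) {
        nd = nd_;
        nyh = nyh_; ny = ny_;
        y_floor = std::max(y_min, 1e-4);
        double l0 = std::log(yh_min), l1 = std::log(yh_max);
        if (l1 - l0 < 1e-9) { l0 -= 1e-3; l1 += 1e-3; }
        double m0 = std::log(y_floor), m1 = std::log(std::max(y_max, y_floor * 1.01));
        lyh.resize(nyh); ly.resize(ny);
        for (int i = 0; i < nyh; ++i)
            lyh[i] = l0 + (l1 - l0) * i / (nyh - 1);
        for (int i = 0; i < ny; ++i)
            ly[i] = m0 + (m1 - m0) * i / (ny - 1);
        val.resize((size_t)nyh * ny);
        for (int iy = 0; iy < ny; ++iy) {
            double yy = std::exp(ly[iy]);
            for (int ih = 0; ih < nyh; ++ih)
                val[(size_t)iy * nyh + ih] =
                    cond1(std::exp(lyh[ih]), yy, nd, tol);
        }
    }

    double lookup(double yhat, double y) const {
        if (yhat <= 0.0) return 0.0;
        if (y < y_floor)                 // additive-only limit, exact
            return lnpdf(yhat, nd.mu_a, nd.sig_a);
        double lh = std::log(yhat), lv = std::log(y);
        lh = std::min(std::max(lh, lyh.front()), lyh.back());
        lv = std::min(std::max(lv, ly.front()), ly.back());
        double th = (lh - lyh.front()) / (lyh.back() - lyh.front()) * (nyh - 1);
        double tv = (lv - ly.front()) / (ly.back() - ly.front()) * (ny - 1);
        int ih = std::min((int)th, nyh - 2);
        int iv = std::min((int)tv, ny - 2);
        double fh = th - ih, fv = tv - iv;
        const double *row0 = &val[(size_t)iv * nyh];
        const double *row1 = &val[(size_t)(iv + 1) * nyh];
        double v0 = row0[ih] * (1 - fh) + row0[ih + 1] * fh;
        double v1 = row1[ih] * (1 - fh) + row1[ih + 1] * fh;
        return v0 * (1 - fv) + v1 * fv;
    }
};

// conditional-probability matrix c_ij = (1/S) sum_k prod_d
//   p(yhat[i,d] | ysim[k, t(i), d, j])
// yhat: M x m; tidx: 1-based snapshot time index per cell;
// ysim: array S x n_t x m x J of simulated true outputs;
// noise: m x 4 matrix (mu_x, sig_x, mu_a, sig_a per dimension)
RcppExport SEXP c_cond_matrix(SEXP yhatS, SEXP tidxS, SEXP ysimS, SEXP dimsS,
                              SEXP noiseS, SEXP tolS, SEXP useGridS,
                              SEXP gridNS) {
    NumericMatrix yhat(yhatS);
    IntegerVector tidx(tidxS);
    NumericVector ysim(ysimS);
    IntegerVector dims(dimsS);      // S, n_t, m, J
    NumericMatrix noise(noiseS);
    double tol = as<double>(tolS);
    bool use_grid = as<bool>(useGridS);
    IntegerVector gridN(gridNS);

    int S = dims[0], nt = dims[1], m = dims[2], J = dims[3];
    int M = yhat.nrow();
    std::vector<NoiseDim> nds(m);
    for (int d = 0; d < m; ++d)
        nds[d] = NoiseDim{noise(d, 0), noise(d, 1), noise(d, 2), noise(d, 3)};

    std::vector<DensTable> tabs;
    if (use_grid) {
        tabs.resize(m);
        for (int d = 0; d < m; ++d) {
            double yh_min = R_PosInf, yh_max = 0.0;
            for (int i = 0; i < M; ++i) {
                double v = yhat(i, d);
                if (v > 0) { yh_min = std::min(yh_min, v); yh_max = std::max(yh_max, v); }
            }
            double y_min = R_PosInf, y_max = 0.0;
            for (int j = 0; j < J; ++j)
                for (int t = 0; t < nt; ++t)
                    for (int k = 0; k < S; ++k) {
                        double v = ysim[k + (size_t)S * (t + (size_t)nt * (d + (size_t)m * j))];
                        if (v > 0) { y_min = std::min(y_min, v); y_max = std::max(y_max, v); }
                    }
            if (!R_FINITE(yh_min)) { yh_min = 1e-3; yh_max = 1.0; }
            if (!R_FINITE(y_min)) { y_min = 1e-4; y_max = 1.0; }
            tabs[d].build(yh_min * 0.999, yh_max * 1.001, y_min, y_max,
                          gridN[0], gridN[1], nds[d], tol);
        }
    }

    NumericMatrix C(M, J);
    for (int j = 0; j < J; ++j) {
        for (int i = 0; i < M; ++i) {
            int t = tidx[i] - 1;
            double acc = 0.0;
            for (int k = 0; k < S; ++k) {
                double prod = 1.0;
                for (int d = 0; d < m; ++d) {
                    double ys = ysim[k + (size_t)S * (t + (size_t)nt * (d + (size_t)m * j))];
                    double p = use_grid ? tabs[d].lookup(yhat(i, d), ys)
                                        : cond1(yhat(i, d), ys, nds[d], tol);
                    prod *= p;
                    if (prod == 0.0) break;
                }
                acc += prod;
            }
            C(i, j) = acc / S;
        }
        if (j % 8 == 0) Rcpp::checkUserInterrupt();
    }
    return C;
}
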