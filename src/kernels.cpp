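#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <memory>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exponential integral E1(x) for x >= 0.
// Power series for x <= 1, modified-Lentz continued fraction for x > 1.
// Accuracy ~1e-15 relative; E1(0) = +Inf; underflows to 0 beyond x = 700.
// ---------------------------------------------------------------------------
static double e1_scalar(double x) {
    if (ISNAN(x)) return x;
    if (x < 0.0) return R_NaN;
    if (x == 0.0) return R_PosInf;
    if (x <= 1.0) {
        const double egamma = 0.57721566490153286060651209008240243;
        double sum = 0.0, term = 1.0;
        for (int k = 1; k <= 48; ++k) {
            term *= -x / k;              // (-x)^k / k!
            double add = -term / k;      // (-1)^{k+1} x^k / (k k!)
            sum += add;
            if (std::fabs(add) < 1e-17 * (std::fabs(sum) + 1e-30)) break;
        }
        return -egamma - std::log(x) + sum;
    }
    if (x > 700.0) return 0.0;
    // E1(x) = e^{-x} / (x + 1 - 1/(x + 3 - 4/(x + 5 - 9/(...))))
    double b = x + 1.0, c = 1e308, d = 1.0 / b, h = d;
    for (int i = 1; i <= 300; ++i) {
        double a = -static_cast<double>(i) * static_cast<double>(i);
        b += 2.0;
        d = 1.0 / (a * d + b);
        c = b + a / c;
        double del = c * d;
        h *= del;
        if (std::fabs(del - 1.0) < 1e-16) break;
    }
    return h * std::exp(-x);
}

// [[Rcpp::export]]
NumericVector e1_cpp(NumericVector x) {
    R_xlen_t n = x.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = e1_scalar(x[i]);
    return out;
}

// ---------------------------------------------------------------------------
// Lag tables for constant-slot scans.
//
// All probe activations start on a regular slot grid of width slotLen =
// tau + settle; fields are evaluated at dwell ends t = t_slot + tau.  The
// Gaussian-probe increment contributed by a probe whose slot lags the
// evaluation slot by l depends only on the integer squared pixel offset
// s = dx^2 + dy^2:
//     d0(l) = 2 Ds + 4 D l slotLen          (time since that probe's dwell end,
//                                            or the on-phase floor at l = 0)
//     d1(l) = 2 Ds + 4 D (l slotLen + tau)  (time since that probe's start)
//     inc(l, s) = E1(s c / d1) - E1(s c / d0),  s > 0   (c = pixel size^2)
//     inc(l, 0) = log(d1 / d0)
// The physical distribution is Q0/(4 pi D) * inc.  Tables are exact (the
// lattice is integer); an optional cutoff radius per lag skips increments
// below epsRel times the single-probe peak log(d1(0)/d0(0)).
// ---------------------------------------------------------------------------
struct LagTables {
    double Ds2, fourD, tau, slotLen, c, thr;
    int smax;
    std::vector<std::unique_ptr<std::vector<double>>> tabs;
    std::vector<int> scut;

    LagTables(double Ds, double D, double tau_, double slotLen_, double c_,
              int smax_, int maxLag, double epsRel)
        : Ds2(2.0 * Ds), fourD(4.0 * D), tau(tau_), slotLen(slotLen_),
          c(c_), smax(smax_), tabs(maxLag + 1), scut(maxLag + 1, -1) {
        double peak = std::log((Ds2 + fourD * tau) / Ds2);
        thr = (epsRel > 0.0) ? epsRel * peak : -1.0;
    }

    const std::vector<double>& get(int l, int& cut) {
        if (!tabs[l]) {
            double d0 = Ds2 + fourD * slotLen * l;
            double d1 = d0 + fourD * tau;
            auto tab = std::make_unique<std::vector<double>>(smax + 1);
            (*tab)[0] = std::log(d1 / d0);
            for (int s = 1; s <= smax; ++s) {
                double q = s * c;
                (*tab)[s] = e1_scalar(q / d1) - e1_scalar(q / d0);
            }
            int sc = smax;
            if (thr > 0.0) {
                while (sc > 0 && (*tab)[sc] <= thr) --sc;
            }
            scut[l] = sc;
            tabs[l] = std::move(tab);
        }
        cut = scut[l];
        return *tabs[l];
    }
};

// Add one probe's lag-l increment table into psi (layout: iy * nxp + ix).
static void add_probe(std::vector<double>& psi, int nxp, int nyp,
                      int px, int py, const std::vector<double>& tab, int scut) {
    for (int iy = 0; iy < nyp; ++iy) {
        int dy = iy - py, dy2 = dy * dy;
        if (dy2 > scut) continue;
        double* row = &psi[static_cast<size_t>(iy) * nxp];
        int dx = static_cast<int>(std::floor(std::sqrt(static_cast<double>(scut - dy2))));
        int x0 = px - dx, x1 = px + dx;
        if (x0 < 0) x0 = 0;
        if (x1 > nxp - 1) x1 = nxp - 1;
        for (int ix = x0; ix <= x1; ++ix) {
            int d = ix - px;
            row[ix] += tab[dy2 + d * d];
        }
    }
}

static int grid_smax(const IntegerVector& px, const IntegerVector& py,
                     int nxp, int nyp) {
    int mx = 0, my = 0;
    for (int i = 0; i < px.size(); ++i) {
        mx = std::max(mx, std::max(px[i], nxp - 1 - px[i]));
        my = std::max(my, std::max(py[i], nyp - 1 - py[i]));
    }
    return mx * mx + my * my;
}

// ---------------------------------------------------------------------------
// PM-CDD engine: running point-wise max of the CDD over the dwell-end
// evaluation slots, plus the CDD at the final evaluation instant.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List lag_pmcdd_cpp(IntegerVector px, IntegerVector py, IntegerVector slot,
                   IntegerVector evalSlot, int nxp, int nyp,
                   double Q0, double D, double Ds, double tau, double slotLen,
                   double pix2, double epsRel) {
    int nP = px.size(), nE = evalSlot.size();
    size_t npix = static_cast<size_t>(nxp) * nyp;
    int maxLag = 0;
    for (int e = 0; e < nE; ++e)
        for (int i = 0; i < nP; ++i)
            if (slot[i] <= evalSlot[e]) maxLag = std::max(maxLag, evalSlot[e] - slot[i]);
    LagTables lt(Ds, D, tau, slotLen, pix2, grid_smax(px, py, nxp, nyp),
                 maxLag, epsRel);
    double C = Q0 / (4.0 * M_PI * D);

    std::vector<double> psi(npix), chi(npix, 0.0);
    NumericVector psiMax(nE);
    double best = -1.0;
    int bestPix = 0, bestEval = 0;

    for (int e = 0; e < nE; ++e) {
        std::fill(psi.begin(), psi.end(), 0.0);
        int es = evalSlot[e];
        for (int i = 0; i < nP; ++i) {
            if (slot[i] > es) continue;
            int cut;
            const std::vector<double>& tab = lt.get(es - slot[i], cut);
            add_probe(psi, nxp, nyp, px[i], py[i], tab, cut);
        }
        double m = 0.0;
        for (size_t p = 0; p < npix; ++p) {
            if (psi[p] > chi[p]) chi[p] = psi[p];
            if (psi[p] > m) m = psi[p];
        }
        psiMax[e] = C * m;
        if (m > best) {
            best = m;
            bestEval = e;
            for (size_t p = 0; p < npix; ++p)
                if (psi[p] == m) { bestPix = static_cast<int>(p); break; }
        }
        Rcpp::checkUserInterrupt();
    }

    NumericVector chiOut(npix), psiOut(npix);
    for (size_t p = 0; p < npix; ++p) {
        chiOut[p] = C * chi[p];
        psiOut[p] = C * psi[p];
    }
    return List::create(_["chi"] = chiOut, _["psiFinal"] = psiOut,
                        _["psiMax"] = psiMax, _["gmcdd"] = C * best,
                        _["argmaxPixel"] = bestPix + 1,
                        _["argmaxEval"] = bestEval + 1);
}

// ---------------------------------------------------------------------------
// Greedy diffusion-controlled sampling.  Candidates are visited in trajectory
// order; a candidate is accepted iff the would-be CDD at its own dwell end
// stays strictly below lambda everywhere on the grid.  Under beam-blanker
// timing rejected slots still elapse; under scan-generator timing accepted
// probes are packed into consecutive slots.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List lag_dcs_cpp(IntegerVector px, IntegerVector py, int nxp, int nyp,
                 double Q0, double D, double Ds, double tau, double slotLen,
                 double pix2, double lambda, bool blanker, double epsRel) {
    int nP = px.size();
    size_t npix = static_cast<size_t>(nxp) * nyp;
    LagTables lt(Ds, D, tau, slotLen, pix2, grid_smax(px, py, nxp, nyp),
                 nP, epsRel);
    double C = Q0 / (4.0 * M_PI * D);
    double lamC = lambda / C;

    std::vector<int> apx, apy, aslot;
    std::vector<double> psi(npix), chi(npix, 0.0);
    LogicalVector sel(nP);

    for (int j = 0; j < nP; ++j) {
        int sc = blanker ? j : static_cast<int>(apx.size());
        std::fill(psi.begin(), psi.end(), 0.0);
        int cut;
        {   // the candidate itself (lag 0)
            const std::vector<double>& tab = lt.get(0, cut);
            add_probe(psi, nxp, nyp, px[j], py[j], tab, cut);
        }
        for (size_t i = 0; i < apx.size(); ++i) {
            const std::vector<double>& tab = lt.get(sc - aslot[i], cut);
            add_probe(psi, nxp, nyp, apx[i], apy[i], tab, cut);
        }
        double m = 0.0;
        for (size_t p = 0; p < npix; ++p) if (psi[p] > m) m = psi[p];
        if (m < lamC) {
            sel[j] = true;
            apx.push_back(px[j]);
            apy.push_back(py[j]);
            aslot.push_back(sc);
            for (size_t p = 0; p < npix; ++p)
                if (psi[p] > chi[p]) chi[p] = psi[p];
        }
        Rcpp::checkUserInterrupt();
    }

    double best = 0.0;
    for (size_t p = 0; p < npix; ++p) if (chi[p] > best) best = chi[p];
    NumericVector chiOut(npix);
    for (size_t p = 0; p < npix; ++p) chiOut[p] = C * chi[p];
    return List::create(_["selected"] = sel, _["chi"] = chiOut,
                        _["gmcdd"] = C * best,
                        _["m"] = static_cast<int>(apx.size()));
}

// ---------------------------------------------------------------------------
// Diffusion-induced damage: rectangle-rule time integral over probe slots of
// pupil * g(CDD - lambda), with the CDD evaluated at each slot's dwell end.
// activation: 0 = sign, 1 = ReLU.  lastCover (length npix) gives, per pixel,
// the largest slot index of a selected probe within the pupil radius
// (-1 if none); a zero-length lastCover selects the offline pupil.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector lag_damage_cpp(IntegerVector px, IntegerVector py,
                             IntegerVector slot, int nSlots, int nxp, int nyp,
                             double Q0, double D, double Ds, double tau,
                             double slotLen, double pix2, double lambda,
                             int activation, IntegerVector lastCover,
                             double epsRel) {
    int nP = px.size();
    size_t npix = static_cast<size_t>(nxp) * nyp;
    bool offline = lastCover.size() == 0;
    LagTables lt(Ds, D, tau, slotLen, pix2, grid_smax(px, py, nxp, nyp),
                 nSlots, epsRel);
    double C = Q0 / (4.0 * M_PI * D);

    std::vector<double> psi(npix);
    NumericVector dmg(npix);

    for (int k = 0; k < nSlots; ++k) {
        std::fill(psi.begin(), psi.end(), 0.0);
        for (int i = 0; i < nP; ++i) {
            if (slot[i] > k) continue;
            int cut;
            const std::vector<double>& tab = lt.get(k - slot[i], cut);
            add_probe(psi, nxp, nyp, px[i], py[i], tab, cut);
        }
        double w = (k == nSlots - 1) ? tau : slotLen;
        for (size_t p = 0; p < npix; ++p) {
            if (!offline && k >= lastCover[p]) continue;
            double x = C * psi[p] - lambda;
            if (x < 0.0) continue;
            dmg[p] += w * (activation == 1 ? x : 1.0);
        }
        Rcpp::checkUserInterrupt();
    }
    return dmg;
}

// ---------------------------------------------------------------------------
// Generic Gaussian-probe CDD at arbitrary points and an arbitrary time,
// using the on/off/inactive branches.  The singular r = r_i branch is
// dispatched on exact coordinate equality (probe nodes are grid nodes).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cdd_points_cpp(NumericVector x, NumericVector y,
                             NumericVector pxs, NumericVector pys,
                             NumericVector ti, NumericVector taui,
                             double t, double Q0, double D, double Ds) {
    int nq = x.size(), nP = pxs.size();
    double C = Q0 / (4.0 * M_PI * D);
    NumericVector out(nq);
    for (int j = 0; j < nq; ++j) {
        double acc = 0.0;
        for (int i = 0; i < nP; ++i) {
            double dt = t - ti[i];
            if (dt < 0.0) continue;
            bool on = (t <= ti[i] + taui[i]);
            if (x[j] == pxs[i] && y[j] == pys[i]) {
                double num = Ds + 2.0 * D * dt;
                double den = on ? Ds : (Ds + 2.0 * D * (dt - taui[i]));
                acc += std::log(num / den);
            } else {
                double dx = x[j] - pxs[i], dy = y[j] - pys[i];
                double q = dx * dx + dy * dy;
                double a1 = q / (2.0 * Ds + 4.0 * D * dt);
                double a0 = on ? q / (2.0 * Ds)
                               : q / (2.0 * Ds + 4.0 * D * (dt - taui[i]));
                acc += e1_scalar(a1) - e1_scalar(a0);
            }
        }
        out[j] = C * acc;
    }
    return out;
}
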