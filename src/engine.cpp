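#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: a fast, named, reproducible
// generator so a 32-bit config seed fully determines the trajectory.
struct Xoshiro256pp {
    uint64_t s[4];
    explicit Xoshiro256pp(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t next() {
        const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t;
        s[3] = rotl(s[3], 45);
        return result;
    }
    // uniform in [0, 1)
    inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// DYK state code: s = 4*i + 2*a + h; flips toggle bits 4 (IP3 site),
// 2 (activating Ca site), 1 (inhibiting Ca site).
struct Gating {
    double a_act, b_act, a_inh_ip3, b_inh_ip3, a_inh_noip3, b_inh_noip3,
           a_ip3_noninh, b_ip3_noninh, a_ip3_inh, b_ip3_inh;
    inline void rates(int s, double c, double ip3,
                      double &r_ip3, double &r_act, double &r_inh) const {
        const int i = (s >> 2) & 1, a = (s >> 1) & 1, h = s & 1;
        r_ip3 = i ? (h ? b_ip3_inh : b_ip3_noninh)
                  : (h ? a_ip3_inh : a_ip3_noninh) * ip3;
        r_act = a ? b_act : a_act * c;
        r_inh = h ? (i ? b_inh_ip3 : b_inh_noip3)
                  : (i ? a_inh_ip3 : a_inh_noip3) * c;
    }
};

// Per-step outcome thresholds for one concentration: for each state the
// cumulative probabilities of (no flip | IP3 flip | act flip | inh flip)
// under the per-subunit rule "three independent Bernoulli draws, redraw
// the subunit's step if two or more fire" (sampled exactly via its
// conditional distribution with a single uniform).
struct Tables {
    double t0[8], t1[8], t2[8];
};

inline void buildTable(const Gating &g, double c, double ip3, double dt,
                       Tables &T) {
    for (int s = 0; s < 8; ++s) {
        double r1, r2, r3;
        g.rates(s, c, ip3, r1, r2, r3);
        const double p1 = r1 * dt, p2 = r2 * dt, p3 = r3 * dt;
        const double q1 = 1 - p1, q2 = 1 - p2, q3 = 1 - p3;
        const double w0 = q1 * q2 * q3, w1 = p1 * q2 * q3,
                     w2 = q1 * p2 * q3, w3 = q1 * q2 * p3;
        const double Z = w0 + w1 + w2 + w3;
        T.t0[s] = w0 / Z;
        T.t1[s] = T.t0[s] + w1 / Z;
        T.t2[s] = T.t1[s] + w2 / Z;
    }
}

const int64_t FAR_AWAY = INT64_MAX / 4;

} // namespace

// [[Rcpp::export(name = ".sim_cluster_cpp")]]
List sim_cluster_cpp(NumericVector gating, double c0, double c1,
                     double c_high, double k, double ip3, int n_channels,
                     double dt, double record_dt, double duration,
                     double burn_in, int seed, double freeze_tol = 1e-6) {
    Gating g;
    g.a_act = gating[0];        g.b_act = gating[1];
    g.a_inh_ip3 = gating[2];    g.b_inh_ip3 = gating[3];
    g.a_inh_noip3 = gating[4];  g.b_inh_noip3 = gating[5];
    g.a_ip3_noninh = gating[6]; g.b_ip3_noninh = gating[7];
    g.a_ip3_inh = gating[8];    g.b_ip3_inh = gating[9];

    const double ek = std::exp(-k * dt);
    const int64_t recEvery  = llround(record_dt / dt);
    const int64_t burnSteps = llround(burn_in / dt);
    const int64_t nSteps    = burnSteps + llround(duration / dt);
    const int64_t nRec      = (nSteps - burnSteps) / recEvery + 1;
    const int nSub = n_channels * 4;

    Xoshiro256pp rng(static_cast<uint64_t>(static_cast<uint32_t>(seed)));

    std::vector<int> sub(nSub, 0);          // all sites unbound
    std::vector<char> chOpen(n_channels, 0);
    int nOpen = 0;
    double c = c0;

    Tables highTab, domTab, restTab;
    buildTable(g, c_high, ip3, dt, highTab);
    buildTable(g, c0, ip3, dt, restTab);

    NumericVector recTime(nRec), recC(nRec);
    IntegerVector recOpen(nRec), rec111(nRec), rec011(nRec), recAvail(nRec);

    auto recordAt = [&](int64_t step) {
        const int64_t idx = (step - burnSteps) / recEvery;
        if (idx < 0 || idx >= nRec) return;
        recTime[idx] = (step - burnSteps) * dt;
        recOpen[idx] = nOpen;
        recC[idx] = c;
        int n111 = 0, n011 = 0, nav = 0;
        for (int ch = 0; ch < n_channels; ++ch) {
            int nIp3 = 0;
            for (int u = 0; u < 4; ++u) {
                const int s = sub[ch * 4 + u];
                if (s == 7) ++n111;
                if (s == 3) ++n011;
                if (s >= 4) ++nIp3;
            }
            if (nIp3 >= 3) ++nav;
        }
        rec111[idx] = n111; rec011[idx] = n011; recAvail[idx] = nav;
    };

    auto countOpen = [&]() {
        int tot = 0;
        for (int ch = 0; ch < n_channels; ++ch) {
            int n110 = 0;
            for (int u = 0; u < 4; ++u)
                if (sub[ch * 4 + u] == 6) ++n110;
            chOpen[ch] = (n110 >= 3);
            if (chOpen[ch]) ++tot;
        }
        return tot;
    };

    // steps until a subunit with per-step no-flip probability pNone fires
    auto geomSteps = [&](double pNone) -> int64_t {
        if (pNone >= 1.0) return FAR_AWAY;
        double u = rng.unif();
        if (u <= 0.0) u = 5e-324;
        const double n = std::ceil(std::log(u) / std::log(pNone));
        if (!(n >= 1.0)) return 1;
        if (n > 4e18) return FAR_AWAY;
        return static_cast<int64_t>(n);
    };

    std::vector<int64_t> fireStep(nSub, 0);
    bool frozen = false;
    int64_t step = 0;

    auto enterFrozen = [&]() {
        frozen = true;
        c = c0;  // quench the sub-tolerance residual
        for (int j = 0; j < nSub; ++j)
            fireStep[j] = step + geomSteps(restTab.t0[sub[j]]);
    };

    auto nextRecordAfter = [&](int64_t s) -> int64_t {
        if (s < burnSteps) return burnSteps;
        return burnSteps + ((s - burnSteps) / recEvery + 1) * recEvery;
    };

    if (burnSteps == 0) recordAt(0);  // initial sample of the rest state
    if (nOpen == 0) enterFrozen();

    int64_t sinceInterrupt = 0;
    while (step < nSteps) {
        if (frozen) {
            // All channels closed, c pinned at c0: per-subunit step outcomes
            // are i.i.d., so skip ahead geometrically to the next flip.
            int64_t mf = FAR_AWAY;
            for (int j = 0; j < nSub; ++j) mf = std::min(mf, fireStep[j]);
            if (mf > nSteps) {
                for (int64_t r = nextRecordAfter(step); r <= nSteps;
                     r += recEvery)
                    recordAt(r);
                step = nSteps;
                break;
            }
            for (int64_t r = nextRecordAfter(step); r < mf; r += recEvery)
                recordAt(r);
            // apply the flip(s) completing during step mf
            for (int j = 0; j < nSub; ++j) {
                if (fireStep[j] != mf) continue;
                const int s = sub[j];
                const double t0 = restTab.t0[s], t1 = restTab.t1[s],
                             t2 = restTab.t2[s];
                const double u = t0 + rng.unif() * (1.0 - t0);
                if (u < t1)      sub[j] = s ^ 4;
                else if (u < t2) sub[j] = s ^ 2;
                else             sub[j] = s ^ 1;
            }
            step = mf;
            const int newOpen = countOpen();
            if (newOpen > 0) {
                c = std::max(c, c0 + c1 * newOpen);  // instantaneous upward jump
                nOpen = newOpen;
                const double cstat = c0 + c1 * nOpen;
                c = cstat + (c - cstat) * ek;
                frozen = false;
            } else {
                nOpen = 0;
                for (int j = 0; j < nSub; ++j)
                    if (fireStep[j] == mf)
                        fireStep[j] = mf + geomSteps(restTab.t0[sub[j]]);
            }
            if (step >= burnSteps && (step - burnSteps) % recEvery == 0)
                recordAt(step);
        } else {
            buildTable(g, c, ip3, dt, domTab);
            // synchronous update: all subunits see start-of-step
            // concentrations and open/closed statuses
            for (int ch = 0; ch < n_channels; ++ch) {
                const Tables &T = chOpen[ch] ? highTab : domTab;
                const int base = ch * 4;
                for (int u = 0; u < 4; ++u) {
                    const int s = sub[base + u];
                    const double x = rng.unif();
                    if (x < T.t0[s]) continue;
                    if (x < T.t1[s])      sub[base + u] = s ^ 4;
                    else if (x < T.t2[s]) sub[base + u] = s ^ 2;
                    else                  sub[base + u] = s ^ 1;
                }
            }
            const int newOpen = countOpen();
            if (newOpen > nOpen) c = std::max(c, c0 + c1 * newOpen);
            nOpen = newOpen;
            const double cstat = c0 + c1 * nOpen;
            c = cstat + (c - cstat) * ek;
            ++step;
            if (step >= burnSteps && (step - burnSteps) % recEvery == 0)
                recordAt(step);
            if (nOpen == 0 && std::fabs(c - c0) < freeze_tol) enterFrozen();
            if (++sinceInterrupt >= 2000000) {
                sinceInterrupt = 0;
                Rcpp::checkUserInterrupt();
            }
        }
    }

    return List::create(_["time"] = recTime, _["n_open"] = recOpen,
                        _["c"] = recC, _["n111"] = rec111,
                        _["n011"] = rec011, _["n_avail"] = recAvail);
}
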