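#include <Rcpp.h>
using namespace Rcpp;

// State space: 1 expired, 2 spawn, 3 interior, 4 sound-away, 5 hinchinbrook,
// 6 strait, 7 passages, 8 gulf. Observation codes 1..6 with deterministic
// emission; code x is compatible with the states flagged below.
static const int FEAS[7][8] = {
    {0, 0, 0, 0, 0, 0, 0, 0}, // code 0: inactive, never queried
    {1, 0, 0, 1, 0, 0, 0, 1}, // 1 = no detection  <-> {1,4,8}
    {0, 1, 0, 0, 0, 0, 0, 0}, // 2 = spawn         <-> {2}
    {0, 0, 1, 0, 0, 0, 0, 0}, // 3 = interior      <-> {3}
    {0, 0, 0, 0, 1, 0, 0, 0}, // 4 = hinchinbrook  <-> {5}
    {0, 0, 0, 0, 0, 1, 0, 0}, // 5 = strait        <-> {6}
    {0, 0, 0, 0, 0, 0, 1, 0}  // 6 = passages      <-> {7}
};

// trans is an (8, 8, n_class, n_season) array, rows = origin state.
// Transition from occasion j to j+1 uses the season of the origin occasion j.
static inline const double *trans_block(const double *trans, int y, int k,
                                        int nclass) {
    return trans + 64 * (y + (std::ptrdiff_t)nclass * k);
}

// Marginal log-likelihood per fish by the scaled forward recursion.
// X: n x f observation codes (0 outside the active window); rel/lastocc are
// 1-based occasion indices; cls in 1..n_class; season in 1..n_season per
// occasion. Returns -Inf for a fish whose sequence has probability zero.
// [[Rcpp::export]]
NumericVector cpp_forward_loglik(IntegerMatrix X, IntegerVector rel,
                                 IntegerVector lastocc, IntegerVector cls,
                                 IntegerVector season, NumericVector trans,
                                 int nclass, int nseason) {
    int n = X.nrow();
    NumericVector ll(n);
    double p[8], q[8];
    const double *tr = trans.begin();
    for (int i = 0; i < n; ++i) {
        std::fill(p, p + 8, 0.0);
        p[1] = 1.0; // released on the spawning grounds: state 2
        double lli = 0.0;
        int y = cls[i] - 1;
        for (int j = rel[i] + 1; j <= lastocc[i]; ++j) {
            int k = season[j - 2] - 1; // season of origin occasion j-1
            const double *T = trans_block(tr, y, k, nclass);
            for (int s = 0; s < 8; ++s) q[s] = 0.0;
            for (int r = 0; r < 8; ++r) {
                double pr = p[r];
                if (pr == 0.0) continue;
                const double *Tr = T + r;
                for (int s = 0; s < 8; ++s) q[s] += pr * Tr[8 * s];
            }
            int x = X(i, j - 1);
            double tot = 0.0;
            for (int s = 0; s < 8; ++s) {
                double v = q[s] * FEAS[x][s];
                p[s] = v;
                tot += v;
            }
            if (tot <= 0.0) {
                lli = R_NegInf;
                break;
            }
            lli += std::log(tot);
            for (int s = 0; s < 8; ++s) p[s] /= tot;
        }
        ll[i] = lli;
    }
    return ll;
}

// One forward-filtering backward-sampling draw of every latent path.
// Returns an n x f integer matrix; 0 outside [rel, lastocc], states 1..8
// inside (the release occasion itself is fixed at state 2). Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_ffbs(IntegerMatrix X, IntegerVector rel,
                       IntegerVector lastocc, IntegerVector cls,
                       IntegerVector season, NumericVector trans, int nclass,
                       int nseason) {
    int n = X.nrow(), f = X.ncol();
    IntegerMatrix path(n, f);
    const double *tr = trans.begin();
    std::vector<double> filt(8 * (size_t)(f + 1));
    double q[8], w[8];
    for (int i = 0; i < n; ++i) {
        int y = cls[i] - 1;
        int L = lastocc[i] - rel[i]; // number of post-release occasions
        if (rel[i] >= 1 && rel[i] <= f) path(i, rel[i] - 1) = 2;
        if (L <= 0) continue;
        // forward pass: filt[t] = P(Z_{rel+t} | x up to rel+t)
        std::fill(filt.begin(), filt.begin() + 8, 0.0);
        filt[1] = 1.0;
        for (int t = 1; t <= L; ++t) {
            int j = rel[i] + t;
            int k = season[j - 2] - 1;
            const double *T = trans_block(tr, y, k, nclass);
            const double *prev = &filt[8 * (size_t)(t - 1)];
            for (int s = 0; s < 8; ++s) q[s] = 0.0;
            for (int r = 0; r < 8; ++r) {
                double pr = prev[r];
                if (pr == 0.0) continue;
                const double *Tr = T + r;
                for (int s = 0; s < 8; ++s) q[s] += pr * Tr[8 * s];
            }
            int x = X(i, j - 1);
            double tot = 0.0;
            double *cur = &filt[8 * (size_t)t];
            for (int s = 0; s < 8; ++s) {
                double v = q[s] * FEAS[x][s];
                cur[s] = v;
                tot += v;
            }
            if (tot <= 0.0)
                stop("observation sequence of fish %d has probability zero",
                     i + 1);
            for (int s = 0; s < 8; ++s) cur[s] /= tot;
        }
        // backward sampling
        int znext = 0;
        {
            const double *cur = &filt[8 * (size_t)L];
            double u = unif_rand();
            double acc = 0.0;
            for (int s = 0; s < 8; ++s) {
                acc += cur[s];
                if (u <= acc || s == 7) {
                    znext = s;
                    break;
                }
            }
            path(i, rel[i] + L - 1) = znext + 1;
        }
        for (int t = L - 1; t >= 1; --t) {
            int j = rel[i] + t; // transition j -> j+1 uses season of j
            int k = season[j - 1] - 1;
            const double *T = trans_block(tr, y, k, nclass);
            const double *cur = &filt[8 * (size_t)t];
            double tot = 0.0;
            for (int r = 0; r < 8; ++r) {
                w[r] = cur[r] * T[r + 8 * znext];
                tot += w[r];
            }
            double u = unif_rand() * tot;
            double acc = 0.0;
            int z = 7;
            for (int r = 0; r < 8; ++r) {
                acc += w[r];
                if (u <= acc) {
                    z = r;
                    break;
                }
            }
            path(i, j - 1) = z + 1;
            znext = z;
        }
    }
    return path;
}

// Complete-data transition counts n^{rs}_{yk} from latent paths.
// Returns an (8, 8, n_class, n_season) integer array.
// [[Rcpp::export]]
IntegerVector cpp_count_transitions(IntegerMatrix path, IntegerVector rel,
                                    IntegerVector lastocc, IntegerVector cls,
                                    IntegerVector season, int nclass,
                                    int nseason) {
    int n = path.nrow();
    IntegerVector cnt(64 * nclass * nseason);
    for (int i = 0; i < n; ++i) {
        int y = cls[i] - 1;
        for (int j = rel[i]; j < lastocc[i]; ++j) {
            int r = path(i, j - 1) - 1;
            int s = path(i, j) - 1;
            int k = season[j - 1] - 1; // season of origin occasion j
            cnt[r + 8 * s + 64 * (y + (std::ptrdiff_t)nclass * k)] += 1;
        }
    }
    cnt.attr("dim") =
        IntegerVector::create(8, 8, nclass, nseason);
    return cnt;
}
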