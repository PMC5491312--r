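#include <Rcpp.h>
using namespace Rcpp;

// Sequences are passed as 1-based integer state matrices (R convention) and
// handled 0-based internally.  Fields h are L x q; couplings J are a dense
// symmetric (L*q) x (L*q) matrix with zero same-position blocks; lam has
// L/2 + 1 entries indexed by the half-vs-half match count.

static inline int match_count(const std::vector<int>& s, int L) {
    int half = L / 2, m = 0;
    for (int i = 0; i < half; ++i)
        if (s[i] == s[i + half]) ++m;
    return m;
}

static double energy_one(const std::vector<int>& s, int L, int q,
                         const NumericMatrix& h, const NumericMatrix& J,
                         const NumericVector& lam, bool use_lambda) {
    double e = 0.0;
    for (int i = 0; i < L; ++i)
        e -= h(i, s[i]);
    for (int i = 0; i < L; ++i) {
        const int ri = i * q + s[i];
        for (int j = i + 1; j < L; ++j)
            e += J(ri, j * q + s[j]);
    }
    if (use_lambda)
        e -= lam[match_count(s, L)];
    return e;
}

// [[Rcpp::export]]
NumericVector cpp_energies(IntegerMatrix S, NumericMatrix h, NumericMatrix J,
                           NumericVector lam, bool use_lambda) {
    const int n = S.nrow(), L = S.ncol(), q = h.ncol();
    NumericVector out(n);
    std::vector<int> s(L);
    for (int r = 0; r < n; ++r) {
        for (int i = 0; i < L; ++i)
            s[i] = S(r, i) - 1;
        out[r] = energy_one(s, L, q, h, J, lam, use_lambda);
    }
    return out;
}

// Metropolis chain over sequences: single-site proposals uniform over the
// position and over the q-1 alternative states; acceptance min(1, e^{-dE}).
// Records n sequences, one every `thin` steps, after `burn` discarded steps.
// [[Rcpp::export]]
IntegerMatrix cpp_metropolis(NumericMatrix h, NumericMatrix J, NumericVector lam,
                             int n, int thin, int burn, IntegerVector init,
                             bool use_lambda) {
    const int L = h.nrow(), q = h.ncol();
    const int half = L / 2;
    std::vector<int> s(L);
    for (int i = 0; i < L; ++i)
        s[i] = init[i] - 1;
    int m = (L % 2 == 0) ? match_count(s, L) : 0;

    IntegerMatrix out(n, L);
    const long total = (long)burn + (long)n * (long)thin;
    long recorded = 0;
    for (long step = 1; step <= total; ++step) {
        const int pos = (int)(unif_rand() * L);
        const int a = s[pos];
        int b = (int)(unif_rand() * (q - 1));
        if (b >= a) ++b;

        double dE = -(h(pos, b) - h(pos, a));
        const int rb = pos * q + b, ra = pos * q + a;
        for (int j = 0; j < L; ++j) {
            if (j == pos) continue;
            const int cj = j * q + s[j];
            dE += J(rb, cj) - J(ra, cj);
        }
        int m_new = m;
        if (use_lambda) {
            const int p = (pos < half) ? pos + half : pos - half;
            m_new = m + (s[p] == b) - (s[p] == a);
            dE -= lam[m_new] - lam[m];
        }
        if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
            s[pos] = b;
            m = m_new;
        }
        if (step > burn && (step - burn) % thin == 0) {
            for (int i = 0; i < L; ++i)
                out(recorded, i) = s[i] + 1;
            ++recorded;
            if (recorded == n) break;
        }
    }
    return out;
}

// Single-site and pairwise state frequencies.  f2 is returned as a dense
// symmetric (L*q) x (L*q) matrix with same-position blocks left at zero.
// [[Rcpp::export]]
List cpp_pair_frequencies(IntegerMatrix S, int q) {
    const int n = S.nrow(), L = S.ncol();
    NumericMatrix f1(L, q), f2(L * q, L * q);
    for (int r = 0; r < n; ++r) {
        for (int i = 0; i < L; ++i) {
            const int ri = i * q + (S(r, i) - 1);
            f1(i, S(r, i) - 1) += 1.0;
            for (int j = i + 1; j < L; ++j) {
                const int cj = j * q + (S(r, j) - 1);
                f2(ri, cj) += 1.0;
            }
        }
    }
    const double inv = 1.0 / n;
    for (int i = 0; i < L; ++i)
        for (int a = 0; a < q; ++a)
            f1(i, a) *= inv;
    for (int i = 0; i < L * q; ++i)
        for (int j = i + 1; j < L * q; ++j) {
            f2(i, j) *= inv;
            f2(j, i) = f2(i, j);
        }
    return List::create(_["f1"] = f1, _["f2"] = f2);
}
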