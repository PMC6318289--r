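#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Global alignment with affine gaps (Gotoh three-state DP).
// Gap cost model: first gap base costs gap_open, each further base of the
// same gap costs gap_extend (so a length-L gap scores open + (L-1)*extend).
// States: M = ref[i] aligned to qry[j]; X = gap in query (ref base consumed,
// a deletion relative to ref); Y = gap in ref (query base consumed, an
// insertion relative to ref).
// Traceback ties are broken deterministically: diagonal (M) over vertical
// (X, deletion) over horizontal (Y, insertion), both for the final state and
// for each state's predecessor.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// predecessor codes: 0 = M, 1 = X, 2 = Y
static inline int argmax3(double m, double x, double y) {
    if (m >= x && m >= y) return 0;
    if (x >= y) return 1;
    return 2;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string qry,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
    const int n = (int) ref.size();
    const int m = (int) qry.size();
    if (n == 0 || m == 0)
        stop("both sequences must be non-empty");

    const size_t W = (size_t) m + 1;
    std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
                        Y((n + 1) * W, NEG_INF);
    // traceback pointers: predecessor state for each cell/state
    std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
                             pY((n + 1) * W, -1);

    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
        X[i * W] = gap_open + (i - 1) * gap_extend;
        pX[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
        Y[j] = gap_open + (j - 1) * gap_extend;
        pY[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n; ++i) {
        const char rc = ref[i - 1];
        for (int j = 1; j <= m; ++j) {
            const size_t cur = i * W + j;
            const size_t diag = (i - 1) * W + (j - 1);
            const size_t up   = (i - 1) * W + j;
            const size_t left = i * W + (j - 1);

            const double s = (rc == qry[j - 1]) ? match : mismatch;
            int a = argmax3(M[diag], X[diag], Y[diag]);
            double best = (a == 0 ? M[diag] : (a == 1 ? X[diag] : Y[diag]));
            if (best > NEG_INF) { M[cur] = best + s; pM[cur] = (signed char) a; }

            // X: consume ref[i-1] against a gap
            double xm = (M[up] > NEG_INF) ? M[up] + gap_open : NEG_INF;
            double xx = (X[up] > NEG_INF) ? X[up] + gap_extend : NEG_INF;
            double xy = (Y[up] > NEG_INF) ? Y[up] + gap_open : NEG_INF;
            a = argmax3(xm, xx, xy);
            best = (a == 0 ? xm : (a == 1 ? xx : xy));
            if (best > NEG_INF) { X[cur] = best; pX[cur] = (signed char) a; }

            // Y: consume qry[j-1] against a gap
            double ym = (M[left] > NEG_INF) ? M[left] + gap_open : NEG_INF;
            double yx = (X[left] > NEG_INF) ? X[left] + gap_open : NEG_INF;
            double yy = (Y[left] > NEG_INF) ? Y[left] + gap_extend : NEG_INF;
            a = argmax3(ym, yx, yy);
            best = (a == 0 ? ym : (a == 1 ? yx : yy));
            if (best > NEG_INF) { Y[cur] = best; pY[cur] = (signed char) a; }
        }
    }

    const size_t end = (size_t) n * W + m;
    int state = argmax3(M[end], X[end], Y[end]);
    const double score = (state == 0 ? M[end] : (state == 1 ? X[end] : Y[end]));

    std::string ra, qa;
    ra.reserve(n + m);
    qa.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const size_t cur = (size_t) i * W + j;
        if (state == 0) {
            ra.push_back(ref[i - 1]);
            qa.push_back(qry[j - 1]);
            state = pM[cur];
            --i; --j;
        } else if (state == 1) {
            ra.push_back(ref[i - 1]);
            qa.push_back('-');
            state = pX[cur];
            --i;
        } else {
            ra.push_back('-');
            qa.push_back(qry[j - 1]);
            state = pY[cur];
            --j;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(qa.begin(), qa.end());

    return List::create(_["ref_aln"] = ra, _["qry_aln"] = qa,
                        _["score"] = score);
}
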