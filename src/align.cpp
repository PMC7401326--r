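#include <Rcpp.h>
#include <vector>
#include <string>
#include <set>
#include <utility>
using namespace Rcpp;

static const double NEG = -1e18;

static inline double gapcost(int k, double go, double ge) {
    return k > 0 ? go + k * ge : 0.0;
}

// Pairwise global alignment with affine gaps (a gap of length k costs
// gap_open + k * gap_extend) and optionally free terminal gap runs.
// The four free_* flags refer to the unaligned terminal run of the query
// (q) or the window (w) at the 5' (start) or 3' (end) terminus.
//
// Semantics: an alignment is a monotone matching of positions. Score =
// sum of match/mismatch over matched columns + affine cost of each
// maximal unmatched run between consecutive matched pairs + affine cost
// of terminal runs unless the corresponding free flag is set.
//
// Returns the optimal score and an operation string over {M, Q, W}:
// M = aligned column, Q = query base against a gap, W = window base
// against a gap. Ties are broken deterministically, preferring an
// aligned column over a gap and a gap in the query row over a gap in
// the window row.
// [[Rcpp::export]]
List cpp_affine_align(std::string q, std::string w,
                      double match, double mismatch,
                      double gap_open, double gap_extend,
                      bool free_q_start, bool free_q_end,
                      bool free_w_start, bool free_w_end) {
    const int n = (int) q.size(), m = (int) w.size();

    // empty-matching score (no aligned column at all)
    double empty_q = (free_q_start || free_q_end) ? 0.0 : gapcost(n, gap_open, gap_extend);
    double empty_w = (free_w_start || free_w_end) ? 0.0 : gapcost(m, gap_open, gap_extend);
    double empty_score = empty_q + empty_w;

    if (n == 0 || m == 0) {
        std::string ops(n, 'Q');
        ops.append(m, 'W');
        return List::create(_["score"] = empty_score, _["ops"] = ops);
    }

    std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
        Y((n + 1) * (m + 1), NEG);
    std::vector<char> pM((n + 1) * (m + 1), 0), pX((n + 1) * (m + 1), 0),
        pY((n + 1) * (m + 1), 0);
#define IDX(i, j) ((i) * (m + 1) + (j))

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (q[i - 1] == w[j - 1]) ? match : mismatch;
            // start option: everything before (i,j) is a terminal run
            double st = (free_q_start ? 0.0 : gapcost(i - 1, gap_open, gap_extend)) +
                        (free_w_start ? 0.0 : gapcost(j - 1, gap_open, gap_extend));
            double best = M[IDX(i - 1, j - 1)];
            char ptr = 'M';
            if (Y[IDX(i - 1, j - 1)] > best) { best = Y[IDX(i - 1, j - 1)]; ptr = 'Y'; }
            if (X[IDX(i - 1, j - 1)] > best) { best = X[IDX(i - 1, j - 1)]; ptr = 'X'; }
            if (st > best) { best = st; ptr = 'S'; }
            M[IDX(i, j)] = s + best;
            pM[IDX(i, j)] = ptr;

            // X: gap run in the window row (consumes query), internal only
            double xb = M[IDX(i - 1, j)] + gap_open + gap_extend;
            char xp = 'M';
            if (X[IDX(i - 1, j)] + gap_extend > xb) { xb = X[IDX(i - 1, j)] + gap_extend; xp = 'X'; }
            if (Y[IDX(i - 1, j)] + gap_open + gap_extend > xb) { xb = Y[IDX(i - 1, j)] + gap_open + gap_extend; xp = 'Y'; }
            X[IDX(i, j)] = xb;
            pX[IDX(i, j)] = xp;

            // Y: gap run in the query row (consumes window), internal only
            double yb = M[IDX(i, j - 1)] + gap_open + gap_extend;
            char yp = 'M';
            if (Y[IDX(i, j - 1)] + gap_extend > yb) { yb = Y[IDX(i, j - 1)] + gap_extend; yp = 'Y'; }
            if (X[IDX(i, j - 1)] + gap_open + gap_extend > yb) { yb = X[IDX(i, j - 1)] + gap_open + gap_extend; yp = 'X'; }
            Y[IDX(i, j)] = yb;
            pY[IDX(i, j)] = yp;
        }
    }

    // end: close at the last aligned column (i,j), rest is terminal runs
    double best_final = empty_score;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double en = (free_q_end ? 0.0 : gapcost(n - i, gap_open, gap_extend)) +
                        (free_w_end ? 0.0 : gapcost(m - j, gap_open, gap_extend));
            double v = M[IDX(i, j)] + en;
            if (v > best_final) { best_final = v; bi = i; bj = j; }
        }
    }

    std::string rev;
    if (bi == 0) { // empty matching won
        std::string ops(n, 'Q');
        ops.append(m, 'W');
        return List::create(_["score"] = best_final, _["ops"] = ops);
    }
    // 3' terminal runs: window run first, then query run (post core)
    rev.append(n - bi, 'Q');
    rev.append(m - bj, 'W');
    int i = bi, j = bj;
    char state = 'M';
    while (true) {
        if (state == 'M') {
            rev.push_back('M');
            char ptr = pM[IDX(i, j)];
            --i; --j;
            if (ptr == 'S') {
                rev.append(j, 'W');
                rev.append(i, 'Q');
                break;
            }
            state = ptr;
        } else if (state == 'X') {
            rev.push_back('Q');
            char ptr = pX[IDX(i, j)];
            --i;
            state = ptr;
        } else { // 'Y'
            rev.push_back('W');
            char ptr = pY[IDX(i, j)];
            --j;
            state = ptr;
        }
    }
    std::string ops(rev.rbegin(), rev.rend());
    return List::create(_["score"] = best_final, _["ops"] = ops);
#undef IDX
}

static inline bool rna_can_pair(char a, char b) {
    return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
           (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
           (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pair folding (Watson-Crick + GU) with a minimum hairpin
// loop and hard constraints: positions forced unpaired, pairs forced,
// pairs banned. Sequence must be canonical upper-case RNA (T already
// mapped to U). All index vectors are 1-based. Returns the pair list,
// the pair count, and a feasibility flag (FALSE when the constraints
// are contradictory). Traceback is deterministic: the 3'-most base of a
// span pairs with its 5'-most admissible partner; pairing is preferred
// over leaving the base unpaired when both are optimal.
// [[Rcpp::export]]
List cpp_fold(std::string seq, int min_loop,
              LogicalVector unpaired,
              IntegerVector forced_i, IntegerVector forced_j,
              IntegerVector banned_i, IntegerVector banned_j) {
    const int n = (int) seq.size();
    const int NEGI = -1000000000;

    std::vector<int> partner(n + 1, 0); // forced partner, 0 = none
    for (int k = 0; k < forced_i.size(); ++k) {
        int a = forced_i[k], b = forced_j[k];
        if (a > b) std::swap(a, b);
        if (a < 1 || b > n || a == b) return List::create(_["feasible"] = false);
        if ((partner[a] != 0 && partner[a] != b) || (partner[b] != 0 && partner[b] != a))
            return List::create(_["feasible"] = false);
        partner[a] = b;
        partner[b] = a;
    }
    std::set<std::pair<int, int> > banned;
    for (int k = 0; k < banned_i.size(); ++k) {
        int a = banned_i[k], b = banned_j[k];
        if (a > b) std::swap(a, b);
        banned.insert(std::make_pair(a, b));
    }

    std::vector<bool> must_pair(n + 1, false), no_pair(n + 1, false);
    for (int i = 1; i <= n; ++i) {
        no_pair[i] = (i <= unpaired.size()) && unpaired[i - 1];
        must_pair[i] = partner[i] != 0;
        if (must_pair[i] && no_pair[i]) return List::create(_["feasible"] = false);
    }

    // allowed(i, j): may i pair with j
    std::vector<char> allow(n * n, 0);
#define ALW(i, j) allow[((i) - 1) * n + ((j) - 1)]
    for (int i = 1; i <= n; ++i) {
        for (int j = i + 1; j <= n; ++j) {
            if (j - i <= min_loop) continue;
            if (no_pair[i] || no_pair[j]) continue;
            if (must_pair[i] && partner[i] != j) continue;
            if (must_pair[j] && partner[j] != i) continue;
            if (!rna_can_pair(seq[i - 1], seq[j - 1])) continue;
            if (banned.count(std::make_pair(i, j))) continue;
            ALW(i, j) = 1;
        }
    }

    // N[i][j] over 1..n, spans of increasing length
    std::vector<int> N((n + 2) * (n + 2), 0);
#define NN(i, j) N[(i) * (n + 2) + (j)]
    for (int i = 1; i <= n; ++i) {
        NN(i, i) = must_pair[i] ? NEGI : 0;
        if (i > 1) NN(i, i - 1) = 0; // empty span
    }
    NN(n + 1, n) = 0;
    for (int len = 2; len <= n; ++len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
            int j = i + len - 1;
            int best = NEGI;
            if (!must_pair[j]) best = NN(i, j - 1);
            for (int k = i; k <= j - min_loop - 1; ++k) {
                if (!ALW(k, j)) continue;
                int left = (k > i) ? NN(i, k - 1) : 0;
                int inner = NN(k + 1, j - 1);
                if (left <= NEGI / 2 || inner <= NEGI / 2) continue;
                int v = left + 1 + inner;
                if (v > best) best = v;
            }
            NN(i, j) = best;
        }
    }

    if (n >= 1 && NN(1, n) <= NEGI / 2)
        return List::create(_["feasible"] = false);

    // traceback
    std::vector<int> pi, pj;
    std::vector<std::pair<int, int> > stack;
    if (n >= 1) stack.push_back(std::make_pair(1, n));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        int target = NN(i, j);
        if (target <= NEGI / 2) continue;
        // prefer pairing j with its 5'-most admissible partner
        bool done = false;
        for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
            if (!ALW(k, j)) continue;
            int left = (k > i) ? NN(i, k - 1) : 0;
            int inner = NN(k + 1, j - 1);
            if (left <= NEGI / 2 || inner <= NEGI / 2) continue;
            if (left + 1 + inner == target) {
                pi.push_back(k);
                pj.push_back(j);
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                stack.push_back(std::make_pair(k + 1, j - 1));
                done = true;
            }
        }
        if (!done) stack.push_back(std::make_pair(i, j - 1));
    }

    return List::create(_["feasible"] = true,
                        _["pair_i"] = wrap(pi),
                        _["pair_j"] = wrap(pj),
                        _["n_pairs"] = (int) pi.size());
}

// Maximum-weight nested structure over alignment columns. W is a
// symmetric matrix; only entries > 0 are admissible pairs. min_loop is
// applied on column indices. Ties prefer leaving the 3'-most column
// unpaired, then the 5'-most partner.
// [[Rcpp::export]]
List cpp_fold_weighted(NumericMatrix W, int min_loop) {
    const int n = W.nrow();
    std::vector<double> N((n + 2) * (n + 2), 0.0);
#define WN(i, j) N[(i) * (n + 2) + (j)]
    for (int len = 2; len <= n; ++len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
            int j = i + len - 1;
            double best = WN(i, j - 1);
            for (int k = i; k <= j - min_loop - 1; ++k) {
                double w = W(k - 1, j - 1);
                if (!(w > 0)) continue;
                double left = (k > i) ? WN(i, k - 1) : 0.0;
                double v = left + w + WN(k + 1, j - 1);
                if (v > best) best = v;
            }
            WN(i, j) = best;
        }
    }
    std::vector<int> pi, pj;
    std::vector<std::pair<int, int> > stack;
    if (n >= 1) stack.push_back(std::make_pair(1, n));
    const double EPS = 1e-9;
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        double target = WN(i, j);
        if (WN(i, j - 1) >= target - EPS) { // unpaired j attains optimum
            stack.push_back(std::make_pair(i, j - 1));
            continue;
        }
        for (int k = i; k <= j - min_loop - 1; ++k) {
            double w = W(k - 1, j - 1);
            if (!(w > 0)) continue;
            double left = (k > i) ? WN(i, k - 1) : 0.0;
            if (left + w + WN(k + 1, j - 1) >= target - EPS) {
                pi.push_back(k);
                pj.push_back(j);
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                stack.push_back(std::make_pair(k + 1, j - 1));
                break;
            }
        }
    }
    double total = (n >= 1) ? WN(1, n) : 0.0;
    return List::create(_["pair_i"] = wrap(pi), _["pair_j"] = wrap(pj),
                        _["score"] = total);
}
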