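#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Zhang-Shasha ordered labeled tree edit distance with unit costs
// (insert 1, delete 1, relabel 1 if labels differ else 0).
//
// Trees are given in postorder: labels[k] is the integer label of node
// k+1, lml[k] is the index (1-based, postorder) of the leftmost leaf of
// the subtree rooted at node k+1. The last node is the root.
// [[Rcpp::export]]
double cpp_tree_dist(IntegerVector labels1, IntegerVector lml1,
                     IntegerVector labels2, IntegerVector lml2) {
    const int n1 = labels1.size(), n2 = labels2.size();
    if (n1 == 0 || n2 == 0) return (double) (n1 + n2);

    // keyroots: for each distinct lml value, the highest postorder index
    std::vector<int> kr1, kr2;
    {
        std::vector<int> last(n1 + 1, 0);
        for (int k = 1; k <= n1; ++k) last[lml1[k - 1]] = k;
        for (int k = 1; k <= n1; ++k) if (last[lml1[k - 1]] == k) kr1.push_back(k);
        std::vector<int> last2(n2 + 1, 0);
        for (int k = 1; k <= n2; ++k) last2[lml2[k - 1]] = k;
        for (int k = 1; k <= n2; ++k) if (last2[lml2[k - 1]] == k) kr2.push_back(k);
    }

    std::vector<std::vector<double> > td(n1 + 1, std::vector<double>(n2 + 1, 0.0));
    std::vector<std::vector<double> > fd(n1 + 2, std::vector<double>(n2 + 2, 0.0));

    for (size_t a = 0; a < kr1.size(); ++a) {
        int i1 = kr1[a];
        int li1 = lml1[i1 - 1];
        for (size_t b = 0; b < kr2.size(); ++b) {
            int j1 = kr2[b];
            int lj1 = lml2[j1 - 1];

            fd[li1 - 1][lj1 - 1] = 0.0;
            for (int di = li1; di <= i1; ++di)
                fd[di][lj1 - 1] = fd[di - 1][lj1 - 1] + 1.0;
            for (int dj = lj1; dj <= j1; ++dj)
                fd[li1 - 1][dj] = fd[li1 - 1][dj - 1] + 1.0;

            for (int di = li1; di <= i1; ++di) {
                for (int dj = lj1; dj <= j1; ++dj) {
                    int ldi = lml1[di - 1], ldj = lml2[dj - 1];
                    double del = fd[di - 1][dj] + 1.0;
                    double ins = fd[di][dj - 1] + 1.0;
                    if (ldi == li1 && ldj == lj1) {
                        double rel = (labels1[di - 1] == labels2[dj - 1]) ? 0.0 : 1.0;
                        double sub = fd[di - 1][dj - 1] + rel;
                        double v = std::min(del, std::min(ins, sub));
                        fd[di][dj] = v;
                        td[di][dj] = v;
                    } else {
                        double sub = fd[ldi - 1][ldj - 1] + td[di][dj];
                        fd[di][dj] = std::min(del, std::min(ins, sub));
                    }
                }
            }
        }
    }
    return td[n1][n2];
}
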