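#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Undirected adjacency in CSR layout with support for removing one edge and
// restoring it (remove parks the neighbor at the end of the node's slot, so
// restore is just a length increment).  Slot capacities are the original
// degrees; only remove-then-restore of the same edge is supported.
struct Graph {
    int n;
    std::vector<int> off;  // n+1 slot offsets
    std::vector<int> len;  // current degree
    std::vector<int> nbr;  // neighbor storage

    Graph(int n_, const IntegerVector& u, const IntegerVector& v)
        : n(n_), off(n_ + 1, 0), len(n_, 0) {
        const int m = u.size();
        for (int e = 0; e < m; ++e) { ++off[u[e] + 1]; ++off[v[e] + 1]; }
        for (int i = 0; i < n; ++i) off[i + 1] += off[i];
        nbr.assign(off[n], 0);
        for (int e = 0; e < m; ++e) {
            nbr[off[u[e]] + len[u[e]]++] = v[e];
            nbr[off[v[e]] + len[v[e]]++] = u[e];
        }
    }
    inline int deg(int g) const { return len[g]; }
    void removeHalf(int a, int b) {
        const int s = off[a], l = len[a];
        for (int i = 0; i < l; ++i) {
            if (nbr[s + i] == b) {
                nbr[s + i] = nbr[s + l - 1];
                nbr[s + l - 1] = b;
                len[a] = l - 1;
                return;
            }
        }
    }
    void removeEdge(int a, int b) { removeHalf(a, b); removeHalf(b, a); }
    void restoreEdge(int a, int b) { ++len[a]; ++len[b]; }
};

// Pooled cross-validated average precision for one group, straightforward
// path: per fold, every gene's score is compared against each held-out
// positive.  Per fold: held-out members are scored by neighbor voting
// against the remaining (training) members -- score(g) = (# neighbors of g
// in training) / degree(g), with zero-degree genes falling back to the
// training prevalence |training| / n.  Candidates are all genes except
// training positives.  Ranks use (score desc, tie key asc); keys are
// distinct so ranks are tie-free.  Each held-out positive contributes the
// precision at its rank within its fold's ranking; AP is the mean
// contribution over all k positives.
//
// 'votes' and 'mark' are caller-provided zeroed workspaces of size n; they
// are returned zeroed.  If 'scores_acc' is non-null, per-gene voting scores
// are accumulated into it: non-members add score/F per fold, members add
// their holdout-fold score once.
static double group_ap_simple(const Graph& G, const std::vector<int>& members,
                              const std::vector<int>& foldid, int F,
                              const double* key, int n,
                              std::vector<int>& votes,
                              std::vector<char>& mark,
                              double* scores_acc) {
    const int k = (int)members.size();
    double apsum = 0.0;
    std::vector<int> hold, train;
    hold.reserve(k);
    train.reserve(k);
    std::vector<double> sp;
    std::vector<int> cnt;

    for (int f = 0; f < F; ++f) {
        hold.clear();
        train.clear();
        for (int i = 0; i < k; ++i) {
            if (foldid[i] == f) hold.push_back(members[i]);
            else train.push_back(members[i]);
        }
        if (hold.empty() || train.empty()) continue;

        for (int t : train) {
            mark[t] = 1;
            const int s = G.off[t], l = G.len[t];
            for (int i = 0; i < l; ++i) ++votes[G.nbr[s + i]];
        }
        for (int h : hold) mark[h] = 2;
        const double prev = (double)train.size() / (double)n;

        const int nh = (int)hold.size();
        sp.assign(nh, 0.0);
        cnt.assign(nh, 0);
        for (int j = 0; j < nh; ++j) {
            const int p = hold[j];
            sp[j] = G.deg(p) > 0 ? (double)votes[p] / (double)G.deg(p)
                                 : prev;
        }
        for (int q = 0; q < n; ++q) {
            if (mark[q] == 1) continue;  // training positives not candidates
            const double sq = G.deg(q) > 0
                ? (double)votes[q] / (double)G.deg(q) : prev;
            if (scores_acc) {
                if (mark[q] == 2) scores_acc[q] += sq;
                else scores_acc[q] += sq / (double)F;
            }
            const double kq = key[q];
            for (int j = 0; j < nh; ++j) {
                const int p = hold[j];
                if (q == p) continue;
                if (sq > sp[j] || (sq == sp[j] && kq < key[p])) ++cnt[j];
            }
        }
        for (int j = 0; j < nh; ++j) {
            int le = 0;
            for (int j2 = 0; j2 < nh; ++j2)
                if (cnt[j2] <= cnt[j]) ++le;
            apsum += (double)le / (double)(cnt[j] + 1);
        }

        for (int t : train) {
            mark[t] = 0;
            const int s = G.off[t], l = G.len[t];
            for (int i = 0; i < l; ++i) votes[G.nbr[s + i]] = 0;
        }
        for (int h : hold) mark[h] = 0;
    }
    return apsum / (double)k;
}

// Fast path for sparse networks, mathematically identical to
// group_ap_simple: candidate scores take only a handful of distinct values
// (0 for unvoted genes with connections, the training prevalence for
// zero-degree genes, and votes/degree for voted genes), so a positive's
// rank is counted by scanning only the voted genes plus O(1) block
// arithmetic on precomputed key-rank tables.  All score comparisons are the
// same double-precision predicates as the simple path.
struct FastEval {
    const Graph& G;
    int n;
    const double* key;
    std::vector<int> keyrank;  // # genes with key < key[g]
    std::vector<int> zdless;   // # zero-degree genes with key < key[g]
    int n0_total;              // # zero-degree genes
    std::vector<int> votes;
    std::vector<char> mark;
    std::vector<int> voted;    // scratch: genes with votes > 0 this fold

    FastEval(const Graph& G_, const double* key_)
        : G(G_), n(G_.n), key(key_), keyrank(G_.n), zdless(G_.n),
          n0_total(0), votes(G_.n, 0), mark(G_.n, 0) {
        std::vector<int> ord(n);
        for (int i = 0; i < n; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(),
                  [&](int a, int b) { return key[a] < key[b]; });
        int zc = 0;
        for (int i = 0; i < n; ++i) {
            const int g = ord[i];
            keyrank[g] = i;
            zdless[g] = zc;
            if (G.deg(g) == 0) ++zc;
        }
        n0_total = zc;
        voted.reserve(256);
    }

    double group_ap(const std::vector<int>& members,
                    const std::vector<int>& foldid, int F) {
        const int k = (int)members.size();
        double apsum = 0.0;
        std::vector<int> hold, train;
        hold.reserve(k);
        train.reserve(k);

        for (int f = 0; f < F; ++f) {
            hold.clear();
            train.clear();
            for (int i = 0; i < k; ++i) {
                if (foldid[i] == f) hold.push_back(members[i]);
                else train.push_back(members[i]);
            }
            if (hold.empty() || train.empty()) continue;

            voted.clear();
            int n0_train = 0;
            for (int t : train) {
                mark[t] = 1;
                if (G.deg(t) == 0) ++n0_train;
                const int s = G.off[t], l = G.len[t];
                for (int i = 0; i < l; ++i) {
                    const int q = G.nbr[s + i];
                    if (votes[q]++ == 0) voted.push_back(q);
                }
            }
            const double prev = (double)train.size() / (double)n;
            const int n0_cand = n0_total - n0_train;

            const int nh = (int)hold.size();
            std::vector<int> cnt(nh, 0);
            for (int j = 0; j < nh; ++j) {
                const int p = hold[j];
                const double kp = key[p];
                const double sp = G.deg(p) > 0
                    ? (double)votes[p] / (double)G.deg(p) : prev;
                int c = 0;
                // voted candidates (score > 0, degree > 0)
                for (int q : voted) {
                    if (mark[q] == 1 || q == p) continue;
                    const double sq = (double)votes[q] / (double)G.deg(q);
                    if (sq > sp || (sq == sp && key[q] < kp)) ++c;
                }
                // zero-degree candidates, all at the prevalence score
                if (sp < prev) {
                    c += n0_cand;
                } else if (sp == prev) {
                    int cz = zdless[p];
                    for (int t : train)
                        if (G.deg(t) == 0 && key[t] < kp) --cz;
                    c += cz;
                }
                // zero-score candidates (degree > 0, no votes)
                if (sp == 0.0) {
                    int cz = keyrank[p] - zdless[p];
                    for (int q : voted)
                        if (key[q] < kp) --cz;
                    for (int t : train)
                        if (G.deg(t) > 0 && votes[t] == 0 && key[t] < kp)
                            --cz;
                    c += cz;
                }
                cnt[j] = c;
            }
            for (int j = 0; j < nh; ++j) {
                int le = 0;
                for (int j2 = 0; j2 < nh; ++j2)
                    if (cnt[j2] <= cnt[j]) ++le;
                apsum += (double)le / (double)(cnt[j] + 1);
            }
            for (int t : train) mark[t] = 0;
            for (int q : voted) votes[q] = 0;
        }
        return apsum / (double)k;
    }
};

static void unpack_group(const List& groups, const List& folds, int g,
                         std::vector<int>& members,
                         std::vector<int>& foldid) {
    IntegerVector mem = groups[g];
    IntegerVector fid = folds[g];
    members.assign(mem.begin(), mem.end());
    foldid.assign(fid.begin(), fid.end());
}

// [[Rcpp::export(name = ".cpp_eval_groups")]]
List cpp_eval_groups(int n, IntegerVector u, IntegerVector v,
                     List groups, List folds, int n_folds,
                     NumericVector key, bool want_scores) {
    Graph G(n, u, v);
    const int ng = groups.size();
    NumericVector ap(ng);
    std::vector<int> members, foldid;
    if (want_scores) {
        // simple path: the full score vector is needed anyway
        NumericMatrix scores(n, ng);
        std::vector<int> votes(n, 0);
        std::vector<char> mark(n, 0);
        for (int g = 0; g < ng; ++g) {
            unpack_group(groups, folds, g, members, foldid);
            ap[g] = group_ap_simple(G, members, foldid, n_folds,
                                    key.begin(), n, votes, mark,
                                    &scores(0, g));
            if (g % 32 == 0) Rcpp::checkUserInterrupt();
        }
        return List::create(_["ap"] = ap, _["scores"] = scores);
    }
    FastEval ev(G, key.begin());
    for (int g = 0; g < ng; ++g) {
        unpack_group(groups, folds, g, members, foldid);
        ap[g] = ev.group_ap(members, foldid, n_folds);
        if (g % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["ap"] = ap);
}

// Simple-path evaluation of all groups, exposed for equivalence testing of
// the fast path.
// [[Rcpp::export(name = ".cpp_eval_groups_simple")]]
NumericVector cpp_eval_groups_simple(int n, IntegerVector u, IntegerVector v,
                                     List groups, List folds, int n_folds,
                                     NumericVector key) {
    Graph G(n, u, v);
    const int ng = groups.size();
    NumericVector ap(ng);
    std::vector<int> votes(n, 0);
    std::vector<char> mark(n, 0);
    std::vector<int> members, foldid;
    for (int g = 0; g < ng; ++g) {
        unpack_group(groups, folds, g, members, foldid);
        ap[g] = group_ap_simple(G, members, foldid, n_folds, key.begin(),
                                n, votes, mark, nullptr);
        if (g % 32 == 0) Rcpp::checkUserInterrupt();
    }
    return ap;
}

// Leave-one-edge-out scan.  For every scanned group and every edge, the AP
// of the network minus that edge is computed under the same folds and tie
// keys as the baseline.  A cell is provably unchanged (and skipped) when
// neither endpoint is a group member, neither endpoint has any neighbor in
// the group (so it never receives a vote for this group), and both
// endpoints keep degree >= 1 after removal: then no candidate's score, nor
// the candidate set, nor any tie key changes.  Recomputed cells whose AP
// differs from the baseline by more than 'tol' are returned as sparse
// triplets.
// [[Rcpp::export(name = ".cpp_edge_scan")]]
List cpp_edge_scan(int n, IntegerVector u, IntegerVector v,
                   List groups, List folds, int n_folds,
                   NumericVector key, LogicalVector scan_group,
                   double tol) {
    Graph G(n, u, v);
    const int ng = groups.size();
    const int m = u.size();
    NumericVector ap_full(ng);
    std::vector<int> votes(n, 0);
    std::vector<char> mark(n, 0), memb(n, 0);
    std::vector<int> members, foldid;

    std::vector<int> out_e, out_g;
    std::vector<double> out_ap;

    for (int g = 0; g < ng; ++g) {
        unpack_group(groups, folds, g, members, foldid);
        ap_full[g] = group_ap_simple(G, members, foldid, n_folds,
                                     key.begin(), n, votes, mark, nullptr);
    }
    for (int g = 0; g < ng; ++g) {
        if (!scan_group[g]) continue;
        unpack_group(groups, folds, g, members, foldid);
        for (int p : members) memb[p] = 1;
        for (int e = 0; e < m; ++e) {
            const int a = u[e], b = v[e];
            bool skip = !memb[a] && !memb[b] && G.deg(a) > 1 && G.deg(b) > 1;
            if (skip) {
                const int sa = G.off[a], la = G.len[a];
                for (int i = 0; i < la && skip; ++i)
                    if (memb[G.nbr[sa + i]]) skip = false;
                const int sb = G.off[b], lb = G.len[b];
                for (int i = 0; i < lb && skip; ++i)
                    if (memb[G.nbr[sb + i]]) skip = false;
            }
            if (!skip) {
                G.removeEdge(a, b);
                const double apr = group_ap_simple(G, members, foldid,
                                                   n_folds, key.begin(), n,
                                                   votes, mark, nullptr);
                G.restoreEdge(a, b);
                if (std::abs(apr - ap_full[g]) > tol) {
                    out_e.push_back(e + 1);
                    out_g.push_back(g + 1);
                    out_ap.push_back(apr);
                }
            }
            if (e % 256 == 0) Rcpp::checkUserInterrupt();
        }
        for (int p : members) memb[p] = 0;
    }
    return List::create(_["ap_full"] = ap_full,
                        _["edge"] = wrap(out_e),
                        _["group"] = wrap(out_g),
                        _["ap_removed"] = wrap(out_ap));
}
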