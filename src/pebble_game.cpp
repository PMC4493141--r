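#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// 6-DOF body-bar pebble game ((6,6)-sparsity matroid).
//
// Each body carries 6 pebbles (its free rigid-body degrees of freedom).
// A bar between bodies u and v is independent iff 7 pebbles can be gathered
// on {u, v}; accepting it consumes one pebble and orients the bar away from
// the endpoint that paid. Pebbles are recovered along reversed directed
// paths. Rigid clusters are found post hoc: a pair with at most 6 gatherable
// pebbles has zero relative DOF, and the blocked region of the failed search
// is mutually rigid with the pair.

struct PebbleGame {
    int n;
    std::vector<int> peb;
    std::vector< std::unordered_map<int, int> > out; // oriented bar counts
    std::vector<int> mark;
    std::vector<int> parent;
    int stamp;

    PebbleGame(int n_) : n(n_), peb(n_, 6), out(n_), mark(n_, -1),
                         parent(n_, -1), stamp(0) {}

    // Depth-first search from src for a vertex holding a free pebble.
    // Vertices excl1/excl2 are never traversed and never donate.
    // On success the pebble is moved to src and the path is reversed.
    bool find_pebble(int src, int excl1, int excl2) {
        ++stamp;
        mark[src] = stamp;
        parent[src] = -2;
        std::vector<int> stack;
        stack.push_back(src);
        while (!stack.empty()) {
            int x = stack.back();
            stack.pop_back();
            for (std::unordered_map<int, int>::iterator it = out[x].begin();
                 it != out[x].end(); ++it) {
                if (it->second <= 0) continue;
                int w = it->first;
                if (w == excl1 || w == excl2 || mark[w] == stamp) continue;
                mark[w] = stamp;
                parent[w] = x;
                if (peb[w] > 0) {
                    peb[w]--;
                    peb[src]++;
                    int cur = w;
                    while (parent[cur] != -2) {
                        int p = parent[cur];
                        // reverse one bar p -> cur
                        if (--out[p][cur] == 0) out[p].erase(cur);
                        out[cur][p]++;
                        cur = p;
                    }
                    return true;
                }
                stack.push_back(w);
            }
        }
        return false;
    }

    // Try to gather >= 7 pebbles on {u, v}. Leaves the pebble distribution
    // rearranged (matroid state unchanged).
    bool gather7(int u, int v) {
        while (peb[u] + peb[v] < 7) {
            bool moved = false;
            if (peb[u] < 6 && find_pebble(u, v, -1)) moved = true;
            else if (peb[v] < 6 && find_pebble(v, u, -1)) moved = true;
            if (!moved) return false;
        }
        return true;
    }

    // Insert one bar between u and v; returns true if independent.
    bool insert_bar(int u, int v) {
        if (!gather7(u, v)) return false;
        if (peb[u] > 0) {
            peb[u]--;
            out[u][v]++;
        } else {
            peb[v]--;
            out[v][u]++;
        }
        return true;
    }

    // Vertices reachable from u or v along oriented bars (inclusive).
    std::vector<int> reach(int u, int v) {
        ++stamp;
        std::vector<int> stack, res;
        mark[u] = stamp; stack.push_back(u); res.push_back(u);
        if (mark[v] != stamp) { mark[v] = stamp; stack.push_back(v); res.push_back(v); }
        while (!stack.empty()) {
            int x = stack.back();
            stack.pop_back();
            for (std::unordered_map<int, int>::iterator it = out[x].begin();
                 it != out[x].end(); ++it) {
                if (it->second <= 0) continue;
                int w = it->first;
                if (mark[w] == stamp) continue;
                mark[w] = stamp;
                stack.push_back(w);
                res.push_back(w);
            }
        }
        return res;
    }
};

struct UnionFind {
    std::vector<int> up;
    UnionFind(int n) : up(n) { for (int i = 0; i < n; i++) up[i] = i; }
    int find(int x) { while (up[x] != x) { up[x] = up[up[x]]; x = up[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) up[a] = b; }
};

// Play the pebble game on a multigraph. Edges must be pre-sorted by the
// caller so that the processing order (and hence cluster labeling) is
// reproducible. Indices are 1-based on the R side.
// [[Rcpp::export]]
List pebble_game_cpp(int n_bodies, IntegerVector body_a, IntegerVector body_b,
                     IntegerVector bars, bool find_clusters) {
    int m = body_a.size();
    PebbleGame g(n_bodies);
    int independent = 0, redundant = 0;

    for (int e = 0; e < m; e++) {
        int u = body_a[e] - 1, v = body_b[e] - 1;
        if (u < 0 || u >= n_bodies || v < 0 || v >= n_bodies || u == v)
            stop("invalid edge endpoint");
        for (int k = 0; k < bars[e]; k++) {
            if (g.insert_bar(u, v)) independent++; else redundant++;
        }
    }

    IntegerVector cluster(n_bodies, NA_INTEGER);
    if (find_clusters) {
        UnionFind uf(n_bodies);
        for (int e = 0; e < m; e++) {
            int u = body_a[e] - 1, v = body_b[e] - 1;
            if (uf.find(u) == uf.find(v)) continue;
            if (!g.gather7(u, v)) {
                // pair is mutually rigid; the blocked region it spans too
                std::vector<int> region = g.reach(u, v);
                for (size_t i = 1; i < region.size(); i++)
                    uf.unite(region[0], region[i]);
            }
        }
        for (int i = 0; i < n_bodies; i++) cluster[i] = uf.find(i) + 1;
    }

    int free_total = 0;
    for (int i = 0; i < n_bodies; i++) free_total += g.peb[i];

    return List::create(_["independent"] = independent,
                        _["redundant"] = redundant,
                        _["free_pebbles"] = free_total,
                        _["cluster_raw"] = cluster);
}

// Play the game, then report for each queried pair whether it is mutually
// rigid (zero relative DOF). Used for cross-checks against the rigidity
// matrix oracle.
// [[Rcpp::export]]
LogicalVector pebble_pair_rigid_cpp(int n_bodies, IntegerVector body_a,
                                    IntegerVector body_b, IntegerVector bars,
                                    IntegerVector pair_a, IntegerVector pair_b) {
    int m = body_a.size();
    PebbleGame g(n_bodies);
    for (int e = 0; e < m; e++) {
        int u = body_a[e] - 1, v = body_b[e] - 1;
        if (u < 0 || u >= n_bodies || v < 0 || v >= n_bodies || u == v)
            stop("invalid edge endpoint");
        for (int k = 0; k < bars[e]; k++) g.insert_bar(u, v);
    }
    int q = pair_a.size();
    LogicalVector rigid(q);
    for (int i = 0; i < q; i++) {
        int u = pair_a[i] - 1, v = pair_b[i] - 1;
        if (u < 0 || u >= n_bodies || v < 0 || v >= n_bodies)
            stop("invalid pair endpoint");
        rigid[i] = (u == v) ? true : !g.gather7(u, v);
    }
    return rigid;
}
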