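#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int uf_find(std::vector<int>& parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static inline void uf_union(std::vector<int>& parent, std::vector<int>& rank_,
                            int a, int b) {
    a = uf_find(parent, a);
    b = uf_find(parent, b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
}

// One-sided TFCE on a non-negative statistic field over a vertex graph.
// stat: n_v values (>= 0); edges: n_e x 2 matrix of 0-based vertex indices;
// area: per-vertex surface area (mm^2). The cluster extent e_v(h) is the
// summed area of the connected supra-threshold (stat >= h) component
// containing v. Heights run h = dh, 2dh, ... <= max(stat).
// [[Rcpp::export]]
NumericVector tfce_onesided_cpp(NumericVector stat, IntegerMatrix edges,
                                NumericVector area, double E, double H,
                                double dh) {
    const int nv = stat.size();
    const int ne = edges.nrow();
    NumericVector out(nv);
    double hmax = 0.0;
    for (int i = 0; i < nv; ++i) if (stat[i] > hmax) hmax = stat[i];
    if (hmax <= 0.0 || dh <= 0.0) return out;

    std::vector<int> parent(nv), rank_(nv);
    std::vector<double> comp_area(nv);

    const int nh = (int)std::floor(hmax / dh * (1.0 + 1e-12) + 1e-9);
    for (int kh = 1; kh <= nh; ++kh) {
        const double h = kh * dh;
        for (int i = 0; i < nv; ++i) { parent[i] = i; rank_[i] = 0; }
        for (int e = 0; e < ne; ++e) {
            int a = edges(e, 0), b = edges(e, 1);
            if (stat[a] >= h && stat[b] >= h) uf_union(parent, rank_, a, b);
        }
        std::fill(comp_area.begin(), comp_area.end(), 0.0);
        for (int i = 0; i < nv; ++i)
            if (stat[i] >= h) comp_area[uf_find(parent, i)] += area[i];
        const double hH = std::pow(h, H) * dh;
        for (int i = 0; i < nv; ++i)
            if (stat[i] >= h)
                out[i] += std::pow(comp_area[uf_find(parent, i)], E) * hH;
    }
    return out;
}

// Connected components of a vertex graph (0-based labels).
// [[Rcpp::export]]
IntegerVector graph_components_cpp(int nv, IntegerMatrix edges) {
    std::vector<int> parent(nv), rank_(nv);
    for (int i = 0; i < nv; ++i) { parent[i] = i; rank_[i] = 0; }
    for (int e = 0; e < edges.nrow(); ++e)
        uf_union(parent, rank_, edges(e, 0), edges(e, 1));
    IntegerVector lab(nv);
    std::vector<int> remap(nv, -1);
    int next = 0;
    for (int i = 0; i < nv; ++i) {
        int r = uf_find(parent, i);
        if (remap[r] < 0) remap[r] = next++;
        lab[i] = remap[r];
    }
    return lab;
}
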