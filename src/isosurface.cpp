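#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Marching-tetrahedra isosurface extraction on a regular scalar grid.
// Each grid cell is split into six tetrahedra sharing the main diagonal;
// surface/edge intersections are linearly interpolated at `iso`. Vertices
// are returned in 0-based grid-index coordinates; triangle winding is set
// so normals point from the supra-iso (inside) side toward the outside.

struct MTState {
    std::unordered_map<uint64_t, int> edge_vertex;
    std::vector<double> vx, vy, vz;
    std::vector<int> f0, f1, f2;
};

static int edge_point(MTState& st, const double* gx, const double* gy,
                      const double* gz, const double* gv, int a, int b,
                      uint64_t ga, uint64_t gb, double iso, uint64_t ngrid) {
    if (ga > gb) { std::swap(ga, gb); std::swap(a, b); }
    uint64_t key = ga * ngrid + gb;
    auto it = st.edge_vertex.find(key);
    if (it != st.edge_vertex.end()) return it->second;
    double t = (iso - gv[a]) / (gv[b] - gv[a]);
    int idx = (int)st.vx.size();
    st.vx.push_back(gx[a] + t * (gx[b] - gx[a]));
    st.vy.push_back(gy[a] + t * (gy[b] - gy[a]));
    st.vz.push_back(gz[a] + t * (gz[b] - gz[a]));
    st.edge_vertex[key] = idx;
    return idx;
}

static void emit_tri(MTState& st, int p, int q, int r,
                     double dx, double dy, double dz) {
    // orient so the normal points along (dx,dy,dz): inside -> outside
    double ux = st.vx[q] - st.vx[p], uy = st.vy[q] - st.vy[p],
           uz = st.vz[q] - st.vz[p];
    double wx = st.vx[r] - st.vx[p], wy = st.vy[r] - st.vy[p],
           wz = st.vz[r] - st.vz[p];
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz,
           nz = ux * wy - uy * wx;
    if (nx * dx + ny * dy + nz * dz < 0) std::swap(q, r);
    st.f0.push_back(p); st.f1.push_back(q); st.f2.push_back(r);
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector vol, IntegerVector dim,
                             double iso) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const uint64_t ngrid = (uint64_t)nx * ny * nz;
    MTState st;

    // cube corner offsets
    static const int co[8][3] = {
        {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
    // six tetrahedra around diagonal corner0-corner6
    static const int tets[6][4] = {
        {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};

    double cx[8], cy[8], cz[8], cv[8];
    uint64_t cg[8];

    for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
    for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
            int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
            cx[c] = ii; cy[c] = jj; cz[c] = kk;
            cg[c] = (uint64_t)ii + (uint64_t)nx * (jj + (uint64_t)ny * kk);
            cv[c] = vol[cg[c]];
            if (cv[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
            int vi[4];
            bool in[4];
            int nin = 0;
            for (int c = 0; c < 4; ++c) {
                vi[c] = tets[t][c];
                in[c] = cv[vi[c]] > iso;
                if (in[c]) nin++;
            }
            if (nin == 0 || nin == 4) continue;

            // inside -> outside direction from tet vertex centroids
            double icx = 0, icy = 0, icz = 0, ocx = 0, ocy = 0, ocz = 0;
            for (int c = 0; c < 4; ++c) {
                if (in[c]) { icx += cx[vi[c]]; icy += cy[vi[c]]; icz += cz[vi[c]]; }
                else       { ocx += cx[vi[c]]; ocy += cy[vi[c]]; ocz += cz[vi[c]]; }
            }
            double dx = ocx / (4 - nin) - icx / nin;
            double dy = ocy / (4 - nin) - icy / nin;
            double dz = ocz / (4 - nin) - icz / nin;

            int ins[4], outs[4];
            int ni = 0, no = 0;
            for (int c = 0; c < 4; ++c) (in[c] ? ins[ni++] : outs[no++]) = c;

            if (nin == 1 || nin == 3) {
                int apex = (nin == 1) ? ins[0] : outs[0];
                int others[3], m = 0;
                for (int c = 0; c < 4; ++c) if (c != apex) others[m++] = c;
                int p = edge_point(st, cx, cy, cz, cv, vi[apex], vi[others[0]],
                                   cg[vi[apex]], cg[vi[others[0]]], iso, ngrid);
                int q = edge_point(st, cx, cy, cz, cv, vi[apex], vi[others[1]],
                                   cg[vi[apex]], cg[vi[others[1]]], iso, ngrid);
                int r = edge_point(st, cx, cy, cz, cv, vi[apex], vi[others[2]],
                                   cg[vi[apex]], cg[vi[others[2]]], iso, ngrid);
                emit_tri(st, p, q, r, dx, dy, dz);
            } else { // 2-2: quad e_AC e_AD e_BD e_BC
                int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
                int eAC = edge_point(st, cx, cy, cz, cv, vi[A], vi[C],
                                     cg[vi[A]], cg[vi[C]], iso, ngrid);
                int eAD = edge_point(st, cx, cy, cz, cv, vi[A], vi[D],
                                     cg[vi[A]], cg[vi[D]], iso, ngrid);
                int eBD = edge_point(st, cx, cy, cz, cv, vi[B], vi[D],
                                     cg[vi[B]], cg[vi[D]], iso, ngrid);
                int eBC = edge_point(st, cx, cy, cz, cv, vi[B], vi[C],
                                     cg[vi[B]], cg[vi[C]], iso, ngrid);
                emit_tri(st, eAC, eAD, eBD, dx, dy, dz);
                emit_tri(st, eAC, eBD, eBC, dx, dy, dz);
            }
        }
    }

    int nvert = (int)st.vx.size(), nface = (int)st.f0.size();
    NumericMatrix V(nvert, 3);
    IntegerMatrix F(nface, 3);
    for (int i = 0; i < nvert; ++i) {
        V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
    }
    for (int i = 0; i < nface; ++i) {
        F(i, 0) = st.f0[i]; F(i, 1) = st.f1[i]; F(i, 2) = st.f2[i];
    }
    return List::create(_["vertices"] = V, _["faces"] = F);
}
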