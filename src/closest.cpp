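#include <Rcpp.h>
#include <vector>
#include <cfloat>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5.
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
    double ab[3], ac[3], ap[3];
    for (int i = 0; i < 3; ++i) {
        ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
    }
    double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
    double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
    if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = d1 / (d1 - d3);
        for (int i=0;i<3;++i) out[i] = a[i] + v*ab[i];
        return;
    }
    double cp[3];
    for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
    double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
    double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
    if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
        double w = d2 / (d2 - d6);
        for (int i=0;i<3;++i) out[i] = a[i] + w*ac[i];
        return;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
        double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
        for (int i=0;i<3;++i) out[i] = b[i] + w*(c[i]-b[i]);
        return;
    }
    double denom = 1.0 / (va + vb + vc);
    double v = vb * denom, w = vc * denom;
    for (int i=0;i<3;++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
}

// For each query point: nearest mesh vertex (exhaustive), then exact
// closest point restricted to faces incident to that vertex's one-ring.
// Returns the closest surface point and the index (1-based) of the nearest
// vertex. Adequate for densely sampled organ surfaces.
// [[Rcpp::export]]
List closest_point_mesh_cpp(NumericMatrix query, NumericMatrix verts,
                            IntegerMatrix faces) {
    const int nq = query.nrow(), nv = verts.nrow(), nf = faces.nrow();

    // vertex -> incident faces (CSR)
    std::vector<int> cnt(nv, 0);
    for (int f = 0; f < nf; ++f)
        for (int c = 0; c < 3; ++c) cnt[faces(f, c)]++;
    std::vector<int> start(nv + 1, 0);
    for (int v = 0; v < nv; ++v) start[v + 1] = start[v] + cnt[v];
    std::vector<int> inc(start[nv]);
    std::vector<int> fill = start;
    for (int f = 0; f < nf; ++f)
        for (int c = 0; c < 3; ++c) inc[fill[faces(f, c)]++] = f;

    NumericMatrix out(nq, 3);
    IntegerVector nearest(nq);
    std::vector<char> seen(nf, 0);
    std::vector<int> cand;

    for (int q = 0; q < nq; ++q) {
        double p[3] = { query(q,0), query(q,1), query(q,2) };
        int best = 0;
        double bestd = DBL_MAX;
        for (int v = 0; v < nv; ++v) {
            double dx = verts(v,0)-p[0], dy = verts(v,1)-p[1],
                   dz = verts(v,2)-p[2];
            double d = dx*dx + dy*dy + dz*dz;
            if (d < bestd) { bestd = d; best = v; }
        }
        nearest[q] = best + 1;

        // faces incident to the nearest vertex's one-ring
        cand.clear();
        for (int s = start[best]; s < start[best + 1]; ++s) {
            int f = inc[s];
            for (int c = 0; c < 3; ++c) {
                int v2 = faces(f, c);
                for (int s2 = start[v2]; s2 < start[v2 + 1]; ++s2) {
                    int f2 = inc[s2];
                    if (!seen[f2]) { seen[f2] = 1; cand.push_back(f2); }
                }
            }
        }
        double bp[3] = { verts(best,0), verts(best,1), verts(best,2) };
        double bd = (bp[0]-p[0])*(bp[0]-p[0]) + (bp[1]-p[1])*(bp[1]-p[1]) +
                    (bp[2]-p[2])*(bp[2]-p[2]);
        for (size_t ci = 0; ci < cand.size(); ++ci) {
            int f = cand[ci];
            seen[f] = 0;
            double a[3] = { verts(faces(f,0),0), verts(faces(f,0),1),
                            verts(faces(f,0),2) };
            double b[3] = { verts(faces(f,1),0), verts(faces(f,1),1),
                            verts(faces(f,1),2) };
            double cc[3] = { verts(faces(f,2),0), verts(faces(f,2),1),
                             verts(faces(f,2),2) };
            double cand_pt[3];
            closest_on_tri(p, a, b, cc, cand_pt);
            double d = (cand_pt[0]-p[0])*(cand_pt[0]-p[0]) +
                       (cand_pt[1]-p[1])*(cand_pt[1]-p[1]) +
                       (cand_pt[2]-p[2])*(cand_pt[2]-p[2]);
            if (d < bd) { bd = d; bp[0]=cand_pt[0]; bp[1]=cand_pt[1];
                          bp[2]=cand_pt[2]; }
        }
        out(q,0) = bp[0]; out(q,1) = bp[1]; out(q,2) = bp[2];
    }
    return List::create(_["points"] = out, _["nearest_vertex"] = nearest);
}
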