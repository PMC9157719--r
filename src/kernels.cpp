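#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// The 13 unique 3-D directions at Chebyshev distance 1 (first nonzero
// component positive); the opposite orientations are implied.
static const int DIRS[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0},
    {1, 0, 1}, {1, 0, -1},
    {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int lin(int x, int y, int z, const int *d) {
    return x + d[0] * (y + d[1] * z);
}

static inline bool inb(int x, int y, int z, const int *d) {
    return x >= 0 && y >= 0 && z >= 0 && x < d[0] && y < d[1] && z < d[2];
}

// ---- union-find ----------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
}

// Label 26-connected components of equal gray level within a mask.
// Returns integer labels 1..n_components (0 outside the mask). Binary
// connected components are the special case of a constant level image.
// [[Rcpp::export]]
IntegerVector cpp_label_zones(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const int n = d[0] * d[1] * d[2];
    std::vector<int> parent(n);
    for (int i = 0; i < n; ++i) parent[i] = i;

    for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
            for (int x = 0; x < d[0]; ++x) {
                int i = lin(x, y, z, d);
                if (!mask[i]) continue;
                for (int k = 0; k < 13; ++k) {
                    int nx = x + DIRS[k][0], ny = y + DIRS[k][1],
                        nz = z + DIRS[k][2];
                    if (!inb(nx, ny, nz, d)) continue;
                    int j = lin(nx, ny, nz, d);
                    if (mask[j] && levels[j] == levels[i])
                        uf_union(parent, i, j);
                }
            }

    IntegerVector out(n, 0);
    std::vector<int> relabel(n, 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int r = uf_find(parent, i);
        if (relabel[r] == 0) relabel[r] = ++next;
        out[i] = relabel[r];
    }
    return out;
}

// Pooled symmetric co-occurrence counts over the 13 directions (both
// orientations), Chebyshev distance 1, restricted to the mask.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector levels, LogicalVector mask,
                              IntegerVector dim, int G) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    NumericMatrix counts(G, G);
    for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
            for (int x = 0; x < d[0]; ++x) {
                int i = lin(x, y, z, d);
                if (!mask[i]) continue;
                for (int k = 0; k < 13; ++k) {
                    int nx = x + DIRS[k][0], ny = y + DIRS[k][1],
                        nz = z + DIRS[k][2];
                    if (!inb(nx, ny, nz, d)) continue;
                    int j = lin(nx, ny, nz, d);
                    if (!mask[j]) continue;
                    int a = levels[i] - 1, b = levels[j] - 1;
                    counts(a, b) += 1.0;
                    counts(b, a) += 1.0;
                }
            }
    return counts;
}

// Pooled run-length counts over the 13 directions. Runs are maximal
// sequences of equal level along a direction, truncated at the mask
// boundary. Rows are gray levels, columns run lengths 1..max_run.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerVector levels, LogicalVector mask,
                               IntegerVector dim, int G) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    int maxExtent = std::max(d[0], std::max(d[1], d[2]));
    NumericMatrix counts(G, maxExtent);
    for (int k = 0; k < 13; ++k) {
        const int dx = DIRS[k][0], dy = DIRS[k][1], dz = DIRS[k][2];
        for (int z = 0; z < d[2]; ++z)
            for (int y = 0; y < d[1]; ++y)
                for (int x = 0; x < d[0]; ++x) {
                    int i = lin(x, y, z, d);
                    if (!mask[i]) continue;
                    int px = x - dx, py = y - dy, pz = z - dz;
                    if (inb(px, py, pz, d)) {
                        int p = lin(px, py, pz, d);
                        if (mask[p] && levels[p] == levels[i])
                            continue;  // not a run start
                    }
                    int len = 1;
                    int nx = x + dx, ny = y + dy, nz = z + dz;
                    while (inb(nx, ny, nz, d)) {
                        int j = lin(nx, ny, nz, d);
                        if (!mask[j] || levels[j] != levels[i]) break;
                        ++len;
                        nx += dx; ny += dy; nz += dz;
                    }
                    counts(levels[i] - 1, len - 1) += 1.0;
                }
    }
    return counts;
}

// Neighbourhood gray-tone difference accumulators: for each level i,
// n_i = number of masked voxels of level i that have at least one masked
// 26-neighbour, s_i = sum over those voxels of |i - mean(neighbour levels)|.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, LogicalVector mask, IntegerVector dim,
               int G) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    NumericVector ni(G), si(G);
    for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
            for (int x = 0; x < d[0]; ++x) {
                int i = lin(x, y, z, d);
                if (!mask[i]) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz2 = -1; dz2 <= 1; ++dz2)
                    for (int dy2 = -1; dy2 <= 1; ++dy2)
                        for (int dx2 = -1; dx2 <= 1; ++dx2) {
                            if (dx2 == 0 && dy2 == 0 && dz2 == 0) continue;
                            int nx = x + dx2, ny = y + dy2, nz = z + dz2;
                            if (!inb(nx, ny, nz, d)) continue;
                            int j = lin(nx, ny, nz, d);
                            if (!mask[j]) continue;
                            sum += levels[j];
                            ++cnt;
                        }
                if (cnt == 0) continue;  // neighbourless voxels are skipped
                int g = levels[i] - 1;
                ni[g] += 1.0;
                si[g] += std::fabs(levels[i] - sum / cnt);
            }
    return List::create(_["n"] = ni, _["s"] = si);
}

// ---- exact Euclidean distance transform ----------------------------------

// Felzenszwalb & Huttenlocher 1-D squared distance transform with
// anisotropic sample spacing.
static void dt1d(const double *f, double *out, int n, double w) {
    const double INF = std::numeric_limits<double>::infinity();
    const double w2 = w * w;

    // parabola sites with finite height only
    std::vector<int> sites;
    sites.reserve(n);
    for (int q = 0; q < n; ++q)
        if (f[q] < INF) sites.push_back(q);
    if (sites.empty()) {
        for (int q = 0; q < n; ++q) out[q] = INF;
        return;
    }

    std::vector<int> v(sites.size());
    std::vector<double> zb(sites.size() + 1);
    int k = 0;
    v[0] = sites[0];
    zb[0] = -INF;
    zb[1] = INF;
    for (size_t m = 1; m < sites.size(); ++m) {
        int q = sites[m];
        double s;
        while (true) {
            s = ((f[q] + w2 * (double)q * q) -
                 (f[v[k]] + w2 * (double)v[k] * v[k])) /
                (2.0 * w2 * (q - v[k]));
            if (s <= zb[k] && k > 0) { --k; continue; }
            break;
        }
        ++k;
        v[k] = q;
        zb[k] = s;
        zb[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (zb[k + 1] < q) ++k;
        double dq = w * (q - v[k]);
        out[q] = dq * dq + f[v[k]];
    }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// voxel centre of the mask, honouring anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const int n = d[0] * d[1] * d[2];
    const double INF = std::numeric_limits<double>::infinity();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

    std::vector<double> buf(std::max(d[0], std::max(d[1], d[2])));
    std::vector<double> res(buf.size());

    // along x
    for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y) {
            for (int x = 0; x < d[0]; ++x) buf[x] = out[lin(x, y, z, d)];
            dt1d(buf.data(), res.data(), d[0], spacing[0]);
            for (int x = 0; x < d[0]; ++x) out[lin(x, y, z, d)] = res[x];
        }
    // along y
    for (int z = 0; z < d[2]; ++z)
        for (int x = 0; x < d[0]; ++x) {
            for (int y = 0; y < d[1]; ++y) buf[y] = out[lin(x, y, z, d)];
            dt1d(buf.data(), res.data(), d[1], spacing[1]);
            for (int y = 0; y < d[1]; ++y) out[lin(x, y, z, d)] = res[y];
        }
    // along z
    for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
            for (int z = 0; z < d[2]; ++z) buf[z] = out[lin(x, y, z, d)];
            dt1d(buf.data(), res.data(), d[2], spacing[2]);
            for (int z = 0; z < d[2]; ++z) out[lin(x, y, z, d)] = res[z];
        }
    return out;
}

// ---- iso-surface area ----------------------------------------------------

struct P3 { double x, y, z; };

static inline P3 interp(const P3 &a, const P3 &b, double va, double vb,
                        double level) {
    double t = (level - va) / (vb - va);
    P3 p;
    p.x = a.x + t * (b.x - a.x);
    p.y = a.y + t * (b.y - a.y);
    p.z = a.z + t * (b.z - a.z);
    return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
    double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
    double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
    double cx = uy * vz - uz * vy;
    double cy = uz * vx - ux * vz;
    double cz = ux * vy - uy * vx;
    return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Six-tetrahedra decomposition of the unit cell around the main diagonal
// (corner 0 to corner 7); corners are bit-coded (x | y<<1 | z<<2).
static const int TETS[6][4] = {
    {0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
    {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}
};

// Area (mm^2) of the iso-surface of a scalar field at the given level,
// by marching tetrahedra with linear interpolation along cell edges.
// The field is treated as 0 outside its bounds.
// [[Rcpp::export]]
double cpp_isosurface_area(NumericVector field, IntegerVector dim,
                           NumericVector spacing, double level) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    double area = 0.0;
    P3 pos[8];
    double val[8];

    // iterate cells of the padded grid: corner coordinates in [-1, d]
    for (int z = -1; z < d[2]; ++z)
        for (int y = -1; y < d[1]; ++y)
            for (int x = -1; x < d[0]; ++x) {
                bool anyIn = false, allIn = true;
                for (int c = 0; c < 8; ++c) {
                    int cx = x + (c & 1), cy = y + ((c >> 1) & 1),
                        cz = z + ((c >> 2) & 1);
                    double v = 0.0;
                    if (inb(cx, cy, cz, d)) v = field[lin(cx, cy, cz, d)];
                    val[c] = v;
                    pos[c].x = cx * spacing[0];
                    pos[c].y = cy * spacing[1];
                    pos[c].z = cz * spacing[2];
                    if (v > level) anyIn = true; else allIn = false;
                }
                if (!anyIn || allIn) continue;
                for (int t = 0; t < 6; ++t) {
                    const int *T = TETS[t];
                    int ins[4], nin = 0;
                    for (int c = 0; c < 4; ++c)
                        if (val[T[c]] > level) ins[nin++] = c;
                    if (nin == 0 || nin == 4) continue;
                    if (nin == 1 || nin == 3) {
                        int a = -1;
                        if (nin == 1) a = ins[0];
                        else { // the single outside vertex
                            bool used[4] = {false, false, false, false};
                            for (int c = 0; c < nin; ++c) used[ins[c]] = true;
                            for (int c = 0; c < 4; ++c) if (!used[c]) a = c;
                        }
                        P3 e[3];
                        int m = 0;
                        for (int c = 0; c < 4; ++c) {
                            if (c == a) continue;
                            e[m++] = interp(pos[T[a]], pos[T[c]],
                                            val[T[a]], val[T[c]], level);
                        }
                        area += tri_area(e[0], e[1], e[2]);
                    } else { // 2 vs 2: quad split into two triangles
                        int a = ins[0], b = ins[1], co[2], m = 0;
                        for (int c = 0; c < 4; ++c)
                            if (c != a && c != b) co[m++] = c;
                        P3 eac = interp(pos[T[a]], pos[T[co[0]]],
                                        val[T[a]], val[T[co[0]]], level);
                        P3 ead = interp(pos[T[a]], pos[T[co[1]]],
                                        val[T[a]], val[T[co[1]]], level);
                        P3 ebc = interp(pos[T[b]], pos[T[co[0]]],
                                        val[T[b]], val[T[co[0]]], level);
                        P3 ebd = interp(pos[T[b]], pos[T[co[1]]],
                                        val[T[b]], val[T[co[1]]], level);
                        area += tri_area(eac, ead, ebd);
                        area += tri_area(eac, ebd, ebc);
                    }
                }
            }
    return area;
}
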