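#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Large-but-finite stand-in for +Inf inside the parabola envelope; chosen so
// that INF + q^2 == INF exactly in double precision for any q^2 < 2^53*ulp.
static const double EDT_INF = 1e30;

// Felzenszwalb & Huttenlocher exact 1D squared distance transform.
// f: input squared distances along the line; d: output; v/z: scratch.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
    int k = 0;
    v[0] = 0;
    z[0] = -EDT_INF;
    z[1] = EDT_INF;
    for (int q = 1; q < n; ++q) {
        double s = 0.0;
        while (true) {
            int vk = v[k];
            s = ((f[q] + (double)q * q) - (f[vk] + (double)vk * vk)) /
                (2.0 * q - 2.0 * vk);
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = EDT_INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = (double)q - v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest TRUE voxel of `feature`. Returns EDT_INF-scale values when no
// feature voxel exists. dims is the column-major array dimension (n1,n2,n3).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims) {
    if (dims.size() != 3) stop("dims must have length 3");
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    if (feature.size() != n) stop("feature length does not match dims");
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = feature[i] ? 0.0 : EDT_INF;

    int nmax = std::max(n1, std::max(n2, n3));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along dimension 1 (stride 1)
    for (int k3 = 0; k3 < n3; ++k3) {
        for (int k2 = 0; k2 < n2; ++k2) {
            R_xlen_t base = (R_xlen_t)n1 * (k2 + (R_xlen_t)n2 * k3);
            for (int i = 0; i < n1; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, n1);
            for (int i = 0; i < n1; ++i) out[base + i] = d[i];
        }
    }
    // pass along dimension 2 (stride n1)
    for (int k3 = 0; k3 < n3; ++k3) {
        for (int k1 = 0; k1 < n1; ++k1) {
            R_xlen_t base = k1 + (R_xlen_t)n1 * n2 * k3;
            for (int i = 0; i < n2; ++i) f[i] = out[base + (R_xlen_t)n1 * i];
            dt1d(f, d, v, z, n2);
            for (int i = 0; i < n2; ++i) out[base + (R_xlen_t)n1 * i] = d[i];
        }
    }
    // pass along dimension 3 (stride n1*n2)
    const R_xlen_t s3 = (R_xlen_t)n1 * n2;
    for (int k2 = 0; k2 < n2; ++k2) {
        for (int k1 = 0; k1 < n1; ++k1) {
            R_xlen_t base = k1 + (R_xlen_t)n1 * k2;
            for (int i = 0; i < n3; ++i) f[i] = out[base + s3 * i];
            dt1d(f, d, v, z, n3);
            for (int i = 0; i < n3; ++i) out[base + s3 * i] = d[i];
        }
    }
    // collapse anything still at the INF scale to R's Inf
    for (R_xlen_t i = 0; i < n; ++i)
        if (out[i] >= EDT_INF * 0.5) out[i] = R_PosInf;
    return out;
}

// Label connected components of a logical mask. Labels are assigned in
// column-major scan order of each component's first voxel, starting at 1;
// background voxels get 0. connectivity is 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    if (dims.size() != 3) stop("dims must have length 3");
    if (connectivity != 6 && connectivity != 26)
        stop("connectivity must be 6 or 26");
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    if (mask.size() != n) stop("mask length does not match dims");

    std::vector<int> off1, off2, off3;
    for (int d3 = -1; d3 <= 1; ++d3)
        for (int d2 = -1; d2 <= 1; ++d2)
            for (int d1 = -1; d1 <= 1; ++d1) {
                int ad = std::abs(d1) + std::abs(d2) + std::abs(d3);
                if (ad == 0) continue;
                if (connectivity == 6 && ad != 1) continue;
                off1.push_back(d1);
                off2.push_back(d2);
                off3.push_back(d3);
            }
    const int noff = (int)off1.size();

    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> stack;
    stack.reserve(1024);
    int cur = 0;
    for (R_xlen_t i0 = 0; i0 < n; ++i0) {
        if (!mask[i0] || lab[i0] != 0) continue;
        ++cur;
        lab[i0] = cur;
        stack.push_back(i0);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int c1 = (int)(p % n1);
            R_xlen_t rest = p / n1;
            int c2 = (int)(rest % n2);
            int c3 = (int)(rest / n2);
            for (int j = 0; j < noff; ++j) {
                int a1 = c1 + off1[j];
                int a2 = c2 + off2[j];
                int a3 = c3 + off3[j];
                if (a1 < 0 || a1 >= n1 || a2 < 0 || a2 >= n2 ||
                    a3 < 0 || a3 >= n3)
                    continue;
                R_xlen_t q = a1 + (R_xlen_t)n1 * (a2 + (R_xlen_t)n2 * a3);
                if (mask[q] && lab[q] == 0) {
                    lab[q] = cur;
                    stack.push_back(q);
                }
            }
        }
    }
    return lab;
}

// Separable Gaussian smoothing with reflected boundaries (used by the
// equiaxed-foam phantom generator). sigma in voxels; kernel radius 3*sigma.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector x, IntegerVector dims,
                                  double sigma) {
    if (dims.size() != 3) stop("dims must have length 3");
    if (sigma <= 0) stop("sigma must be positive");
    const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
    if (x.size() != n) stop("x length does not match dims");

    int rad = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> ker(2 * rad + 1);
    double ksum = 0.0;
    for (int i = -rad; i <= rad; ++i) {
        ker[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
        ksum += ker[i + rad];
    }
    for (size_t i = 0; i < ker.size(); ++i) ker[i] /= ksum;

    NumericVector cur = clone(x);
    NumericVector nxt(n);
    int nn[3] = {n1, n2, n3};
    R_xlen_t strides[3] = {1, (R_xlen_t)n1, (R_xlen_t)n1 * n2};
    std::vector<double> line(std::max(n1, std::max(n2, n3)));

    for (int axis = 0; axis < 3; ++axis) {
        int len = nn[axis];
        R_xlen_t st = strides[axis];
        int oa = (axis == 0) ? 1 : 0;
        int ob = (axis == 2) ? 1 : 2;
        for (int kb = 0; kb < nn[ob]; ++kb) {
            for (int ka = 0; ka < nn[oa]; ++ka) {
                R_xlen_t base = strides[oa] * ka + strides[ob] * kb;
                for (int i = 0; i < len; ++i) line[i] = cur[base + st * i];
                for (int i = 0; i < len; ++i) {
                    double acc = 0.0;
                    for (int j = -rad; j <= rad; ++j) {
                        int idx = i + j;
                        // reflect (symmetric, no edge repeat for interior)
                        while (idx < 0 || idx >= len) {
                            if (idx < 0) idx = -idx - 1;
                            if (idx >= len) idx = 2 * len - idx - 1;
                        }
                        acc += ker[j + rad] * line[idx];
                    }
                    nxt[base + st * i] = acc;
                }
            }
        }
        std::swap(cur, nxt);
    }
    return cur;
}
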