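#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy with Chebyshev distance, self-matches excluded.
// Templates of length m are taken from indices 0..n-m-1 so that every
// template also has an (m+1)-length extension (Richman & Moorman counting).
// A match is distance <= r. Returns 0 for a constant series (all templates
// match, -log(1)); NA when no m-matches or no (m+1)-matches exist.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || m < 1 || r < 0) return NA_REAL;
  const double* p = x.begin();
  long long A = 0, B = 0;
  int nm = n - m;  // template starts 0..nm-1
  // Iterate over pair offsets d = j - i; along each diagonal a template
  // match of length m is a run of >= m consecutive within-r sample pairs,
  // counted in O(n) by run length.
  for (int d = 1; d <= nm - 1; ++d) {
    int iMax = nm - 1 - d;
    int tmax = n - 1 - d;
    int run = 0;
    for (int t = 0; t <= tmax; ++t) {
      if (std::fabs(p[t] - p[t + d]) <= r) ++run; else run = 0;
      if (run >= m && t - m + 1 <= iMax) ++B;
      if (run >= m + 1 && t - m <= iMax) ++A;
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Local functional connectivity density. z is a t x V matrix of
// standardized series scaled so that crossprod(z)[i,j] is the Pearson
// correlation. coords holds 1-based (x,y,z) grid coordinates of the V
// voxels; dims the grid extent. For each voxel i a cluster is grown from i
// by repeatedly adding face-adjacent (6-connectivity) voxels whose
// correlation WITH VOXEL i is >= threshold; the returned count excludes i.
// [[Rcpp::export]]
IntegerVector lfcd_cpp(NumericMatrix z, IntegerMatrix coords,
                       IntegerVector dims, double threshold) {
  int V = z.ncol(), T = z.nrow();
  int dx = dims[0], dy = dims[1], dz = dims[2];
  std::vector<int> lut((size_t)dx * dy * dz, -1);
  for (int v = 0; v < V; ++v) {
    size_t ix = coords(v, 0) - 1, iy = coords(v, 1) - 1, iz = coords(v, 2) - 1;
    lut[ix + dx * (iy + (size_t)dy * iz)] = v;
  }
  const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  IntegerVector out(V);
  std::vector<int> stamp(V, -1);
  std::vector<int> queue;
  queue.reserve(V);
  for (int i = 0; i < V; ++i) {
    queue.clear();
    queue.push_back(i);
    stamp[i] = i;
    int count = 0;
    size_t head = 0;
    while (head < queue.size()) {
      int cur = queue[head++];
      int cx = coords(cur, 0) - 1, cy = coords(cur, 1) - 1, cz = coords(cur, 2) - 1;
      for (int k = 0; k < 6; ++k) {
        int px = cx + nb[k][0], py = cy + nb[k][1], pz = cz + nb[k][2];
        if (px < 0 || px >= dx || py < 0 || py >= dy || pz < 0 || pz >= dz) continue;
        int j = lut[(size_t)px + dx * ((size_t)py + (size_t)dy * pz)];
        if (j < 0 || stamp[j] == i) continue;
        stamp[j] = i;  // examined once per index voxel; r(i,j) is path-independent
        double r = 0.0;
        for (int t = 0; t < T; ++t) r += z(t, i) * z(t, j);
        if (r >= threshold) { queue.push_back(j); ++count; }
      }
    }
    out[i] = count;
  }
  return out;
}
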