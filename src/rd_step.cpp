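#include <Rcpp.h>
using namespace Rcpp;

// Explicit forward-Euler integration of the reaction-diffusion-therapy
// equation on a masked voxel grid with frozen diffusivity:
//
//   dN/dt = div(D grad N) + k N (1 - N/theta) - ac N tf(t)
//
// The flux term uses face-averaged D and a zero-flux condition on faces that
// leave the mask (or the grid), which conserves total cell number exactly
// when k = ac = 0. `tf` holds the therapy decay factor sampled once per step
// (at the step midpoint by the caller). N is clipped to [0, theta] after each
// step when `clip` is true.
//
// The 6-neighborhood of every mask voxel is flattened into index/weight
// lists once per call so the inner loop is branch-free.
//
// [[Rcpp::export]]
NumericVector rd_run_cpp(NumericVector N0, NumericVector D, LogicalVector mask,
                         NumericVector k, double theta, NumericVector ac,
                         NumericVector tf, IntegerVector dims, NumericVector h,
                         double dt, bool clip) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const int nsteps = tf.size();
  const double w_ax[3] = {1.0 / (h[0] * h[0]), 1.0 / (h[1] * h[1]),
                          1.0 / (h[2] * h[2])};

  std::vector<double> cur(N0.begin(), N0.end());
  std::vector<double> nxt(n);

  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i)
    if (mask[i]) idx.push_back(i);
  const int m = (int)idx.size();

  // Flattened neighbor lists: nb_start[q]..nb_start[q+1]-1 index into
  // nb_idx/nb_w for the valid in-mask neighbors of mask voxel q.
  std::vector<int> nb_start(m + 1, 0);
  std::vector<int> nb_idx;
  std::vector<double> nb_w;
  nb_idx.reserve(6 * m);
  nb_w.reserve(6 * m);
  const int strides[3] = {1, nx, nx * ny};
  for (int q = 0; q < m; ++q) {
    const int c = idx[q];
    const int ci = c % nx;
    const int cj = (c / nx) % ny;
    const int ck = c / (nx * ny);
    const int lo[3] = {ci, cj, ck};
    const int hi[3] = {nx - 1 - ci, ny - 1 - cj, nz - 1 - ck};
    for (int a = 0; a < 3; ++a) {
      if (lo[a] > 0 && mask[c - strides[a]]) {
        nb_idx.push_back(c - strides[a]);
        nb_w.push_back(w_ax[a]);
      }
      if (hi[a] > 0 && mask[c + strides[a]]) {
        nb_idx.push_back(c + strides[a]);
        nb_w.push_back(w_ax[a]);
      }
    }
    nb_start[q + 1] = (int)nb_idx.size();
  }

  for (int step = 0; step < nsteps; ++step) {
    const double tfs = tf[step];
    for (int q = 0; q < m; ++q) {
      const int c = idx[q];
      const double Nc = cur[c], Dc = D[c];
      double lap = 0.0;
      for (int p = nb_start[q]; p < nb_start[q + 1]; ++p) {
        const int nb = nb_idx[p];
        lap += nb_w[p] * 0.5 * (Dc + D[nb]) * (cur[nb] - Nc);
      }
      double Nn = Nc + dt * (lap + k[c] * Nc * (1.0 - Nc / theta)
                                 - ac[c] * Nc * tfs);
      if (clip) {
        if (Nn < 0.0) Nn = 0.0;
        if (Nn > theta) Nn = theta;
      }
      nxt[c] = Nn;
    }
    for (int q = 0; q < m; ++q) cur[idx[q]] = nxt[idx[q]];
  }

  NumericVector out(n);
  std::copy(cur.begin(), cur.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}
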