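#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler advance of the reaction-diffusion state on a regular grid.
//
//   dN/dt = div(D grad N) + kH (1 - N/theta) N - (M1 c1(t) + M2 c2(t)) N
//
// Flux form with face-averaged D and zero flux across the breast-mask
// boundary, so with kH = 0 and no therapy the total cell number telescopes
// exactly. After each sub-step the state is clipped to [0, theta]; the
// number of clipped voxels is reported so callers can log how often the
// (non-positivity-preserving) explicit scheme needed the guard.
//
// c1, c2: therapy time factors (1/day) for the scan-1 and scan-2 drug maps,
// evaluated at the start of each of the nsteps sub-steps. Totals and
// threshold-voxel counts are recorded after every `record_every`-th
// sub-step.
// [[Rcpp::export]]
List rd_advance(NumericVector N, NumericVector D, NumericVector kH,
                double theta, LogicalVector mask, IntegerVector dims,
                NumericVector spacing, double dt, int nsteps,
                NumericVector M1, NumericVector M2,
                NumericVector c1, NumericVector c2,
                int record_every, double vol_threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (N.size() != nvox || D.size() != nvox || kH.size() != nvox ||
      mask.size() != nvox || M1.size() != nvox || M2.size() != nvox)
    stop("rd_advance: field size mismatch");
  if (c1.size() < nsteps || c2.size() < nsteps)
    stop("rd_advance: therapy factor series shorter than nsteps");
  const double ax = 1.0 / (spacing[0] * spacing[0]);
  const double ay = 1.0 / (spacing[1] * spacing[1]);
  const double az = 1.0 / (spacing[2] * spacing[2]);
  const double thr = vol_threshold * theta;

  std::vector<double> cur(N.begin(), N.end());
  std::vector<double> nxt(nvox, 0.0);
  const int nrec = record_every > 0 ? nsteps / record_every : 0;
  NumericVector tot_rec(nrec);
  IntegerVector cnt_rec(nrec);
  long clipped = 0;
  int irec = 0;

  for (int s = 0; s < nsteps; ++s) {
    const double cc1 = c1[s], cc2 = c2[s];
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t p = base + i;
          if (!mask[p]) { nxt[p] = 0.0; continue; }
          const double n0 = cur[p], d0 = D[p];
          double lap = 0.0;
          if (i + 1 < nx && mask[p + 1])
            lap += 0.5 * (d0 + D[p + 1]) * (cur[p + 1] - n0) * ax;
          if (i > 0 && mask[p - 1])
            lap += 0.5 * (d0 + D[p - 1]) * (cur[p - 1] - n0) * ax;
          if (j + 1 < ny && mask[p + nx])
            lap += 0.5 * (d0 + D[p + nx]) * (cur[p + nx] - n0) * ay;
          if (j > 0 && mask[p - nx])
            lap += 0.5 * (d0 + D[p - nx]) * (cur[p - nx] - n0) * ay;
          if (k + 1 < nz && mask[p + (R_xlen_t)nx * ny])
            lap += 0.5 * (d0 + D[p + (R_xlen_t)nx * ny]) *
                   (cur[p + (R_xlen_t)nx * ny] - n0) * az;
          if (k > 0 && mask[p - (R_xlen_t)nx * ny])
            lap += 0.5 * (d0 + D[p - (R_xlen_t)nx * ny]) *
                   (cur[p - (R_xlen_t)nx * ny] - n0) * az;
          const double react = kH[p] * (1.0 - n0 / theta) * n0;
          const double ther = (M1[p] * cc1 + M2[p] * cc2) * n0;
          double v = n0 + dt * (lap + react - ther);
          if (v < 0.0) { v = 0.0; ++clipped; }
          else if (v > theta) { v = theta; ++clipped; }
          nxt[p] = v;
        }
      }
    }
    cur.swap(nxt);
    if (record_every > 0 && (s + 1) % record_every == 0 && irec < nrec) {
      double tot = 0.0; int cnt = 0;
      for (R_xlen_t p = 0; p < nvox; ++p) {
        tot += cur[p];
        if (cur[p] >= thr) ++cnt;
      }
      tot_rec[irec] = tot;
      cnt_rec[irec] = cnt;
      ++irec;
    }
  }
  for (R_xlen_t p = 0; p < nvox; ++p) {
    if (!R_finite(cur[p]))
      stop("rd_advance: non-finite state (explicit scheme instability)");
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dims;
  return List::create(_["N"] = out, _["totals"] = tot_rec,
                      _["counts"] = cnt_rec, _["clipped"] = clipped);
}
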