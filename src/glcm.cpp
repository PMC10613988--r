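#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel GLCM texture features over a moving window.
//
// For each pixel the window (clipped at raster edges, never padded) yields
// the co-occurrence pairs for one shift (dr, dc); with symmetric
// accumulation each pair is counted in both orders.  The eight Haralick
// statistics are evaluated directly from the aggregated pair counts.
// Windows with no valid pair (possible only on degenerate rasters) give NA.

// [[Rcpp::export]]
List glcm_texture_rasters_cpp(IntegerMatrix q, int window, int dr, int dc,
                              bool symmetric) {
  const int nr = q.nrow(), nc = q.ncol();
  const int h = (window - 1) / 2;
  NumericMatrix mea(nr, nc), var(nr, nc), hom(nr, nc), con(nr, nc),
      dis(nr, nc), ent(nr, nc), sem(nr, nc), cor(nr, nc);

  const int maxpairs = 2 * window * window;
  std::vector<int> pi(maxpairs), pj(maxpairs), cnt(maxpairs);

  for (int r = 0; r < nr; ++r) {
    const int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
    for (int c = 0; c < nc; ++c) {
      const int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);
      int m = 0;
      for (int a = r0; a <= r1; ++a) {
        const int a2 = a + dr;
        if (a2 < r0 || a2 > r1) continue;
        for (int b = c0; b <= c1; ++b) {
          const int b2 = b + dc;
          if (b2 < c0 || b2 > c1) continue;
          const int vi = q(a, b), vj = q(a2, b2);
          // aggregate duplicates (m is tiny: <= window^2 pairs)
          bool found = false;
          for (int k = 0; k < m; ++k)
            if (pi[k] == vi && pj[k] == vj) { cnt[k]++; found = true; break; }
          if (!found) { pi[m] = vi; pj[m] = vj; cnt[m] = 1; ++m; }
          if (symmetric) {
            found = false;
            for (int k = 0; k < m; ++k)
              if (pi[k] == vj && pj[k] == vi) { cnt[k]++; found = true; break; }
            if (!found) { pi[m] = vj; pj[m] = vi; cnt[m] = 1; ++m; }
          }
        }
      }
      if (m == 0) {
        mea(r, c) = var(r, c) = hom(r, c) = con(r, c) = dis(r, c) =
            ent(r, c) = sem(r, c) = cor(r, c) = NA_REAL;
        continue;
      }
      double tot = 0;
      for (int k = 0; k < m; ++k) tot += cnt[k];
      double mi = 0, mj = 0;
      for (int k = 0; k < m; ++k) {
        const double p = cnt[k] / tot;
        mi += pi[k] * p;
        mj += pj[k] * p;
      }
      double vi_ = 0, vj_ = 0, hom_ = 0, con_ = 0, dis_ = 0, ent_ = 0,
             sem_ = 0, cov_ = 0;
      for (int k = 0; k < m; ++k) {
        const double p = cnt[k] / tot;
        const int d = pi[k] - pj[k];
        vi_ += (pi[k] - mi) * (pi[k] - mi) * p;
        vj_ += (pj[k] - mj) * (pj[k] - mj) * p;
        hom_ += p / (1.0 + d * d);
        con_ += d * d * p;
        dis_ += std::abs(d) * p;
        ent_ -= p * std::log(p);
        sem_ += p * p;
        cov_ += (pi[k] - mi) * (pj[k] - mj) * p;
      }
      mea(r, c) = mi;
      var(r, c) = vi_;
      hom(r, c) = hom_;
      con(r, c) = con_;
      dis(r, c) = dis_;
      ent(r, c) = ent_;
      sem(r, c) = sem_;
      cor(r, c) = (vi_ > 1e-12 && vj_ > 1e-12)
                      ? cov_ / std::sqrt(vi_ * vj_)
                      : 0.0;
    }
  }
  return List::create(
      Named("MEA") = mea, Named("VAR") = var, Named("HOM") = hom,
      Named("CON") = con, Named("DIS") = dis, Named("ENT") = ent,
      Named("SEM") = sem, Named("COR") = cor);
}
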