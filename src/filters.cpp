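#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <map>
#include <functional>
using namespace Rcpp;

// Reflect index into [0, n): d c b a | a b c d | d c b a
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // rows direction (convolve down columns)
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int j = -r; j <= r; ++j) s += k[j + r] * img(refl(i + j, nr), c);
      tmp(i, c) = s;
    }
  // cols direction
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int j = -r; j <= r; ++j) s += k[j + r] * tmp(i, refl(c + j, nc));
      out(i, c) = s;
    }
  return out;
}

// Sliding-window mean over a w x w window (w odd), reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_box_mean(NumericMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol();
  int r = w / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int j = -r; j <= r; ++j) s += img(refl(i + j, nr), c);
      tmp(i, c) = s;
    }
  double n2 = (double)w * (double)w;
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int j = -r; j <= r; ++j) s += tmp(i, refl(c + j, nc));
      out(i, c) = s / n2;
    }
  return out;
}

// Local min/max/range and sample std over w x w windows, reflect padding.
// [[Rcpp::export]]
List cpp_local_stats(NumericMatrix img, int w) {
  int nr = img.nrow(), nc = img.ncol();
  int r = w / 2;
  NumericMatrix rng(nr, nc), sd(nr, nc);
  double n = (double)w * (double)w;
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      double mn = R_PosInf, mx = R_NegInf, s = 0.0, s2 = 0.0;
      for (int a = -r; a <= r; ++a)
        for (int b = -r; b <= r; ++b) {
          double v = img(refl(i + a, nr), refl(c + b, nc));
          if (v < mn) mn = v;
          if (v > mx) mx = v;
          s += v; s2 += v * v;
        }
      rng(i, c) = mx - mn;
      double var = (s2 - s * s / n) / (n - 1.0);
      sd(i, c) = var > 0 ? std::sqrt(var) : 0.0;
    }
  return List::create(_["range"] = rng, _["std"] = sd);
}

// Shannon entropy (bits) of the w x w local histogram of quantized levels.
// `q` holds integer levels in [0, nbins).
// [[Rcpp::export]]
NumericMatrix cpp_local_entropy(IntegerMatrix q, int w, int nbins) {
  int nr = q.nrow(), nc = q.ncol();
  int r = w / 2;
  NumericMatrix out(nr, nc);
  std::vector<int> hist(nbins);
  double n = (double)w * (double)w;
  for (int i = 0; i < nr; ++i) {
    // build histogram for (i, 0), then slide along the row
    std::fill(hist.begin(), hist.end(), 0);
    for (int a = -r; a <= r; ++a)
      for (int b = -r; b <= r; ++b)
        hist[q(refl(i + a, nr), refl(b, nc))]++;
    for (int c = 0; c < nc; ++c) {
      if (c > 0) {
        int cout_ = c - 1 - r, cin_ = c + r;
        for (int a = -r; a <= r; ++a) {
          hist[q(refl(i + a, nr), refl(cout_, nc))]--;
          hist[q(refl(i + a, nr), refl(cin_, nc))]++;
        }
      }
      double H = 0.0;
      for (int b = 0; b < nbins; ++b)
        if (hist[b] > 0) {
          double p = hist[b] / n;
          H -= p * std::log2(p);
        }
      out(i, c) = H;
    }
  }
  return out;
}

// Sobel gradients; Gx along columns (+x), Gy along rows (+y), reflect padding.
// [[Rcpp::export]]
List cpp_sobel(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      int im = refl(i - 1, nr), ip = refl(i + 1, nr);
      int cm = refl(c - 1, nc), cp = refl(c + 1, nc);
      gx(i, c) = (img(im, cp) + 2.0 * img(i, cp) + img(ip, cp)
                  - img(im, cm) - 2.0 * img(i, cm) - img(ip, cm)) / 8.0;
      gy(i, c) = (img(ip, cm) + 2.0 * img(ip, c) + img(ip, cp)
                  - img(im, cm) - 2.0 * img(im, c) - img(im, cp)) / 8.0;
    }
  return List::create(_["gx"] = gx, _["gy"] = gy);
}

static std::vector<std::pair<int,int> > disk_offsets(int radius) {
  std::vector<std::pair<int,int> > off;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) off.push_back(std::make_pair(a, b));
  return off;
}

// [[Rcpp::export]]
NumericMatrix cpp_erode_disk(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      double mn = R_PosInf;
      for (size_t k = 0; k < off.size(); ++k) {
        double v = img(refl(i + off[k].first, nr), refl(c + off[k].second, nc));
        if (v < mn) mn = v;
      }
      out(i, c) = mn;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_dilate_disk(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  std::vector<std::pair<int,int> > off = disk_offsets(radius);
  for (int i = 0; i < nr; ++i)
    for (int c = 0; c < nc; ++c) {
      double mx = R_NegInf;
      for (size_t k = 0; k < off.size(); ++k) {
        double v = img(refl(i + off[k].first, nr), refl(c + off[k].second, nc));
        if (v > mx) mx = v;
      }
      out(i, c) = mx;
    }
  return out;
}

// Coherence-enhancing diffusion (Weickert lineage).  Structure tensor is
// smoothed at scale rho; the diffusion tensor passes conductance alpha across
// coherent structures and up to 1 along them.  The explicit update is clamped
// to the input range so the discrete maximum principle holds exactly.
// [[Rcpp::export]]
NumericMatrix cpp_coherence_diffuse(NumericMatrix img, int n_iter, double tau,
                                    double alpha, double contrast, double rho,
                                    double sigma_grad) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix u = clone(img);
  double gmin = R_PosInf, gmax = R_NegInf;
  for (int i = 0; i < nr * nc; ++i) {
    if (img[i] < gmin) gmin = img[i];
    if (img[i] > gmax) gmax = img[i];
  }
  double C = contrast * contrast * contrast * contrast; // |grad|^4 scale
  if (C <= 0) C = 1e-12;
  double C2 = contrast * contrast; // |grad|^2 scale for the edge stopper
  NumericMatrix ux(nr, nc), uy(nr, nc), gxs(nr, nc), gys(nr, nc),
                j1(nr, nc), j2(nr, nc);
  for (int it = 0; it < n_iter; ++it) {
    // regularized gradients (Catte-Lions-Morel) drive the tensor so pixel
    // noise cannot seed spurious coherent structures; the flux itself uses
    // the raw gradient of u
    NumericMatrix ug = sigma_grad > 0 ? cpp_gaussian_blur(u, sigma_grad) : u;
    for (int i = 0; i < nr; ++i)
      for (int c = 0; c < nc; ++c) {
        gxs(i, c) = 0.5 * (ug(i, refl(c + 1, nc)) - ug(i, refl(c - 1, nc)));
        gys(i, c) = 0.5 * (ug(refl(i + 1, nr), c) - ug(refl(i - 1, nr), c));
        ux(i, c) = 0.5 * (u(i, refl(c + 1, nc)) - u(i, refl(c - 1, nc)));
        uy(i, c) = 0.5 * (u(refl(i + 1, nr), c) - u(refl(i - 1, nr), c));
      }
    NumericMatrix J11(nr, nc), J22(nr, nc), J12(nr, nc);
    for (int i = 0; i < nr * nc; ++i) {
      J11[i] = gxs[i] * gxs[i];
      J22[i] = gys[i] * gys[i];
      J12[i] = gxs[i] * gys[i];
    }
    J11 = cpp_gaussian_blur(J11, rho);
    J22 = cpp_gaussian_blur(J22, rho);
    J12 = cpp_gaussian_blur(J12, rho);
    for (int i = 0; i < nr; ++i)
      for (int c = 0; c < nc; ++c) {
        double a = J11(i, c), b = J12(i, c), d = J22(i, c);
        double tr = a + d;
        double disc = std::sqrt((a - d) * (a - d) + 4.0 * b * b);
        double mu1 = 0.5 * (tr + disc), mu2 = 0.5 * (tr - disc);
        double phi = 0.5 * std::atan2(2.0 * b, a - d); // dominant gradient dir
        double diff2 = (mu1 - mu2) * (mu1 - mu2);
        // across-structure conductance: Perona-Malik edge stopper -- near 1
        // in flat (noise-only) regions so they smooth isotropically, small
        // across real edges/striations
        double e = mu1 / (C2 > 0 ? C2 : 1e-12);
        double c1 = alpha + (1.0 - alpha) * std::exp(-e * e);
        double c2 = c1; // along-structure conductance >= across
        if (diff2 > 1e-30) {
          double ced = alpha + (1.0 - alpha) * std::exp(-C / diff2);
          if (ced > c2) c2 = ced;
        }
        double cs = std::cos(phi), sn = std::sin(phi);
        double D11 = c1 * cs * cs + c2 * sn * sn;
        double D22 = c1 * sn * sn + c2 * cs * cs;
        double D12 = (c1 - c2) * cs * sn;
        j1(i, c) = D11 * ux(i, c) + D12 * uy(i, c);
        j2(i, c) = D12 * ux(i, c) + D22 * uy(i, c);
      }
    for (int i = 0; i < nr; ++i)
      for (int c = 0; c < nc; ++c) {
        double div = 0.5 * (j1(i, refl(c + 1, nc)) - j1(i, refl(c - 1, nc)))
                   + 0.5 * (j2(refl(i + 1, nr), c) - j2(refl(i - 1, nr), c));
        double v = u(i, c) + tau * div;
        if (v < gmin) v = gmin;
        if (v > gmax) v = gmax;
        u(i, c) = v;
      }
  }
  return u;
}

// Connected components of a binary mask (4- or 8-connectivity);
// labels 1..K, 0 where mask == 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity = 4) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = connectivity == 8 ? 8 : 4;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int i0 = 0; i0 < nr; ++i0) {
      if (mask(i0, c0) == 0 || lab(i0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i0 + c0 * nr);
      lab(i0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % nr, c = p / nr;
        for (int k = 0; k < nn; ++k) {
          int ni = i + di8[k], ncc = c + dc8[k];
          if (ni < 0 || ni >= nr || ncc < 0 || ncc >= nc) continue;
          if (mask(ni, ncc) != 0 && lab(ni, ncc) == 0) {
            lab(ni, ncc) = next;
            stack.push_back(ni + ncc * nr);
          }
        }
      }
    }
  return lab;
}

// SLIC superpixels on a grayscale image.  Deterministic (grid init, fixed
// iteration count).  Post-processing enforces 4-connectivity by absorbing
// orphan fragments into the neighbouring region with the longest shared
// border.  Labels are 1..K.
// [[Rcpp::export]]
IntegerMatrix cpp_slic(NumericMatrix img, int K, double compactness, int n_iter) {
  int nr = img.nrow(), nc = img.ncol();
  int N = nr * nc;
  double S = std::sqrt((double)N / (double)K);
  // grid initialization
  int gr = std::max(1, (int)std::round(nr / S));
  int gc = std::max(1, (int)std::round(nc / S));
  std::vector<double> cy, cx, cg;
  for (int a = 0; a < gr; ++a)
    for (int b = 0; b < gc; ++b) {
      double y = (a + 0.5) * nr / gr, x = (b + 0.5) * nc / gc;
      cy.push_back(y); cx.push_back(x);
      cg.push_back(img((int)y, (int)x));
    }
  int k = (int)cy.size();
  std::vector<int> label(N, -1);
  std::vector<double> dist(N);
  double invS2 = 1.0 / (S * S);
  double m2 = compactness * compactness;
  for (int it = 0; it < n_iter; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int j = 0; j < k; ++j) {
      int r0 = std::max(0, (int)(cy[j] - 2 * S)), r1 = std::min(nr - 1, (int)(cy[j] + 2 * S));
      int c0 = std::max(0, (int)(cx[j] - 2 * S)), c1 = std::min(nc - 1, (int)(cx[j] + 2 * S));
      for (int c = c0; c <= c1; ++c)
        for (int i = r0; i <= r1; ++i) {
          double dg = img(i, c) - cg[j];
          double dy = i - cy[j], dx = c - cx[j];
          double d = dg * dg + m2 * (dy * dy + dx * dx) * invS2;
          int p = i + c * nr;
          if (d < dist[p]) { dist[p] = d; label[p] = j; }
        }
    }
    // update centers
    std::vector<double> sy(k, 0), sx(k, 0), sg(k, 0);
    std::vector<int> cnt(k, 0);
    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < nr; ++i) {
        int j = label[i + c * nr];
        if (j < 0) continue;
        sy[j] += i; sx[j] += c; sg[j] += img(i, c); cnt[j]++;
      }
    for (int j = 0; j < k; ++j)
      if (cnt[j] > 0) {
        cy[j] = sy[j] / cnt[j]; cx[j] = sx[j] / cnt[j]; cg[j] = sg[j] / cnt[j];
      }
  }
  // assign any unlabeled pixel (shouldn't happen) to nearest center by scan
  for (int p = 0; p < N; ++p) if (label[p] < 0) label[p] = 0;
  // connectivity: relabel connected components, absorb small fragments
  IntegerMatrix lab0(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i) lab0(i, c) = label[i + c * nr] + 1;
  // components of equal-label regions
  IntegerMatrix comp(nr, nc);
  int ncomp = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0)
    for (int i0 = 0; i0 < nr; ++i0) {
      if (comp(i0, c0) != 0) continue;
      ++ncomp;
      int v = lab0(i0, c0);
      stack.clear(); stack.push_back(i0 + c0 * nr);
      comp(i0, c0) = ncomp;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int i = p % nr, c = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; ++q) {
          int ni = i + di[q], ncc = c + dc[q];
          if (ni < 0 || ni >= nr || ncc < 0 || ncc >= nc) continue;
          if (comp(ni, ncc) == 0 && lab0(ni, ncc) == v) {
            comp(ni, ncc) = ncomp;
            stack.push_back(ni + ncc * nr);
          }
        }
      }
    }
  std::vector<int> csize(ncomp + 1, 0);
  std::vector<std::vector<int> > cpix(ncomp + 1);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i) {
      int id = comp(i, c);
      csize[id]++;
      cpix[id].push_back(i + c * nr);
    }
  int minsize = std::max(4, (int)(S * S / 4.0));
  // union-find over components; absorb small ones into the neighbour with
  // the longest shared border (single pass over sizes, touching only each
  // small component's own pixels)
  std::vector<int> parent(ncomp + 1);
  for (int j = 0; j <= ncomp; ++j) parent[j] = j;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  bool changed = true;
  for (int pass = 0; pass < 10 && changed; ++pass) {
    changed = false;
    for (int target = 1; target <= ncomp; ++target) {
      if (find(target) != target) continue;          // already absorbed
      if (csize[target] >= minsize) continue;
      std::map<int, int> border;
      for (size_t pi = 0; pi < cpix[target].size(); ++pi) {
        int p = cpix[target][pi];
        int i = p % nr, c = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; ++q) {
          int ni = i + di[q], ncc = c + dc[q];
          if (ni < 0 || ni >= nr || ncc < 0 || ncc >= nc) continue;
          int oc = find(comp(ni, ncc));
          if (oc != target) border[oc]++;
        }
      }
      int best = -1, bestn = -1;
      for (std::map<int,int>::iterator itb = border.begin(); itb != border.end(); ++itb)
        if (itb->second > bestn) { bestn = itb->second; best = itb->first; }
      if (best > 0) {
        parent[target] = best;
        csize[best] += csize[target];
        cpix[best].insert(cpix[best].end(), cpix[target].begin(),
                          cpix[target].end());
        cpix[target].clear();
        changed = true;
      }
    }
  }
  // compact labels to 1..K'
  std::vector<int> remap(ncomp + 1, 0);
  int nk = 0;
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < nr; ++i) {
      int cmp = find(comp(i, c));
      if (remap[cmp] == 0) remap[cmp] = ++nk;
      out(i, c) = remap[cmp];
    }
  return out;
}

// ---------------- CART decision tree (Gini impurity) ----------------

struct CartNode {
  int feature;     // -1 for leaf
  double thresh;
  int left, right; // 0-based node indices, -1 if leaf
  int pred;        // majority class (0-based)
  int n;
};

static double gini_from_counts(const std::vector<int> &cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t i = 0; i < cnt.size(); ++i) {
    double p = (double)cnt[i] / n;
    g -= p * p;
  }
  return g;
}

static void cart_grow(const NumericMatrix &X, const IntegerVector &y, int nclass,
                      std::vector<int> &idx, int depth, int max_depth, int min_leaf,
                      std::vector<CartNode> &nodes) {
  int me = (int)nodes.size();
  nodes.push_back(CartNode());
  CartNode &node = nodes[me];
  int n = (int)idx.size();
  std::vector<int> cnt(nclass, 0);
  for (int i = 0; i < n; ++i) cnt[y[idx[i]]]++;
  int pred = 0;
  for (int k = 1; k < nclass; ++k) if (cnt[k] > cnt[pred]) pred = k;
  node.feature = -1; node.thresh = NA_REAL;
  node.left = node.right = -1;
  node.pred = pred; node.n = n;
  bool pure = (cnt[pred] == n);
  if (pure || depth >= max_depth || n < 2 * min_leaf) return;

  double parent_imp = gini_from_counts(cnt, n);
  double best_gain = 1e-12;
  int best_f = -1, best_pos = -1;
  double best_thresh = 0.0;
  int p = X.ncol();
  std::vector<int> ord(idx);
  std::vector<int> best_ord;
  for (int f = 0; f < p; ++f) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double xa = X(a, f), xb = X(b, f);
      if (xa != xb) return xa < xb;
      return a < b;
    });
    std::vector<int> lc(nclass, 0);
    std::vector<int> rc(cnt);
    for (int i = 0; i < n - 1; ++i) {
      int cls = y[ord[i]];
      lc[cls]++; rc[cls]--;
      int nl = i + 1, nrr = n - nl;
      if (nl < min_leaf || nrr < min_leaf) continue;
      if (X(ord[i], f) == X(ord[i + 1], f)) continue; // no split point here
      double gain = parent_imp
        - ((double)nl / n) * gini_from_counts(lc, nl)
        - ((double)nrr / n) * gini_from_counts(rc, nrr);
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_pos = i;
        best_thresh = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        best_ord = ord;
      }
    }
  }
  if (best_f < 0) return;
  std::vector<int> lidx(best_ord.begin(), best_ord.begin() + best_pos + 1);
  std::vector<int> ridx(best_ord.begin() + best_pos + 1, best_ord.end());
  nodes[me].feature = best_f;
  nodes[me].thresh = best_thresh;
  int lchild = (int)nodes.size();
  cart_grow(X, y, nclass, lidx, depth + 1, max_depth, min_leaf, nodes);
  int rchild = (int)nodes.size();
  cart_grow(X, y, nclass, ridx, depth + 1, max_depth, min_leaf, nodes);
  nodes[me].left = lchild;
  nodes[me].right = rchild;
}

// Train a CART classification tree.  y in 0..nclass-1.  Deterministic:
// exhaustive threshold search, first best split kept.
// [[Rcpp::export]]
List cpp_cart_train(NumericMatrix X, IntegerVector y, int nclass,
                    int max_depth, int min_leaf) {
  int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<CartNode> nodes;
  cart_grow(X, y, nclass, idx, 0, max_depth, min_leaf, nodes);
  int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m), pred(m), nn(m);
  NumericVector thresh(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    thresh[i] = nodes[i].thresh;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
    nn[i] = nodes[i].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = thresh,
                      _["left"] = left, _["right"] = right,
                      _["pred"] = pred, _["n"] = nn);
}

// [[Rcpp::export]]
IntegerVector cpp_cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"];
  NumericVector thresh = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= thresh[node]) ? left[node] : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
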