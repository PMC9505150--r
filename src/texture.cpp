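#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 13 unique 3D directions (distance-1 Chebyshev, positive lexicographic);
// with their negatives they span the full 26-neighbourhood.
static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-connected component labelling of a binary 3D array (column-major,
// dims attached). 0 stays 0; components numbered from 1.
// [[Rcpp::export]]
IntegerVector label_components_26(IntegerVector binary) {
  IntegerVector dims = binary.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = idx3(x, y, z, nx, ny);
        if (binary[v] == 0 || lab[v] != 0) continue;
        ++next;
        lab[v] = next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          int cz = c / (nx * ny), rem = c % (nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int qx = cx + dx, qy = cy + dy, qz = cz + dz;
                if (qx < 0 || qy < 0 || qz < 0 ||
                    qx >= nx || qy >= ny || qz >= nz) continue;
                int q = idx3(qx, qy, qz, nx, ny);
                if (binary[q] != 0 && lab[q] == 0) {
                  lab[q] = next;
                  stack.push_back(q);
                }
              }
        }
      }
  return lab;
}

// All texture matrices for a discretized ROI in one pass-set.
// `levels`: integer grey levels 1..nlevels, 0 = outside ROI / missing.
// Returns GLCM (nlevels x nlevels x 13, symmetric per direction), GLRLM
// (nlevels x maxrun x 13), GLSZM zones as a (level, size) two-column
// matrix, NGTDM per-level (n_i, s_i), and NGLDM (nlevels x 27, dependence
// counts 0..26 with coarseness alpha = 0).
// [[Rcpp::export]]
List texture_matrices_cpp(IntegerVector levels, int nlevels) {
  IntegerVector dims = levels.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int maxdim = std::max(nx, std::max(ny, nz));

  // --- GLCM ---------------------------------------------------------
  NumericVector glcm(nlevels * nlevels * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *G = &glcm[d * nlevels * nlevels];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = levels[idx3(x, y, z, nx, ny)];
          if (i == 0) continue;
          int qx = x + dx, qy = y + dy, qz = z + dz;
          if (qx < 0 || qy < 0 || qz < 0 ||
              qx >= nx || qy >= ny || qz >= nz) continue;
          int j = levels[idx3(qx, qy, qz, nx, ny)];
          if (j == 0) continue;
          G[(i - 1) + nlevels * (j - 1)] += 1.0;
          G[(j - 1) + nlevels * (i - 1)] += 1.0;  // symmetric
        }
  }
  glcm.attr("dim") = IntegerVector::create(nlevels, nlevels, 13);

  // --- GLRLM --------------------------------------------------------
  NumericVector glrlm(nlevels * maxdim * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    double *Rm = &glrlm[d * nlevels * maxdim];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = levels[idx3(x, y, z, nx, ny)];
          if (i == 0) continue;
          // run start: predecessor out of grid, missing, or other level
          int px = x - dx, py = y - dy, pz = z - dz;
          bool start = (px < 0 || py < 0 || pz < 0 ||
                        px >= nx || py >= ny || pz >= nz);
          if (!start && levels[idx3(px, py, pz, nx, ny)] != i) start = true;
          if (!start) continue;
          int len = 1;
          int qx = x + dx, qy = y + dy, qz = z + dz;
          while (qx >= 0 && qy >= 0 && qz >= 0 &&
                 qx < nx && qy < ny && qz < nz &&
                 levels[idx3(qx, qy, qz, nx, ny)] == i) {
            ++len; qx += dx; qy += dy; qz += dz;
          }
          Rm[(i - 1) + nlevels * (len - 1)] += 1.0;
        }
  }
  glrlm.attr("dim") = IntegerVector::create(nlevels, maxdim, 13);

  // --- GLSZM (26-connected equal-level zones) ------------------------
  std::vector<int> zlevel, zsize;
  {
    int n = nx * ny * nz;
    std::vector<char> seen(n, 0);
    std::vector<int> stack;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int v = idx3(x, y, z, nx, ny);
          int lev = levels[v];
          if (lev == 0 || seen[v]) continue;
          seen[v] = 1;
          stack.clear(); stack.push_back(v);
          int size = 0;
          while (!stack.empty()) {
            int c = stack.back(); stack.pop_back();
            ++size;
            int cz = c / (nx * ny), rem = c % (nx * ny);
            int cy = rem / nx, cx = rem % nx;
            for (int dz = -1; dz <= 1; ++dz)
              for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                  if (!dx && !dy && !dz) continue;
                  int qx = cx + dx, qy = cy + dy, qz = cz + dz;
                  if (qx < 0 || qy < 0 || qz < 0 ||
                      qx >= nx || qy >= ny || qz >= nz) continue;
                  int q = idx3(qx, qy, qz, nx, ny);
                  if (!seen[q] && levels[q] == lev) {
                    seen[q] = 1;
                    stack.push_back(q);
                  }
                }
          }
          zlevel.push_back(lev);
          zsize.push_back(size);
        }
  }
  IntegerMatrix zones(zlevel.size(), 2);
  for (size_t k = 0; k < zlevel.size(); ++k) {
    zones(k, 0) = zlevel[k];
    zones(k, 1) = zsize[k];
  }

  // --- NGTDM and NGLDM (26-neighbourhood, alpha = 0) ------------------
  NumericMatrix ngtdm(nlevels, 2);           // columns: n_i, s_i
  NumericMatrix ngldm(nlevels, 27);          // dependence count 0..26
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = levels[idx3(x, y, z, nx, ny)];
        if (i == 0) continue;
        double sum = 0.0;
        int nnb = 0, dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int qx = x + dx, qy = y + dy, qz = z + dz;
              if (qx < 0 || qy < 0 || qz < 0 ||
                  qx >= nx || qy >= ny || qz >= nz) continue;
              int j = levels[idx3(qx, qy, qz, nx, ny)];
              if (j == 0) continue;
              sum += j;
              ++nnb;
              if (j == i) ++dep;
            }
        if (nnb > 0) {
          ngtdm(i - 1, 0) += 1.0;
          ngtdm(i - 1, 1) += std::fabs((double)i - sum / nnb);
        }
        ngldm(i - 1, dep) += 1.0;
      }

  return List::create(_["glcm"] = glcm, _["glrlm"] = glrlm,
                      _["glszm_zones"] = zones, _["ngtdm"] = ngtdm,
                      _["ngldm"] = ngldm);
}
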