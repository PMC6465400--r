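#include <Rcpp.h>
using namespace Rcpp;

// Euclidean dilation of a binary mask: out(i,j) = 1 iff some mask cell
// center lies within `radius` meters of center (i,j).  Brute-force over the
// disc of offsets; grids are small (hundreds of cells a side) and the disc
// radius is ~520/cellsize cells, so this is well within budget.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(IntegerMatrix mask, double cellsize, double radius) {
  int nx = mask.nrow(), ny = mask.ncol();
  int r = (int)std::floor(radius / cellsize);
  // collect in-disc offsets once
  std::vector<std::pair<int,int>> offs;
  double r2 = (radius / cellsize) * (radius / cellsize);
  for (int dx = -r; dx <= r; ++dx)
    for (int dy = -r; dy <= r; ++dy)
      if ((double)dx * dx + (double)dy * dy <= r2)
        offs.push_back(std::make_pair(dx, dy));
  IntegerMatrix out(nx, ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (mask(i, j) != 1) continue;
      for (size_t k = 0; k < offs.size(); ++k) {
        int ii = i + offs[k].first, jj = j + offs[k].second;
        if (ii >= 0 && ii < nx && jj >= 0 && jj < ny) out(ii, jj) = 1;
      }
    }
  }
  return out;
}
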