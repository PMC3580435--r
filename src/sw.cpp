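#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// Full-matrix Gotoh local alignment score (affine gaps).
// A gap of length L costs gap_open + L * gap_ext, i.e. the first gap
// position is charged gap_open + gap_ext.
// [[Rcpp::export]]
double sw_score_cpp(std::string query, std::string subject,
                    double match, double mismatch,
                    double gap_open, double gap_ext) {
  const int n = query.size();
  const int m = subject.size();
  const double NEG = -1e18;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][0]
    double Hij_left = 0.0;   // H[i][0]
    double F = NEG;          // vertical gap state for column j in row i
    for (int j = 1; j <= m; ++j) {
      double Eij = std::max(H[j] - gap_open - gap_ext, E[j] - gap_ext);
      F = std::max(Hij_left - gap_open - gap_ext, F - gap_ext);
      double s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      double Hij = std::max(0.0, std::max(diag + s, std::max(Eij, F)));
      diag = H[j];
      H[j] = Hij;
      E[j] = Eij;
      Hij_left = Hij;
      if (Hij > best) best = Hij;
    }
  }
  return best;
}
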