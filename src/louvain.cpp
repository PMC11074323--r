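#include <Rcpp.h>
using namespace Rcpp;

// Louvain optimisation of a generic (signed) modularity matrix B:
//   Q(partition) = sum_{i,j in same module} B[i][j]   (diagonal included).
// The signed asymmetric quality function is linear in the co-assignment
// indicator, so both Louvain phases (local moves, aggregation) operate on B
// alone; aggregation sums B over module blocks and the null model stays tied
// to the original graph. Randomness (sweep order) comes from R's RNG so that
// set.seed() governs restarts.

static double total_gain(const std::vector<std::vector<double> >& B,
                         const std::vector<int>& comm, int n) {
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (comm[i] == comm[j]) q += B[i][j];
  return q;
}

// one level: local moves until no improvement; comm relabelled 0..k-1
static bool one_level(const std::vector<std::vector<double> >& B,
                      std::vector<int>& comm, double tol) {
  int n = (int)B.size();
  bool any_move = false;
  std::vector<double> link(n, 0.0); // B-weight from node i to each community
  bool improved = true;
  int sweep = 0;
  while (improved && sweep < 1000) {
    improved = false;
    ++sweep;
    // random sweep order via R RNG
    IntegerVector ord = sample(n, n, false) - 1;
    for (int oi = 0; oi < n; ++oi) {
      int i = ord[oi];
      std::fill(link.begin(), link.end(), 0.0);
      for (int j = 0; j < n; ++j)
        if (j != i) link[comm[j]] += B[i][j];
      int cur = comm[i];
      double best_gain = link[cur];
      int best_c = cur;
      for (int c = 0; c < n; ++c) {
        if (c == cur) continue;
        if (link[c] > best_gain + tol) { best_gain = link[c]; best_c = c; }
      }
      if (best_c != cur) {
        comm[i] = best_c;
        improved = true;
        any_move = true;
      }
    }
  }
  // relabel contiguously
  std::vector<int> map(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
  return any_move;
}

// [[Rcpp::export(name = ".louvain_B")]]
List louvain_B(NumericMatrix Bmat, double tol = 1e-12) {
  int n = Bmat.nrow();
  std::vector<std::vector<double> > B(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) B[i][j] = Bmat(i, j);

  std::vector<int> node2mod(n);
  for (int i = 0; i < n; ++i) node2mod[i] = i;

  // outer fine-tuning loop: after each full two-phase hierarchy, re-run
  // single-node moves over the *original* nodes from the current partition
  // and repeat the hierarchy while the quality keeps improving
  double q_best = total_gain(B, node2mod, n);
  for (int outer = 0; outer < 100; ++outer) {
    // local moves on original nodes starting from the current partition
    one_level(B, node2mod, tol);

    // aggregate and run the remaining hierarchy
    int k = 0;
    for (int i = 0; i < n; ++i) k = std::max(k, node2mod[i] + 1);
    std::vector<std::vector<double> > Bcur(k, std::vector<double>(k, 0.0));
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        Bcur[node2mod[i]][node2mod[j]] += B[i][j];
    std::vector<int> agg2mod(k);
    for (int i = 0; i < k; ++i) agg2mod[i] = i;
    bool moved = true;
    while (moved) {
      std::vector<int> comm((int)Bcur.size());
      for (size_t i = 0; i < Bcur.size(); ++i) comm[i] = (int)i;
      moved = one_level(Bcur, comm, tol);
      for (int i = 0; i < k; ++i) agg2mod[i] = comm[agg2mod[i]];
      int k2 = 0;
      for (size_t i = 0; i < comm.size(); ++i) k2 = std::max(k2, comm[i] + 1);
      if (!moved || k2 == (int)Bcur.size()) break;
      std::vector<std::vector<double> > Bnew(k2, std::vector<double>(k2, 0.0));
      for (size_t i = 0; i < Bcur.size(); ++i)
        for (size_t j = 0; j < Bcur.size(); ++j)
          Bnew[comm[i]][comm[j]] += Bcur[i][j];
      Bcur = Bnew;
    }
    for (int i = 0; i < n; ++i) node2mod[i] = agg2mod[node2mod[i]];

    double q = total_gain(B, node2mod, n);
    if (q <= q_best + tol) break;
    q_best = q;
  }

  // relabel contiguously
  std::vector<int> map(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (map[node2mod[i]] < 0) map[node2mod[i]] = k++;
    node2mod[i] = map[node2mod[i]];
  }

  double q = total_gain(B, node2mod, n);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = node2mod[i] + 1;
  return List::create(_["membership"] = out, _["Q"] = q);
}

// Quality of a given partition under the same matrix (used by consensus).
// [[Rcpp::export(name = ".partition_quality_B")]]
double partition_quality_B(NumericMatrix Bmat, IntegerVector membership) {
  int n = Bmat.nrow();
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (membership[i] == membership[j]) q += Bmat(i, j);
  return q;
}
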