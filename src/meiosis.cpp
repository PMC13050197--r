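#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Forward simulation of autotetraploid bivalent meiosis for one chromosome.
//
// The four homologs are partitioned uniformly at random into two bivalents
// (three equiprobable pairings). Each bivalent transmits one chromatid:
// a random starting homolog of the pair, with homolog switches along the
// chromosome generated by a Poisson crossover process of rate 1 per Morgan
// on the transmitted chromatid. The per-interval switch probability then
// equals the Haldane recombination fraction c = (1 - exp(-2*d))/2, i.e. the
// process is exactly the no-interference Markov walk, but costs O(1) RNG
// draws per chromatid instead of one per marker interval.
//
// H:   4 x q matrix of 0/1 alleles (rows = homologs), pos: length-q Morgan
// positions (non-decreasing). Returns alleles of the two transmitted
// chromatids (n x q each) and, optionally, the homolog of origin (1-4) at
// every marker for gamete-classification tests.

static const int PAIRINGS[3][4] = {
  {0, 1, 2, 3},  // bivalents {1,2} and {3,4}
  {0, 2, 1, 3},  // bivalents {1,3} and {2,4}
  {0, 3, 1, 2}   // bivalents {1,4} and {2,3}
};

// walk one chromatid: fill alleles (and origins) for gamete i
static void walk_chromatid(const IntegerMatrix& H, const NumericVector& pos,
                           int homA, int homB, int i, IntegerMatrix& alleles,
                           IntegerMatrix* origins, double span, double pos0,
                           std::vector<double>& xo) {
  const int q = pos.size();
  int cur = (unif_rand() < 0.5) ? homA : homB;
  int other = (cur == homA) ? homB : homA;
  int k = (span > 0.0) ? (int) R::rpois(span) : 0;
  xo.clear();
  for (int j = 0; j < k; ++j) xo.push_back(pos0 + unif_rand() * span);
  std::sort(xo.begin(), xo.end());
  int nxt = 0;
  for (int m = 0; m < q; ++m) {
    while (nxt < k && xo[nxt] < pos[m]) {
      std::swap(cur, other);
      ++nxt;
    }
    alleles(i, m) = H(cur, m);
    if (origins) (*origins)(i, m) = cur + 1;
  }
}

// [[Rcpp::export(name = ".sim_gametes_chr")]]
List sim_gametes_chr(IntegerMatrix H, NumericVector pos, int n,
                     bool origins = false) {
  const int q = pos.size();
  if (H.nrow() != 4 || H.ncol() != q)
    stop("haplotype matrix must be 4 x length(pos)");
  IntegerMatrix ch1(n, q), ch2(n, q);
  IntegerMatrix o1, o2;
  if (origins) { o1 = IntegerMatrix(n, q); o2 = IntegerMatrix(n, q); }
  double pos0 = pos[0], span = pos[q - 1] - pos[0];
  std::vector<double> xo;
  xo.reserve(8);
  for (int i = 0; i < n; ++i) {
    int pr = (int) (unif_rand() * 3.0);
    if (pr > 2) pr = 2;
    const int* p = PAIRINGS[pr];
    walk_chromatid(H, pos, p[0], p[1], i, ch1, origins ? &o1 : nullptr,
                   span, pos0, xo);
    walk_chromatid(H, pos, p[2], p[3], i, ch2, origins ? &o2 : nullptr,
                   span, pos0, xo);
  }
  if (origins)
    return List::create(_["ch1"] = ch1, _["ch2"] = ch2,
                        _["o1"] = o1, _["o2"] = o2);
  return List::create(_["ch1"] = ch1, _["ch2"] = ch2);
}
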