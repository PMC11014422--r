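#include <Rcpp.h>
using namespace Rcpp;

// Batch recombination of parent pairs into offspring genomes.
//
// Row i of P1/P2 holds the two parental haplotypes for offspring i.  For each
// offspring, in this order, the kernel draws from R's global RNG:
//   1. nr ~ Binomial(L * snp_spacing - 1, r)      (crossover count, bp scale)
//   2. nr uniform bp positions on [1, L*spacing - 1], each mapped to the SNP
//      interval ceil(pos / spacing), clipped to [1, L-1]; duplicates collapse
//      to a single switch
//   3. one Uniform(0,1) draw; < 0.5 swaps the parental roles
// The offspring then starts on the (possibly swapped) first parent and
// switches parent after every breakpoint SNP.  This consumes the RNG stream
// identically to sample_crossovers() + recombine_offspring() in R.
// [[Rcpp::export]]
IntegerMatrix cpp_cross_parents(const IntegerMatrix& P1, const IntegerMatrix& P2,
                                int snp_spacing, double r) {
  const int n = P1.nrow(), L = P1.ncol();
  if (P2.nrow() != n || P2.ncol() != L)
    stop("parent matrices must have identical dimensions");
  const double nbp = (double)L * (double)snp_spacing - 1.0;
  IntegerMatrix out(n, L);
  std::vector<char> brk(L + 1, 0);

  for (int i = 0; i < n; ++i) {
    std::fill(brk.begin(), brk.end(), 0);
    int nr = (int) R::rbinom(nbp, r);
    for (int k = 0; k < nr; ++k) {
      double pos = std::floor(unif_rand() * nbp) + 1.0;  // 1 .. nbp
      int iv = (int) std::ceil(pos / (double)snp_spacing);
      if (iv < 1) iv = 1;
      if (iv > L - 1) iv = L - 1;
      brk[iv] = 1;
    }
    int cur = (unif_rand() < 0.5) ? 1 : 0;  // 1 = start on P2
    for (int l = 0; l < L; ++l) {
      out(i, l) = cur ? P2(i, l) : P1(i, l);
      if (l < L - 1 && brk[l + 1]) cur = 1 - cur;  // switch after SNP l+1 (1-based)
    }
  }
  return out;
}
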