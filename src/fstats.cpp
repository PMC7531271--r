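#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Weir & Cockerham (1984) theta for biallelic genotype data.
// Inputs are per-(population, locus) matrices: typed sample sizes n,
// derived-allele frequencies p (NA where untyped), observed heterozygote
// proportions h. Multilocus combination is the ratio of sums of the
// per-locus variance components over loci typed in both populations.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_wc(NumericMatrix n, NumericMatrix p,
                              NumericMatrix h) {
  int P = n.nrow(), L = n.ncol();
  NumericMatrix out(P, P);
  for (int i = 0; i < P - 1; ++i) {
    for (int j = i + 1; j < P; ++j) {
      double num = 0.0, den = 0.0;
      bool any = false;
      for (int l = 0; l < L; ++l) {
        double ni = n(i, l), nj = n(j, l);
        if (ni < 1.0 || nj < 1.0) continue;
        double nbar = 0.5 * (ni + nj);
        if (nbar <= 1.0) continue;
        double r = 2.0;
        double nc = (r * nbar - (ni * ni + nj * nj) / (r * nbar)) / (r - 1.0);
        double pi = p(i, l), pj = p(j, l);
        if (ISNAN(pi) || ISNAN(pj)) continue;
        double pbar = (ni * pi + nj * pj) / (r * nbar);
        double s2 = (ni * (pi - pbar) * (pi - pbar) +
                     nj * (pj - pbar) * (pj - pbar)) / ((r - 1.0) * nbar);
        double hbar = (ni * h(i, l) + nj * h(j, l)) / (r * nbar);
        double a = nbar / nc *
          (s2 - (pbar * (1.0 - pbar) - (r - 1.0) / r * s2 - hbar / 4.0) /
                    (nbar - 1.0));
        double b = nbar / (nbar - 1.0) *
          (pbar * (1.0 - pbar) - (r - 1.0) / r * s2 -
           (2.0 * nbar - 1.0) / (4.0 * nbar) * hbar);
        double c = hbar / 2.0;
        num += a;
        den += a + b + c;
        any = true;
      }
      double th = (any && den != 0.0) ? num / den : NA_REAL;
      out(i, j) = th;
      out(j, i) = th;
    }
  }
  return out;
}

// Haploid allele-count analogue for pooled data: per-locus MSP/MSG moment
// components from haploid totals `tot` and frequencies `p`.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_wc_counts(NumericMatrix tot, NumericMatrix p) {
  int P = tot.nrow(), L = tot.ncol();
  NumericMatrix out(P, P);
  for (int i = 0; i < P - 1; ++i) {
    for (int j = i + 1; j < P; ++j) {
      double num = 0.0, den = 0.0;
      bool any = false;
      for (int l = 0; l < L; ++l) {
        double ti = tot(i, l), tj = tot(j, l);
        if (ti < 1.0 || tj < 1.0 || ti + tj <= 2.0) continue;
        double pi = p(i, l), pj = p(j, l);
        if (ISNAN(pi) || ISNAN(pj)) continue;
        double T = ti + tj;
        double pw = (ti * pi + tj * pj) / T;
        double msp = ti * (pi - pw) * (pi - pw) + tj * (pj - pw) * (pj - pw);
        double msg = (ti * pi * (1.0 - pi) + tj * pj * (1.0 - pj)) /
                     (ti + tj - 2.0);
        double nc = T - (ti * ti + tj * tj) / T;
        num += msp - msg;
        den += msp + (nc - 1.0) * msg;
        any = true;
      }
      double th = (any && den != 0.0) ? num / den : NA_REAL;
      out(i, j) = th;
      out(j, i) = th;
    }
  }
  return out;
}
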