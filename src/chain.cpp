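#include <Rcpp.h>
using namespace Rcpp;

// log(exp(a) + exp(b)) without overflow; -Inf-safe
static inline double lse2(double a, double b) {
  double m = a > b ? a : b;
  if (m == R_NegInf) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Forward recursion of the four-state domain chain over per-bin state
// scores S (n x 4, states sb, i, eb, e). Returns log Z.
// Transitions: sb<-{eb,e}, i<-{sb,i}, eb<-{sb,i}, e<-{eb,e};
// start in {sb,e} (via the virtual initial gap state), end in {eb,e}.
// [[Rcpp::export(name = ".logZChain")]]
double logZChain(NumericMatrix S) {
  int n = S.nrow();
  double p0 = R_NegInf, p1 = R_NegInf, p2 = R_NegInf, p3 = 0.0;
  for (int v = 0; v < n; ++v) {
    double fromGap = lse2(p2, p3);  // eb or e before
    double fromDom = lse2(p0, p1);  // sb or i before
    double a0 = fromGap + S(v, 0);
    double a1 = fromDom + S(v, 1);
    double a2 = fromDom + S(v, 2);
    double a3 = fromGap + S(v, 3);
    p0 = a0; p1 = a1; p2 = a2; p3 = a3;
  }
  return lse2(p2, p3);
}

// Full forward and backward log variables for the same chain.
// [[Rcpp::export(name = ".fbChain")]]
List fbChain(NumericMatrix S) {
  int n = S.nrow();
  NumericMatrix la(n, 4), lb(n, 4);
  double p0 = R_NegInf, p1 = R_NegInf, p2 = R_NegInf, p3 = 0.0;
  for (int v = 0; v < n; ++v) {
    double fromGap = lse2(p2, p3);
    double fromDom = lse2(p0, p1);
    la(v, 0) = fromGap + S(v, 0);
    la(v, 1) = fromDom + S(v, 1);
    la(v, 2) = fromDom + S(v, 2);
    la(v, 3) = fromGap + S(v, 3);
    p0 = la(v, 0); p1 = la(v, 1); p2 = la(v, 2); p3 = la(v, 3);
  }
  lb(n - 1, 0) = R_NegInf;
  lb(n - 1, 1) = R_NegInf;
  lb(n - 1, 2) = 0.0;
  lb(n - 1, 3) = 0.0;
  for (int v = n - 2; v >= 0; --v) {
    double n0 = lb(v + 1, 0) + S(v + 1, 0);
    double n1 = lb(v + 1, 1) + S(v + 1, 1);
    double n2 = lb(v + 1, 2) + S(v + 1, 2);
    double n3 = lb(v + 1, 3) + S(v + 1, 3);
    double toDom = lse2(n1, n2);  // successors of sb and i
    double toGap = lse2(n0, n3);  // successors of eb and e
    lb(v, 0) = toDom;
    lb(v, 1) = toDom;
    lb(v, 2) = toGap;
    lb(v, 3) = toGap;
  }
  double logZ = lse2(la(n - 1, 2), la(n - 1, 3));
  return List::create(_["la"] = la, _["lb"] = lb, _["logZ"] = logZ);
}
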