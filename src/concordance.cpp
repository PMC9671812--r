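#include <Rcpp.h>
using namespace Rcpp;

// Harrell's C by exhaustive pair enumeration.
//
// A pair is comparable iff the member with the earlier time had an event;
// with tied times an event/censored pair is comparable (the censored member
// is known to have survived at least as long), a tied event/event pair is
// not ordered and is skipped. Tied scores count 0.5.
//
// [[Rcpp::export]]
List cpp_concordance(NumericVector time, IntegerVector event,
                     NumericVector score) {
  const R_xlen_t n = time.size();
  if (event.size() != n || score.size() != n)
    stop("time, event and score must have equal length");
  double conc = 0.0, tied = 0.0;
  double comparable = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      R_xlen_t a, b; // a = earlier, must be an event
      if (time[i] < time[j]) {
        if (!event[i]) continue;
        a = i; b = j;
      } else if (time[j] < time[i]) {
        if (!event[j]) continue;
        a = j; b = i;
      } else { // tied times
        if (event[i] && !event[j]) { a = i; b = j; }
        else if (event[j] && !event[i]) { a = j; b = i; }
        else continue;
      }
      comparable += 1.0;
      if (score[a] > score[b]) conc += 1.0;
      else if (score[a] == score[b]) tied += 1.0;
    }
  }
  double c = comparable > 0 ? (conc + 0.5 * tied) / comparable : NA_REAL;
  return List::create(_["concordant"] = conc, _["tied"] = tied,
                      _["comparable"] = comparable, _["cindex"] = c);
}
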