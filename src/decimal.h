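// Fixed-precision decimal floating-point arithmetic.
//
// Values are sign * coefficient * 10^e with the coefficient held as base-1e9
// limbs in a fixed-size array (no heap allocation on the arithmetic path).
// Every operation rounds its exact result to the context precision with
// round-half-even, so a context of N significant digits behaves like an
// IEEE-754-2008 style decimal format of N digits.  Supported context
// precision: 1..50 significant digits (elementary functions use up to 10
// internal guard digits, which the limb capacity below accommodates).
#ifndef TECGEN_DECIMAL_H
#define TECGEN_DECIMAL_H

#include <cstdint>
#include <cstring>
#include <string>

namespace tecdec {

constexpr uint32_t BASE = 1000000000u;  // 1e9
constexpr int LIMB_DIGITS = 9;
constexpr int LMAX = 18;                // 162 decimal digits of capacity
constexpr int MAX_PREC = 50;            // user-facing context limit
constexpr int MAX_GUARD = 10;

// error codes
enum DecErr { DEC_OK = 0, DEC_DIV0 = 1, DEC_DOMAIN = 2, DEC_OVERFLOW = 3,
              DEC_PARSE = 4, DEC_CAPACITY = 5 };

struct Dec {
  int sign;                // -1, 0, +1 (0 iff value is zero, then n == 0)
  int n;                   // limbs in use, little-endian
  long long e;             // power-of-ten exponent of the coefficient
  uint32_t d[LMAX];
  Dec() : sign(0), n(0), e(0) {}
};

int nd(const Dec& a);                    // significant digits of coefficient
void trim(Dec& a);
int cmp(const Dec& a, const Dec& b);     // -1/0/+1, numeric compare
bool is_int(const Dec& a);
long long to_ll(const Dec& a, int* err); // exact integer value if |.| < 2^62

Dec from_ll(long long v);
Dec from_string(const char* s, int prec, int* err);
std::string to_string(const Dec& a);
double to_double(const Dec& a);

void round_to(Dec& a, int prec, bool sticky);

Dec add(const Dec& a, const Dec& b, int prec);
Dec sub(const Dec& a, const Dec& b, int prec);
Dec mul(const Dec& a, const Dec& b, int prec);
Dec div(const Dec& a, const Dec& b, int prec, int* err);
Dec neg(const Dec& a);

Dec dsqrt(const Dec& a, int prec, int* err);
Dec dexp(const Dec& a, int prec, int* err);
Dec dln(const Dec& a, int prec, int* err);
Dec powi(const Dec& a, long long k, int prec, int* err);
Dec dpow(const Dec& a, const Dec& b, int prec, int* err);

}  // namespace tecdec

#endif
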