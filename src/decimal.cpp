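#include "decimal.h"

#include <cmath>
#include <cstdio>
#include <cstdlib>
#include <vector>

namespace tecdec {

static const uint32_t P10[10] = {1u, 10u, 100u, 1000u, 10000u, 100000u,
                                 1000000u, 10000000u, 100000000u, 1000000000u};

static int limb_digits(uint32_t x) {
  int k = 1;
  while (x >= P10[k] && k < 9) ++k;
  return x == 0 ? 1 : k;
}

int nd(const Dec& a) {
  if (a.n == 0) return 0;
  return (a.n - 1) * LIMB_DIGITS + limb_digits(a.d[a.n - 1]);
}

void trim(Dec& a) {
  while (a.n > 0 && a.d[a.n - 1] == 0) --a.n;
  if (a.n == 0) { a.sign = 0; a.e = 0; }
}

static int get_digit(const Dec& a, long long i) {
  // digit i of the coefficient, 0 = least significant
  if (i < 0) return 0;
  long long limb = i / LIMB_DIGITS;
  if (limb >= a.n) return 0;
  return (int)((a.d[limb] / P10[i % LIMB_DIGITS]) % 10u);
}

// multiply coefficient by 10^k (k >= 0); exponent adjusted so value unchanged
static void shift_up(Dec& a, int k) {
  if (a.n == 0 || k <= 0) return;
  int q = k / LIMB_DIGITS, r = k % LIMB_DIGITS;
  if (r > 0) {
    uint64_t carry = 0;
    for (int i = 0; i < a.n; ++i) {
      uint64_t v = (uint64_t)a.d[i] * P10[r] + carry;
      a.d[i] = (uint32_t)(v % BASE);
      carry = v / BASE;
    }
    if (carry) a.d[a.n++] = (uint32_t)carry;
  }
  if (q > 0) {
    for (int i = a.n - 1; i >= 0; --i) a.d[i + q] = a.d[i];
    for (int i = 0; i < q; ++i) a.d[i] = 0;
    a.n += q;
  }
  a.e -= k;
}

// divide coefficient by 10^k, discarding the remainder; exponent adjusted
static void shift_down(Dec& a, long long k) {
  if (a.n == 0 || k <= 0) return;
  if (k >= (long long)nd(a)) { a.n = 0; trim(a); a.e += k; return; }
  long long q = k / LIMB_DIGITS, r = k % LIMB_DIGITS;
  if (q > 0) {
    for (long long i = q; i < a.n; ++i) a.d[i - q] = a.d[i];
    a.n -= (int)q;
  }
  if (r > 0) {
    uint64_t rem = 0;
    for (int i = a.n - 1; i >= 0; --i) {
      uint64_t v = rem * BASE + a.d[i];
      a.d[i] = (uint32_t)(v / P10[r]);
      rem = v % P10[r];
    }
  }
  trim(a);
  a.e += k;
}

static void increment_coef(Dec& a) {
  uint32_t carry = 1;
  for (int i = 0; i < a.n && carry; ++i) {
    a.d[i] += carry;
    if (a.d[i] >= BASE) { a.d[i] -= BASE; carry = 1; } else carry = 0;
  }
  if (carry) a.d[a.n++] = 1;
}

void round_to(Dec& a, int prec, bool sticky) {
  if (a.n == 0) return;
  long long digits = nd(a);
  long long k = digits - prec;
  if (k <= 0) return;  // sticky alone never flips a kept digit (rd == 0)
  int rd = get_digit(a, k - 1);
  bool st = sticky;
  for (long long i = 0; i < k - 1 && !st; ++i)
    if (get_digit(a, i) != 0) st = true;
  shift_down(a, k);
  if (a.n == 0) {
    // all digits dropped: coefficient was < 10^k
    if (rd > 5 || (rd == 5 && st)) { a.d[0] = 1; a.n = 1; }
    else { a.sign = 0; a.e = 0; return; }
  } else if (rd > 5 || (rd == 5 && (st || (get_digit(a, 0) & 1)))) {
    increment_coef(a);
    if (nd(a) > prec) shift_down(a, 1);  // 99..9 + 1 rolled over
  }
  trim(a);
}

int cmpmag_aligned(const Dec& a, const Dec& b) {
  // coefficients at equal exponents
  if (a.n != b.n) return a.n < b.n ? -1 : 1;
  for (int i = a.n - 1; i >= 0; --i)
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  return 0;
}

static void addmag_aligned(Dec& a, const Dec& b) {
  uint32_t carry = 0;
  int n = a.n > b.n ? a.n : b.n;
  for (int i = 0; i < n; ++i) {
    uint32_t x = (i < a.n ? a.d[i] : 0) + (i < b.n ? b.d[i] : 0) + carry;
    if (x >= BASE) { x -= BASE; carry = 1; } else carry = 0;
    a.d[i] = x;
  }
  a.n = n;
  if (carry) a.d[a.n++] = 1;
}

static void submag_aligned(Dec& a, const Dec& b) {
  // requires |a| >= |b|
  int borrow = 0;
  for (int i = 0; i < a.n; ++i) {
    int64_t x = (int64_t)a.d[i] - (i < b.n ? b.d[i] : 0) - borrow;
    if (x < 0) { x += BASE; borrow = 1; } else borrow = 0;
    a.d[i] = (uint32_t)x;
  }
  trim(a);
}

Dec neg(const Dec& a) { Dec r = a; r.sign = -r.sign; return r; }

Dec add(const Dec& a0, const Dec& b0, int prec) {
  if (a0.n == 0) { Dec r = b0; round_to(r, prec, false); return r; }
  if (b0.n == 0) { Dec r = a0; round_to(r, prec, false); return r; }
  Dec a = a0, b = b0;
  long long top_a = a.e + nd(a), top_b = b.e + nd(b);
  long long top = top_a > top_b ? top_a : top_b;
  // replace a negligible operand with a same-signed sentinel just below the
  // rounding horizon so sticky/round digits come out right without huge shifts
  long long floor_e = top - (prec + 2 * LIMB_DIGITS);
  if (top_a < floor_e) { a.n = 1; a.d[0] = 1; a.e = floor_e - 2; }
  if (top_b < floor_e) { b.n = 1; b.d[0] = 1; b.e = floor_e - 2; }
  long long emin = a.e < b.e ? a.e : b.e;
  shift_up(a, (int)(a.e - emin));
  shift_up(b, (int)(b.e - emin));
  Dec r;
  if (a.sign == b.sign) {
    r = a;
    addmag_aligned(r, b);
  } else {
    int c = cmpmag_aligned(a, b);
    if (c == 0) return Dec();
    if (c > 0) { r = a; submag_aligned(r, b); }
    else { r = b; submag_aligned(r, a); }
  }
  round_to(r, prec, false);
  return r;
}

Dec sub(const Dec& a, const Dec& b, int prec) { return add(a, neg(b), prec); }

Dec mul(const Dec& a, const Dec& b, int prec) {
  if (a.n == 0 || b.n == 0) return Dec();
  uint64_t acc[2 * LMAX + 1] = {0};
  int rn = a.n + b.n;
  for (int i = 0; i < a.n; ++i) {
    uint64_t carry = 0;
    for (int j = 0; j < b.n; ++j) {
      uint64_t v = acc[i + j] + (uint64_t)a.d[i] * b.d[j] + carry;
      acc[i + j] = v % BASE;
      carry = v / BASE;
    }
    int j = i + b.n;
    while (carry) { uint64_t v = acc[j] + carry; acc[j] = v % BASE; carry = v / BASE; ++j; }
  }
  Dec r;
  r.sign = a.sign * b.sign;
  r.e = a.e + b.e;
  r.n = rn + 1 <= 2 * LMAX + 1 ? rn + 1 : 2 * LMAX + 1;
  // copy (result limbs fit LMAX after rounding; raw product may not, so round
  // from a temporary when needed)
  if (r.n > LMAX) {
    // drop whole low limbs first, tracking sticky
    int dropl = r.n - LMAX;
    bool st = false;
    for (int i = 0; i < dropl; ++i) if (acc[i]) st = true;
    for (int i = 0; i < LMAX; ++i) r.d[i] = (uint32_t)acc[i + dropl];
    r.n = LMAX;
    r.e += (long long)dropl * LIMB_DIGITS;
    trim(r);
    round_to(r, prec, st);
    return r;
  }
  for (int i = 0; i < r.n; ++i) r.d[i] = (uint32_t)acc[i];
  trim(r);
  round_to(r, prec, false);
  return r;
}

// ---------------------------------------------------------------------------
// big-integer long division helpers (schoolbook with estimated quotient limbs)

struct BigInt {
  int n;
  uint32_t d[2 * LMAX];
};

// compare the limb segment a[off .. off+len-1] (zero-extended) with t[0..len-1]
static int seg_cmp(const BigInt& a, int off, const uint32_t* t, int len) {
  for (int i = len - 1; i >= 0; --i) {
    uint32_t av = (off + i < a.n) ? a.d[off + i] : 0;
    if (av != t[i]) return av < t[i] ? -1 : 1;
  }
  return 0;
}

// a[off ..] -= t[0..len-1]; caller guarantees the segment is >= t
static void seg_sub(BigInt& a, int off, const uint32_t* t, int len) {
  int borrow = 0;
  for (int i = 0; i < len; ++i) {
    uint32_t av = (off + i < a.n) ? a.d[off + i] : 0;
    int64_t x = (int64_t)av - t[i] - borrow;
    if (x < 0) { x += BASE; borrow = 1; } else borrow = 0;
    if (off + i < a.n) a.d[off + i] = (uint32_t)x;
  }
}

// t[0..n] -= d[0..n-1] (in place, t is non-negative and >= d)
static void arr_sub(uint32_t* t, const uint32_t* d, int dn, int tn) {
  int borrow = 0;
  for (int i = 0; i < tn; ++i) {
    int64_t x = (int64_t)t[i] - (i < dn ? d[i] : 0) - borrow;
    if (x < 0) { x += BASE; borrow = 1; } else borrow = 0;
    t[i] = (uint32_t)x;
  }
}

Dec div(const Dec& a, const Dec& b, int prec, int* err) {
  if (b.n == 0) { *err = DEC_DIV0; return Dec(); }
  if (a.n == 0) return Dec();
  // scale the numerator so the integer quotient has prec + 3 or so digits
  int want = prec + 3;
  int s = nd(b) + want - nd(a);
  if (s < 0) s = 0;
  Dec as = a;
  if (s > 0 && nd(as) + s > (2 * LMAX - 2) * LIMB_DIGITS) { *err = DEC_CAPACITY; return Dec(); }
  // build numerator limbs (shift by s digits)
  BigInt N; N.n = 0;
  {
    Dec tmp = as;
    // emulate shift_up with the larger BigInt capacity
    int q = s / LIMB_DIGITS, r = s % LIMB_DIGITS;
    uint64_t carry = 0;
    uint32_t buf[2 * LMAX] = {0};
    for (int i = 0; i < tmp.n; ++i) {
      uint64_t v = (uint64_t)tmp.d[i] * P10[r] + carry;
      buf[i] = (uint32_t)(v % BASE);
      carry = v / BASE;
    }
    int bn = tmp.n;
    if (carry) buf[bn++] = (uint32_t)carry;
    for (int i = bn - 1; i >= 0; --i) N.d[i + q] = buf[i];
    for (int i = 0; i < q; ++i) N.d[i] = 0;
    N.n = bn + q;
  }
  BigInt D; D.n = b.n;
  for (int i = 0; i < b.n; ++i) D.d[i] = b.d[i];
  // normalize: scale both so the top divisor limb is >= BASE/2 (keeps the
  // estimated quotient limb within 2 of the true one)
  {
    uint64_t m = BASE / (uint64_t)(D.d[D.n - 1] + 1);
    if (m > 1) {
      uint64_t carry = 0;
      for (int i = 0; i < D.n; ++i) {
        uint64_t v = (uint64_t)D.d[i] * m + carry;
        D.d[i] = (uint32_t)(v % BASE); carry = v / BASE;
      }
      if (carry) D.d[D.n++] = (uint32_t)carry;
      carry = 0;
      for (int i = 0; i < N.n; ++i) {
        uint64_t v = (uint64_t)N.d[i] * m + carry;
        N.d[i] = (uint32_t)(v % BASE); carry = v / BASE;
      }
      if (carry) N.d[N.n++] = (uint32_t)carry;
    }
  }
  int qn = N.n - D.n + 1;
  if (qn < 1) qn = 1;
  uint32_t qd[2 * LMAX] = {0};
  uint64_t dtop = D.d[D.n - 1];
  int seg = D.n + 1;
  for (int j = qn - 1; j >= 0; --j) {
    // estimate quotient limb from the top two live limbs of the remainder;
    // with a normalized divisor the estimate overshoots by at most 2
    uint64_t hi = (j + D.n < N.n) ? N.d[j + D.n] : 0;
    uint64_t lo = (j + D.n - 1 < N.n) ? N.d[j + D.n - 1] : 0;
    uint64_t qhat = (hi * BASE + lo) / dtop;
    if (qhat >= BASE) qhat = BASE - 1;
    if (qhat == 0) { qd[j] = 0; continue; }
    // t = D * qhat over seg limbs
    uint32_t t[2 * LMAX + 1] = {0};
    uint64_t carry = 0;
    for (int i = 0; i < D.n; ++i) {
      uint64_t v = (uint64_t)D.d[i] * qhat + carry;
      t[i] = (uint32_t)(v % BASE);
      carry = v / BASE;
    }
    t[D.n] = (uint32_t)carry;
    while (qhat > 0 && seg_cmp(N, j, t, seg) < 0) {
      --qhat;
      arr_sub(t, D.d, D.n, seg);
    }
    seg_sub(N, j, t, seg);
    qd[j] = (uint32_t)qhat;
  }
  // remainder nonzero?
  bool rem = false;
  for (int i = 0; i < N.n; ++i) if (N.d[i]) { rem = true; break; }
  Dec r;
  r.sign = a.sign * b.sign;
  int rn = qn;
  while (rn > 1 && qd[rn - 1] == 0) --rn;
  if (rn > LMAX) { *err = DEC_CAPACITY; return Dec(); }
  for (int i = 0; i < rn; ++i) r.d[i] = qd[i];
  r.n = rn;
  trim(r);
  if (r.n == 0) { r.e = 0; return r; }
  r.e = (a.e - s) - b.e;
  round_to(r, prec, rem);
  return r;
}

int cmp(const Dec& a, const Dec& b) {
  if (a.sign != b.sign) return a.sign < b.sign ? -1 : 1;
  if (a.sign == 0) return 0;
  int mag;
  long long top_a = a.e + nd(a), top_b = b.e + nd(b);
  if (top_a != top_b) mag = top_a < top_b ? -1 : 1;
  else {
    // compare digit by digit from the top
    long long ndig = nd(a) > nd(b) ? nd(a) : nd(b);
    mag = 0;
    for (long long i = 1; i <= ndig; ++i) {
      int da = get_digit(a, nd(a) - i);
      int db = get_digit(b, nd(b) - i);
      if (da != db) { mag = da < db ? -1 : 1; break; }
    }
  }
  return a.sign > 0 ? mag : -mag;
}

bool is_int(const Dec& a) {
  if (a.n == 0) return true;
  if (a.e >= 0) return true;
  if (-a.e >= nd(a) + 1) {
    // fractional unless all low digits zero
  }
  for (long long i = 0; i < -a.e; ++i)
    if (get_digit(a, i) != 0) return false;
  return true;
}

long long to_ll(const Dec& a, int* err) {
  if (a.n == 0) return 0;
  if (!is_int(a) || a.e + nd(a) > 18) { *err = DEC_DOMAIN; return 0; }
  long long v = 0;
  for (int i = a.n - 1; i >= 0; --i) v = v * BASE + a.d[i];
  for (long long k = 0; k < a.e; ++k) v *= 10;
  if (a.e < 0) for (long long k = 0; k < -a.e; ++k) v /= 10;
  return a.sign * v;
}

Dec from_ll(long long v) {
  Dec r;
  if (v == 0) return r;
  r.sign = v < 0 ? -1 : 1;
  unsigned long long u = v < 0 ? (unsigned long long)(-(v + 1)) + 1ull : (unsigned long long)v;
  while (u) { r.d[r.n++] = (uint32_t)(u % BASE); u /= BASE; }
  return r;
}

Dec from_string(const char* s, int prec, int* err) {
  Dec r;
  const char* p = s;
  while (*p == ' ' || *p == '\t') ++p;
  int sign = 1;
  if (*p == '+') ++p;
  else if (*p == '-') { sign = -1; ++p; }
  std::string digits;
  long long frac = 0;
  bool seen_digit = false, seen_dot = false;
  for (; *p; ++p) {
    if (*p >= '0' && *p <= '9') {
      digits.push_back(*p);
      if (seen_dot) ++frac;
      seen_digit = true;
    } else if (*p == '.' && !seen_dot) {
      seen_dot = true;
    } else break;
  }
  long long ex = 0;
  if ((*p == 'e' || *p == 'E') && seen_digit) {
    ++p;
    int es = 1;
    if (*p == '+') ++p; else if (*p == '-') { es = -1; ++p; }
    if (!(*p >= '0' && *p <= '9')) { *err = DEC_PARSE; return r; }
    while (*p >= '0' && *p <= '9') { ex = ex * 10 + (*p - '0'); ++p; }
    ex *= es;
  }
  while (*p == ' ' || *p == '\t') ++p;
  if (!seen_digit || *p != '\0') { *err = DEC_PARSE; return r; }
  // strip leading zeros
  size_t lead = 0;
  while (lead + 1 < digits.size() && digits[lead] == '0') ++lead;
  digits = digits.substr(lead);
  // cap very long literals, tracking sticky
  bool st = false;
  int cap = (LMAX - 2) * LIMB_DIGITS;
  if ((int)digits.size() > cap) {
    for (size_t i = cap; i < digits.size(); ++i)
      if (digits[i] != '0') st = true;
    frac -= (long long)(digits.size() - cap);
    digits = digits.substr(0, cap);
  }
  if (digits == "0") { if (st) { /* tiny nonzero rounds to 0 at any prec */ } return r; }
  r.sign = sign;
  r.e = ex - frac;
  // build limbs from the digit string
  int ndg = (int)digits.size();
  r.n = (ndg + LIMB_DIGITS - 1) / LIMB_DIGITS;
  for (int i = 0; i < r.n; ++i) r.d[i] = 0;
  for (int i = 0; i < ndg; ++i) {
    int pos = ndg - 1 - i;                 // 0 = least significant
    int limb = pos / LIMB_DIGITS;
    r.d[limb] += (uint32_t)(digits[i] - '0') * P10[pos % LIMB_DIGITS];
  }
  trim(r);
  round_to(r, prec, st);
  return r;
}

std::string to_string(const Dec& a) {
  if (a.n == 0) return "0";
  std::string digits;
  digits.reserve(nd(a));
  for (long long i = nd(a) - 1; i >= 0; --i)
    digits.push_back((char)('0' + get_digit(a, i)));
  long long adj = a.e + (long long)digits.size() - 1;  // exponent of lead digit
  std::string out;
  if (a.sign < 0) out.push_back('-');
  if (adj >= -6 && adj < 21) {
    if (a.e >= 0) {
      out += digits;
      for (long long i = 0; i < a.e; ++i) out.push_back('0');
    } else if (adj >= 0) {
      out += digits.substr(0, (size_t)(adj + 1));
      std::string fr = digits.substr((size_t)(adj + 1));
      if (!fr.empty()) { out.push_back('.'); out += fr; }
    } else {
      out += "0.";
      for (long long i = 0; i < -adj - 1; ++i) out.push_back('0');
      out += digits;
    }
  } else {
    out.push_back(digits[0]);
    if (digits.size() > 1) { out.push_back('.'); out += digits.substr(1); }
    out.push_back('e');
    char buf[32];
    std::snprintf(buf, sizeof(buf), "%lld", adj);
    out += buf;
  }
  return out;
}

double to_double(const Dec& a) {
  if (a.n == 0) return 0.0;
  // round-trip through text for correctly rounded conversion
  std::string digits;
  int take = nd(a) < 25 ? nd(a) : 25;
  for (int i = 0; i < take; ++i)
    digits.push_back((char)('0' + get_digit(a, nd(a) - 1 - i)));
  long long adj = a.e + nd(a) - 1;
  char buf[80];
  std::snprintf(buf, sizeof(buf), "%s0.%se%lld", a.sign < 0 ? "-" : "",
                digits.c_str(), adj + 1);
  return std::strtod(buf, nullptr);
}

// ---------------------------------------------------------------------------
// elementary functions

Dec dsqrt(const Dec& a, int prec, int* err) {
  if (a.sign < 0) { *err = DEC_DOMAIN; return Dec(); }
  if (a.n == 0) return Dec();
  int wp = prec + 8 > MAX_PREC + MAX_GUARD ? MAX_PREC + MAX_GUARD : prec + 8;
  // seed from double of the mantissa to keep exponents in range
  long long adj = a.e + nd(a) - 1;
  long long half = adj / 2;                   // sqrt(m * 10^adj)
  Dec m = a; m.e -= 2 * half;                 // m in [1, 100)
  double seed = std::sqrt(to_double(m));
  char buf[40];
  std::snprintf(buf, sizeof(buf), "%.17g", seed);
  int perr = DEC_OK;
  Dec x = from_string(buf, wp, &perr);
  Dec halfc = from_string("0.5", wp, &perr);
  for (int it = 0; it < 4; ++it) {
    int derr = DEC_OK;
    Dec q = div(m, x, wp, &derr);
    if (derr != DEC_OK) { *err = derr; return Dec(); }
    x = mul(add(x, q, wp), halfc, wp);
  }
  x.e += half;
  round_to(x, prec, true);
  return x;
}

Dec dexp(const Dec& a, int prec, int* err) {
  int wp = prec + MAX_GUARD;
  if (wp > MAX_PREC + MAX_GUARD) wp = MAX_PREC + MAX_GUARD;
  Dec one = from_ll(1);
  if (a.n == 0) return one;
  double ad = to_double(a);
  if (ad > 2.3e6) { *err = DEC_OVERFLOW; return Dec(); }
  if (ad < -2.3e6) return Dec();  // underflows to zero
  int k = 0;
  double mag = std::fabs(ad);
  while (mag > 0.0625 && k < 40) { mag *= 0.5; ++k; }
  int derr = DEC_OK;
  Dec r = k > 0 ? div(a, from_ll(1ll << k), wp, &derr) : a;
  // Taylor series around 0
  Dec sum = one, term = one;
  long long sum_top = 1;
  for (long long n = 1; n < 200; ++n) {
    term = mul(term, r, wp);
    term = div(term, from_ll(n), wp, &derr);
    if (term.n == 0) break;
    sum = add(sum, term, wp);
    long long ttop = term.e + nd(term);
    if (ttop < sum.e + nd(sum) - (wp + 4)) break;
    (void)sum_top;
  }
  for (int i = 0; i < k; ++i) sum = mul(sum, sum, wp);
  round_to(sum, prec, true);
  return sum;
}

// ln of m (any positive value) via sqrt reduction + atanh series, at wp digits
static Dec ln_core(Dec m, int wp, int* err) {
  int derr = DEC_OK;
  Dec one = from_ll(1);
  int cnt = 0;
  Dec lim = from_string("1.2", wp, &derr);
  while (cmp(m, lim) > 0 && cnt < 80) { m = dsqrt(m, wp, &derr); ++cnt; }
  if (derr != DEC_OK) { *err = derr; return Dec(); }
  Dec y = div(sub(m, one, wp), add(m, one, wp), wp, &derr);
  if (y.n == 0) return Dec();
  Dec y2 = mul(y, y, wp);
  Dec term = y, s = y;
  for (long long n = 3; n < 400; n += 2) {
    term = mul(term, y2, wp);
    Dec t = div(term, from_ll(n), wp, &derr);
    if (t.n == 0) break;
    s = add(s, t, wp);
    if (t.e + nd(t) < s.e + nd(s) - (wp + 4)) break;
  }
  Dec r = mul(s, from_ll(2), wp);
  if (cnt > 0) r = mul(r, from_ll(1ll << (cnt < 62 ? cnt : 62)), wp);
  return r;
}

Dec dln(const Dec& a, int prec, int* err) {
  if (a.sign <= 0) { *err = DEC_DOMAIN; return Dec(); }
  int wp = prec + MAX_GUARD;
  if (wp > MAX_PREC + MAX_GUARD) wp = MAX_PREC + MAX_GUARD;
  long long adj = a.e + nd(a) - 1;
  Dec m = a; m.e -= adj;  // m in [1, 10)
  Dec one = from_ll(1);
  Dec lnm = (cmp(m, one) == 0) ? Dec() : ln_core(m, wp, err);
  Dec r = lnm;
  if (adj != 0) {
    Dec ln10 = ln_core(from_ll(10), wp, err);
    r = add(lnm, mul(from_ll(adj), ln10, wp), wp);
  }
  round_to(r, prec, true);
  return r;
}

Dec powi(const Dec& a, long long k, int prec, int* err) {
  if (k == 0) return from_ll(1);
  bool inv = k < 0;
  unsigned long long kk = inv ? (unsigned long long)(-(k + 1)) + 1ull : (unsigned long long)k;
  Dec base = a, acc = from_ll(1);
  bool acc_set = false;
  while (kk) {
    if (kk & 1ull) {
      acc = acc_set ? mul(acc, base, prec) : base;
      acc_set = true;
    }
    kk >>= 1;
    if (kk) base = mul(base, base, prec);
  }
  if (inv) {
    int derr = DEC_OK;
    acc = div(from_ll(1), acc, prec, &derr);
    if (derr != DEC_OK) { *err = derr; return Dec(); }
  }
  return acc;
}

Dec dpow(const Dec& a, const Dec& b, int prec, int* err) {
  if (is_int(b)) {
    int ierr = DEC_OK;
    long long k = to_ll(b, &ierr);
    if (ierr == DEC_OK) return powi(a, k, prec, err);
  }
  if (a.sign < 0) { *err = DEC_DOMAIN; return Dec(); }
  if (a.n == 0) return Dec();  // 0^b with b non-integer positive -> 0
  int wp = prec + 6 > MAX_PREC + MAX_GUARD ? MAX_PREC + MAX_GUARD : prec + 6;
  Dec l = dln(a, wp, err);
  if (*err != DEC_OK) return Dec();
  Dec r = dexp(mul(b, l, wp), wp, err);
  round_to(r, prec, true);
  return r;
}

}  // namespace tecdec
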