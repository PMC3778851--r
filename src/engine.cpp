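// Stack-machine evaluator and time-stepping driver for flat programs.
//
// A flat program arrives from R as concatenated postfix bytecode plus an
// assignment table (code segment + target slot).  The same code runs in two
// arithmetic modes: IEEE double and fixed-precision decimal (see decimal.h),
// selected by `digits` (0 = double).
#include <Rcpp.h>

#include <cmath>
#include <cstring>
#include <vector>

#include "decimal.h"

using namespace Rcpp;
using tecdec::Dec;

enum Op {
  OP_LOAD = 1, OP_LIT = 2, OP_ADD = 3, OP_SUB = 4, OP_MUL = 5, OP_DIV = 6,
  OP_POW = 7, OP_NEG = 8, OP_EXP = 9, OP_LN = 10, OP_LOG10 = 11, OP_LOGB = 12,
  OP_ROOT2 = 13, OP_ROOTN = 14, OP_POWI = 15, OP_LT = 16, OP_LE = 17,
  OP_GT = 18, OP_GE = 19, OP_EQ = 20, OP_NEQ = 21, OP_JZ = 22, OP_JMP = 23,
  OP_NOCASE = 24
};

struct EvalStatus {
  int err = 0;           // 0 ok; otherwise a DecErr-compatible code
  const char* what = ""; // short diagnostic
};

// ---------------------------------------------------------------------------
// arithmetic adapters

struct DoubleArith {
  typedef double num;
  int prec;
  EvalStatus* st;
  num lit(const std::string& s) { return std::strtod(s.c_str(), nullptr); }
  num add(num a, num b) { return a + b; }
  num sub(num a, num b) { return a - b; }
  num mul(num a, num b) { return a * b; }
  num div(num a, num b) {
    if (b == 0.0) { st->err = tecdec::DEC_DIV0; st->what = "division by zero"; return 0.0; }
    return a / b;
  }
  num neg(num a) { return -a; }
  num expf_(num a) { return std::exp(a); }
  num lnf(num a) {
    if (a <= 0.0) { st->err = tecdec::DEC_DOMAIN; st->what = "log of non-positive value"; return 0.0; }
    return std::log(a);
  }
  num log10f_(num a) {
    if (a <= 0.0) { st->err = tecdec::DEC_DOMAIN; st->what = "log of non-positive value"; return 0.0; }
    return std::log10(a);
  }
  num logb(num base, num x) { return lnf(x) / lnf(base); }
  num sqrtf_(num a) {
    if (a < 0.0) { st->err = tecdec::DEC_DOMAIN; st->what = "square root of negative value"; return 0.0; }
    return std::sqrt(a);
  }
  num rootn(num k, num x) {
    long long ki = (long long)std::llround(k);
    if (std::fabs(k - (double)ki) < 1e-12 && (ki % 2 != 0) && x < 0.0)
      return -std::pow(-x, 1.0 / k);
    if (x < 0.0) { st->err = tecdec::DEC_DOMAIN; st->what = "even root of negative value"; return 0.0; }
    return std::pow(x, 1.0 / k);
  }
  num pw(num a, num b) {
    double r = std::pow(a, b);
    if (std::isnan(r) && !std::isnan(a) && !std::isnan(b)) {
      st->err = tecdec::DEC_DOMAIN; st->what = "power domain error";
    }
    return r;
  }
  num powi(num a, long long k) { return std::pow(a, (double)k); }
  int cmp(num a, num b) { return a < b ? -1 : (a > b ? 1 : 0); }
  bool is_zero(num a) { return a == 0.0; }
  bool bad(num a) { return !std::isfinite(a); }
  double as_double(num a) { return a; }
  std::string as_string(num a) {
    char buf[40];
    std::snprintf(buf, sizeof(buf), "%.17g", a);
    return buf;
  }
};

struct DecArith {
  typedef Dec num;
  int prec;
  EvalStatus* st;
  void chk(int e, const char* msg) { if (e != tecdec::DEC_OK && st->err == 0) { st->err = e; st->what = msg; } }
  num lit(const std::string& s) {
    int e = tecdec::DEC_OK;
    Dec r = tecdec::from_string(s.c_str(), prec, &e);
    chk(e, "bad numeric literal");
    return r;
  }
  num add(num a, num b) { return tecdec::add(a, b, prec); }
  num sub(num a, num b) { return tecdec::sub(a, b, prec); }
  num mul(num a, num b) { return tecdec::mul(a, b, prec); }
  num div(num a, num b) {
    int e = tecdec::DEC_OK;
    Dec r = tecdec::div(a, b, prec, &e);
    chk(e, "division by zero");
    return r;
  }
  num neg(num a) { return tecdec::neg(a); }
  num expf_(num a) { int e = 0; Dec r = tecdec::dexp(a, prec, &e); chk(e, "exp overflow"); return r; }
  num lnf(num a) { int e = 0; Dec r = tecdec::dln(a, prec, &e); chk(e, "log of non-positive value"); return r; }
  num log10f_(num a) {
    int e = 0;
    Dec l = tecdec::dln(a, prec + 2, &e);
    Dec l10 = tecdec::dln(tecdec::from_ll(10), prec + 2, &e);
    chk(e, "log of non-positive value");
    Dec r = tecdec::div(l, l10, prec, &e);
    return r;
  }
  num logb(num base, num x) {
    int e = 0;
    Dec lx = tecdec::dln(x, prec + 2, &e);
    Dec lb = tecdec::dln(base, prec + 2, &e);
    chk(e, "log domain error");
    return tecdec::div(lx, lb, prec, &e);
  }
  num sqrtf_(num a) { int e = 0; Dec r = tecdec::dsqrt(a, prec, &e); chk(e, "square root of negative value"); return r; }
  num rootn(num k, num x) {
    int e = 0;
    if (tecdec::is_int(k)) {
      long long ki = tecdec::to_ll(k, &e);
      if (e == 0 && (ki % 2 != 0) && x.sign < 0) {
        Dec r = rootn(k, tecdec::neg(x));
        return tecdec::neg(r);
      }
    }
    e = 0;
    Dec inv = tecdec::div(tecdec::from_ll(1), k, prec + 4, &e);
    Dec r = tecdec::dpow(x, inv, prec, &e);
    chk(e, "root domain error");
    return r;
  }
  num pw(num a, num b) { int e = 0; Dec r = tecdec::dpow(a, b, prec, &e); chk(e, "power domain error"); return r; }
  num powi(num a, long long k) { int e = 0; Dec r = tecdec::powi(a, k, prec, &e); chk(e, "power error"); return r; }
  int cmp(num a, num b) { return tecdec::cmp(a, b); }
  bool is_zero(num a) { return a.sign == 0; }
  bool bad(num a) { return a.sign != 0 && (a.e + tecdec::nd(a)) > 100000; }
  double as_double(num a) { return tecdec::to_double(a); }
  std::string as_string(num a) { return tecdec::to_string(a); }
};

// ---------------------------------------------------------------------------
// bytecode executor: one assignment's code segment

template <typename A>
static typename A::num exec_segment(const int* op, const int* arg, int len,
                                    const std::vector<typename A::num>& slots,
                                    const std::vector<typename A::num>& lits,
                                    A& ar, EvalStatus* st) {
  typedef typename A::num num;
  static const int STACK_MAX = 256;
  num stack[STACK_MAX];
  int sp = 0;
  int pc = 0;
  while (pc < len) {
    int o = op[pc], a = arg[pc];
    switch (o) {
      case OP_LOAD: stack[sp++] = slots[a]; break;
      case OP_LIT: stack[sp++] = lits[a]; break;
      case OP_ADD: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.add(x, b); } break;
      case OP_SUB: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.sub(x, b); } break;
      case OP_MUL: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.mul(x, b); } break;
      case OP_DIV: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.div(x, b); } break;
      case OP_POW: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.pw(x, b); } break;
      case OP_NEG: stack[sp - 1] = ar.neg(stack[sp - 1]); break;
      case OP_EXP: stack[sp - 1] = ar.expf_(stack[sp - 1]); break;
      case OP_LN: stack[sp - 1] = ar.lnf(stack[sp - 1]); break;
      case OP_LOG10: stack[sp - 1] = ar.log10f_(stack[sp - 1]); break;
      case OP_LOGB: { num x = stack[--sp]; num b = stack[--sp]; stack[sp++] = ar.logb(b, x); } break;
      case OP_ROOT2: stack[sp - 1] = ar.sqrtf_(stack[sp - 1]); break;
      case OP_ROOTN: { num x = stack[--sp]; num k = stack[--sp]; stack[sp++] = ar.rootn(k, x); } break;
      case OP_POWI: stack[sp - 1] = ar.powi(stack[sp - 1], a); break;
      case OP_LT: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.lit(ar.cmp(x, b) < 0 ? "1" : "0"); } break;
      case OP_LE: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.lit(ar.cmp(x, b) <= 0 ? "1" : "0"); } break;
      case OP_GT: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.lit(ar.cmp(x, b) > 0 ? "1" : "0"); } break;
      case OP_GE: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.lit(ar.cmp(x, b) >= 0 ? "1" : "0"); } break;
      case OP_EQ: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.lit(ar.cmp(x, b) == 0 ? "1" : "0"); } break;
      case OP_NEQ: { num b = stack[--sp]; num x = stack[--sp]; stack[sp++] = ar.lit(ar.cmp(x, b) != 0 ? "1" : "0"); } break;
      case OP_JZ: { num c = stack[--sp]; if (ar.is_zero(c)) { pc = a; continue; } } break;
      case OP_JMP: pc = a; continue;
      case OP_NOCASE:
        st->err = tecdec::DEC_DOMAIN;
        st->what = "piecewise expression: no condition matched";
        return typename A::num();
      default:
        st->err = tecdec::DEC_PARSE;
        st->what = "corrupt bytecode";
        return typename A::num();
    }
    if (st->err != 0) return typename A::num();
    if (sp >= STACK_MAX - 1) { st->err = tecdec::DEC_CAPACITY; st->what = "expression too deep"; return typename A::num(); }
    ++pc;
  }
  return stack[sp - 1];
}

// ---------------------------------------------------------------------------
// full simulation run

template <typename A>
static List run_impl(const IntegerMatrix& code, const IntegerMatrix& bounds,
                     const CharacterVector& lit_pool,
                     const CharacterVector& init, int nslots,
                     const IntegerMatrix& feedback, int time_slot, int delta_slot,
                     double nsteps_d, int stride, const IntegerVector& sample_slots,
                     int digits) {
  typedef typename A::num num;
  EvalStatus st;
  A ar; ar.prec = digits > 0 ? digits : 17; ar.st = &st;

  std::vector<num> lits(lit_pool.size());
  for (int i = 0; i < lit_pool.size(); ++i) lits[i] = ar.lit(as<std::string>(lit_pool[i]));
  std::vector<num> slots(nslots);
  for (int i = 0; i < nslots && i < init.size(); ++i)
    slots[i] = ar.lit(as<std::string>(init[i]));
  if (st.err) stop("bad initial value: %s", st.what);

  const int* opc = &code(0, 0);
  const int* argc_ = &code(0, 1);
  long long nsteps = (long long)nsteps_d;
  int nassign = bounds.nrow();
  int nsample = (int)(nsteps / stride) + 1;
  int nvar = sample_slots.size();
  NumericVector tgrid(nsample);
  NumericMatrix vals(nsample, nvar);
  CharacterMatrix chr(digits > 0 ? nsample : 0, digits > 0 ? nvar : 0);

  long long divergent = -1;
  int row = 0;
  // record initial state
  tgrid[row] = time_slot >= 0 ? ar.as_double(slots[time_slot]) : 0.0;
  for (int v = 0; v < nvar; ++v) {
    vals(row, v) = ar.as_double(slots[sample_slots[v]]);
    if (digits > 0) chr(row, v) = ar.as_string(slots[sample_slots[v]]);
  }
  ++row;

  for (long long step = 1; step <= nsteps; ++step) {
    for (int k = 0; k < nassign; ++k) {
      int s = bounds(k, 0), e = bounds(k, 1), tgt = bounds(k, 2);
      num r = exec_segment<A>(opc + s, argc_ + s, e - s, slots, lits, ar, &st);
      if (st.err) { divergent = step; break; }
      slots[tgt] = r;
    }
    if (divergent < 0) {
      for (int f = 0; f < feedback.nrow(); ++f) {
        num v = slots[feedback(f, 0)];
        if (ar.bad(v)) { divergent = step; break; }
        slots[feedback(f, 1)] = v;
      }
    }
    if (divergent >= 0) break;
    if (time_slot >= 0 && delta_slot >= 0)
      slots[time_slot] = ar.add(slots[time_slot], slots[delta_slot]);
    if (step % stride == 0) {
      tgrid[row] = time_slot >= 0 ? ar.as_double(slots[time_slot]) : (double)step;
      for (int v = 0; v < nvar; ++v) {
        vals(row, v) = ar.as_double(slots[sample_slots[v]]);
        if (digits > 0) chr(row, v) = ar.as_string(slots[sample_slots[v]]);
      }
      ++row;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  if (divergent >= 0 && row < nsample) {
    // truncate: mark remaining rows NA
    for (int r2 = row; r2 < nsample; ++r2) {
      tgrid[r2] = NA_REAL;
      for (int v = 0; v < nvar; ++v) vals(r2, v) = NA_REAL;
    }
  }
  return List::create(
      _["t"] = tgrid, _["values"] = vals,
      _["values_chr"] = digits > 0 ? (SEXP)chr : R_NilValue,
      _["divergent_step"] = divergent >= 0 ? (double)divergent : -1.0,
      _["rows"] = row,
      _["error"] = st.err ? std::string(st.what) : std::string(""));
}

// [[Rcpp::export]]
List cpp_run_program(IntegerMatrix code, IntegerMatrix bounds,
                     CharacterVector lit_pool, CharacterVector init, int nslots,
                     IntegerMatrix feedback, int time_slot, int delta_slot,
                     double nsteps, int stride, IntegerVector sample_slots,
                     int digits) {
  if (digits < 0 || digits > tecdec::MAX_PREC)
    stop("decimal precision must be between 1 and %d digits", tecdec::MAX_PREC);
  if (digits == 0)
    return run_impl<DoubleArith>(code, bounds, lit_pool, init, nslots, feedback,
                                 time_slot, delta_slot, nsteps, stride,
                                 sample_slots, digits);
  return run_impl<DecArith>(code, bounds, lit_pool, init, nslots, feedback,
                            time_slot, delta_slot, nsteps, stride, sample_slots,
                            digits);
}

// single-expression evaluation (used by evaluate_expr)
// [[Rcpp::export]]
List cpp_eval_expr(IntegerMatrix code, CharacterVector lit_pool,
                   CharacterVector slot_values, int digits) {
  if (digits < 0 || digits > tecdec::MAX_PREC)
    stop("decimal precision must be between 1 and %d digits", tecdec::MAX_PREC);
  EvalStatus st;
  const int* opc = &code(0, 0);
  const int* argc_ = &code(0, 1);
  if (digits == 0) {
    DoubleArith ar; ar.prec = 17; ar.st = &st;
    std::vector<double> lits(lit_pool.size()), slots(slot_values.size());
    for (int i = 0; i < lit_pool.size(); ++i) lits[i] = ar.lit(as<std::string>(lit_pool[i]));
    for (int i = 0; i < slot_values.size(); ++i) slots[i] = ar.lit(as<std::string>(slot_values[i]));
    double r = exec_segment<DoubleArith>(opc, argc_, code.nrow(), slots, lits, ar, &st);
    return List::create(_["value"] = r, _["chr"] = ar.as_string(r),
                        _["error"] = st.err ? std::string(st.what) : std::string(""));
  }
  DecArith ar; ar.prec = digits; ar.st = &st;
  std::vector<Dec> lits(lit_pool.size()), slots(slot_values.size());
  for (int i = 0; i < lit_pool.size(); ++i) lits[i] = ar.lit(as<std::string>(lit_pool[i]));
  for (int i = 0; i < slot_values.size(); ++i) slots[i] = ar.lit(as<std::string>(slot_values[i]));
  Dec r = exec_segment<DecArith>(opc, argc_, code.nrow(), slots, lits, ar, &st);
  return List::create(_["value"] = tecdec::to_double(r), _["chr"] = tecdec::to_string(r),
                      _["error"] = st.err ? std::string(st.what) : std::string(""));
}

// scalar decimal arithmetic, exposed for tests and closed-form oracles
// [[Rcpp::export]]
std::string cpp_dec_op(std::string op, std::string a, std::string b, int digits) {
  if (digits < 1 || digits > tecdec::MAX_PREC)
    stop("decimal precision must be between 1 and %d digits", tecdec::MAX_PREC);
  int err = tecdec::DEC_OK;
  Dec x = tecdec::from_string(a.c_str(), digits, &err);
  Dec y = tecdec::from_string(b.c_str(), digits, &err);
  if (err) stop("bad decimal literal");
  Dec r;
  if (op == "add") r = tecdec::add(x, y, digits);
  else if (op == "sub") r = tecdec::sub(x, y, digits);
  else if (op == "mul") r = tecdec::mul(x, y, digits);
  else if (op == "div") r = tecdec::div(x, y, digits, &err);
  else if (op == "pow") r = tecdec::dpow(x, y, digits, &err);
  else stop("unknown decimal operation '%s'", op.c_str());
  if (err) stop("decimal arithmetic error (code %d)", err);
  return tecdec::to_string(r);
}

// [[Rcpp::export]]
std::string cpp_dec_fun(std::string fn, std::string a, int digits) {
  if (digits < 1 || digits > tecdec::MAX_PREC)
    stop("decimal precision must be between 1 and %d digits", tecdec::MAX_PREC);
  int err = tecdec::DEC_OK;
  Dec x = tecdec::from_string(a.c_str(), digits, &err);
  if (err) stop("bad decimal literal");
  Dec r;
  if (fn == "neg") r = tecdec::neg(x);
  else if (fn == "sqrt") r = tecdec::dsqrt(x, digits, &err);
  else if (fn == "exp") r = tecdec::dexp(x, digits, &err);
  else if (fn == "ln") r = tecdec::dln(x, digits, &err);
  else stop("unknown decimal function '%s'", fn.c_str());
  if (err) stop("decimal arithmetic error (code %d)", err);
  return tecdec::to_string(r);
}

// [[Rcpp::export]]
int cpp_dec_cmp(std::string a, std::string b) {
  int err = tecdec::DEC_OK;
  Dec x = tecdec::from_string(a.c_str(), tecdec::MAX_PREC, &err);
  Dec y = tecdec::from_string(b.c_str(), tecdec::MAX_PREC, &err);
  if (err) stop("bad decimal literal");
  return tecdec::cmp(x, y);
}
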