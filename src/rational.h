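#ifndef OPTCYCLE_RATIONAL_H
#define OPTCYCLE_RATIONAL_H

#include <cstdint>
#include <stdexcept>

// Exact rational scalar on int64.  Arithmetic uses the classic
// cross-cancellation scheme (gcd of the int64 operands before multiplying)
// so the hot path never needs a 128-bit gcd.  Overflow is a hard error,
// never a silent wrap: the persistence reduction must stay exact.
namespace optcycle {

typedef __int128 i128;

inline int64_t checked_narrow(i128 v) {
  if (v > INT64_MAX || v < INT64_MIN)
    throw std::overflow_error("rational arithmetic overflow (coefficient exceeds 64 bits)");
  return (int64_t)v;
}

inline int64_t gcd64(int64_t a, int64_t b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  if (a == 0) return b;
  if (b == 0) return a;
  int sh = __builtin_ctzll(a | b);
  a >>= __builtin_ctzll(a);
  do {
    b >>= __builtin_ctzll(b);
    if (a > b) { int64_t t = a; a = b; b = t; }
    b -= a;
  } while (b != 0);
  return a << sh;
}

inline int64_t checked_mul(int64_t a, int64_t b) {
  i128 p = (i128)a * b;
  return checked_narrow(p);
}

struct Rat {
  int64_t num;
  int64_t den;  // always > 0

  Rat() : num(0), den(1) {}
  Rat(int64_t n) : num(n), den(1) {}
  Rat(int64_t n, int64_t d) {
    if (d == 0) throw std::domain_error("rational with zero denominator");
    if (d < 0) { n = -n; d = -d; }
    if (n == 0) { num = 0; den = 1; return; }
    int64_t g = gcd64(n, d);
    num = n / g;
    den = d / g;
  }

  bool is_zero() const { return num == 0; }

  Rat operator+(const Rat& o) const {
    if (den == 1 && o.den == 1) {
      Rat r; r.num = checked_narrow((i128)num + o.num); r.den = 1; return r;
    }
    int64_t g = gcd64(den, o.den);
    int64_t da = den / g, db = o.den / g;
    i128 n = (i128)num * db + (i128)o.num * da;
    // new denominator da*db*g; n shares factors only with g
    int64_t nn = checked_narrow(n);
    if (nn == 0) { Rat z; return z; }
    int64_t g2 = gcd64(nn, g);
    Rat r;
    r.num = nn / g2;
    r.den = checked_mul(checked_mul(da, db), g / g2);
    return r;
  }
  Rat operator-(const Rat& o) const {
    Rat t; t.num = -o.num; t.den = o.den;
    return *this + t;
  }
  Rat operator*(const Rat& o) const {
    if (den == 1 && o.den == 1) {
      Rat r; r.num = checked_mul(num, o.num); r.den = 1; return r;
    }
    int64_t g1 = gcd64(num, o.den);
    int64_t g2 = gcd64(o.num, den);
    Rat r;
    r.num = checked_mul(num / g1, o.num / g2);
    r.den = checked_mul(den / g2, o.den / g1);
    return r;
  }
  Rat operator/(const Rat& o) const {
    if (o.num == 0) throw std::domain_error("rational division by zero");
    Rat inv;
    if (o.num < 0) { inv.num = -o.den; inv.den = -o.num; }
    else { inv.num = o.den; inv.den = o.num; }
    return *this * inv;
  }
  Rat operator-() const { Rat r; r.num = -num; r.den = den; return r; }
  bool operator==(const Rat& o) const { return num == o.num && den == o.den; }
};

}  // namespace optcycle

#endif
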