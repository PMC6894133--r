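// Fan-Vercauteren somewhat-homomorphic encryption over R_q = Z_q[X]/(X^n + 1),
// with q = 2^B a single arbitrary-precision integer held as base-2^32 limbs.
// Exact negacyclic polynomial products go through a CRT of 31-bit NTT-friendly
// primes with Garner reconstruction; no RNS ciphertext representation is used.
// All randomness is drawn from R's RNG so results reproduce from set.seed().

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <map>
#include <utility>
#include <string>

using namespace Rcpp;

typedef uint32_t u32;
typedef uint64_t u64;
typedef __uint128_t u128;

typedef std::vector<u32> BN; // little-endian base-2^32 limbs

// ------------------------------------------------------------------ bignum ---

static int bn_nlimbs(const BN &a) {
  int l = (int)a.size();
  while (l > 0 && a[l - 1] == 0) --l;
  return l;
}

static bool bn_is_zero(const BN &a) { return bn_nlimbs(a) == 0; }

static int bn_cmp(const BN &a, const BN &b) {
  int la = bn_nlimbs(a), lb = bn_nlimbs(b);
  if (la != lb) return la < lb ? -1 : 1;
  for (int i = la - 1; i >= 0; --i)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

static BN bn_add(const BN &a, const BN &b) {
  size_t l = std::max(a.size(), b.size());
  BN r(l + 1, 0);
  u64 carry = 0;
  for (size_t i = 0; i < l; ++i) {
    u64 cur = carry;
    if (i < a.size()) cur += a[i];
    if (i < b.size()) cur += b[i];
    r[i] = (u32)cur;
    carry = cur >> 32;
  }
  r[l] = (u32)carry;
  return r;
}

// assumes a >= b
static BN bn_sub(const BN &a, const BN &b) {
  BN r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t cur = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (cur < 0) { cur += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (u32)cur;
  }
  return r;
}

static BN bn_mul(const BN &a, const BN &b) {
  int la = bn_nlimbs(a), lb = bn_nlimbs(b);
  BN r(la + lb + 1, 0);
  for (int i = 0; i < la; ++i) {
    u64 carry = 0, ai = a[i];
    for (int j = 0; j < lb; ++j) {
      u128 cur = (u128)ai * b[j] + r[i + j] + carry;
      r[i + j] = (u32)cur;
      carry = (u64)(cur >> 32);
    }
    size_t k = i + lb;
    while (carry) {
      u64 cur = (u64)r[k] + (u32)carry;
      r[k] = (u32)cur;
      carry = (carry >> 32) + (cur >> 32);
      ++k;
    }
  }
  return r;
}

static BN bn_mul_small(const BN &a, u64 m) { // m < 2^32
  BN r(a.size() + 2, 0);
  u64 carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    u128 cur = (u128)a[i] * m + carry;
    r[i] = (u32)cur;
    carry = (u64)(cur >> 32);
  }
  r[a.size()] = (u32)carry;
  r[a.size() + 1] = (u32)(carry >> 32);
  return r;
}

// floor(a / d), remainder out; d < 2^32
static BN bn_div_small(const BN &a, u64 d, u64 *rem) {
  BN r(a.size(), 0);
  u64 cur = 0;
  for (int i = (int)a.size() - 1; i >= 0; --i) {
    cur = (cur << 32) | a[i];
    r[i] = (u32)(cur / d);
    cur %= d;
  }
  if (rem) *rem = cur;
  return r;
}

static u64 bn_mod_u64(const BN &a, u64 p) {
  u64 r = 0;
  for (int i = bn_nlimbs(a) - 1; i >= 0; --i)
    r = (u64)((((u128)r << 32) | a[i]) % p);
  return r;
}

static BN bn_from_u64(u64 v) { BN r; r.push_back((u32)v); r.push_back((u32)(v >> 32)); return r; }

static double bn_log2(const BN &a) {
  int l = bn_nlimbs(a);
  if (l == 0) return R_NegInf;
  double top = (double)a[l - 1];
  if (l >= 2) top += (double)a[l - 2] / 4294967296.0;
  return std::log2(top) + 32.0 * (l - 1);
}

static std::string bn_to_dec(BN a) {
  if (bn_is_zero(a)) return "0";
  std::string out;
  while (!bn_is_zero(a)) {
    u64 rem;
    a = bn_div_small(a, 1000000000u, &rem);
    for (int k = 0; k < 9; ++k) { out.push_back('0' + rem % 10); rem /= 10; }
  }
  while (out.size() > 1 && out.back() == '0') out.pop_back();
  std::reverse(out.begin(), out.end());
  return out;
}

// --------------------------------------------------------------- context -----

struct Ctx {
  int n;      // ring dimension
  int B;      // log2(q), q = 2^B
  int Lq;     // limbs per coefficient
  u64 t;      // plaintext modulus (< 2^31)
  BN q;       // 2^B
  BN half;    // 2^(B-1)
  BN delta;   // floor(q / t)
  u32 topmask;
};

static Ctx make_ctx(int n, int B, double t_) {
  Ctx c;
  c.n = n; c.B = B;
  c.Lq = (B + 31) / 32;
  c.t = (u64)t_;
  c.q.assign(c.Lq + 1, 0);
  c.q[B / 32] = (u32)1 << (B % 32);
  c.half.assign(c.Lq, 0);
  c.half[(B - 1) / 32] = (u32)1 << ((B - 1) % 32);
  u64 rem;
  c.delta = bn_div_small(c.q, c.t, &rem);
  c.delta.resize(c.Lq);
  int topbits = B - 32 * (c.Lq - 1);
  c.topmask = (topbits >= 32) ? 0xffffffffu : (((u32)1 << topbits) - 1u);
  return c;
}

// ring elements: n coefficients, coeff i occupies limbs [i*Lq, (i+1)*Lq)
typedef std::vector<u32> PolyQ;

static void coeff_mask(u32 *c, const Ctx &cx) { c[cx.Lq - 1] &= cx.topmask; }

static void coeff_add(u32 *a, const u32 *b, const Ctx &cx) { // a += b mod 2^B
  u64 carry = 0;
  for (int i = 0; i < cx.Lq; ++i) {
    u64 cur = (u64)a[i] + b[i] + carry;
    a[i] = (u32)cur;
    carry = cur >> 32;
  }
  coeff_mask(a, cx);
}

static void coeff_sub(u32 *a, const u32 *b, const Ctx &cx) { // a -= b mod 2^B
  int64_t borrow = 0;
  for (int i = 0; i < cx.Lq; ++i) {
    int64_t cur = (int64_t)a[i] - b[i] - borrow;
    if (cur < 0) { cur += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    a[i] = (u32)cur;
  }
  coeff_mask(a, cx);
}

static void coeff_neg(u32 *a, const Ctx &cx) { // a <- -a mod 2^B
  u64 carry = 1;
  for (int i = 0; i < cx.Lq; ++i) {
    u64 cur = (u64)(~a[i]) + carry;
    a[i] = (u32)cur;
    carry = cur >> 32;
  }
  coeff_mask(a, cx);
}

// centered representative: returns sign (+1/-1/0), writes |x| into mag (Lq limbs)
static int coeff_centered(const u32 *a, u32 *mag, const Ctx &cx) {
  // negative iff a >= half = 2^(B-1)
  bool neg = false;
  int hl = (cx.B - 1) / 32;
  u32 hb = (u32)1 << ((cx.B - 1) % 32);
  for (int i = cx.Lq - 1; i >= 0; --i) {
    u32 h = (i == hl) ? hb : 0u;
    if (a[i] != h) { neg = a[i] > h; break; }
    if (i == 0) neg = true; // exactly q/2: map to -q/2
  }
  if (!neg) {
    bool z = true;
    for (int i = 0; i < cx.Lq; ++i) { mag[i] = a[i]; if (a[i]) z = false; }
    return z ? 0 : 1;
  }
  u64 carry = 1;
  for (int i = 0; i < cx.Lq; ++i) {
    u64 cur = (u64)(~a[i]) + carry;
    mag[i] = (u32)cur;
    carry = cur >> 32;
  }
  mag[cx.Lq - 1] &= cx.topmask;
  return -1;
}

static PolyQ poly_zero(const Ctx &cx) { return PolyQ((size_t)cx.n * cx.Lq, 0); }

static PolyQ poly_from_R(const NumericMatrix &m) {
  int Lq = m.nrow(), n = m.ncol();
  PolyQ p((size_t)n * Lq);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < Lq; ++l)
      p[(size_t)i * Lq + l] = (u32)m(l, i);
  return p;
}

static NumericMatrix poly_to_R(const PolyQ &p, const Ctx &cx) {
  NumericMatrix m(cx.Lq, cx.n);
  for (int i = 0; i < cx.n; ++i)
    for (int l = 0; l < cx.Lq; ++l)
      m(l, i) = (double)p[(size_t)i * cx.Lq + l];
  return m;
}

static void poly_add_ip(PolyQ &a, const PolyQ &b, const Ctx &cx) {
  for (int i = 0; i < cx.n; ++i)
    coeff_add(&a[(size_t)i * cx.Lq], &b[(size_t)i * cx.Lq], cx);
}

// ------------------------------------------------------------ NTT primes -----

struct PrimeTab {
  u64 p;
  std::vector<u64> psi_rev, ipsi_rev; // powers of psi / psi^-1 in bit-reversed order
  u64 ninv;
};

static u64 mulmod(u64 a, u64 b, u64 p) { return (u64)((u128)a * b % p); }

static u64 powmod(u64 a, u64 e, u64 p) {
  u64 r = 1; a %= p;
  while (e) { if (e & 1) r = mulmod(r, a, p); a = mulmod(a, a, p); e >>= 1; }
  return r;
}

static bool is_prime_u32(u64 nn) {
  if (nn < 2) return false;
  for (u64 d : {2ull, 3ull, 5ull, 7ull}) {
    if (nn % d == 0) return nn == d;
  }
  u64 d = nn - 1; int s = 0;
  while ((d & 1) == 0) { d >>= 1; ++s; }
  for (u64 a : {2ull, 3ull, 5ull, 7ull}) {
    u64 x = powmod(a, d, nn);
    if (x == 1 || x == nn - 1) continue;
    bool comp = true;
    for (int i = 1; i < s; ++i) {
      x = mulmod(x, x, nn);
      if (x == nn - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

static std::vector<u64> g_primes; // p == 1 mod 2^17, descending below 2^31

static void ensure_primes(size_t count) {
  static u64 next_k = ((u64)1 << 31) / 131072;
  while (g_primes.size() < count) {
    while (next_k > 0) {
      u64 p = next_k * 131072 + 1;
      --next_k;
      if (is_prime_u32(p)) { g_primes.push_back(p); break; }
    }
    if (next_k == 0 && g_primes.size() < count)
      stop("exhausted NTT prime pool");
  }
}

static std::map<std::pair<u64, int>, PrimeTab> g_tabs;

static u32 bitrev(u32 x, int bits) {
  u32 r = 0;
  for (int i = 0; i < bits; ++i) { r = (r << 1) | (x & 1); x >>= 1; }
  return r;
}

static const PrimeTab &get_tab(u64 p, int n) {
  auto key = std::make_pair(p, n);
  auto it = g_tabs.find(key);
  if (it != g_tabs.end()) return it->second;
  PrimeTab T;
  T.p = p;
  // find psi: primitive 2n-th root of unity mod p
  u64 psi = 0;
  for (u64 g = 2; ; ++g) {
    u64 cand = powmod(g, (p - 1) / (2 * (u64)n), p);
    if (powmod(cand, (u64)n, p) == p - 1) { psi = cand; break; }
    if (g > 1000) stop("no primitive root found");
  }
  int lg = 0; while ((1 << lg) < n) ++lg;
  u64 ipsi = powmod(psi, p - 2, p);
  T.psi_rev.resize(n); T.ipsi_rev.resize(n);
  u64 w = 1, iw = 1;
  std::vector<u64> fwd(n), inv(n);
  for (int i = 0; i < n; ++i) { fwd[i] = w; inv[i] = iw; w = mulmod(w, psi, p); iw = mulmod(iw, ipsi, p); }
  for (int i = 0; i < n; ++i) {
    T.psi_rev[i] = fwd[bitrev(i, lg)];
    T.ipsi_rev[i] = inv[bitrev(i, lg)];
  }
  T.ninv = powmod((u64)n, p - 2, p);
  auto res = g_tabs.emplace(key, std::move(T));
  return res.first->second;
}

// negacyclic forward NTT (Longa-Naehrig), in place
static void ntt_fwd(u64 *a, int n, const PrimeTab &T) {
  u64 p = T.p;
  for (int len = n >> 1, m = 1; len >= 1; len >>= 1, m <<= 1) {
    for (int i = 0; i < m; ++i) {
      u64 w = T.psi_rev[m + i];
      int j1 = 2 * i * len;
      for (int j = j1; j < j1 + len; ++j) {
        u64 u = a[j], v = mulmod(a[j + len], w, p);
        u64 s = u + v; a[j] = s >= p ? s - p : s;
        a[j + len] = u >= v ? u - v : u + p - v;
      }
    }
  }
}

static void ntt_inv(u64 *a, int n, const PrimeTab &T) {
  u64 p = T.p;
  for (int len = 1, m = n >> 1; len < n; len <<= 1, m >>= 1) {
    for (int i = 0; i < m; ++i) {
      u64 w = T.ipsi_rev[m + i];
      int j1 = 2 * i * len;
      for (int j = j1; j < j1 + len; ++j) {
        u64 u = a[j], v = a[j + len];
        u64 s = u + v; a[j] = s >= p ? s - p : s;
        u64 d = u >= v ? u - v : u + p - v;
        a[j + len] = mulmod(d, w, p);
      }
    }
  }
  for (int j = 0; j < n; ++j) a[j] = mulmod(a[j], T.ninv, p);
}

// centered residues of a mod-q polynomial, per prime p
static void centered_residues(const PolyQ &a, const Ctx &cx, u64 p, u64 *out) {
  std::vector<u32> mag(cx.Lq);
  for (int i = 0; i < cx.n; ++i) {
    int sg = coeff_centered(&a[(size_t)i * cx.Lq], mag.data(), cx);
    u64 r = 0;
    for (int l = cx.Lq - 1; l >= 0; --l)
      r = (u64)((((u128)r << 32) | mag[l]) % p);
    out[i] = (sg < 0 && r != 0) ? p - r : r;
  }
}

// choose primes so their product exceeds 2^bound_bits
static std::vector<u64> primes_for(double bound_bits) {
  double acc = 0; size_t k = 0;
  std::vector<u64> ps;
  while (acc <= bound_bits + 1.0) {
    ensure_primes(k + 1);
    ps.push_back(g_primes[k]);
    acc += std::log2((double)g_primes[k]);
    ++k;
  }
  return ps;
}

// Garner: reconstruct signed centered big integers from residues. With four
// or fewer 31-bit primes the mixed-radix value fits in 128 bits and skips all
// heap allocation (the hot path for small parameter sets).
struct Garner {
  std::vector<u64> ps;
  std::vector<std::vector<u64>> inv; // inv[k][j] = (p_j)^{-1} mod p_k, j < k
  BN M, Mhalf;
  bool use128;
  u128 M128, Mhalf128;
  Garner(const std::vector<u64> &primes) : ps(primes) {
    size_t P = ps.size();
    inv.resize(P);
    for (size_t k = 0; k < P; ++k) {
      inv[k].resize(k);
      for (size_t j = 0; j < k; ++j)
        inv[k][j] = powmod(ps[j] % ps[k], ps[k] - 2, ps[k]);
    }
    M = bn_from_u64(1);
    for (size_t k = 0; k < P; ++k) M = bn_mul_small(M, ps[k]);
    u64 rem; Mhalf = bn_div_small(M, 2, &rem);
    use128 = P <= 4;
    if (use128) {
      M128 = 1;
      for (size_t k = 0; k < P; ++k) M128 *= ps[k];
      Mhalf128 = M128 >> 1;
    }
  }
  void digits(const u64 *r, u64 *v) const {
    size_t P = ps.size();
    for (size_t k = 0; k < P; ++k) {
      u64 vk = r[k] % ps[k];
      for (size_t j = 0; j < k; ++j) {
        u64 vj = v[j] % ps[k];
        u64 diff = vk >= vj ? vk - vj : vk + ps[k] - vj;
        vk = mulmod(diff, inv[k][j], ps[k]);
      }
      v[k] = vk;
    }
  }
  // residues r[k]; output sign and magnitude (variable-length BN)
  int reconstruct(const u64 *r, BN &mag) const {
    size_t P = ps.size();
    u64 v[64];
    digits(r, v);
    if (use128) {
      u128 x = v[P - 1];
      for (int k = (int)P - 2; k >= 0; --k) x = x * ps[k] + v[k];
      int sg = 1;
      if (x > Mhalf128) { x = M128 - x; sg = -1; }
      mag.assign(4, 0);
      for (int l = 0; l < 4; ++l) mag[l] = (u32)(x >> (32 * l));
      return x == 0 ? 0 : sg;
    }
    BN x = bn_from_u64(v[P - 1]);
    for (int k = (int)P - 2; k >= 0; --k) {
      x = bn_mul_small(x, ps[k]);
      BN add = bn_from_u64(v[k]);
      x = bn_add(x, add);
    }
    if (bn_cmp(x, Mhalf) > 0) { mag = bn_sub(M, x); return bn_is_zero(mag) ? 0 : -1; }
    mag = x;
    return bn_is_zero(mag) ? 0 : 1;
  }
};

// reduce signed magnitude mod 2^B into out (Lq limbs)
static void signed_mod_q(int sg, const BN &mag, u32 *out, const Ctx &cx) {
  for (int l = 0; l < cx.Lq; ++l) out[l] = l < (int)mag.size() ? mag[l] : 0u;
  coeff_mask(out, cx);
  if (sg < 0) coeff_neg(out, cx);
}

// exact negacyclic product of two mod-q polynomials (centered reps), reduced mod q.
// bound_bits must bound log2 of the max |coefficient| of the exact product.
static PolyQ poly_mult_modq(const PolyQ &a, const PolyQ &b, const Ctx &cx,
                            double bound_bits) {
  std::vector<u64> ps = primes_for(bound_bits);
  size_t P = ps.size();
  int n = cx.n;
  std::vector<std::vector<u64>> res(P);
  {
    std::vector<u64> fa(n), fb(n);
    for (size_t k = 0; k < P; ++k) {
      const PrimeTab &T = get_tab(ps[k], n);
      centered_residues(a, cx, ps[k], fa.data());
      centered_residues(b, cx, ps[k], fb.data());
      ntt_fwd(fa.data(), n, T);
      ntt_fwd(fb.data(), n, T);
      res[k].resize(n);
      for (int i = 0; i < n; ++i) res[k][i] = mulmod(fa[i], fb[i], ps[k]);
      ntt_inv(res[k].data(), n, T);
    }
  }
  Garner G(ps);
  PolyQ out = poly_zero(cx);
  std::vector<u64> r(P);
  BN mag;
  for (int i = 0; i < n; ++i) {
    for (size_t k = 0; k < P; ++k) r[k] = res[k][i];
    int sg = G.reconstruct(r.data(), mag);
    signed_mod_q(sg, mag, &out[(size_t)i * cx.Lq], cx);
  }
  return out;
}

// ---------------------------------------------------------------- sampling ---

static PolyQ sample_uniform_q(const Ctx &cx) {
  PolyQ p((size_t)cx.n * cx.Lq);
  for (int i = 0; i < cx.n; ++i) {
    u32 *c = &p[(size_t)i * cx.Lq];
    for (int l = 0; l < cx.Lq; ++l)
      c[l] = (u32)std::floor(unif_rand() * 4294967296.0);
    coeff_mask(c, cx);
  }
  return p;
}

// small signed value into mod-q coefficient
static void small_to_coeff(int64_t v, u32 *c, const Ctx &cx) {
  for (int l = 0; l < cx.Lq; ++l) c[l] = 0;
  if (v >= 0) {
    c[0] = (u32)v;
    if (cx.Lq > 1) c[1] = (u32)((u64)v >> 32);
  } else {
    u64 av = (u64)(-v);
    c[0] = (u32)av;
    if (cx.Lq > 1) c[1] = (u32)(av >> 32);
    coeff_neg(c, cx);
  }
  coeff_mask(c, cx);
}

static PolyQ sample_ternary(const Ctx &cx) {
  PolyQ p = poly_zero(cx);
  for (int i = 0; i < cx.n; ++i) {
    int v = (int)std::floor(unif_rand() * 3.0) - 1;
    small_to_coeff(v, &p[(size_t)i * cx.Lq], cx);
  }
  return p;
}

// centered binomial: Binom(2k, 1/2) - k, sd = sqrt(k/2)
static PolyQ sample_cbd(const Ctx &cx, int k2) {
  PolyQ p = poly_zero(cx);
  for (int i = 0; i < cx.n; ++i) {
    int64_t v = (int64_t)R::rbinom((double)k2, 0.5) - k2 / 2;
    small_to_coeff(v, &p[(size_t)i * cx.Lq], cx);
  }
  return p;
}

static double small_bound_log2(const PolyQ &a, const Ctx &cx) {
  // max |centered coeff| for a polynomial known to be small; generic scan
  std::vector<u32> mag(cx.Lq);
  BN best(cx.Lq, 0);
  for (int i = 0; i < cx.n; ++i) {
    coeff_centered(&a[(size_t)i * cx.Lq], mag.data(), cx);
    BN m(mag.begin(), mag.end());
    if (bn_cmp(m, best) > 0) best = m;
  }
  double l = bn_log2(best);
  return l < 0 ? 0 : l;
}

// ------------------------------------------------------------------ keygen ---

// [[Rcpp::export]]
List cpp_keygen(int n, int B, double t_, int w_bits) {
  Ctx cx = make_ctx(n, B, t_);
  double lgn = std::log2((double)n);
  PolyQ s = sample_ternary(cx);
  // public key: a uniform, e error; p0 = -(a*s + e), p1 = a
  PolyQ a = sample_uniform_q(cx);
  PolyQ e = sample_cbd(cx, 42);
  PolyQ as = poly_mult_modq(a, s, cx, cx.B + lgn + 2);
  PolyQ p0 = as;
  poly_add_ip(p0, e, cx);
  for (int i = 0; i < n; ++i) coeff_neg(&p0[(size_t)i * cx.Lq], cx);
  // s^2 (exact; coefficients bounded by n)
  PolyQ s2 = poly_mult_modq(s, s, cx, lgn + 2);
  // relinearization key: ell pairs (b_i, a_i), b_i = -(a_i s + e_i) + w^i s^2
  int ell = (B + w_bits - 1) / w_bits;
  List rb(ell), ra(ell);
  for (int i = 0; i < ell; ++i) {
    PolyQ ai = sample_uniform_q(cx);
    PolyQ ei = sample_cbd(cx, 42);
    PolyQ bi = poly_mult_modq(ai, s, cx, cx.B + lgn + 2);
    poly_add_ip(bi, ei, cx);
    for (int j = 0; j < n; ++j) coeff_neg(&bi[(size_t)j * cx.Lq], cx);
    // add w^i * s2: shift each coefficient left by i*w_bits bits mod 2^B
    int sh = i * w_bits;
    PolyQ ws2 = poly_zero(cx);
    for (int j = 0; j < n; ++j) {
      const u32 *src = &s2[(size_t)j * cx.Lq];
      u32 *dst = &ws2[(size_t)j * cx.Lq];
      int limb_sh = sh / 32, bit_sh = sh % 32;
      for (int l = cx.Lq - 1; l >= 0; --l) {
        u64 v = 0;
        int lo = l - limb_sh;
        if (lo >= 0) v = (u64)src[lo] << bit_sh;
        if (bit_sh && lo - 1 >= 0) v |= src[lo - 1] >> (32 - bit_sh);
        dst[l] = (u32)v;
      }
      coeff_mask(dst, cx);
    }
    poly_add_ip(bi, ws2, cx);
    rb[i] = poly_to_R(bi, cx);
    ra[i] = poly_to_R(ai, cx);
  }
  return List::create(_["s"] = poly_to_R(s, cx),
                      _["p0"] = poly_to_R(p0, cx),
                      _["p1"] = poly_to_R(a, cx),
                      _["rlk_b"] = rb, _["rlk_a"] = ra);
}

// ----------------------------------------------------------- encrypt/decrypt -

static void encode_into(PolyQ &c0, double m, const Ctx &cx) {
  // plaintext m in (-t/2, t/2]; add Delta*[m]_t to constant coefficient
  int64_t mi = (int64_t)m;
  int64_t tt = (int64_t)cx.t;
  mi %= tt;
  if (mi * 2 > tt) mi -= tt;
  if (mi * 2 <= -tt) mi += tt;
  BN dm = bn_mul_small(cx.delta, (u64)(mi < 0 ? -mi : mi));
  std::vector<u32> c(cx.Lq, 0);
  for (int l = 0; l < cx.Lq; ++l) c[l] = l < (int)dm.size() ? dm[l] : 0;
  coeff_mask(c.data(), cx);
  if (mi < 0) coeff_neg(c.data(), cx);
  coeff_add(&c0[0], c.data(), cx);
}

static void encrypt_into(PolyQ &c0, PolyQ &c1, const PolyQ &p0, const PolyQ &p1,
                         double m, const Ctx &cx) {
  double lgn = std::log2((double)cx.n);
  PolyQ u = sample_ternary(cx);
  PolyQ e1 = sample_cbd(cx, 42);
  PolyQ e2 = sample_cbd(cx, 42);
  c0 = poly_mult_modq(p0, u, cx, cx.B + lgn + 2);
  poly_add_ip(c0, e1, cx);
  c1 = poly_mult_modq(p1, u, cx, cx.B + lgn + 2);
  poly_add_ip(c1, e2, cx);
  encode_into(c0, m, cx);
}

// [[Rcpp::export]]
List cpp_encrypt(NumericMatrix p0, NumericMatrix p1, int n, int B, double t_,
                 double m) {
  Ctx cx = make_ctx(n, B, t_);
  PolyQ P0 = poly_from_R(p0), P1 = poly_from_R(p1), c0, c1;
  encrypt_into(c0, c1, P0, P1, m, cx);
  return List::create(poly_to_R(c0, cx), poly_to_R(c1, cx));
}

// phase = c0 + c1*s (+ c2*s^2) mod q
static PolyQ phase_of(const std::vector<PolyQ> &parts, const PolyQ &s,
                      const Ctx &cx) {
  double lgn = std::log2((double)cx.n);
  PolyQ ph = parts[0];
  PolyQ c1s = poly_mult_modq(parts[1], s, cx, cx.B + lgn + 2);
  poly_add_ip(ph, c1s, cx);
  if (parts.size() == 3) {
    PolyQ s2 = poly_mult_modq(s, s, cx, lgn + 2);
    PolyQ c2s2 = poly_mult_modq(parts[2], s2, cx, cx.B + lgn + lgn + 3);
    poly_add_ip(ph, c2s2, cx);
  }
  return ph;
}

// [[Rcpp::export]]
List cpp_decrypt(List parts, NumericMatrix s_, int n, int B, double t_) {
  Ctx cx = make_ctx(n, B, t_);
  std::vector<PolyQ> ps;
  for (int i = 0; i < parts.size(); ++i)
    ps.push_back(poly_from_R(as<NumericMatrix>(parts[i])));
  PolyQ s = poly_from_R(s_);
  PolyQ ph = phase_of(ps, s, cx);
  // message: round(t * x0 / 2^B) mod t, centered
  std::vector<u32> mag(cx.Lq);
  int sg = coeff_centered(&ph[0], mag.data(), cx);
  BN y = bn_mul_small(BN(mag.begin(), mag.end()), cx.t);
  y = bn_add(y, cx.half);
  // shift right by B bits
  BN sh(y.begin() + std::min((size_t)(cx.B / 32), y.size()), y.end());
  int bs = cx.B % 32;
  if (bs) {
    for (size_t l = 0; l + 1 < sh.size(); ++l)
      sh[l] = (sh[l] >> bs) | (sh[l + 1] << (32 - bs));
    if (!sh.empty()) sh.back() >>= bs;
  }
  int64_t mraw = (int64_t)(bn_nlimbs(sh) == 0 ? 0 : bn_mod_u64(sh, cx.t));
  if (sg < 0) mraw = ((int64_t)cx.t - mraw) % (int64_t)cx.t;
  if (2 * mraw > (int64_t)cx.t) mraw -= (int64_t)cx.t;
  // noise: residual of phase against Delta * m
  PolyQ enc0 = poly_zero(cx);
  encode_into(enc0, (double)mraw, cx);
  coeff_sub(&ph[0], &enc0[0], cx);
  double nb = small_bound_log2(ph, cx);
  return List::create(_["value"] = (double)mraw, _["noise_log2"] = nb);
}

// ---------------------------------------------------------------- add/mult ---

static std::vector<PolyQ> parts_from_R(List parts) {
  std::vector<PolyQ> ps;
  for (int i = 0; i < parts.size(); ++i)
    ps.push_back(poly_from_R(as<NumericMatrix>(parts[i])));
  return ps;
}

// [[Rcpp::export]]
List cpp_add(List parts1, List parts2, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  std::vector<PolyQ> a = parts_from_R(parts1), b = parts_from_R(parts2);
  size_t sz = std::max(a.size(), b.size());
  List out(sz);
  for (size_t i = 0; i < sz; ++i) {
    PolyQ r = i < a.size() ? a[i] : poly_zero(cx);
    if (i < b.size()) poly_add_ip(r, b[i], cx);
    out[i] = poly_to_R(r, cx);
  }
  return out;
}

// tensor product with t/q scaling: (c10,c11) x (c20,c21) -> 3 parts
static std::vector<PolyQ> tensor3(const std::vector<PolyQ> &a,
                                  const std::vector<PolyQ> &b, const Ctx &cx) {
  int n = cx.n;
  double lgn = std::log2((double)n);
  double bound = 2.0 * cx.B + lgn + 3.0; // |coef| <= 2 n (q/2)^2
  std::vector<u64> ps = primes_for(bound);
  size_t P = ps.size();
  std::vector<std::vector<u64>> r0(P), r1(P), r2(P);
  {
    std::vector<u64> fa0(n), fa1(n), fb0(n), fb1(n);
    for (size_t k = 0; k < P; ++k) {
      const PrimeTab &T = get_tab(ps[k], n);
      centered_residues(a[0], cx, ps[k], fa0.data());
      centered_residues(a[1], cx, ps[k], fa1.data());
      centered_residues(b[0], cx, ps[k], fb0.data());
      centered_residues(b[1], cx, ps[k], fb1.data());
      ntt_fwd(fa0.data(), n, T); ntt_fwd(fa1.data(), n, T);
      ntt_fwd(fb0.data(), n, T); ntt_fwd(fb1.data(), n, T);
      r0[k].resize(n); r1[k].resize(n); r2[k].resize(n);
      for (int i = 0; i < n; ++i) {
        r0[k][i] = mulmod(fa0[i], fb0[i], ps[k]);
        u64 x = mulmod(fa0[i], fb1[i], ps[k]) + mulmod(fa1[i], fb0[i], ps[k]);
        r1[k][i] = x >= ps[k] ? x - ps[k] : x;
        r2[k][i] = mulmod(fa1[i], fb1[i], ps[k]);
      }
      ntt_inv(r0[k].data(), n, T); ntt_inv(r1[k].data(), n, T);
      ntt_inv(r2[k].data(), n, T);
    }
  }
  Garner G(ps);
  std::vector<PolyQ> out(3, poly_zero(cx));
  std::vector<u64> rr(P);
  BN mag;
  for (int part = 0; part < 3; ++part) {
    const std::vector<std::vector<u64>> &R =
        part == 0 ? r0 : (part == 1 ? r1 : r2);
    for (int i = 0; i < n; ++i) {
      for (size_t k = 0; k < P; ++k) rr[k] = R[k][i];
      int sg = G.reconstruct(rr.data(), mag);
      // round(t * x / 2^B), then mod 2^B with sign
      BN y = bn_mul_small(mag, cx.t);
      y = bn_add(y, cx.half);
      // shift right by B
      int ls = cx.B / 32, bs = cx.B % 32;
      BN sh;
      if ((size_t)ls < y.size()) sh.assign(y.begin() + ls, y.end());
      if (bs) {
        for (size_t l = 0; l + 1 < sh.size(); ++l)
          sh[l] = (sh[l] >> bs) | (sh[l + 1] << (32 - bs));
        if (!sh.empty()) sh.back() >>= bs;
      }
      signed_mod_q(bn_is_zero(sh) ? 0 : sg, sh, &out[part][(size_t)i * cx.Lq], cx);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_tensor(List ct1, List ct2, int n, int B, double t_) {
  Ctx cx = make_ctx(n, B, t_);
  std::vector<PolyQ> a = parts_from_R(ct1), b = parts_from_R(ct2);
  std::vector<PolyQ> out = tensor3(a, b, cx);
  return List::create(poly_to_R(out[0], cx), poly_to_R(out[1], cx),
                      poly_to_R(out[2], cx));
}

// relinearize a size-3 ciphertext using base-2^w decomposition of c2
static void relin_ip(std::vector<PolyQ> &parts, const std::vector<PolyQ> &rb,
                     const std::vector<PolyQ> &ra, int w_bits, const Ctx &cx) {
  int n = cx.n;
  int ell = (cx.B + w_bits - 1) / w_bits;
  double lgn = std::log2((double)n);
  double bound = w_bits + cx.B + lgn + std::log2((double)ell) + 2.0;
  std::vector<u64> ps = primes_for(bound);
  size_t P = ps.size();
  u32 wmask = (w_bits >= 32) ? 0xffffffffu : (((u32)1 << w_bits) - 1);
  // decompose c2 into ell digit polynomials (coefficients in [0, 2^w))
  const PolyQ &c2 = parts[2];
  std::vector<std::vector<u64>> acc0(P), acc1(P);
  std::vector<u64> dig(n), kb(n), ka(n);
  for (size_t k = 0; k < P; ++k) { acc0[k].assign(n, 0); acc1[k].assign(n, 0); }
  for (int i = 0; i < ell; ++i) {
    // digit i of every coefficient
    int sh = i * w_bits, ls = sh / 32, bs = sh % 32;
    for (int j = 0; j < n; ++j) {
      const u32 *c = &c2[(size_t)j * cx.Lq];
      u64 v = 0;
      if (ls < cx.Lq) v = c[ls] >> bs;
      if (bs && ls + 1 < cx.Lq) v |= (u64)c[ls + 1] << (32 - bs);
      dig[j] = v & wmask;
    }
    for (size_t k = 0; k < P; ++k) {
      const PrimeTab &T = get_tab(ps[k], n);
      for (int j = 0; j < n; ++j) kb[j] = dig[j] % ps[k];
      ntt_fwd(kb.data(), n, T);
      std::vector<u64> fd = kb; // forward NTT of digit poly
      centered_residues(rb[i], cx, ps[k], kb.data());
      ntt_fwd(kb.data(), n, T);
      for (int j = 0; j < n; ++j) {
        u64 x = acc0[k][j] + mulmod(fd[j], kb[j], ps[k]);
        acc0[k][j] = x >= ps[k] ? x - ps[k] : x;
      }
      centered_residues(ra[i], cx, ps[k], ka.data());
      ntt_fwd(ka.data(), n, T);
      for (int j = 0; j < n; ++j) {
        u64 x = acc1[k][j] + mulmod(fd[j], ka[j], ps[k]);
        acc1[k][j] = x >= ps[k] ? x - ps[k] : x;
      }
    }
  }
  for (size_t k = 0; k < P; ++k) {
    const PrimeTab &T = get_tab(ps[k], cx.n);
    ntt_inv(acc0[k].data(), cx.n, T);
    ntt_inv(acc1[k].data(), cx.n, T);
  }
  Garner G(ps);
  std::vector<u64> rr(P);
  BN mag;
  std::vector<u32> tmp(cx.Lq);
  for (int part = 0; part < 2; ++part) {
    std::vector<std::vector<u64>> &A = part == 0 ? acc0 : acc1;
    for (int i = 0; i < n; ++i) {
      for (size_t k = 0; k < P; ++k) rr[k] = A[k][i];
      int sg = G.reconstruct(rr.data(), mag);
      signed_mod_q(sg, mag, tmp.data(), cx);
      coeff_add(&parts[part][(size_t)i * cx.Lq], tmp.data(), cx);
    }
  }
  parts.resize(2);
}

// [[Rcpp::export]]
List cpp_relin(List parts3, List rlk_b, List rlk_a, int n, int B, int w_bits) {
  Ctx cx = make_ctx(n, B, 2.0);
  std::vector<PolyQ> parts = parts_from_R(parts3);
  if (parts.size() != 3) stop("relinearization expects a size-3 ciphertext");
  std::vector<PolyQ> rb = parts_from_R(rlk_b), ra = parts_from_R(rlk_a);
  relin_ip(parts, rb, ra, w_bits, cx);
  return List::create(poly_to_R(parts[0], cx), poly_to_R(parts[1], cx));
}

// ------------------------------------------------------------- ring utility --

// [[Rcpp::export]]
NumericMatrix cpp_ring_mult(NumericMatrix a, NumericMatrix b, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  PolyQ A = poly_from_R(a), Bp = poly_from_R(b);
  double lgn = std::log2((double)n);
  PolyQ r = poly_mult_modq(A, Bp, cx, 2.0 * cx.B + lgn + 2.0);
  return poly_to_R(r, cx);
}

// [[Rcpp::export]]
NumericMatrix cpp_ring_add(NumericMatrix a, NumericMatrix b, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  PolyQ A = poly_from_R(a), Bp = poly_from_R(b);
  poly_add_ip(A, Bp, cx);
  return poly_to_R(A, cx);
}

// [[Rcpp::export]]
NumericMatrix cpp_poly_from_ints(NumericVector v, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  PolyQ p = poly_zero(cx);
  for (int i = 0; i < n && i < v.size(); ++i)
    small_to_coeff((int64_t)v[i], &p[(size_t)i * cx.Lq], cx);
  return poly_to_R(p, cx);
}

// centered coefficients as doubles (exact when |coef| < 2^53)
// [[Rcpp::export]]
NumericVector cpp_poly_centered(NumericMatrix m, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  PolyQ p = poly_from_R(m);
  NumericVector out(n);
  std::vector<u32> mag(cx.Lq);
  for (int i = 0; i < n; ++i) {
    int sg = coeff_centered(&p[(size_t)i * cx.Lq], mag.data(), cx);
    double v = 0;
    for (int l = cx.Lq - 1; l >= 0; --l) v = v * 4294967296.0 + mag[l];
    out[i] = sg < 0 ? -v : v;
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_pow2_dec(int B) {
  BN q((size_t)(B / 32) + 1, 0);
  q[B / 32] = (u32)1 << (B % 32);
  return bn_to_dec(q);
}

// bulk encryption context: public-key NTT residues and Garner tables are
// computed once and reused across many encryptions
struct BulkEnc {
  const Ctx &cx;
  std::vector<u64> ps;
  Garner G;
  std::vector<std::vector<u64>> fp0, fp1;
  BulkEnc(const Ctx &cx_, const PolyQ &p0, const PolyQ &p1)
      : cx(cx_),
        ps(primes_for(cx_.B + std::log2((double)cx_.n) + 2)),
        G(ps) {
    size_t P = ps.size();
    fp0.resize(P); fp1.resize(P);
    for (size_t k = 0; k < P; ++k) {
      const PrimeTab &T = get_tab(ps[k], cx.n);
      fp0[k].resize(cx.n); fp1[k].resize(cx.n);
      centered_residues(p0, cx, ps[k], fp0[k].data());
      centered_residues(p1, cx, ps[k], fp1[k].data());
      ntt_fwd(fp0[k].data(), cx.n, T);
      ntt_fwd(fp1[k].data(), cx.n, T);
    }
  }
  void encrypt(double m, PolyQ &c0, PolyQ &c1) const {
    int n = cx.n;
    size_t P = ps.size();
    std::vector<int> u(n);
    for (int i = 0; i < n; ++i) u[i] = (int)std::floor(unif_rand() * 3.0) - 1;
    std::vector<std::vector<u64>> r0(P), r1(P);
    std::vector<u64> fu(n);
    for (size_t k = 0; k < P; ++k) {
      const PrimeTab &T = get_tab(ps[k], n);
      u64 p = ps[k];
      for (int i = 0; i < n; ++i)
        fu[i] = u[i] < 0 ? p - 1 : (u64)u[i];
      ntt_fwd(fu.data(), n, T);
      r0[k].resize(n); r1[k].resize(n);
      for (int i = 0; i < n; ++i) {
        r0[k][i] = mulmod(fu[i], fp0[k][i], p);
        r1[k][i] = mulmod(fu[i], fp1[k][i], p);
      }
      ntt_inv(r0[k].data(), n, T);
      ntt_inv(r1[k].data(), n, T);
    }
    c0.assign((size_t)n * cx.Lq, 0);
    c1.assign((size_t)n * cx.Lq, 0);
    BN mag;
    std::vector<u64> rr(P);
    std::vector<u32> tmp(cx.Lq);
    for (int i = 0; i < n; ++i) {
      for (size_t k = 0; k < P; ++k) rr[k] = r0[k][i];
      int sg = G.reconstruct(rr.data(), mag);
      signed_mod_q(sg, mag, &c0[(size_t)i * cx.Lq], cx);
      for (size_t k = 0; k < P; ++k) rr[k] = r1[k][i];
      sg = G.reconstruct(rr.data(), mag);
      signed_mod_q(sg, mag, &c1[(size_t)i * cx.Lq], cx);
    }
    // errors and message
    std::vector<u32> ec(cx.Lq);
    for (int i = 0; i < n; ++i) {
      int64_t e1 = (int64_t)R::rbinom(42.0, 0.5) - 21;
      small_to_coeff(e1, ec.data(), cx);
      coeff_add(&c0[(size_t)i * cx.Lq], ec.data(), cx);
      int64_t e2 = (int64_t)R::rbinom(42.0, 0.5) - 21;
      small_to_coeff(e2, ec.data(), cx);
      coeff_add(&c1[(size_t)i * cx.Lq], ec.data(), cx);
    }
    encode_into(c0, m, cx);
  }
};

// ------------------------------------------------- bulk flag-matrix storage --

struct CtStore {
  int n, Lq, cells;
  std::vector<u32> data; // cell-major: cell * (2*n*Lq), parts c0 then c1
};

// [[Rcpp::export]]
SEXP cpp_encrypt_store(IntegerMatrix flags, NumericMatrix p0, NumericMatrix p1,
                       int n, int B, double t_) {
  Ctx cx = make_ctx(n, B, t_);
  int npat = flags.nrow(), months = flags.ncol();
  int cells = npat * months;
  XPtr<CtStore> xp(new CtStore(), true);
  xp->n = n; xp->Lq = cx.Lq; xp->cells = cells;
  xp->data.assign((size_t)cells * 2 * n * cx.Lq, 0u);
  PolyQ P0 = poly_from_R(p0), P1 = poly_from_R(p1), c0, c1;
  BulkEnc be(cx, P0, P1);
  size_t stride = (size_t)2 * n * cx.Lq;
  // month-major layout: cell = month * npat + patient
  for (int m = 0; m < months; ++m) {
    for (int i = 0; i < npat; ++i) {
      be.encrypt((double)flags(i, m), c0, c1);
      size_t off = ((size_t)m * npat + i) * stride;
      std::copy(c0.begin(), c0.end(), xp->data.begin() + off);
      std::copy(c1.begin(), c1.end(), xp->data.begin() + off + (size_t)n * cx.Lq);
    }
    Rcpp::checkUserInterrupt();
  }
  xp.attr("npat") = npat;
  xp.attr("months") = months;
  return xp;
}

// [[Rcpp::export]]
List cpp_store_col_sums(SEXP store, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  XPtr<CtStore> xp(store);
  int npat = as<int>(xp.attr("npat")), months = as<int>(xp.attr("months"));
  size_t stride = (size_t)2 * n * cx.Lq, plen = (size_t)n * cx.Lq;
  List out(months);
  for (int m = 0; m < months; ++m) {
    PolyQ c0 = poly_zero(cx), c1 = poly_zero(cx);
    for (int i = 0; i < npat; ++i) {
      size_t off = ((size_t)m * npat + i) * stride;
      for (int j = 0; j < n; ++j) {
        coeff_add(&c0[(size_t)j * cx.Lq], &xp->data[off + (size_t)j * cx.Lq], cx);
        coeff_add(&c1[(size_t)j * cx.Lq],
                  &xp->data[off + plen + (size_t)j * cx.Lq], cx);
      }
    }
    out[m] = List::create(poly_to_R(c0, cx), poly_to_R(c1, cx));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_store_get(SEXP store, int patient, int month, int n, int B) {
  Ctx cx = make_ctx(n, B, 2.0);
  XPtr<CtStore> xp(store);
  int npat = as<int>(xp.attr("npat"));
  size_t stride = (size_t)2 * n * cx.Lq, plen = (size_t)n * cx.Lq;
  size_t off = ((size_t)month * npat + patient) * stride;
  PolyQ c0(xp->data.begin() + off, xp->data.begin() + off + plen);
  PolyQ c1(xp->data.begin() + off + plen, xp->data.begin() + off + 2 * plen);
  return List::create(poly_to_R(c0, cx), poly_to_R(c1, cx));
}

// [[Rcpp::export]]
IntegerMatrix cpp_store_decrypt(SEXP store, NumericMatrix s_, int n, int B,
                                double t_) {
  Ctx cx = make_ctx(n, B, t_);
  XPtr<CtStore> xp(store);
  int npat = as<int>(xp.attr("npat")), months = as<int>(xp.attr("months"));
  size_t stride = (size_t)2 * n * cx.Lq, plen = (size_t)n * cx.Lq;
  PolyQ s = poly_from_R(s_);
  IntegerMatrix out(npat, months);
  for (int m = 0; m < months; ++m) {
    for (int i = 0; i < npat; ++i) {
      size_t off = ((size_t)m * npat + i) * stride;
      std::vector<PolyQ> parts(2);
      parts[0].assign(xp->data.begin() + off, xp->data.begin() + off + plen);
      parts[1].assign(xp->data.begin() + off + plen,
                      xp->data.begin() + off + 2 * plen);
      PolyQ ph = phase_of(parts, s, cx);
      std::vector<u32> mag(cx.Lq);
      int sg = coeff_centered(&ph[0], mag.data(), cx);
      BN y = bn_mul_small(BN(mag.begin(), mag.end()), cx.t);
      y = bn_add(y, cx.half);
      int ls = cx.B / 32, bs = cx.B % 32;
      BN sh;
      if ((size_t)ls < y.size()) sh.assign(y.begin() + ls, y.end());
      if (bs) {
        for (size_t l = 0; l + 1 < sh.size(); ++l)
          sh[l] = (sh[l] >> bs) | (sh[l + 1] << (32 - bs));
        if (!sh.empty()) sh.back() >>= bs;
      }
      int64_t mraw = (int64_t)(bn_nlimbs(sh) == 0 ? 0 : bn_mod_u64(sh, cx.t));
      if (sg < 0) mraw = ((int64_t)cx.t - mraw) % (int64_t)cx.t;
      if (2 * mraw > (int64_t)cx.t) mraw -= (int64_t)cx.t;
      out(i, m) = (int)mraw;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// --------------------------------------------- batched encrypted exposure ----

// Per month: enc(weight) * enc(dose) (tensor + relinearize), summed over months.
// Returns the final size-2 ciphertext; decryption happens once, in R.
// [[Rcpp::export]]
List cpp_exposure_ct(IntegerVector w, IntegerVector d, NumericMatrix p0,
                     NumericMatrix p1, List rlk_b, List rlk_a, int n, int B,
                     double t_, int w_bits) {
  Ctx cx = make_ctx(n, B, t_);
  PolyQ P0 = poly_from_R(p0), P1 = poly_from_R(p1);
  BulkEnc be(cx, P0, P1);
  std::vector<PolyQ> rb = parts_from_R(rlk_b), ra = parts_from_R(rlk_a);
  PolyQ acc0 = poly_zero(cx), acc1 = poly_zero(cx);
  for (int m = 0; m < w.size(); ++m) {
    std::vector<PolyQ> cw(2), cd(2);
    be.encrypt((double)w[m], cw[0], cw[1]);
    be.encrypt((double)d[m], cd[0], cd[1]);
    std::vector<PolyQ> prod = tensor3(cw, cd, cx);
    relin_ip(prod, rb, ra, w_bits, cx);
    poly_add_ip(acc0, prod[0], cx);
    poly_add_ip(acc1, prod[1], cx);
    Rcpp::checkUserInterrupt();
  }
  return List::create(poly_to_R(acc0, cx), poly_to_R(acc1, cx));
}
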