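// Dynamic-programming engines for single-sequence RNA folding
// (base-pair maximization over non-crossing structures).
//
// Shared recurrence, with s_{i,j} the half-open substring s_i..s_{j-1}:
//   L[i,j]  = max(Lp[i,j], Lc[i,j])              (j > i+1)
//   Lp[i,j] = max_{k in (i,j)} L[i,k] + L[k,j]   (partitioned)
//   Lc[i,j] = L[i+1,j-1] + beta(s_i, s_{j-1})    (co-terminus)
//   L[i,i] = L[i,i+1] = 0; cells with j < i are a -inf sentinel.
//
// Engines differ only in how the split-point maximization Lp is organised:
//   NAIVE  every k in (i,j), cell by cell.
//   SP     sparsified: k = i+1 plus k with (i,k) STEP and (k,j) OCT.
//   FR     Four-Russians: q-blocks, delta-encoded columns, on-demand
//          MUL/MAX lookup tables; partial groups per cell.
//   SFR    FR gated by sigStep/sigOct bit signatures through the G table;
//          per-cell parts restricted to sparsification candidates.
// The wavefront simulator reuses the FR/SFR group kernel under a
// synchronous round schedule with dependency-stamp assertions.
//
// Counter convention (fixed across engines): each candidate split point
// examined while computing some Lp[i,j] increments split_comparisons by 1;
// every lookup-table event (hit or build) increments its own counter by 1.
// The Lc evaluation and the final two-way max are not counted.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int NEG_SENT = INT_MIN / 4;

struct DeltaV {
  int x0;
  long long delta;
};

// base-D positional encoding of consecutive differences, first difference
// most significant
static long long delta_pack(const std::vector<int>& v, int D) {
  long long d = 0;
  for (size_t l = 1; l < v.size(); ++l) {
    int dig = v[l - 1] - v[l];
    if (dig < 0 || dig >= D)
      stop("vector is not D-discrete: difference %d at position %d outside [0, %d]",
           dig, (int)l, D - 1);
    d = d * (long long)D + dig;
  }
  return d;
}

static std::vector<int> delta_unpack(int x0, long long delta, int q, int D) {
  long long cap = 1;
  for (int l = 1; l < q; ++l) cap *= D;
  if (delta < 0 || delta >= cap) stop("delta out of range for given q and D");
  std::vector<int> dig(q > 0 ? q - 1 : 0);
  for (int l = q - 2; l >= 0; --l) {
    dig[l] = (int)(delta % D);
    delta /= D;
  }
  std::vector<int> v(q);
  if (q > 0) v[0] = x0;
  for (int l = 1; l < q; ++l) v[l] = v[l - 1] - dig[l - 1];
  return v;
}

struct Counters {
  double split = 0, mul_l = 0, mul_b = 0, max_l = 0, max_b = 0, g_b = 0;
};

enum Mode { M_NAIVE = 0, M_SP = 1, M_FR = 2, M_SFR = 3 };

class Solver {
public:
  int n, q, D, min_loop;
  bool gated, debug_checks;
  std::vector<int> s;            // encoded sequence, 0..3
  std::vector<int> score;        // 4x4 pair scores
  std::vector<int> L, Lp, Lc;    // (n+1)^2, row-major
  std::vector<uint8_t> octf, stepf;
  std::vector<std::vector<int>> oct_rows;   // per column j: OCT rows, descending
  std::vector<std::vector<int>> step_rows;  // per column k: STEP rows
  int Gn;                        // number of index groups covering [0, n]
  long long Dq1;                 // D^(q-1)
  std::unordered_map<long long, DeltaV> mul, maxt;
  std::unordered_map<long long, int> mul_per_block;
  std::map<std::pair<int, int>, std::vector<int>> gtab;
  std::vector<std::vector<int>> sigoct;   // [g][j]
  std::vector<std::vector<int>> sigstep;  // [g'][g]
  Counters cnt;

  // wavefront simulation state
  bool par = false;
  int cur_d = 0, cur_j = 0;
  std::vector<int> st_round, st_col;      // finalization stamps
  std::vector<double> col_ops;

  Solver(const IntegerVector& seq, const IntegerMatrix& sc, int q_, int min_loop_,
         bool gated_, bool debug_)
      : q(q_), min_loop(min_loop_), gated(gated_), debug_checks(debug_) {
    n = seq.size();
    s.assign(seq.begin(), seq.end());
    score.assign(16, 0);
    int bmax = 0;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        score[a * 4 + b] = sc(a, b);
        if (sc(a, b) > bmax) bmax = sc(a, b);
      }
    D = bmax + 1;
    if (q < 1) stop("q must be >= 1");
    Gn = n / q + 1;
    Dq1 = 1;
    for (int l = 1; l < q; ++l) Dq1 *= D;
    size_t m = (size_t)(n + 1) * (n + 1);
    L.assign(m, NEG_SENT);
    Lp.assign(m, NEG_SENT);
    Lc.assign(m, NEG_SENT);
    octf.assign(m, 0);
    stepf.assign(m, 0);
    oct_rows.assign(n + 1, {});
    step_rows.assign(n + 1, {});
    sigoct.assign(Gn, std::vector<int>(n + 1, 0));
    sigstep.assign(Gn, std::vector<int>(Gn, 0));
    for (int i = 0; i <= n; ++i) L[idx(i, i)] = 0;
    for (int i = 0; i < n; ++i) L[idx(i, i + 1)] = 0;
    // Seed every column's candidate list with its base sub-instance
    // s_{j-1,j}: a single nucleotide has no split point, so its only folding
    // is vacuously co-terminus and row j-1 is a legal STEP-OCT split-point
    // partner. The strict oct flags (reported) never mark base cells.
    for (int j = 1; j <= n; ++j) oct_rows[j].push_back(j - 1);
  }

  // gate signature for Kgroup g against column j: strict sigOct plus the
  // vacuous base-OCT bit for row j-1 when it falls inside the group
  inline int gateSig(int g, int j) {
    int m = sigoct[g][j];
    if (g == (j - 1) / q) m |= 1 << ((j - 1) - q * ((j - 1) / q));
    return m;
  }

  inline size_t idx(int i, int j) const { return (size_t)i * (n + 1) + j; }
  inline int beta(int a, int b) const { return score[a * 4 + b]; }

  void charge(double k) {
    if (par) col_ops[cur_j] += k;
  }
  inline void addSplit() { cnt.split += 1; charge(1); }

  // per-cell reads: legal from strictly earlier rounds, or earlier columns
  // within the current round, or the current task itself
  inline int getL(int i, int j) {
    if (par) {
      size_t c = idx(i, j);
      if (st_round[c] == INT_MAX)
        stop("scheduler bug: read of uncomputed cell (%d,%d)", i, j);
      if (st_round[c] > cur_d || (st_round[c] == cur_d && st_col[c] > cur_j))
        stop("scheduler bug: dependency violation at cell (%d,%d)", i, j);
    }
    return L[idx(i, j)];
  }
  // block/vector reads must be finalized in a strictly earlier round
  inline int getLStrict(int i, int j) {
    if (par) {
      size_t c = idx(i, j);
      if (st_round[c] == INT_MAX || st_round[c] >= cur_d)
        stop("scheduler bug: block read of cell (%d,%d) not finalized in an earlier round",
             i, j);
    }
    return L[idx(i, j)];
  }
  inline void stamp(int i, int j) {
    if (par) {
      st_round[idx(i, j)] = cur_d;
      st_col[idx(i, j)] = cur_j;
    }
  }

  int computeLc(int i, int j) {
    // pair (i, j-1); hairpin constraint: at least min_loop unpaired inside
    if (j - i - 2 < min_loop) return NEG_SENT;
    return getL(i + 1, j - 1) + beta(s[i], s[j - 1]);
  }

  void finalize(int i, int j, long long lp) {
    int lc = computeLc(i, j);
    int l = (int)std::max(lp, (long long)lc);
    size_t c = idx(i, j);
    Lp[c] = lp <= NEG_SENT ? NEG_SENT : (int)lp;
    Lc[c] = lc;
    L[c] = l;
    stamp(i, j);
    bool is_oct = (l == lc && lc > lp);
    bool is_step = (l > getL(i + 1, j));
    if (is_oct) {
      octf[c] = 1;
      oct_rows[j].push_back(i);
      sigoct[i / q][j] |= 1 << (i - q * (i / q));
    }
    if (is_step) {
      stepf[c] = 1;
      step_rows[j].push_back(i);
      sigstep[i / q][j / q] |= 1 << (j - q * (j / q));
    }
  }

  // all split points k in [klo, khi)
  long long evalAll(int i, int j, int klo, int khi) {
    long long lp = NEG_SENT;
    for (int k = klo; k < khi; ++k) {
      addSplit();
      long long v = (long long)getL(i, k) + getL(k, j);
      if (v > lp) lp = v;
    }
    return lp;
  }

  // sparsified candidates in [klo, khi): mandatory k = i+1 (if requested and
  // in range) plus every k with (k,j) OCT and (i,k) STEP; deduplicated
  long long evalSp(int i, int j, int klo, int khi, bool mandatory) {
    long long lp = NEG_SENT;
    if (mandatory && i + 1 >= klo && i + 1 < khi) {
      addSplit();
      lp = (long long)getL(i, i + 1) + getL(i + 1, j);
    }
    const std::vector<int>& oc = oct_rows[j];
    for (size_t t = 0; t < oc.size(); ++t) {
      int k = oc[t];
      if (k < klo || k >= khi || k == i + 1 || k <= i) continue;
      if (!stepf[idx(i, k)]) continue;
      addSplit();
      long long v = (long long)getL(i, k) + getL(k, j);
      if (v > lp) lp = v;
    }
    return lp;
  }

  // ---- Four-Russians machinery -------------------------------------------

  // delta-encode the subcolumn L[K_g, j] (reads must be strictly earlier
  // rounds in wavefront mode)
  DeltaV encodeSubcolumn(int g, int j) {
    std::vector<int> v(q);
    for (int c = 0; c < q; ++c) v[c] = getLStrict(q * g + c, j);
    DeltaV dv;
    dv.x0 = v[0];
    dv.delta = delta_pack(v, D);
    return dv;
  }

  // direct O(q^2) max-plus product of block L[I_g', K_g] with (0, delta)
  DeltaV blockMulDirect(int gp, int g, long long delta) {
    std::vector<int> v = delta_unpack(0, delta, q, D);
    std::vector<int> y(q);
    for (int r = 0; r < q; ++r) {
      long long best = LLONG_MIN;
      for (int c = 0; c < q; ++c) {
        long long val = (long long)getLStrict(q * gp + r, q * g + c) + v[c];
        if (val > best) best = val;
      }
      y[r] = (int)best;
    }
    DeltaV out;
    out.x0 = y[0];
    out.delta = delta_pack(y, D);
    return out;
  }

  // on-demand MUL: cached result of L[I_g',K_g] (x) (0, delta); caller adds
  // the subcolumn offset L[gq, j]
  DeltaV mulGet(int gp, int g, int j) {
    DeltaV v = encodeSubcolumn(g, j);
    long long key = ((long long)gp * Gn + g) * Dq1 + v.delta;
    std::unordered_map<long long, DeltaV>::iterator it = mul.find(key);
    DeltaV rel;
    if (it != mul.end()) {
      cnt.mul_l += 1;
      charge(1);
      rel = it->second;
    } else {
      cnt.mul_b += 1;
      charge(1);
      rel = blockMulDirect(gp, g, v.delta);
      mul[key] = rel;
      mul_per_block[(long long)gp * Gn + g] += 1;
    }
    DeltaV out;
    out.x0 = rel.x0 + v.x0;  // + L[gq, j]
    out.delta = rel.delta;
    return out;
  }

  // elementwise max of two delta-encoded vectors via the on-demand MAX table.
  // A D-discrete vector drops by at most D-1 per step, so the larger-headed
  // vector dominates everywhere once the head gap exceeds (q-1)(D-1)
  // (which reduces to q-1 in the 2-discrete case).
  DeltaV dmax(DeltaV a, DeltaV b) {
    if (b.x0 < a.x0) std::swap(a, b);
    long long h = (long long)b.x0 - a.x0;
    long long hmax = (long long)(q - 1) * (D - 1);
    if (h > hmax) {
      cnt.max_l += 1;  // O(1) first-element comparison settles it
      return b;
    }
    long long key = (a.delta * Dq1 + b.delta) * (hmax + 1) + h;
    std::unordered_map<long long, DeltaV>::iterator it = maxt.find(key);
    DeltaV rel;
    if (it != maxt.end()) {
      cnt.max_l += 1;
      rel = it->second;
    } else {
      cnt.max_b += 1;
      charge(1);
      std::vector<int> va = delta_unpack(0, a.delta, q, D);
      std::vector<int> vb = delta_unpack((int)h, b.delta, q, D);
      std::vector<int> z(q);
      for (int l = 0; l < q; ++l) z[l] = std::max(va[l], vb[l]);
      rel.x0 = z.empty() ? 0 : z[0];
      rel.delta = delta_pack(z, D);
      maxt[key] = rel;
    }
    DeltaV out;
    out.x0 = rel.x0 + a.x0;
    out.delta = rel.delta;
    return out;
  }

  // on-demand G table: row groups g' <= g whose sigStep(g', g) intersects m
  const std::vector<int>& gLookup(int g, int m) {
    std::pair<int, int> key(g, m);
    std::map<std::pair<int, int>, std::vector<int>>::iterator it = gtab.find(key);
    if (it != gtab.end()) {
      if (debug_checks) {
        const std::vector<int>& set = it->second;
        for (size_t t = 0; t < set.size(); ++t)
          if ((sigstep[set[t]][g] & m) == 0)
            stop("G-table soundness violation at group %d signature %d", g, m);
      }
      return it->second;
    }
    cnt.g_b += 1;
    charge(1);
    std::vector<int> set;
    for (int gp = 0; gp <= g; ++gp)
      if ((sigstep[gp][g] & m) != 0) set.push_back(gp);
    return gtab.insert(std::make_pair(key, set)).first->second;
  }

  // pull-style vector part: accumulate contributions of all full Kgroups
  // strictly between gp and gj into the decoded vector P
  bool vectorPull(int j, int gp, int gj, bool gate, std::vector<int>& P) {
    bool have = false;
    DeltaV acc;
    for (int g = gp + 1; g < gj; ++g) {
      if (gate && (sigstep[gp][g] & gateSig(g, j)) == 0) continue;
      DeltaV y = mulGet(gp, g, j);
      acc = have ? dmax(acc, y) : y;
      have = true;
    }
    if (have) P = delta_unpack(acc.x0, acc.delta, q, D);
    return have;
  }

  // per-cell split points for FR (all k outside full groups)
  long long perCellFR(int i, int j, int gp, int gj) {
    int khi1 = std::min(q * (gp + 1), j);
    long long lp = evalAll(i, j, i + 1, khi1);
    if (i + 1 >= khi1) {  // mandatory k = i+1 falls in the next group
      addSplit();
      long long v = (long long)getL(i, i + 1) + getL(i + 1, j);
      if (v > lp) lp = v;
    }
    if (gp < gj) {
      int klo = std::max(q * gj, i + 2);
      if (klo < j) {
        long long v = evalAll(i, j, klo, j);
        if (v > lp) lp = v;
      }
    }
    return lp;
  }

  // per-cell split points for SFR (sparsification candidates only)
  long long perCellSFR(int i, int j, int gp, int gj) {
    int khi1 = std::min(q * (gp + 1), j);
    long long lp = evalSp(i, j, i + 1, khi1, true);
    if (i + 1 >= khi1) {
      addSplit();
      long long v = (long long)getL(i, i + 1) + getL(i + 1, j);
      if (v > lp) lp = v;
    }
    if (gp < gj) {
      int klo = std::max(q * gj, i + 2);
      if (klo < j) {
        long long v = evalSp(i, j, klo, j, false);
        if (v > lp) lp = v;
      }
    }
    return lp;
  }

  // ---- column drivers -----------------------------------------------------

  void colNaive(int j) {
    for (int i = j - 2; i >= 0; --i) finalize(i, j, evalAll(i, j, i + 1, j));
  }

  void colSP(int j) {
    for (int i = j - 2; i >= 0; --i) finalize(i, j, evalSp(i, j, i + 1, j, true));
  }

  void colFR(int j) {
    int gj = j / q;
    for (int gp = gj; gp >= 0; --gp) {
      std::vector<int> P;
      bool have = (gp < gj) ? vectorPull(j, gp, gj, false, P) : false;
      int ihi = std::min(q * gp + q - 1, j - 2);
      for (int i = ihi; i >= q * gp; --i) {
        long long lp = perCellFR(i, j, gp, gj);
        if (have) lp = std::max(lp, (long long)P[i - q * gp]);
        finalize(i, j, lp);
      }
    }
  }

  // push-style sparse Four-Russians column: as each Kgroup of the column is
  // finalized its sigOct is known, and its contribution is pushed through the
  // G table to exactly the row groups whose sigStep intersects it
  void colSFR(int j) {
    int gj = j / q;
    std::vector<DeltaV> acc(gj + 1);
    std::vector<char> have(gj + 1, 0);
    for (int gp = gj; gp >= 0; --gp) {
      std::vector<int> P;
      if (have[gp]) P = delta_unpack(acc[gp].x0, acc[gp].delta, q, D);
      int ihi = std::min(q * gp + q - 1, j - 2);
      for (int i = ihi; i >= q * gp; --i) {
        long long lp = perCellSFR(i, j, gp, gj);
        if (have[gp]) lp = std::max(lp, (long long)P[i - q * gp]);
        finalize(i, j, lp);
      }
      if (gp >= 1 && gp < gj) {
        if (gated) {
          int m = gateSig(gp, j);
          if (m != 0) {
            const std::vector<int>& set = gLookup(gp, m);
            for (size_t t = 0; t < set.size(); ++t) {
              int g2 = set[t];
              if (g2 >= gp) continue;
              DeltaV y = mulGet(g2, gp, j);
              acc[g2] = have[g2] ? dmax(acc[g2], y) : y;
              have[g2] = 1;
            }
          }
        } else {  // gate disabled (debug): push to every lower row group
          for (int g2 = 0; g2 < gp; ++g2) {
            DeltaV y = mulGet(g2, gp, j);
            acc[g2] = have[g2] ? dmax(acc[g2], y) : y;
            have[g2] = 1;
          }
        }
      }
    }
  }

  void runSerial(int mode) {
    for (int j = 1; j <= n; ++j) {
      switch (mode) {
        case M_NAIVE: colNaive(j); break;
        case M_SP: colSP(j); break;
        case M_FR: colFR(j); break;
        case M_SFR: colSFR(j); break;
      }
    }
  }

  // ---- synchronous wavefront simulation ----------------------------------
  // One logical process per column j; at round d the process computes the
  // subvector L[I_{g_j - d}, j]. Rounds run serially; within a round columns
  // advance in increasing j. Table builds are charged to the first
  // (lowest-index) requesting column.
  void runParallel(bool sparsified) {
    par = true;
    size_t m = (size_t)(n + 1) * (n + 1);
    st_round.assign(m, INT_MAX);
    st_col.assign(m, INT_MAX);
    col_ops.assign(n + 1, 0.0);
    st_round[idx(0, 0)] = -1;
    st_col[idx(0, 0)] = 0;
    int rounds = n / q;
    for (int d = 0; d <= rounds; ++d) {
      cur_d = d;
      for (int j = 1; j <= n; ++j) {
        int gj = j / q;
        if (d > gj) continue;
        cur_j = j;
        int gp = gj - d;
        std::vector<int> P;
        bool have = (gp < gj) ? vectorPull(j, gp, gj, sparsified, P) : false;
        int ihi = std::min(q * gp + q - 1, j);
        for (int i = ihi; i >= q * gp; --i) {
          if (i >= j - 1) {  // base cells: already 0, stamp finalization
            stamp(i, j);
            continue;
          }
          long long lp = sparsified ? perCellSFR(i, j, gp, gj)
                                    : perCellFR(i, j, gp, gj);
          if (have) lp = std::max(lp, (long long)P[i - q * gp]);
          finalize(i, j, lp);
        }
      }
    }
  }

  // ---- result marshalling -------------------------------------------------

  IntegerMatrix matOut(const std::vector<int>& M) const {
    IntegerMatrix out(n + 1, n + 1);
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= n; ++j)
        out(i, j) = (M[idx(i, j)] <= NEG_SENT / 2) ? NA_INTEGER : M[idx(i, j)];
    return out;
  }

  List result() const {
    LogicalMatrix oc(n + 1, n + 1), stm(n + 1, n + 1);
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= n; ++j) {
        oc(i, j) = octf[idx(i, j)] != 0;
        stm(i, j) = stepf[idx(i, j)] != 0;
      }
    double Z = 0;
    IntegerVector step_count(n + 1), oct_count(n + 1);
    for (int j = 0; j <= n; ++j) {
      step_count[j] = (int)step_rows[j].size();
      int zo = 0;  // strict OCT cells only (seeded base candidates excluded)
      for (int i = 0; i < j; ++i) zo += octf[idx(i, j)];
      oct_count[j] = zo;
      Z += zo;
    }
    int mul_block_max = 0;
    for (std::unordered_map<long long, int>::const_iterator it = mul_per_block.begin();
         it != mul_per_block.end(); ++it)
      if (it->second > mul_block_max) mul_block_max = it->second;
    IntegerMatrix so(Gn, n + 1), ss(Gn, Gn);
    for (int g = 0; g < Gn; ++g) {
      for (int j = 0; j <= n; ++j) so(g, j) = sigoct[g][j];
      for (int g2 = 0; g2 < Gn; ++g2) ss(g, g2) = sigstep[g][g2];
    }
    return List::create(
        _["score"] = n >= 0 ? L[idx(0, n)] : 0,
        _["L"] = matOut(L), _["Lp"] = matOut(Lp), _["Lc"] = matOut(Lc),
        _["oct"] = oc, _["step"] = stm,
        _["counters"] = NumericVector::create(
            _["split_comparisons"] = cnt.split, _["mul_lookups"] = cnt.mul_l,
            _["mul_builds"] = cnt.mul_b, _["max_lookups"] = cnt.max_l,
            _["max_builds"] = cnt.max_b, _["g_builds"] = cnt.g_b),
        _["Z"] = Z, _["step_count"] = step_count, _["oct_count"] = oct_count,
        _["q"] = q, _["D"] = D,
        _["mul_entries"] = (double)mul.size(),
        _["mul_block_max"] = mul_block_max,
        _["max_entries"] = (double)maxt.size(),
        _["g_entries"] = (double)gtab.size(),
        _["sig_oct"] = so, _["sig_step"] = ss);
  }
};

// [[Rcpp::export]]
List rs_solve(IntegerVector seq, IntegerMatrix score, int mode, int q,
              int min_loop, bool gated, bool debug_checks) {
  Solver sol(seq, score, q, min_loop, gated, debug_checks);
  sol.runSerial(mode);
  return sol.result();
}

// [[Rcpp::export]]
List rs_solve_parallel(IntegerVector seq, IntegerMatrix score, int q,
                       int min_loop, bool sparsified, bool debug_checks) {
  Solver sol(seq, score, q, min_loop, sparsified, debug_checks);
  sol.runParallel(sparsified);
  List out = sol.result();
  int n = sol.n;
  NumericVector ops(n + 1);
  IntegerVector rounds(n + 1);
  for (int j = 0; j <= n; ++j) {
    ops[j] = sol.col_ops[j];
    rounds[j] = j / q + 1;
  }
  out["col_ops"] = ops;
  out["col_rounds"] = rounds;
  out["total_rounds"] = n / q + 1;
  return out;
}

// ---- exported primitives (same code paths the engines use) ----------------

// [[Rcpp::export]]
List rs_delta_encode(IntegerVector v, int D) {
  std::vector<int> x(v.begin(), v.end());
  if (x.empty()) stop("vector must be non-empty");
  return List::create(_["x0"] = x[0], _["delta"] = (double)delta_pack(x, D),
                      _["q"] = (int)x.size(), _["D"] = D);
}

// [[Rcpp::export]]
IntegerVector rs_delta_decode(int x0, double delta, int q, int D) {
  std::vector<int> v = delta_unpack(x0, (long long)delta, q, D);
  return IntegerVector(v.begin(), v.end());
}

// [[Rcpp::export]]
List rs_block_mul(IntegerMatrix B, int x0, double delta, int D) {
  int q = B.nrow();
  if (B.ncol() != q) stop("block must be square");
  std::vector<int> v = delta_unpack(x0, (long long)delta, q, D);
  std::vector<int> y(q);
  for (int r = 0; r < q; ++r) {
    long long best = LLONG_MIN;
    for (int c = 0; c < q; ++c) {
      long long val = (long long)B(r, c) + v[c];
      if (val > best) best = val;
    }
    y[r] = (int)best;
  }
  return List::create(_["x0"] = y[0], _["delta"] = (double)delta_pack(y, D),
                      _["q"] = q, _["D"] = D);
}

// [[Rcpp::export]]
List rs_delta_max(int v0, double dv, int w0, double dw, int q, int D) {
  long long a0 = v0, b0 = w0, da = (long long)dv, db = (long long)dw;
  if (b0 < a0) {
    std::swap(a0, b0);
    std::swap(da, db);
  }
  long long h = b0 - a0;
  if (h > (long long)(q - 1) * (D - 1))
    return List::create(_["x0"] = (int)b0, _["delta"] = (double)db, _["q"] = q,
                        _["D"] = D);
  std::vector<int> va = delta_unpack(0, da, q, D);
  std::vector<int> vb = delta_unpack((int)h, db, q, D);
  std::vector<int> z(q);
  for (int l = 0; l < q; ++l) z[l] = std::max(va[l], vb[l]);
  return List::create(_["x0"] = z[0] + (int)a0,
                      _["delta"] = (double)delta_pack(z, D), _["q"] = q,
                      _["D"] = D);
}
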