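// Eden growth on a square lattice with full genealogy recording.
//
// Geometries:
//   bounded (1+1): transverse axis x (periodic, width N), depth d >= 0
//   bounded (2+1): transverse axes x,y (periodic, N x N), depth d >= 0
//   unbounded    : open plane, founder at the origin
//
// One event is either a growth step (an empty site adjacent to the cluster
// is chosen uniformly; its parent uniformly among occupied von-Neumann
// neighbours) or, with probability pMove per event, a diffusion attempt (a
// uniformly chosen boundary cell hops into a uniformly chosen empty
// neighbour, rejected unless the destination touches an occupied cell other
// than the mover).  All randomness goes through R's RNG (R_unif_index /
// unif_rand) so set.seed() makes runs bit-reproducible, and the pure-R
// reference stepper can replay the identical draw sequence.

#include <Rcpp.h>
#include <R_ext/Random.h>
using namespace Rcpp;

namespace {

struct EdenSim {
  // geometry
  int geom;        // 0 bounded (1+1), 1 bounded (2+1), 2 unbounded
  int N;           // transverse width (bounded only)
  int side;        // grid side for unbounded (odd), origin at centre
  int depthCap;    // current depth capacity (bounded)
  long nsite;

  // grids (site -> value)
  std::vector<int> cellAt;   // cell index or -1
  std::vector<int> candPos;  // index into cand or -1
  std::vector<int> bndPos;   // index into bnd or -1

  // dynamic sets
  std::vector<int> cand;     // empty sites adjacent to >=1 occupied site
  std::vector<int> bnd;      // occupied sites with >=1 empty neighbour
  std::vector<char> bndLow;  // parallel to bnd: cell generation <= G-1 ?
  long lowCnt;               // number of 'low' entries in bnd

  // records
  std::vector<int> parent;   // 0-based cell index, -1 for founders
  std::vector<int> gen;
  std::vector<int> birth;    // birth site (linear index)
  std::vector<int> cur;      // current site per cell

  int G;                     // target generation
  double pMove;
  long nEvents, nMoves, nRejected;

  int nbuf[6];               // neighbour buffer

  long siteCount() const { return (long)cellAt.size(); }

  // ---- geometry -----------------------------------------------------
  // Bounded layouts are x-major so extending depth appends to the arrays.
  void growDepth(int need) {
    if (need < depthCap) return;
    int newCap = depthCap;
    while (newCap <= need) newCap *= 2;
    long layer = (geom == 0) ? N : (long)N * N;
    long newSize = layer * newCap;
    cellAt.resize(newSize, -1);
    candPos.resize(newSize, -1);
    bndPos.resize(newSize, -1);
    depthCap = newCap;
  }

  // fills nbuf with neighbour site indices (-1 = outside), returns count 4/6
  int neighbours(int s) {
    if (geom == 0) {
      int x = s % N, d = s / N;
      nbuf[0] = (x + 1 == N ? 0 : x + 1) + d * N;
      nbuf[1] = (x == 0 ? N - 1 : x - 1) + d * N;
      if (d + 1 >= depthCap) growDepth(d + 1);
      nbuf[2] = x + (d + 1) * N;
      nbuf[3] = d > 0 ? x + (d - 1) * N : -1;
      return 4;
    } else if (geom == 1) {
      long NN = (long)N * N;
      int x = s % N, y = (s / N) % N, d = (int)(s / NN);
      long base = (long)d * NN;
      nbuf[0] = (int)(base + (x + 1 == N ? 0 : x + 1) + (long)y * N);
      nbuf[1] = (int)(base + (x == 0 ? N - 1 : x - 1) + (long)y * N);
      nbuf[2] = (int)(base + x + (long)(y + 1 == N ? 0 : y + 1) * N);
      nbuf[3] = (int)(base + x + (long)(y == 0 ? N - 1 : y - 1) * N);
      if (d + 1 >= depthCap) growDepth(d + 1);
      nbuf[4] = (int)(base + NN + x + (long)y * N);
      nbuf[5] = d > 0 ? (int)(base - NN + x + (long)y * N) : -1;
      return 6;
    } else {
      int x = s % side, y = s / side;
      nbuf[0] = (x + 1 < side) ? s + 1 : -1;
      nbuf[1] = (x > 0) ? s - 1 : -1;
      nbuf[2] = (y + 1 < side) ? s + side : -1;
      nbuf[3] = (y > 0) ? s - side : -1;
      if (nbuf[0] < 0 || nbuf[1] < 0 || nbuf[2] < 0 || nbuf[3] < 0)
        stop("unbounded Eden lattice margin exceeded");
      return 4;
    }
  }

  bool hasEmptyNb(int s) {
    int k = neighbours(s);
    for (int i = 0; i < k; ++i)
      if (nbuf[i] >= 0 && cellAt[nbuf[i]] < 0) return true;
    return false;
  }
  bool hasOccNb(int s) {
    int k = neighbours(s);
    for (int i = 0; i < k; ++i)
      if (nbuf[i] >= 0 && cellAt[nbuf[i]] >= 0) return true;
    return false;
  }

  // ---- set maintenance ----------------------------------------------
  void addCand(int s) { candPos[s] = (int)cand.size(); cand.push_back(s); }
  void removeCand(int s) {
    int i = candPos[s], last = cand.back();
    cand[i] = last; candPos[last] = i;
    cand.pop_back(); candPos[s] = -1;
  }
  void addBnd(int s, bool low) {
    bndPos[s] = (int)bnd.size(); bnd.push_back(s); bndLow.push_back(low);
    if (low) ++lowCnt;
  }
  void removeBnd(int s) {
    int i = bndPos[s], last = bnd.back();
    if (bndLow[i]) --lowCnt;
    bnd[i] = last; bndLow[i] = bndLow.back(); bndPos[last] = i;
    bnd.pop_back(); bndLow.pop_back(); bndPos[s] = -1;
  }

  // Recompute set membership of site s from the current occupancy.
  // Idempotent; the calling order is part of the determinism contract
  // (mirrored by the R stepper).
  void refresh(int s) {
    if (cellAt[s] >= 0) {
      if (candPos[s] >= 0) removeCand(s);
      bool want = hasEmptyNb(s);
      if (want && bndPos[s] < 0) addBnd(s, gen[cellAt[s]] <= G - 1);
      else if (!want && bndPos[s] >= 0) removeBnd(s);
    } else {
      if (bndPos[s] >= 0) removeBnd(s);
      bool want = hasOccNb(s);
      if (want && candPos[s] < 0) addCand(s);
      else if (!want && candPos[s] >= 0) removeCand(s);
    }
  }

  void refreshAround(int s) {
    refresh(s);
    int k = neighbours(s);
    int nb[6];
    for (int i = 0; i < k; ++i) nb[i] = nbuf[i];
    for (int i = 0; i < k; ++i) if (nb[i] >= 0) refresh(nb[i]);
  }

  // ---- events --------------------------------------------------------
  // returns generation of the newly created cell
  int growthEvent() {
    int gi = (int) R_unif_index((double)cand.size());
    int s = cand[gi];
    int k = neighbours(s);
    int occ[6], nocc = 0;
    for (int i = 0; i < k; ++i)
      if (nbuf[i] >= 0 && cellAt[nbuf[i]] >= 0) occ[nocc++] = nbuf[i];
    int pi = (nocc > 1) ? (int) R_unif_index((double)nocc) : 0;
    int p = cellAt[occ[pi]];
    int id = (int)parent.size();
    parent.push_back(p);
    gen.push_back(gen[p] + 1);
    birth.push_back(s);
    cur.push_back(s);
    cellAt[s] = id;
    refreshAround(s);
    return gen[id];
  }

  // site index from integer coordinates, -1 if outside; transverse axes
  // wrap, depth must be >= 0 (bounded) and coordinates in range (unbounded)
  int siteAt(int x, int y, int z) {
    if (geom == 0) {
      if (y < 0) return -1;
      if (y + 1 >= depthCap) growDepth(y + 1);
      x = ((x % N) + N) % N;
      return x + y * N;
    } else if (geom == 1) {
      if (z < 0) return -1;
      if (z + 1 >= depthCap) growDepth(z + 1);
      x = ((x % N) + N) % N;
      y = ((y % N) + N) % N;
      return (int)(x + (long)y * N + (long)z * N * N);
    } else {
      if (x < 0 || y < 0 || x >= side || y >= side) return -1;
      return x + y * side;
    }
  }

  void coordsOf(int s, int &x, int &y, int &z) {
    if (geom == 0) { x = s % N; y = s / N; z = 0; }
    else if (geom == 1) {
      long NN = (long)N * N;
      x = s % N; y = (int)((s / N) % N); z = (int)(s / NN);
    } else { x = s % side; y = s / side; z = 0; }
  }

  // Local-connectivity check for removing the cell at a: all occupied
  // von-Neumann neighbours of a must be mutually connected (by von-Neumann
  // steps) through the occupied cells of the surrounding ring (the 3^d - 1
  // sites around a), with a itself treated as empty.  If they are, every
  // path through a can be rerouted inside the ring, so the global cluster
  // stays connected after the move.
  bool ringConnected(int a) {
    int ax, ay, az;
    coordsOf(a, ax, ay, az);
    // 2-D fast path: consecutive cells of the 8-ring are lattice-adjacent
    // and no other ring adjacencies exist (for transverse width >= 4), so
    // the occupied cardinals are mutually connected within the ring iff
    // they all lie in one maximal occupied arc of the cyclic ring.
    if (geom != 1 && (geom == 2 || N >= 4)) {
      static const int rdx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
      static const int rdy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
      bool occ8[8];
      int target = 0;
      for (int i = 0; i < 8; ++i) {
        int s = siteAt(ax + rdx[i], ay + rdy[i], 0);
        occ8[i] = (s >= 0 && cellAt[s] >= 0);
        if (occ8[i] && i % 2 == 0) ++target;   // even positions = cardinals
      }
      if (target <= 1) return true;
      int start = -1;
      for (int i = 0; i < 8; ++i) if (!occ8[i]) { start = i; break; }
      if (start < 0) return true;              // full ring
      int curCard = 0;
      for (int k = 1; k <= 8; ++k) {
        int i = (start + k) % 8;
        if (occ8[i]) { if (i % 2 == 0) ++curCard; }
        else {
          if (curCard == target) return true;
          curCard = 0;
        }
      }
      return false;                            // ends on 'start' (empty)
    }
    int zlo = (geom == 1) ? -1 : 0, zhi = (geom == 1) ? 1 : 0;
    int ring[26]; int nr = 0;
    for (int dz = zlo; dz <= zhi; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int s = siteAt(ax + dx, ay + dy, az + dz);
          if (s < 0 || s == a || cellAt[s] < 0) continue;
          bool dup = false;   // periodic wrap can repeat sites at tiny N
          for (int i = 0; i < nr; ++i) if (ring[i] == s) { dup = true; break; }
          if (!dup) ring[nr++] = s;
        }
    // occupied von-Neumann neighbours of a (members of the ring)
    int k = neighbours(a);
    int occ[6], nocc = 0;
    for (int i = 0; i < k; ++i)
      if (nbuf[i] >= 0 && cellAt[nbuf[i]] >= 0) {
        bool dup = false;
        for (int j = 0; j < nocc; ++j) if (occ[j] == nbuf[i]) dup = true;
        if (!dup) occ[nocc++] = nbuf[i];
      }
    if (nocc <= 1) return true;
    // BFS over ring cells with von-Neumann adjacency
    bool seen[26] = {false};
    int queue[26], qh = 0, qt = 0;
    for (int i = 0; i < nr; ++i) if (ring[i] == occ[0]) { seen[i] = true; queue[qt++] = i; }
    while (qh < qt) {
      int i = queue[qh++];
      int cx, cy, cz;
      coordsOf(ring[i], cx, cy, cz);
      for (int j = 0; j < nr; ++j) {
        if (seen[j]) continue;
        int jx, jy, jz;
        coordsOf(ring[j], jx, jy, jz);
        int dd = 0;
        int ddx = cx - jx, ddy = cy - jy, ddz = cz - jz;
        if (geom != 2) { ddx = ((ddx % N) + N) % N; if (ddx > N / 2) ddx = N - ddx; }
        if (geom == 1) { ddy = ((ddy % N) + N) % N; if (ddy > N / 2) ddy = N - ddy; }
        dd = (ddx < 0 ? -ddx : ddx) + (ddy < 0 ? -ddy : ddy) + (ddz < 0 ? -ddz : ddz);
        if (dd == 1) { seen[j] = true; queue[qt++] = j; }
      }
    }
    for (int i = 0; i < nocc; ++i) {
      bool found = false;
      for (int j = 0; j < nr; ++j)
        if (ring[j] == occ[i] && seen[j]) { found = true; break; }
      if (!found) return false;
    }
    return true;
  }

  void moveEvent() {
    ++nMoves;
    int bi = (int) R_unif_index((double)bnd.size());
    int a = bnd[bi];
    int k = neighbours(a);
    int emp[6], nemp = 0;
    for (int i = 0; i < k; ++i)
      if (nbuf[i] >= 0 && cellAt[nbuf[i]] < 0) emp[nemp++] = nbuf[i];
    if (nemp == 0) { ++nRejected; return; }  // cannot happen for boundary
    int di = (nemp > 1) ? (int) R_unif_index((double)nemp) : 0;
    int b = emp[di];
    // guard 1: b must touch an occupied cell other than the mover
    int kb = neighbours(b);
    bool ok = false;
    for (int i = 0; i < kb; ++i)
      if (nbuf[i] >= 0 && nbuf[i] != a && cellAt[nbuf[i]] >= 0) { ok = true; break; }
    // guard 2: vacating a must not disconnect its neighbours
    if (ok) ok = ringConnected(a);
    if (!ok) { ++nRejected; return; }
    int c = cellAt[a];
    cellAt[a] = -1; cellAt[b] = c; cur[c] = b;
    refreshAround(a);
    refreshAround(b);
  }

  // run until stop; stopMode 0: first birth of a generation-G cell,
  // stopMode 1: no boundary cell has generation <= G-1 (generation G final)
  void run(int stopMode, long maxEvents,
           bool recordWidth, int widthEvery,
           std::vector<double> &wEvent, std::vector<double> &wVal) {
    if (stopMode == 1 && lowCnt == 0) return;
    while (true) {
      if (maxEvents > 0 && nEvents >= maxEvents)
        stop("event budget exceeded before reaching the stop condition");
      ++nEvents;
      bool isMove = false;
      if (pMove > 0.0) isMove = unif_rand() < pMove;
      int newGen = -1;
      if (isMove) moveEvent(); else newGen = growthEvent();
      if (recordWidth && (nEvents % widthEvery == 0)) {
        // front width: sd of boundary depths (bounded geometries)
        long n = (long)bnd.size();
        double m = 0;
        for (long i = 0; i < n; ++i) m += depthOf(bnd[i]);
        m /= n;
        double v = 0;
        for (long i = 0; i < n; ++i) {
          double dd = depthOf(bnd[i]) - m; v += dd * dd;
        }
        wEvent.push_back((double)nEvents);
        wVal.push_back(n > 1 ? std::sqrt(v / (n - 1)) : 0.0);
      }
      if (stopMode == 0) { if (newGen >= G) break; }
      else { if (lowCnt == 0) break; }
      if (nEvents % 65536 == 0) Rcpp::checkUserInterrupt();
    }
  }

  int depthOf(int s) const {
    if (geom == 0) return s / N;
    if (geom == 1) return (int)(s / ((long)N * N));
    return 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".cppSimEden")]]
List cppSimEden(int geometry, int width, int generations,
                bool fullLayer, double pMove,
                int stopMode, double maxEvents,
                bool recordWidth, int widthEvery) {
  EdenSim S;
  S.geom = geometry;
  S.N = width;
  S.G = generations;
  S.pMove = pMove;
  S.nEvents = S.nMoves = S.nRejected = 0;
  S.lowCnt = 0;

  if (geometry == 2) {
    S.side = 2 * (generations + 64) + 1;
    long ns = (long)S.side * S.side;
    S.cellAt.assign(ns, -1);
    S.candPos.assign(ns, -1);
    S.bndPos.assign(ns, -1);
    int origin = (S.side / 2) * S.side + (S.side / 2);
    S.parent.push_back(-1); S.gen.push_back(0);
    S.birth.push_back(origin); S.cur.push_back(origin);
    S.cellAt[origin] = 0;
    S.refreshAround(origin);
  } else {
    S.depthCap = 8;
    long layer = (geometry == 0) ? width : (long)width * width;
    S.cellAt.assign(layer * S.depthCap, -1);
    S.candPos.assign(layer * S.depthCap, -1);
    S.bndPos.assign(layer * S.depthCap, -1);
    if (fullLayer) {
      for (long i = 0; i < layer; ++i) {
        S.parent.push_back(-1); S.gen.push_back(0);
        S.birth.push_back((int)i); S.cur.push_back((int)i);
        S.cellAt[i] = 0;  // placeholder, fixed below
      }
      for (long i = 0; i < layer; ++i) S.cellAt[i] = (int)i;
      for (long i = 0; i < layer; ++i) S.refresh((int)i);
      // depth-1 candidate sites appear when refreshing the empty layer above;
      // refresh() on occupied sites only fixes bnd, so sweep their neighbours
      for (long i = 0; i < layer; ++i) {
        int k = S.neighbours((int)i);
        int nb[6];
        for (int j = 0; j < k; ++j) nb[j] = S.nbuf[j];
        for (int j = 0; j < k; ++j)
          if (nb[j] >= 0 && S.cellAt[nb[j]] < 0 && S.candPos[nb[j]] < 0)
            S.refresh(nb[j]);
      }
    } else {
      int s0 = (geometry == 0) ? width / 2
                               : (int)((long)(width / 2) * width + width / 2);
      S.parent.push_back(-1); S.gen.push_back(0);
      S.birth.push_back(s0); S.cur.push_back(s0);
      S.cellAt[s0] = 0;
      S.refreshAround(s0);
    }
  }

  std::vector<double> wEvent, wVal;
  S.run(stopMode, (long)maxEvents, recordWidth, widthEvery, wEvent, wVal);

  int n = (int)S.parent.size();
  IntegerVector par(n), gn(n);
  int ncol = (geometry == 1) ? 3 : 2;
  IntegerMatrix bs(n, ncol), cs(n, ncol);
  LogicalVector isB(n);
  for (int i = 0; i < n; ++i) {
    par[i] = S.parent[i] < 0 ? NA_INTEGER : S.parent[i] + 1;  // 1-based
    gn[i] = S.gen[i];
    int b = S.birth[i], c = S.cur[i];
    if (geometry == 0) {
      bs(i, 0) = b % width;      bs(i, 1) = b / width;
      cs(i, 0) = c % width;      cs(i, 1) = c / width;
    } else if (geometry == 1) {
      long NN = (long)width * width;
      bs(i, 0) = b % width; bs(i, 1) = (b / width) % width; bs(i, 2) = (int)(b / NN);
      cs(i, 0) = c % width; cs(i, 1) = (c / width) % width; cs(i, 2) = (int)(c / NN);
    } else {
      int h = S.side / 2;
      bs(i, 0) = b % S.side - h; bs(i, 1) = b / S.side - h;
      cs(i, 0) = c % S.side - h; cs(i, 1) = c / S.side - h;
    }
    isB[i] = S.bndPos[S.cur[i]] >= 0;
  }

  List ws = R_NilValue;
  if (recordWidth)
    ws = List::create(_["event"] = wrap(wEvent), _["width"] = wrap(wVal));

  return List::create(
    _["parent"] = par, _["generation"] = gn,
    _["birthSite"] = bs, _["site"] = cs, _["isBoundary"] = isB,
    _["widthSeries"] = ws,
    _["nEvents"] = (double)S.nEvents, _["nMoves"] = (double)S.nMoves,
    _["nRejected"] = (double)S.nRejected);
}
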