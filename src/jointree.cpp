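#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "neighbors.h"
using namespace Rcpp;

// Join tree of the superlevel sets of a distance field over void space
// (edt > 0), built by a descending sweep with union-find. Ties are broken
// by column-major voxel order (simulation of simplicity); plateaus that
// would create several same-value critical points are collapsed so that
// leaf-to-root node values strictly decrease. Every void voxel is mapped
// to the tree arc whose level span contains its value.

struct UF {
  std::vector<R_xlen_t> p;
  UF(R_xlen_t n) : p(n, (R_xlen_t)-1) {}
  R_xlen_t find(R_xlen_t x) {
    R_xlen_t r = x;
    while (p[r] != r) r = p[r];
    while (p[x] != r) { R_xlen_t nx = p[x]; p[x] = r; x = nx; }
    return r;
  }
};

// [[Rcpp::export]]
List cpp_join_tree(NumericVector edt, IntegerVector dims, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  Offsets off = make_offsets(connectivity);
  const int no = (int)off.di.size();

  std::vector<R_xlen_t> order;
  order.reserve(n / 2);
  for (R_xlen_t s = 0; s < n; ++s)
    if (edt[s] > 0.0) order.push_back(s);
  if (order.empty()) stop("empty void space");
  std::stable_sort(order.begin(), order.end(),
                   [&](R_xlen_t a, R_xlen_t b) {
                     if (edt[a] != edt[b]) return edt[a] > edt[b];
                     return a < b;
                   });

  UF uf(n);
  std::vector<int> compArc(n, -1);

  std::vector<double> nodeValue;
  std::vector<R_xlen_t> nodeVoxel;
  std::vector<int> nodeKind;              // 1 leaf, 2 branch, 3 root
  std::vector<char> nodeAlive;
  std::vector<int> arcUpper, arcLower, arcAlias;
  std::vector<char> arcAlive;
  std::vector<std::vector<int> > children; // live arcs whose lower == node
  std::vector<int> voxelArc(n, -1);

  auto newNode = [&](double val, R_xlen_t vox, int kind) {
    nodeValue.push_back(val);
    nodeVoxel.push_back(vox);
    nodeKind.push_back(kind);
    nodeAlive.push_back(1);
    children.push_back(std::vector<int>());
    return (int)nodeValue.size() - 1;
  };
  auto newArc = [&](int upper) {
    arcUpper.push_back(upper);
    arcLower.push_back(-1);
    arcAlias.push_back(-1);
    arcAlive.push_back(1);
    return (int)arcUpper.size() - 1;
  };
  auto resolveArc = [&](int a) {
    while (arcAlias[a] != -1) a = arcAlias[a];
    return a;
  };

  std::vector<R_xlen_t> roots;
  for (size_t t = 0; t < order.size(); ++t) {
    R_xlen_t v = order[t];
    double val = edt[v];
    int i = (int)(v % n1);
    int j = (int)((v / n1) % n2);
    int k = (int)(v / ((R_xlen_t)n1 * n2));
    roots.clear();
    for (int q = 0; q < no; ++q) {
      int ii = i + off.di[q], jj = j + off.dj[q], kk = k + off.dk[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= n1 || jj >= n2 || kk >= n3)
        continue;
      R_xlen_t w = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
      if (uf.p[w] == (R_xlen_t)-1) continue; // not processed yet
      R_xlen_t r = uf.find(w);
      bool seen = false;
      for (size_t z = 0; z < roots.size(); ++z)
        if (roots[z] == r) { seen = true; break; }
      if (!seen) roots.push_back(r);
    }

    if (roots.empty()) {
      int nd = newNode(val, v, 1);
      int a = newArc(nd);
      uf.p[v] = v;
      compArc[v] = a;
      voxelArc[v] = a;
    } else if (roots.size() == 1) {
      R_xlen_t r = roots[0];
      voxelArc[v] = compArc[r];
      uf.p[v] = r;
    } else {
      int nb = newNode(val, v, 2);
      int attached = 0, lastArc = -1;
      std::vector<int> absorbed;
      for (size_t z = 0; z < roots.size(); ++z) {
        int a = resolveArc(compArc[roots[z]]);
        int ua = arcUpper[a];
        if (nodeValue[ua] == val) {
          // zero-span arc from a same-value plateau: absorb it
          if (nodeKind[ua] == 2) {
            for (size_t c = 0; c < children[ua].size(); ++c) {
              int ca = children[ua][c];
              arcLower[ca] = nb;
              children[nb].push_back(ca);
              ++attached;
              lastArc = ca;
            }
          }
          nodeAlive[ua] = 0;
          arcAlive[a] = 0;
          absorbed.push_back(a);
        } else {
          arcLower[a] = nb;
          children[nb].push_back(a);
          ++attached;
          lastArc = a;
        }
      }
      int finalArc;
      if (attached >= 2) {
        finalArc = newArc(nb);
      } else if (attached == 1) {
        // degree-2 node after plateau absorption: contract it
        arcLower[lastArc] = -1;
        nodeAlive[nb] = 0;
        finalArc = lastArc;
      } else {
        // whole merge was a plateau: the node is the plateau's single leaf
        nodeKind[nb] = 1;
        finalArc = newArc(nb);
      }
      for (size_t z = 0; z < absorbed.size(); ++z)
        arcAlias[absorbed[z]] = finalArc;
      R_xlen_t r0 = roots[0];
      uf.p[v] = r0;
      for (size_t z = 1; z < roots.size(); ++z) uf.p[roots[z]] = r0;
      R_xlen_t rr = uf.find(r0);
      compArc[rr] = finalArc;
      voxelArc[v] = finalArc;
    }
  }

  // close remaining components with a root node at level 0
  std::vector<char> done(0);
  {
    std::vector<char> rootSeen(n, 0);
    for (size_t t = 0; t < order.size(); ++t) {
      R_xlen_t r = uf.find(order[t]);
      if (rootSeen[r]) continue;
      rootSeen[r] = 1;
      int nd = newNode(0.0, (R_xlen_t)-1, 3);
      int a = resolveArc(compArc[r]);
      arcLower[a] = nd;
      children[nd].push_back(a);
    }
  }

  // compact live nodes and arcs to 1-based ids
  int nNodes = (int)nodeValue.size(), nArcs = (int)arcUpper.size();
  std::vector<int> nodeMap(nNodes, 0), arcMap(nArcs, 0);
  int cn = 0, ca = 0;
  for (int t = 0; t < nNodes; ++t) if (nodeAlive[t]) nodeMap[t] = ++cn;
  for (int t = 0; t < nArcs; ++t) if (arcAlive[t]) arcMap[t] = ++ca;

  NumericVector outNodeValue(cn);
  IntegerVector outNodeVoxel(cn), outNodeKind(cn);
  IntegerVector outArcUpper(ca), outArcLower(ca);
  for (int t = 0; t < nNodes; ++t) {
    if (!nodeAlive[t]) continue;
    int id = nodeMap[t] - 1;
    outNodeValue[id] = nodeValue[t];
    outNodeVoxel[id] = nodeVoxel[t] < 0 ? NA_INTEGER : (int)(nodeVoxel[t] + 1);
    outNodeKind[id] = nodeKind[t];
  }
  for (int t = 0; t < nArcs; ++t) {
    if (!arcAlive[t]) continue;
    int id = arcMap[t] - 1;
    outArcUpper[id] = nodeMap[arcUpper[t]];
    outArcLower[id] = nodeMap[arcLower[t]];
  }
  IntegerVector outVoxelArc(n);
  for (R_xlen_t s = 0; s < n; ++s)
    outVoxelArc[s] = voxelArc[s] < 0 ? 0 : arcMap[resolveArc(voxelArc[s])];

  return List::create(_["nodeValue"] = outNodeValue,
                      _["nodeVoxel"] = outNodeVoxel,
                      _["nodeKind"] = outNodeKind,
                      _["arcUpper"] = outArcUpper,
                      _["arcLower"] = outArcLower,
                      _["voxelArc"] = outVoxelArc);
}
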