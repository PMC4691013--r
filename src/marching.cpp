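#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction on a 3D scalar field by per-cube contour tracing:
// within each grid cube the isosurface's intersection with every cube face
// is a set of line segments joining interpolated edge crossings; segments
// link into closed loops which are fan-triangulated. Ambiguous faces (four
// crossings) are resolved by the mean of the four corner values, applied
// identically on the shared face of both adjacent cubes, so the mesh is
// watertight away from the grid boundary. Vertices on grid edges are
// shared between cubes; loop centroids are local.

// corner c = (dz<<2)|(dy<<1)|dx
static const int EC[12][2] = {
  {0,1},{0,2},{0,4},{1,3},{1,5},{2,3},{2,6},{3,7},{4,5},{4,6},{5,7},{6,7}};
// axis of each edge in (z,y,x)=(0,1,2) index order
static const int EAX[12] = {2,1,0,1,0,2,0,0,2,1,1,2};
// faces as cyclic corner quadruples
static const int FACES[6][4] = {
  {0,1,3,2},{4,5,7,6},{0,1,5,4},{2,3,7,6},{0,2,6,4},{1,3,7,5}};

// [[Rcpp::export]]
List cpp_march(NumericVector field, IntegerVector dims, double iso) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int eidx[8][8];
  for (int a = 0; a < 8; ++a)
    for (int b = 0; b < 8; ++b) eidx[a][b] = -1;
  for (int e = 0; e < 12; ++e) {
    eidx[EC[e][0]][EC[e][1]] = e;
    eidx[EC[e][1]][EC[e][0]] = e;
  }
  int cz[8], cy[8], cx[8];
  for (int c = 0; c < 8; ++c) {
    cz[c] = (c >> 2) & 1; cy[c] = (c >> 1) & 1; cx[c] = c & 1;
  }

  std::vector<double> verts;   // (i,j,k) triples in index space
  std::vector<int> tris;       // 1-based vertex ids
  std::unordered_map<long long, int> edgeVert;

  double vals[8];
  bool ins[8];
  double ep[12][3];
  int epid[12];
  int adj[12][2], deg[12];

  for (int i = 0; i < n1 - 1; ++i)
    for (int j = 0; j < n2 - 1; ++j)
      for (int k = 0; k < n3 - 1; ++k) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          R_xlen_t s = (R_xlen_t)(i + cz[c]) +
                       (R_xlen_t)n1 * ((j + cy[c]) + (R_xlen_t)n2 * (k + cx[c]));
          vals[c] = field[s];
          ins[c] = vals[c] > iso;
          if (ins[c]) ++nin;
        }
        if (nin == 0 || nin == 8) continue;

        for (int e = 0; e < 12; ++e) { deg[e] = 0; epid[e] = -1; }
        for (int e = 0; e < 12; ++e) {
          int a = EC[e][0], b = EC[e][1];
          if (ins[a] == ins[b]) continue;
          double t = (iso - vals[a]) / (vals[b] - vals[a]);
          ep[e][0] = i + cz[a] + t * (cz[b] - cz[a]);
          ep[e][1] = j + cy[a] + t * (cy[b] - cy[a]);
          ep[e][2] = k + cx[a] + t * (cx[b] - cx[a]);
          // global shared-vertex key: origin voxel of the grid edge + axis
          long long ovox = (long long)(i + cz[a]) +
                           (long long)n1 * ((j + cy[a]) +
                           (long long)n2 * (k + cx[a]));
          long long key = ovox * 3 + EAX[e];
          std::unordered_map<long long, int>::iterator it = edgeVert.find(key);
          if (it == edgeVert.end()) {
            int id = (int)(verts.size() / 3);
            verts.push_back(ep[e][0]);
            verts.push_back(ep[e][1]);
            verts.push_back(ep[e][2]);
            edgeVert[key] = id;
            epid[e] = id;
          } else {
            epid[e] = it->second;
          }
        }

        for (int f = 0; f < 6; ++f) {
          const int *fc = FACES[f];
          int cross[4], ncr = 0;
          for (int m = 0; m < 4; ++m) {
            int a = fc[m], b = fc[(m + 1) % 4];
            if (ins[a] != ins[b]) cross[ncr++] = m;
          }
          if (ncr == 0) continue;
          int fe[4];
          for (int m = 0; m < 4; ++m) fe[m] = eidx[fc[m]][fc[(m + 1) % 4]];
          if (ncr == 2) {
            int a = fe[cross[0]], b = fe[cross[1]];
            adj[a][deg[a]++] = b;
            adj[b][deg[b]++] = a;
          } else {
            // ambiguous face: corners alternate in/out around the cycle
            double centre = 0.25 * (vals[fc[0]] + vals[fc[1]] +
                                    vals[fc[2]] + vals[fc[3]]);
            bool cen_in = centre > iso;
            bool diag_in = ins[fc[0]];
            int p0a, p0b, p1a, p1b;
            if (cen_in == diag_in) {
              p0a = fe[0]; p0b = fe[1]; p1a = fe[2]; p1b = fe[3];
            } else {
              p0a = fe[0]; p0b = fe[3]; p1a = fe[1]; p1b = fe[2];
            }
            adj[p0a][deg[p0a]++] = p0b;
            adj[p0b][deg[p0b]++] = p0a;
            adj[p1a][deg[p1a]++] = p1b;
            adj[p1b][deg[p1b]++] = p1a;
          }
        }

        bool visited[12] = {false};
        for (int e0 = 0; e0 < 12; ++e0) {
          if (deg[e0] != 2 || visited[e0]) continue;
          int loop[12], ln = 0;
          int prev = -1, cur = e0;
          do {
            loop[ln++] = cur;
            visited[cur] = true;
            int nxt = (adj[cur][0] != prev) ? adj[cur][0] : adj[cur][1];
            prev = cur;
            cur = nxt;
          } while (cur != e0 && ln < 12);
          if (ln < 3) continue;
          if (ln == 3) {
            tris.push_back(epid[loop[0]] + 1);
            tris.push_back(epid[loop[1]] + 1);
            tris.push_back(epid[loop[2]] + 1);
          } else {
            double cx0 = 0, cy0 = 0, cz0 = 0;
            for (int m = 0; m < ln; ++m) {
              cz0 += ep[loop[m]][0];
              cy0 += ep[loop[m]][1];
              cx0 += ep[loop[m]][2];
            }
            int cid = (int)(verts.size() / 3);
            verts.push_back(cz0 / ln);
            verts.push_back(cy0 / ln);
            verts.push_back(cx0 / ln);
            for (int m = 0; m < ln; ++m) {
              tris.push_back(cid + 1);
              tris.push_back(epid[loop[m]] + 1);
              tris.push_back(epid[loop[(m + 1) % ln]] + 1);
            }
          }
        }
      }

  const int nv = (int)(verts.size() / 3);
  const int nt = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int t = 0; t < nv; ++t) {
    V(t, 0) = verts[3 * t];      // i (z)
    V(t, 1) = verts[3 * t + 1];  // j (y)
    V(t, 2) = verts[3 * t + 2];  // k (x)
  }
  IntegerMatrix T(nt, 3);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tris[3 * t];
    T(t, 1) = tris[3 * t + 1];
    T(t, 2) = tris[3 * t + 2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
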