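#ifndef TOMOACCESS_NEIGHBORS_H
#define TOMOACCESS_NEIGHBORS_H

#include <vector>
#include <cstdlib>

// Voxel neighbourhood offsets in (i,j,k) = (z,y,x) index order.
// connectivity 6: face neighbours, 18: face+edge, 26: full.
struct Offsets {
  std::vector<int> di, dj, dk;
};

inline Offsets make_offsets(int connectivity) {
  Offsets o;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        o.di.push_back(a); o.dj.push_back(b); o.dk.push_back(c);
      }
  return o;
}

#endif
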