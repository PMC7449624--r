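#!/usr/bin/env python
"""Reference Markov clustering (MCL) implementation used as an independent
oracle by the test suite.

Reads a square weighted-adjacency matrix from a TSV file (no header) and
prints one line per node: the 0-based cluster index. Clusters are the
supports of attractor rows of the limit matrix; nodes claimed by several
clusters go to the largest cluster, ties broken by smallest node index.
Cluster indices are assigned by decreasing size, then smallest member.

Usage: mcl_reference.py MATRIX_TSV INFLATION [EXPANSION] [PRUNE] [TOL] [MAX_ITER] [SELF_LOOPS]
"""
import sys

import numpy as np


def mcl(S, inflation, expansion=2, prune=1e-5, tol=1e-8, max_iter=200,
        self_loops=1.0):
    S = S.astype(float).copy()
    np.fill_diagonal(S, self_loops)
    M = S / S.sum(axis=0, keepdims=True)
    for _ in range(max_iter):
        Mx = np.linalg.matrix_power(M, expansion)
        Mx = Mx ** inflation
        Mx[Mx < prune] = 0.0
        cs = Mx.sum(axis=0, keepdims=True)
        cs[cs == 0] = 1.0
        Mx = Mx / cs
        delta = np.abs(Mx - M).max()
        M = Mx
        if delta < tol:
            break
    n = M.shape[0]
    attractors = [i for i in range(n) if M[i, i] > tol]
    supports = []
    for i in attractors:
        s = tuple(np.nonzero(M[i, :] > tol)[0])
        if s and s not in supports:
            supports.append(s)
    supports.sort(key=lambda s: (-len(s), min(s)))
    membership = [-1] * n
    cid = 0
    for s in supports:
        free = [j for j in s if membership[j] < 0]
        if not free:
            continue
        for j in free:
            membership[j] = cid
        cid += 1
    for j in range(n):
        if membership[j] < 0:
            membership[j] = cid
            cid += 1
    clusters = {}
    for j, c in enumerate(membership):
        clusters.setdefault(c, []).append(j)
    order = sorted(clusters, key=lambda c: (-len(clusters[c]), min(clusters[c])))
    relabel = {c: k for k, c in enumerate(order)}
    return [relabel[c] for c in membership]


def main():
    path = sys.argv[1]
    inflation = float(sys.argv[2])
    expansion = int(sys.argv[3]) if len(sys.argv) > 3 else 2
    prune = float(sys.argv[4]) if len(sys.argv) > 4 else 1e-5
    tol = float(sys.argv[5]) if len(sys.argv) > 5 else 1e-8
    max_iter = int(sys.argv[6]) if len(sys.argv) > 6 else 200
    self_loops = float(sys.argv[7]) if len(sys.argv) > 7 else 1.0
    S = np.loadtxt(path, delimiter="\t")
    for c in mcl(S, inflation, expansion, prune, tol, max_iter, self_loops):
        print(c)


if __name__ == "__main__":
    main()
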