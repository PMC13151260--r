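"""Independent reference implementation of DirectLiNGAM causal ordering.

Written directly from the published algorithm (maximum-entropy
differential-entropy approximation, min(0, log-LR)^2 exogeneity score,
iterative residualization). Used once to produce reference causal orders
on seeded datasets; those orders are frozen into the package's test suite.

Usage: python directlingam_oracle.py data1.csv data2.csv ...
Prints one 1-based order per line.
"""
import sys

import numpy as np

K1, K2, GAM = 79.047, 7.4129, 0.37457


def entropy(u):
    hnu = 0.5 * (1 + np.log(2 * np.pi))
    return (hnu - K1 * (np.mean(np.log(np.cosh(u))) - GAM) ** 2
            - K2 * np.mean(u * np.exp(-(u ** 2) / 2)) ** 2)


def std(x):
    return (x - x.mean()) / x.std(ddof=1)


def causal_order(X):
    X = np.apply_along_axis(std, 0, np.asarray(X, float))
    n, p = X.shape
    remaining = list(range(p))
    order = []
    while len(remaining) > 1:
        cols = {j: X[:, j] for j in remaining}
        H = {j: entropy(cols[j]) for j in remaining}
        scores = {}
        for i in remaining:
            t = 0.0
            for j in remaining:
                if j == i:
                    continue
                rho = np.dot(cols[i], cols[j]) / (n - 1)
                ri_j = std(cols[i] - rho * cols[j])
                rj_i = std(cols[j] - rho * cols[i])
                # log-LR favoring i -> j
                m = H[j] + entropy(ri_j) - H[i] - entropy(rj_i)
                t += min(0.0, m) ** 2
            scores[i] = t
        k = min(remaining, key=lambda i: (scores[i], i))
        order.append(k)
        xk = cols[k]
        for j in remaining:
            if j != k:
                rho = np.dot(cols[j], xk) / (n - 1)
                X[:, j] = std(cols[j] - rho * xk)
        remaining.remove(k)
    order.append(remaining[0])
    return [o + 1 for o in order]


if __name__ == "__main__":
    for path in sys.argv[1:]:
        X = np.loadtxt(path, delimiter=",", skiprows=1)
        print(",".join(map(str, causal_order(X))))
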