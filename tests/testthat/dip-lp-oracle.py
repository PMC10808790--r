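import sys, json
import numpy as np
from scipy.optimize import linprog

def dip_lp(x, n_mid=6, eps_frac=1e-6):
    x = np.sort(np.asarray(x, float)); n = len(x)
    ux = np.unique(x)
    rng = ux[-1] - ux[0]
    if rng == 0: return 0.0
    # rescale to unit min-gap for conditioning (dip is x-affine-invariant)
    eps = eps_frac * rng
    pts = [ux[0] - rng/2, ux[-1] + rng/2]
    pts += list(ux) + list(ux - eps)
    for i in range(len(ux)-1):
        pts += list(np.linspace(ux[i], ux[i+1], n_mid+2)[1:-1])
    grid = np.unique(np.array(pts)); M = len(grid)
    F = np.searchsorted(x, grid, side='right') / n
    h = np.diff(grid)
    best = np.inf
    for g in range(M-1):          # mode gap = (grid[g], grid[g+1])
        A_ub, b_ub = [], []
        # tube: G_k - d <= F_k ; -G_k - d <= -F_k
        for k in range(M):
            r = np.zeros(M+1); r[k] = 1; r[M] = -1; A_ub.append(r); b_ub.append(F[k])
            r = np.zeros(M+1); r[k] = -1; r[M] = -1; A_ub.append(r); b_ub.append(-F[k])
        # monotone: G_k - G_{k+1} <= 0
        for k in range(M-1):
            r = np.zeros(M+1); r[k] = 1; r[k+1] = -1; A_ub.append(r); b_ub.append(0.0)
        # curvature: segments 0..M-2; pair (k,k+1)
        for k in range(M-2):
            r = np.zeros(M+1)
            r[k] = -1/h[k]; r[k+1] = 1/h[k] + 1/h[k+1]; r[k+2] = -1/h[k+1]
            sc = max(abs(r[k]), abs(r[k+1]), abs(r[k+2]))
            r /= sc
            if k + 1 <= g - 1:  A_ub.append(r); b_ub.append(0.0)   # convex left
            elif k >= g + 1:    A_ub.append(-r); b_ub.append(0.0)  # concave right
        A_eq = np.zeros((2, M+1)); A_eq[0,0] = 1; A_eq[1,M-1] = 1
        b_eq = [0.0, 1.0]
        c = np.zeros(M+1); c[M] = 1
        res = linprog(c, A_ub=np.array(A_ub), b_ub=np.array(b_ub),
                      A_eq=A_eq, b_eq=b_eq, bounds=[(0, 1.5)]*M + [(0, 0.5)],
                      method='highs')
        if res.status == 0:
            best = min(best, res.fun)
    return best

cases = json.load(open(sys.argv[1]))
nm = int(sys.argv[2]) if len(sys.argv) > 2 else 6
print(json.dumps([dip_lp(c, n_mid=nm) for c in cases]))
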