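import sys, json
import numpy as np
from scipy.optimize import linprog
from scipy import sparse

# stdin: JSON {y:[...], i_sp:[...], i_sa:[...], P:int, Q:int, sp_ctrl:[...], sa_ctrl:[...]}
d = json.load(sys.stdin)
y = np.array(d["y"]); n = len(y); P = d["P"]; Q = d["Q"]
p = 1 + P + Q
rows = np.arange(n)
X = sparse.coo_matrix(
    (np.ones(3*n),
     (np.concatenate([rows, rows, rows]),
      np.concatenate([np.zeros(n, int),
                      np.array(d["i_sp"], int),
                      np.array(np.array(d["i_sa"], int) + P)]))),
    shape=(n, p)).tocsc()
# vars: beta (p, free) then t (n, >=0); min sum t  s.t. -t <= y - X beta <= t
A1 = sparse.hstack([X, -sparse.eye(n)])    # X b - t <= y
A2 = sparse.hstack([-X, -sparse.eye(n)])   # -X b - t <= -y
A_ub = sparse.vstack([A1, A2]).tocsc()
b_ub = np.concatenate([y, -y])
# gauge constraints: mean of ctrl phi = 0, mean of ctrl psi = 0
rows_eq = []
for ctrl, off in ((d["sp_ctrl"], 1), (d["sa_ctrl"], 1 + P)):
    r = np.zeros(p + n)
    for j in ctrl: r[off + int(j) - 1] = 1.0
    rows_eq.append(r)
A_eq = np.vstack(rows_eq); b_eq = np.zeros(2)
c = np.concatenate([np.zeros(p), np.ones(n)])
bounds = [(None, None)]*p + [(0, None)]*n
res = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
              bounds=bounds, method="highs")
print(json.dumps({"objective": res.fun, "status": int(res.status),
                  "beta": list(res.x[:p])}))
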