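"""Linear/mixed-integer programming worker.

Solves a stream of sparse LP/MIP instances received over a localhost socket
using SciPy's HiGHS interface.  Binary little-endian protocol, one request
per message:

  int32[4]  : msgtype (0 quit, 1 solve), problemtype (0 LP, 1 MIP,
              2 LP via interior point), nvar, ncon
  int32[1]  : nnz
  float64   : time_limit (seconds, <= 0 means none)
  float64[nvar] : objective
  int32[nnz]    : constraint row indices (1-based)
  int32[nnz]    : constraint column indices (1-based)
  float64[nnz]  : constraint values
  float64[ncon] : equality right-hand sides
  float64[nvar] : lower bounds (-1e300 means free below)
  float64[nvar] : upper bounds (1e300 means free above)
  int32[nvar]   : integrality flags (MIP only; ignored for LP)

Response:

  int32[1]      : status (0 optimal, 2 infeasible, 3 unbounded, 4 failed)
  float64[1]    : objective value (NaN unless optimal)
  float64[nvar] : solution values (zeros unless optimal)
"""

import socket
import struct
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, linprog, milp


def read_exact(f, n):
    buf = b""
    while len(buf) < n:
        chunk = f.read(n - len(buf))
        if not chunk:
            raise EOFError
        buf += chunk
    return buf


def read_array(f, dtype, n):
    itemsize = np.dtype(dtype).itemsize
    return np.frombuffer(read_exact(f, itemsize * n), dtype=dtype).copy()


def solve_lp(c, A, b, lb, ub, time_limit, method="highs"):
    opts = {"presolve": True}
    if time_limit > 0:
        opts["time_limit"] = time_limit
    res = linprog(c, A_eq=A, b_eq=b, bounds=np.column_stack([lb, ub]),
                  method=method, options=opts)
    return res


def solve_mip(c, A, b, lb, ub, integrality, time_limit):
    opts = {}
    if time_limit > 0:
        opts["time_limit"] = time_limit
    cons = LinearConstraint(A, b, b)
    res = milp(c, constraints=cons, bounds=Bounds(lb, ub),
               integrality=integrality, options=opts)
    return res


def main():
    port = int(sys.argv[1])
    sock = socket.create_connection(("127.0.0.1", port))
    f = sock.makefile("rwb")
    while True:
        try:
            header = read_array(f, np.int32, 4)
        except EOFError:
            break
        msgtype, problemtype, nvar, ncon = (int(v) for v in header)
        if msgtype == 0:
            break
        nnz = int(read_array(f, np.int32, 1)[0])
        time_limit = float(read_array(f, np.float64, 1)[0])
        c = read_array(f, np.float64, nvar)
        ai = read_array(f, np.int32, nnz) - 1
        aj = read_array(f, np.int32, nnz) - 1
        ax = read_array(f, np.float64, nnz)
        b = read_array(f, np.float64, ncon)
        lb = read_array(f, np.float64, nvar)
        ub = read_array(f, np.float64, nvar)
        integrality = read_array(f, np.int32, nvar)
        lb[lb <= -1e300] = -np.inf
        ub[ub >= 1e300] = np.inf
        A = sparse.coo_matrix((ax, (ai, aj)), shape=(ncon, nvar)).tocsc()
        try:
            if problemtype == 1:
                res = solve_mip(c, A, b, lb, ub, integrality, time_limit)
            elif problemtype == 2:
                res = solve_lp(c, A, b, lb, ub, time_limit, method="highs-ipm")
            else:
                res = solve_lp(c, A, b, lb, ub, time_limit)
            status = int(res.status)
            # scipy: 0 optimal, 2 infeasible, 3 unbounded; anything else -> failed
            if status not in (0, 2, 3):
                status = 4
            if status == 0 and res.x is not None:
                obj = float(res.fun)
                x = np.asarray(res.x, dtype=np.float64)
            else:
                obj = float("nan")
                x = np.zeros(nvar)
        except Exception:
            status, obj, x = 4, float("nan"), np.zeros(nvar)
        f.write(struct.pack("<i", status))
        f.write(struct.pack("<d", obj))
        f.write(x.astype("<f8").tobytes())
        f.flush()
    f.close()
    sock.close()


if __name__ == "__main__":
    main()
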