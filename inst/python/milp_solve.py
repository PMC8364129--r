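"""Driver for the HiGHS mixed-integer solver behind the R abstraction layer.

Reads a JSON model {n, obj, lb, ub, integrality, a_row, a_col, a_val,
n_rows, row_lb, row_ub, time_limit}, solves it with scipy.optimize.milp,
and writes {status, message, x, feasible_incumbent}.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def main(fin, fout):
    with open(fin) as fh:
        p = json.load(fh)
    arr = lambda key, dt: np.atleast_1d(np.asarray(p[key], dtype=dt))
    n = int(p["n"])
    c = arr("obj", float)
    lb = arr("lb", float)
    ub = arr("ub", float)
    integrality = arr("integrality", int)
    n_rows = int(p["n_rows"])
    constraints = []
    if n_rows:
        A = sparse.csr_matrix(
            (arr("a_val", float), (arr("a_row", int), arr("a_col", int))),
            shape=(n_rows, n),
        )
        constraints = [LinearConstraint(A, arr("row_lb", float), arr("row_ub", float))]
    res = milp(
        c=c,
        constraints=constraints,
        bounds=Bounds(lb, ub),
        integrality=integrality,
        options={"time_limit": float(p.get("time_limit", 300)),
                 "presolve": True},
    )
    out = {
        "status": int(res.status),
        "message": str(res.message),
        "x": None if res.x is None else [float(v) for v in res.x],
        "feasible_incumbent": bool(res.x is not None),
    }
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
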