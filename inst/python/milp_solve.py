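"""Branch-and-cut backend: solves serialized MILP models with scipy/HiGHS.

Usage: python milp_solve.py <in.json> <out.json>

The input holds {"models": [...]} where each model carries the objective,
variable bounds, integrality flags, constraint matrix triplets (0-based) and
row bounds, plus a time limit and relative MIP gap. Values with magnitude
>= 1e29 are treated as infinite. The output holds {"solutions": [...]} with
status, objective, dual bound and the variable vector.
"""
import json
import sys

import numpy as np
from scipy.optimize import Bounds, LinearConstraint, milp
from scipy.sparse import coo_matrix

INF_SENTINEL = 1e29

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "other"}


def definf(a):
    a = np.asarray(a, dtype=float)
    a[a >= INF_SENTINEL] = np.inf
    a[a <= -INF_SENTINEL] = -np.inf
    return a


def solve_one(m):
    ncol = int(m["ncol"])
    nrow = len(m["cl"])
    A = coo_matrix(
        (np.asarray(m["ax"], dtype=float),
         (np.asarray(m["ai"], dtype=int), np.asarray(m["aj"], dtype=int))),
        shape=(nrow, ncol),
    ).tocsc()
    res = milp(
        c=np.asarray(m["obj"], dtype=float),
        constraints=LinearConstraint(A, definf(m["cl"]), definf(m["cu"])),
        integrality=np.asarray(m["integrality"], dtype=int),
        bounds=Bounds(definf(m["lb"]), definf(m["ub"])),
        options={
            "time_limit": float(m.get("time_limit", 120)),
            "mip_rel_gap": float(m.get("mip_gap", 1e-6)),
        },
    )
    status = STATUS.get(res.status, "other")
    out = {"status": status}
    if res.x is not None:
        out["objective"] = float(res.fun)
        out["x"] = [float(v) for v in res.x]
        bound = getattr(res, "mip_dual_bound", None)
        if bound is not None and np.isfinite(bound):
            out["bound"] = float(bound)
    elif status == "limit":
        out["status"] = "no_solution"
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    solutions = [solve_one(m) for m in payload["models"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"solutions": solutions}, fh)


if __name__ == "__main__":
    main()
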