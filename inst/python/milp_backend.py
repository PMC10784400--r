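"""Generic LP/MILP batch solver backed by HiGHS via scipy.optimize.milp.

Reads a JSON file describing a list of problems, each with shared constraints
and a list of objective vectors (sparse), solves every (problem, objective)
pair and writes a JSON file with status/objective/solution per pair.

Usage: python milp_backend.py <input.json> <output.json>

Input schema (all indices 0-based):
{
  "problems": [
    {
      "n": int,
      "lb": [float]*n, "ub": [float]*n,
      "integrality": [0|1]*n,
      "con": {"i": [int], "j": [int], "x": [float], "m": int,
              "cl": [float]*m, "cu": [float]*m},
      "objectives": [{"idx": [int], "val": [float], "sense": "min"|"max"}]
    }, ...
  ],
  "options": {"mip_rel_gap": float, "time_limit": float}
}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e30


def _clean(v):
    v = float(v)
    if v >= INF:
        return np.inf
    if v <= -INF:
        return -np.inf
    return v


def _aslist(v):
    # length-1 vectors arrive as bare scalars from the R JSON serializer
    if isinstance(v, (int, float)):
        return [v]
    return v


def solve_problem(prob, options):
    n = int(prob["n"])
    lb = np.array([_clean(v) for v in _aslist(prob["lb"])], dtype=float)
    ub = np.array([_clean(v) for v in _aslist(prob["ub"])], dtype=float)
    integrality = np.array(_aslist(prob.get("integrality", [0] * n)), dtype=int)
    con = prob["con"]
    m = int(con["m"])
    A = sparse.csr_matrix(
        (np.array(_aslist(con["x"]), dtype=float),
         (np.array(_aslist(con["i"]), dtype=int),
          np.array(_aslist(con["j"]), dtype=int))),
        shape=(m, n))
    cl = np.array([_clean(v) for v in _aslist(con["cl"])], dtype=float)
    cu = np.array([_clean(v) for v in _aslist(con["cu"])], dtype=float)
    constraints = LinearConstraint(A, cl, cu)
    bounds = Bounds(lb, ub)
    opts = {}
    if "mip_rel_gap" in options:
        opts["mip_rel_gap"] = float(options["mip_rel_gap"])
    if "time_limit" in options:
        opts["time_limit"] = float(options["time_limit"])

    results = []
    for obj in prob["objectives"]:
        c = np.zeros(n)
        idx = np.array(_aslist(obj.get("idx", [])), dtype=int)
        if idx.size:
            c[idx] = np.array(_aslist(obj["val"]), dtype=float)
        sense = obj.get("sense", "min")
        if sense == "max":
            c = -c
        res = milp(c=c, constraints=constraints, bounds=bounds,
                   integrality=integrality, options=opts)
        if res.status == 0 and res.x is not None:
            fun = float(res.fun)
            if sense == "max":
                fun = -fun
            results.append({"status": "optimal", "objective": fun,
                            "x": [float(v) for v in res.x]})
        elif res.status == 2:
            results.append({"status": "infeasible"})
        elif res.status == 3:
            results.append({"status": "unbounded"})
        elif res.status == 1:
            results.append({"status": "timeout"})
        else:
            results.append({"status": "failed",
                            "message": str(getattr(res, "message", ""))})
    return results


def main(argv):
    with open(argv[1]) as fh:
        payload = json.load(fh)
    options = payload.get("options", {})
    out = [solve_problem(p, options) for p in payload["problems"]]
    with open(argv[2], "w") as fh:
        json.dump({"results": out}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
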