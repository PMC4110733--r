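"""Independent graphical-lasso oracle used by the test suite.

Reads a JSON file {"instances": [{"S": [[...]], "alpha": x}, ...]}, solves
each instance with scikit-learn's graphical_lasso (which keeps the diagonal
of the covariance estimate unpenalised), and writes the list of precision
matrices as JSON.
"""
import json
import sys

import numpy as np
from sklearn.covariance import graphical_lasso


def main(fin, fout):
    with open(fin) as fh:
        req = json.load(fh)
    out = []
    for inst in req["instances"]:
        S = np.asarray(inst["S"], dtype=float)
        res = graphical_lasso(S, alpha=float(inst["alpha"]),
                              tol=1e-8, max_iter=1000)
        prec = res[1]
        out.append(prec.tolist())
    with open(fout, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
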