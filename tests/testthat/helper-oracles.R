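# Independent oracles the implementation is checked against.

# literal summation of the combined loss: explicit double loops, no shared
# code with combined_loss()
literal_combined_loss <- function(p, g, eps = 1e-6) {
  N <- nrow(p); C <- ncol(p)
  dice_sum <- 0
  for (j in seq_len(C)) {
    num <- 0; den <- 0
    for (i in seq_len(N)) {
      num <- num + 2 * p[i, j] * g[i, j]
      den <- den + p[i, j] + g[i, j]
    }
    dice_sum <- dice_sum + (num + eps) / (den + eps)
  }
  ce <- 0
  for (j in seq_len(C))
    for (i in seq_len(N))
      ce <- ce - g[i, j] * log(min(max(p[i, j], 1e-7), 1))
  (1 - dice_sum / C) + ce / (N * C)
}

# brute-force transport oracle: the full linear program solved by
# scipy.optimize.linprog (HiGHS) through the system python -- an
# implementation route entirely separate from the package's min-cost-flow
lp_emd_oracle <- function(instances) {
  payload <- lapply(instances, function(ins)
    list(wa = ins$a$weights, wb = ins$b$weights,
         pa = unname(as.matrix(ins$a$positions)),
         pb = unname(as.matrix(ins$b$positions))))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, auto_unbox = FALSE, digits = NA)
  script <- sprintf('
import json, sys
import numpy as np
from scipy.optimize import linprog
with open(%s) as fh:
    cases = json.load(fh)
out = []
for case in cases:
    wa = np.asarray(case["wa"], float).ravel()
    wb = np.asarray(case["wb"], float).ravel()
    pa = np.asarray(case["pa"], float).reshape(len(wa), 3)
    pb = np.asarray(case["pb"], float).reshape(len(wb), 3)
    na, nb = len(wa), len(wb)
    cost = np.sqrt(((pa[:, None, :] - pb[None, :, :]) ** 2).sum(-1)).ravel()
    A_eq = []
    for i in range(na):
        row = np.zeros(na * nb); row[i * nb:(i + 1) * nb] = 1; A_eq.append(row)
    for j in range(nb):
        row = np.zeros(na * nb); row[j::nb] = 1; A_eq.append(row)
    b_eq = np.concatenate([wa, wb])
    res = linprog(cost, A_eq=np.array(A_eq), b_eq=b_eq, bounds=(0, None),
                  method="highs")
    assert res.success, res.message
    out.append(float(res.fun))
with open(%s, "w") as fh:
    json.dump(out, fh)
', deparse(fin), deparse(fout))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("LP oracle python call failed")
  unlist(jsonlite::read_json(fout, simplifyVector = TRUE))
}
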