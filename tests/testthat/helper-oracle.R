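# Independent oracles used across the suite.

# Exact-in-the-limit 1-D total-variation prox via its dual box QP
# (coordinate descent on u in [-lam, lam]^{n-1}); independent of the
# production Condat implementation.
tv_prox_oracle <- function(y, lam, sweeps = 100000, tol = 1e-14) {
  n <- length(y)
  if (n == 1 || lam <= 0) return(y)
  u <- numeric(n - 1)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (i in seq_len(n - 1)) {
      lo <- if (i > 1) u[i - 1] else 0
      hi <- if (i < n - 1) u[i + 1] else 0
      cand <- max(-lam, min(lam, (lo + hi + y[i + 1] - y[i]) / 2))
      delta <- max(delta, abs(cand - u[i]))
      u[i] <- cand
    }
    if (delta < tol) break
  }
  x <- y
  x[1] <- y[1] + u[1]
  if (n > 2) for (j in 2:(n - 1)) x[j] <- y[j] - u[j - 1] + u[j]
  x[n] <- y[n] - u[n - 1]
  x
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# Generic convex-minimizer oracle for the fused-LASSO objective
#   ||yc - Xc b||^2 + l1 ||b||_1 + l2 sum_chains TV(b)
# solved as a smooth QP with split variables via scipy trust-constr.
# `problems` is a list of lists with X, y, lambda1, lambda2, k.
# Returns a numeric vector of optimal objective values.
fused_oracle_objectives <- function(problems) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(pr) {
    list(X = unname(as.matrix(pr$X)), y = as.numeric(pr$y),
         lambda1 = pr$lambda1, lambda2 = pr$lambda2, k = pr$k)
  })
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import minimize, LinearConstraint",
    "probs = json.load(open(sys.argv[1]))",
    "def objective(b, Xc, yc, l1, l2, k):",
    "    m = b.size // k",
    "    tv = sum(np.abs(np.diff(b[t*k:(t+1)*k])).sum() for t in range(m))",
    "    return float(((yc - Xc @ b)**2).sum() + l1*np.abs(b).sum() + l2*tv)",
    "def refine_at(b, Xc, yc, l1, l2, k, tol_rel):",
    "    # exact solve on the detected block/sign pattern (active-set polish)",
    "    p = b.size; m = p // k",
    "    amax = np.abs(b).max()",
    "    if amax == 0: return b",
    "    tol = tol_rel * amax",
    "    bid = np.zeros(p, int); nb = -1",
    "    for t in range(m):",
    "        for j in range(k):",
    "            i = t*k + j",
    "            if j == 0 or abs(b[i]-b[i-1]) > tol: nb += 1",
    "            bid[i] = nb",
    "    nb += 1",
    "    sizes = np.bincount(bid, minlength=nb).astype(float)",
    "    vals = np.bincount(bid, weights=b, minlength=nb) / sizes",
    "    free = np.abs(vals) > tol",
    "    if not free.any():",
    "        z = np.zeros(p)",
    "        return z if objective(z,Xc,yc,l1,l2,k) <= objective(b,Xc,yc,l1,l2,k) else b",
    "    sgn = np.sign(vals)",
    "    w = np.zeros(nb)",
    "    for i in range(1, p):",
    "        if i % k != 0 and bid[i] != bid[i-1]:",
    "            d = np.sign(vals[bid[i-1]] - vals[bid[i]])",
    "            w[bid[i-1]] += l2*d; w[bid[i]] -= l2*d",
    "    fid = np.where(free)[0]",
    "    B = np.zeros((p, fid.size))",
    "    for col, blk in enumerate(fid): B[bid == blk, col] = 1.0",
    "    G = Xc.T @ Xc",
    "    A = 2.0 * B.T @ G @ B",
    "    rhs = 2.0 * B.T @ (Xc.T @ yc) - l1*sizes[fid]*sgn[fid] - w[fid]",
    "    try: c = np.linalg.solve(A, rhs)",
    "    except np.linalg.LinAlgError: return b",
    "    if (np.sign(c) != sgn[fid]).any(): return b",
    "    vnew = np.zeros(nb); vnew[fid] = c",
    "    for i in range(1, p):",
    "        if i % k != 0 and bid[i] != bid[i-1]:",
    "            if np.sign(vnew[bid[i-1]]-vnew[bid[i]]) != np.sign(vals[bid[i-1]]-vals[bid[i]]):",
    "                return b",
    "    bn = vnew[bid]",
    "    return bn if objective(bn,Xc,yc,l1,l2,k) <= objective(b,Xc,yc,l1,l2,k) else b",
    "def refine(b, Xc, yc, l1, l2, k):",
    "    # interior-point iterates blur the active pattern; sweep tolerances",
    "    best = b",
    "    for tol_rel in (1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 0.05):",
    "        cand = refine_at(best, Xc, yc, l1, l2, k, tol_rel)",
    "        if objective(cand,Xc,yc,l1,l2,k) < objective(best,Xc,yc,l1,l2,k):",
    "            best = cand",
    "    z = np.zeros(b.size)  # the all-zero pattern is never reachable by a",
    "    if objective(z,Xc,yc,l1,l2,k) < objective(best,Xc,yc,l1,l2,k):",
    "        best = z          # relative tolerance; test it explicitly",
    "    return best",
    "out = []",
    "for pr in probs:",
    "    X = np.array(pr['X'], dtype=float); y = np.array(pr['y'], dtype=float)",
    "    l1, l2, k = float(pr['lambda1']), float(pr['lambda2']), int(pr['k'])",
    "    n, p = X.shape",
    "    Xc = X - X.mean(0); yc = y - y.mean()",
    "    m = p // k",
    "    rows = []",
    "    for t in range(m):",
    "        for j in range(k - 1):",
    "            r = np.zeros(p); r[t*k+j] = -1.0; r[t*k+j+1] = 1.0",
    "            rows.append(r)",
    "    D = np.array(rows) if rows else np.zeros((0, p))",
    "    e = D.shape[0]",
    "    H = 2.0 * Xc.T @ Xc",
    "    g0 = -2.0 * Xc.T @ yc",
    "    nv = p + p + e",
    "    lin = np.concatenate([np.zeros(p), l1*np.ones(p), l2*np.ones(e)])",
    "    def fun(w):",
    "        b = w[:p]",
    "        return yc @ yc + g0 @ b + 0.5 * b @ H @ b + lin @ w",
    "    def jac(w):",
    "        b = w[:p]",
    "        out = lin.copy(); out[:p] += g0 + H @ b",
    "        return out",
    "    Hfull = np.zeros((nv, nv)); Hfull[:p, :p] = H",
    "    A = np.zeros((2*p + 2*e, nv))",
    "    A[:p, :p] = np.eye(p);  A[:p, p:2*p] = -np.eye(p)",
    "    A[p:2*p, :p] = -np.eye(p); A[p:2*p, p:2*p] = -np.eye(p)",
    "    if e:",
    "        A[2*p:2*p+e, :p] = D;  A[2*p:2*p+e, 2*p:] = -np.eye(e)",
    "        A[2*p+e:, :p] = -D;    A[2*p+e:, 2*p:] = -np.eye(e)",
    "    con = LinearConstraint(A, -np.inf, 0.0)",
    "    w0 = np.zeros(nv)",
    "    res = minimize(fun, w0, jac=jac, hess=lambda w: Hfull,",
    "                   method='trust-constr', constraints=[con],",
    "                   options={'gtol': 1e-12, 'xtol': 1e-14,",
    "                            'maxiter': 5000, 'verbose': 0})",
    "    b = refine(res.x[:p], Xc, yc, l1, l2, k)",
    "    out.append(objective(b, Xc, yc, l1, l2, k))",
    "json.dump(out, open(sys.argv[2], 'w'))"
  ), script)
  status <- system2(py, c(script, infile, outfile), stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  }
  as.numeric(unlist(jsonlite::read_json(outfile)))
}

# objective of the package's loss convention, from raw (uncentered) data
fused_objective_value <- function(beta, beta0, X, y, lambda1, lambda2, k) {
  m <- length(beta) %/% k
  bm <- matrix(beta, nrow = k)
  tv <- if (k > 1) sum(abs(bm[-1, , drop = FALSE] - bm[-k, , drop = FALSE])) else 0
  sum((y - beta0 - drop(as.matrix(X) %*% beta))^2) +
    lambda1 * sum(abs(beta)) + lambda2 * tv
}

# KKT certificate: minimal Euclidean norm of a subgradient of the objective
# at beta, minimized over the free subgradient intervals by box-constrained
# least squares (L-BFGS-B). Small norm => beta is (near-)stationary.
kkt_min_subgradient_norm <- function(beta, X, y, lambda1, lambda2, k,
                                     tol = NULL) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  g <- 2 * drop(crossprod(Xc, Xc %*% beta - yc))
  p <- length(beta)
  m <- p %/% k
  if (is.null(tol)) tol <- 1e-8 * max(abs(beta), 1)
  edges <- chain_graph(m, k)$edges
  e <- nrow(edges)
  d <- if (e) beta[edges[, 2]] - beta[edges[, 1]] else numeric(0)
  s_fixed <- abs(beta) > tol
  t_fixed <- if (e) abs(d) > tol else logical(0)
  resid <- function(s, t) {
    r <- g + lambda1 * s
    if (e) {
      r[edges[, 1]] <- r[edges[, 1]] - lambda2 * t
      r[edges[, 2]] <- r[edges[, 2]] + lambda2 * t
    }
    r
  }
  s0 <- ifelse(s_fixed, sign(beta), 0)
  t0 <- if (e) ifelse(t_fixed, sign(d), 0) else numeric(0)
  nfree_s <- sum(!s_fixed)
  nfree_t <- sum(!t_fixed)
  if (nfree_s + nfree_t == 0) return(sqrt(sum(resid(s0, t0)^2)))
  fn <- function(par) {
    s <- s0; t <- t0
    if (nfree_s) s[!s_fixed] <- par[seq_len(nfree_s)]
    if (nfree_t) t[!t_fixed] <- par[nfree_s + seq_len(nfree_t)]
    sum(resid(s, t)^2)
  }
  opt <- stats::optim(numeric(nfree_s + nfree_t), fn, method = "L-BFGS-B",
                      lower = -1, upper = 1,
                      control = list(maxit = 1000, factr = 10))
  sqrt(opt$value)
}
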