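# Independent reference implementations used as oracles. Each is written
# directly from the mathematical definition, separately from the package
# code paths it checks.

# Quadratic UPGMA: clusters kept as index sets, inter-cluster distance
# recomputed from the original matrix at every step.
upgmaReferenceHeights <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# Reference-scaled median rollup, written as plain loops from the rule:
# reference = fewest missing then highest mean; shift others by the median
# difference over shared channels; protein value = median of shifted.
rollupReference <- function(pep_values, drop_warn = FALSE) {
  nobs <- apply(pep_values, 1, function(x) sum(!is.na(x)))
  mabund <- apply(pep_values, 1, function(x) mean(x, na.rm = TRUE))
  ref <- which(nobs == max(nobs))
  if (length(ref) > 1) ref <- ref[which.max(mabund[ref])]
  shifted <- NULL
  for (p in seq_len(nrow(pep_values))) {
    shared <- !is.na(pep_values[ref, ]) & !is.na(pep_values[p, ])
    if (!any(shared)) next
    delta <- median(pep_values[ref, shared] - pep_values[p, shared])
    shifted <- rbind(shifted, pep_values[p, ] + delta)
  }
  apply(shifted, 2, function(col)
    if (all(is.na(col))) NA_real_ else median(col, na.rm = TRUE))
}

# Step-up BH from the definition: sort, multiply by n/rank, enforce
# monotonicity from the largest p downward.
bhReference <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  if (n == 1) adj <- pmin(p, 1)
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Conditional NB exact p-value by direct dnbinom summation over the whole
# conditional outcome space.
nbExactReference <- function(sa, sb, na, nb, phi) {
  s <- round(sa + sb)
  if (s == 0) return(1)
  mu <- s / (na + nb)
  k <- 0:s
  if (phi < 1e-10) {
    f <- dbinom(k, s, na / (na + nb))
  } else {
    f <- dnbinom(k, size = na / phi, mu = na * mu) *
      dnbinom(s - k, size = nb / phi, mu = nb * mu)
  }
  obs <- f[round(sa) + 1]
  sum(f[f <= obs * (1 + 1e-10) + 1e-300]) / sum(f)
}

# Exhaustive PWM null distribution: every 4^w window scored on the same
# discretized grid; upper-tail probability under the background model.
pwmTailReference <- function(pwm, background, granularity = 1e-3,
                             pseudocount = 0.1) {
  p <- sweep(pwm$matrix + pseudocount * background, 2, 1 + pseudocount, "/")
  ints <- round(log2(p / background) / granularity)
  w <- ncol(ints)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(grid)); probs <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    idx <- cbind(grid[r, ], seq_len(w))
    scores[r] <- sum(ints[idx])
    probs[r] <- prod(background[grid[r, ]])
  }
  function(score_int) sum(probs[scores >= score_int])
}

# Independent LP oracle: scipy.optimize.linprog through the system python.
scipyLP <- function(obj, Aeq, beq, lb, ub, Ain = NULL, bin = NULL,
                    maximize = TRUE) {
  infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
  payload <- list(c = if (maximize) -obj else obj,
                  A = unname(as.matrix(Aeq)), b = beq, lb = lb, ub = ub)
  if (!is.null(Ain)) {
    payload$Aub <- unname(as.matrix(Ain)); payload$bub <- bin
  }
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = FALSE)
  script <- sprintf(paste0(
    "import json\nimport numpy as np\nfrom scipy.optimize import linprog\n",
    "d = json.load(open('%s'))\n",
    "kw = {}\n",
    "if 'Aub' in d: kw = dict(A_ub=np.array(d['Aub']), b_ub=np.array(d['bub']))\n",
    "res = linprog(np.array(d['c']), A_eq=np.array(d['A']),\n",
    "              b_eq=np.array(d['b']),\n",
    "              bounds=list(zip(d['lb'], d['ub'])), method='highs', **kw)\n",
    "json.dump({'status': int(res.status),\n",
    "           'fun': None if res.fun is None else float(res.fun)},\n",
    "          open('%s', 'w'))\n"), infile, outfile)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  system2("python", sf, stdout = FALSE, stderr = FALSE)
  res <- jsonlite::fromJSON(outfile)
  if (res$status != 0) return(list(status = "not_optimal", objective = NA))
  list(status = "optimal",
       objective = if (maximize) -res$fun else res$fun)
}

# Small random peptide table with missingness for rollup checks.
randomPeptideTable <- function(n_pep, n_chan, miss = 0.3) {
  vals <- matrix(rnorm(n_pep * n_chan, 20, 3), n_pep)
  m <- matrix(runif(n_pep * n_chan) < miss, n_pep)
  allm <- rowSums(!m) == 0
  m[cbind(which(allm), sample.int(n_chan, sum(allm), replace = TRUE))] <- FALSE
  vals[m] <- NA_real_
  vals
}

# Tiny in-code metabolic models for LP / loopless construction tests.
tinyChainModel <- function() {
  met <- data.frame(id = c("a_e", "a_c", "b_c"),
                    compartment = c("e", "c", "c"),
                    carbon = c(1, 1, 1), nitrogen = c(0, 0, 0),
                    stringsAsFactors = FALSE)
  rxn <- data.frame(id = c("EX_a_e", "UP", "CONV", "BIO"),
                    lower = c(-5, 0, 0, 0), upper = c(0, 1000, 1000, 1000),
                    exchange = c(TRUE, FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  S <- matrix(0, 3, 4, dimnames = list(met$id, rxn$id))
  S["a_e", "EX_a_e"] <- -1
  S["a_e", "UP"] <- -1; S["a_c", "UP"] <- 1
  S["a_c", "CONV"] <- -1; S["b_c", "CONV"] <- 1
  S["b_c", "BIO"] <- -1
  new("MetabolicModel", metabolites = met, reactions = rxn, stoich = S,
      objective = "BIO")
}
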