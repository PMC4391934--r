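# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately written via different routes than the package code
# (direct formula evaluation, exhaustive enumeration, permutation).

default_lib <- build_default_library()
default_E <- as.matrix(default_lib)

small_scene <- function(seed = 1, ...) {
  args <- list(height = 96, width = 96, n_nests = 2, nest_axes = c(14, 22),
               seed = seed)
  do.call(scene_params, utils::modifyList(args, list(...)))
}

# Exhaustive grid-search NNLS oracle at `step` resolution. Coarse full grid
# over [0, hi]^3 followed by exhaustive local grids; valid because the NNLS
# objective is convex, so the refined local optimum is global.
grid_nnls <- function(y, E, step = 1e-3, hi = 1.5) {
  stopifnot(ncol(E) == 3)
  res2 <- function(a) sum((E %*% a - y)^2)
  best <- c(0, 0, 0); bstep <- 0.05
  g <- seq(0, hi, by = bstep)
  vals <- expand.grid(a1 = g, a2 = g, a3 = g)
  M <- crossprod(E); Ety <- crossprod(E, y)
  A <- t(as.matrix(vals))
  r2 <- colSums(A * (M %*% A)) - 2 * colSums(A * as.vector(Ety)) + sum(y^2)
  best <- as.numeric(vals[which.min(r2), ])
  for (s in c(0.01, 0.002, 0.001)) {
    g <- seq(-6 * s, 6 * s, by = s)
    cand <- expand.grid(a1 = best[1] + g, a2 = best[2] + g, a3 = best[3] + g)
    cand <- as.matrix(cand[cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0, ])
    A <- t(cand)
    r2 <- colSums(A * (M %*% A)) - 2 * colSums(A * as.vector(Ety)) + sum(y^2)
    best <- as.numeric(cand[which.min(r2), ])
  }
  list(abundance = best, residual = sqrt(max(res2(best), 0)))
}

# Hand product-limit worked set: times (1,3,3,5,7,8), events (1,1,0,1,1,0).
# S(1) = 5/6; S(3) = 5/6 * 4/5 = 2/3; S(5) = 2/3 * 2/3 = 4/9;
# S(7) = 4/9 * 1/2 = 2/9.
km_hand_set <- list(time = c(1, 3, 3, 5, 7, 8), event = c(1, 1, 0, 1, 1, 0),
                    surv_at_events = c(5 / 6, 2 / 3, 4 / 9, 2 / 9))

# Breslow partial log-likelihood for one binary/numeric covariate; used as a
# grid-search oracle for the Cox coefficient.
breslow_loglik <- function(b, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(event == 1 & time == t)
    risk <- which(time >= t)
    ll <- ll + sum(b * x[d]) - length(d) * log(sum(exp(b * x[risk])))
  }
  ll
}

# Exhaustive pairwise concordance AUC oracle (ties counted half).
pairwise_auc <- function(predictor, outcome) {
  pos <- predictor[outcome == 1]; neg <- predictor[outcome == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Two-group log-rank chi-square oracle via survival::survdiff.
survdiff_chi2 <- function(time, event, group) {
  survival::survdiff(survival::Surv(time, event) ~ group)$chisq
}
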