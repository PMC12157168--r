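# Shared fixtures, built in code.

# Independent child seeds for multi-seed replicate loops (kept below 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729 + 17) %% 2147483629)
}

# Two-excipient space plus a derived total, as in an albumin screen.
rhsa_space <- function(constraints = list()) {
  design_space(
    feature_spec("residual_rHSA", 0, 1.5, "mg/mL"),
    feature_spec("spiked_rHSA", 0, 5, "mg/mL"),
    constraints = constraints
  )
}

rhsa_space_with_total <- function() {
  design_space(
    feature_spec("residual_rHSA", 0, 1.5, "mg/mL"),
    feature_spec("spiked_rHSA", 0, 5, "mg/mL"),
    feature_spec("total_rHSA", 0, 6.5, "mg/mL", role = "derived",
                 parents = c("residual_rHSA", "spiked_rHSA"))
  )
}

# Small dataset on the two-excipient space with a smooth noiseless response.
small_dataset <- function(n = 12, noise_sd = 0, seed = 42) {
  sp <- rhsa_space()
  X <- sample_design(sp, n, scheme = "latin", seed = seed)
  y <- 1.5 - 0.5 * pmin(X$residual_rHSA, 0.2) / 0.2 + 0.1 * X$spiked_rHSA
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed + 1, rnorm(n, 0, noise_sd))
  }
  X$loss <- y
  formulation_dataset(sp, X, "loss", unit = "log10 PFU/mL")
}

# Brute-force GP posterior via direct matrix inversion (independent of the
# package's Cholesky path).
bruteforce_gp_posterior <- function(X, y, xnew, l, s2, sn2) {
  n <- nrow(X)
  ym <- mean(y); ysd <- stats::sd(y); if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ym) / ysd
  k <- function(a, b) {
    d <- sqrt(sum((a - b)^2))
    r <- sqrt(5) * d / l
    s2 * (1 + r + r^2 / 3) * exp(-r)
  }
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- k(X[i, ], X[j, ])
  A <- K + diag(sn2 + 1e-10, n)
  Ainv <- solve(A)
  ks <- vapply(1:n, function(i) k(X[i, ], xnew), numeric(1))
  mu <- sum(ks * (Ainv %*% ys))
  v <- s2 - drop(t(ks) %*% Ainv %*% ks) + sn2
  list(mean = mu * ysd + ym, var = max(v, 0) * ysd^2)
}

# Permutation-enumeration Shapley oracle: average marginal contribution over
# all M! orderings, with the same interventional value function.
bruteforce_shap <- function(model, instance, background) {
  feats <- model$feature_names
  M <- length(feats)
  x <- as.numeric(as.data.frame(as.list(instance))[1, feats])
  bg <- as.matrix(as.data.frame(background)[, feats, drop = FALSE])
  vfun <- function(S) {
    hyb <- bg
    if (length(S)) hyb[, S] <- matrix(rep(x[S], each = nrow(bg)), nrow(bg), length(S))
    mean(predict(model, hyb))
  }
  perms <- combinat_perms(M)
  phi <- numeric(M)
  for (p in perms) {
    prev <- numeric(0)
    v_prev <- vfun(integer(0))
    for (i in p) {
      v_new <- vfun(c(prev, i))
      phi[i] <- phi[i] + (v_new - v_prev)
      prev <- c(prev, i)
      v_prev <- v_new
    }
  }
  stats::setNames(phi / length(perms), feats)
}

combinat_perms <- function(M) {
  if (M == 1) return(list(1L))
  out <- list()
  for (i in seq_len(M)) {
    rest <- combinat_perms(M - 1L)
    for (r in rest) {
      v <- seq_len(M)[-i]
      out[[length(out) + 1L]] <- c(i, v[r])
    }
  }
  out
}
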