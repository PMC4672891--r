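# Independent reference implementations used only to cross-check the
# package's solvers on small instances.

# brute-force AUC: count positive-negative pairs, ties worth one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (s in pos) total <- total + sum(s > neg) + 0.5 * sum(s == neg)
  total / (length(pos) * length(neg))
}

# penalized logistic objective: (1/n) NLL + lambda * sum(|beta|)
lasso_objective <- function(X, y, b0, beta, lambda) {
  eta <- b0 + drop(X %*% beta)
  mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
    lambda * sum(abs(beta))
}

# exact KKT violation of the lasso logistic problem at (b0, beta)
lasso_kkt <- function(X, y, b0, beta, lambda) {
  p <- plogis(b0 + drop(X %*% beta))
  g <- drop(crossprod(X, p - y)) / length(y)
  v <- abs(mean(p - y))
  for (j in seq_along(beta)) {
    v <- max(v, if (beta[j] != 0) abs(g[j] + lambda * sign(beta[j]))
             else max(0, abs(g[j]) - lambda))
  }
  v
}

# overlapped (latent) group-lasso logistic objective.
# latent = c(b0, mains(p), per-pair 3-vectors); pairs is a 2-column
# 1-based index matrix; product columns are raw x_j * x_k (no scaling).
group_objective <- function(X, y, pairs, latent, lambda, pw = sqrt(3)) {
  p <- ncol(X)
  G <- nrow(pairs)
  b0 <- latent[1]
  am <- latent[2:(p + 1)]
  eta <- b0 + drop(X %*% am)
  pen <- lambda * sum(abs(am))
  for (g in seq_len(G)) {
    a <- latent[(1 + p + 3 * (g - 1) + 1):(1 + p + 3 * g)]
    j <- pairs[g, 1]; k <- pairs[g, 2]
    eta <- eta + X[, j] * a[1] + X[, k] * a[2] + X[, j] * X[, k] * a[3]
    pen <- pen + lambda * pw * sqrt(sum(a^2))
  }
  mean(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) + pen
}

# generic ADMM solver for the same latent group-lasso objective; used as
# the convex-programming oracle on tiny instances.
group_lasso_admm <- function(X, y, pairs, lambda, pw = sqrt(3),
                             rho = 1, iters = 4000) {
  n <- nrow(X); p <- ncol(X); G <- nrow(pairs)
  # latent design (without intercept): mains then 3 columns per pair
  Z <- X
  for (g in seq_len(G)) {
    j <- pairs[g, 1]; k <- pairs[g, 2]
    Z <- cbind(Z, X[, j], X[, k], X[, j] * X[, k])
  }
  d <- ncol(Z)
  alpha <- numeric(d); z <- numeric(d); u <- numeric(d); b0 <- 0
  best <- Inf; best_latent <- c(b0, z)
  for (it in seq_len(iters)) {
    # x-update: logistic + (rho/2)||alpha - z + u||^2 by Newton
    for (nw in 1:25) {
      eta <- b0 + drop(Z %*% alpha)
      pr <- plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-9)
      g0 <- mean(pr - y)
      ga <- drop(crossprod(Z, pr - y)) / n + rho * (alpha - z + u)
      H <- crossprod(Z * w, Z) / n + diag(rho, d)
      h0 <- mean(w)
      hx <- drop(crossprod(Z, w)) / n
      Hfull <- rbind(c(h0, hx), cbind(hx, H))
      step <- solve(Hfull, c(g0, ga))
      b0 <- b0 - step[1]
      alpha <- alpha - step[-1]
      if (max(abs(step)) < 1e-12) break
    }
    # z-update: proximal operator of the group norms
    v <- alpha + u
    z[1:p] <- sign(v[1:p]) * pmax(0, abs(v[1:p]) - lambda / rho)
    for (g in seq_len(G)) {
      idx <- (p + 3 * (g - 1) + 1):(p + 3 * g)
      nm <- sqrt(sum(v[idx]^2))
      z[idx] <- if (nm > 0) max(0, 1 - lambda * pw / (rho * nm)) * v[idx]
                else 0
    }
    u <- u + alpha - z
    obj <- group_objective(X, y, pairs, c(b0, z), lambda, pw)
    if (obj < best) {
      best <- obj
      best_latent <- c(b0, z)
    }
  }
  list(objective = best, latent = best_latent)
}

# unpenalized logistic MLE by Newton-Raphson (oracle for lambda = 0)
logistic_mle <- function(X, y, iters = 100) {
  Z <- cbind(1, X)
  b <- numeric(ncol(Z))
  for (it in seq_len(iters)) {
    pr <- plogis(drop(Z %*% b))
    w <- pmax(pr * (1 - pr), 1e-10)
    step <- solve(crossprod(Z * w, Z), crossprod(Z, y - pr))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

# exhaustive per-pair likelihood-ratio interaction screen: deviance drop
# of adding x_j * x_k to the two-main-effect logistic model
lr_pair_screen <- function(ds) {
  p <- length(ds$feature_names)
  combos <- t(utils::combn(p, 2))
  dev_drop <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    a <- ds$X[, combos[i, 1]]
    b <- ds$X[, combos[i, 2]]
    f0 <- glm(ds$y ~ a + b, family = binomial())
    f1 <- glm(ds$y ~ a * b, family = binomial())
    dev_drop[i] <- f0$deviance - f1$deviance
  }
  data.frame(left = ds$feature_names[combos[, 1]],
             right = ds$feature_names[combos[, 2]],
             dev_drop = dev_drop)[order(-dev_drop), ]
}
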