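# Independent oracles used across the suite. These deliberately avoid the
# code paths (and where possible the distribution functions) they check.

# direct summation of the binomial upper tail via log factorials
binomTailOracle <- function(m, n, p0) {
  if (m <= 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  k <- m:n
  sum(exp(lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)))
}

# two-sided Fisher p by full enumeration of tables with the observed margins
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  logp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
  }
  probs <- exp(vapply(a_range, logp, numeric(1)))
  p_obs <- exp(logp(tab[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating group assignments
mwuEnumOracle <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  lo <- mean(all_u <= u_obs); hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# exhaustive parsimony oracle for the 7-taxon pair design. States are
# logical (TRUE = BM). Enumerates all 2^5 internal labelings over
# (P1, P2, P3, Ninner, Root), counts changes on the ten ingroup branches,
# and applies the outgroup tie rule for the root.
PAIR_BRANCHES <- list(
  c("Root", "P1"), c("Root", "Ninner"), c("Ninner", "P2"), c("Ninner", "P3"),
  c("P1", "Ama"), c("P1", "Mgu"), c("P2", "Rap"), c("P2", "Ptr"),
  c("P3", "Sal"), c("P3", "Egr"))

parsimonyOracle <- function(leaves, osa) {
  # leaves: named logical for the six ingroup tips; osa: logical
  nodes <- c("P1", "P2", "P3", "Ninner", "Root")
  best <- list(total = Inf)
  min_by_root <- c(`FALSE` = Inf, `TRUE` = Inf)
  for (mask in 0:31) {
    lab <- as.logical(bitwAnd(mask, 2^(0:4)))
    names(lab) <- nodes
    st <- c(leaves, lab)
    changes <- sum(vapply(PAIR_BRANCHES,
                          function(b) st[b[1]] != st[b[2]], logical(1)))
    key <- as.character(lab[["Root"]])
    if (changes < min_by_root[[key]]) min_by_root[[key]] <- changes
  }
  overall <- min(min_by_root)
  tie <- min_by_root[["TRUE"]] == min_by_root[["FALSE"]]
  root <- if (tie) osa else unname(min_by_root[["TRUE"]] < min_by_root[["FALSE"]])
  list(min_changes = unname(min_by_root[[as.character(root)]]),
       overall_min = unname(overall), root = root, tie = tie)
}

# convergence truth table straight from the printed rule
convergenceOracle <- function(leaves, osa, root) {
  mang <- c("Ama", "Rap", "Sal"); nonm <- c("Mgu", "Ptr", "Egr")
  n_m <- sum(leaves[mang]); n_n <- sum(leaves[nonm])
  n_all <- sum(c(leaves, osa))
  conv_m <- !root && n_m >= 2
  conv_n <- !root && n_n >= 2
  label <- if (conv_m) "convBMM" else if (conv_n) "convBMN"
    else if (n_all >= 2) "non-convBM" else "none"
  list(label = label, both = conv_m && conv_n, group = n_all)
}

# implied change count of a resolved assignment on the ingroup tree
impliedChanges <- function(assignment, cluster = 1L) {
  tree <- assignment$tree
  labs <- c(tree$tip.label,
            if (!is.null(tree$node.label)) tree$node.label else
              paste0("node", seq_len(tree$Nnode) + length(tree$tip.label)))
  st <- assignment$states[cluster, ]
  sum(vapply(seq_len(nrow(tree$edge)), function(e) {
    st[labs[tree$edge[e, 1]]] != st[labs[tree$edge[e, 2]]]
  }, logical(1)))
}

# independent Newton-Raphson logistic regression (counts response);
# returns coefficients and standard errors
irlsOracle <- function(X, meth, unmeth, iter = 50) {
  beta <- rep(0, ncol(X))
  tot <- meth + unmeth
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- tot * mu * (1 - mu)
    score <- drop(t(X) %*% (meth - tot * mu))
    info <- t(X) %*% (W * X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- t(X) %*% ((tot * mu * (1 - mu)) * X)
  list(beta = beta, se = sqrt(diag(solve(info))))
}
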