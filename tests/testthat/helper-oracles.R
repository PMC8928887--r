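# Independent oracles and small fixtures used across the test files.

# Exhaustive-subset oracle for the contingency diet: enumerates every subset
# of feasible prey (finite handling time) of consumer j and returns the
# maximum achievable intake rate R(D) = sum(lambda*E) / (1 + sum(lambda*H))
# together with all subsets attaining it. Completely independent of the
# package's sequential algorithm.
oracle_best_diet <- function(traits, j) {
  H <- traits$H[, j]
  feas <- which(is.finite(H))
  lambda <- traits$A[, j] * traits$N
  best_rate <- 0          # R(empty set) = 0
  best_sets <- list(integer(0))
  if (length(feas)) {
    n <- length(feas)
    for (mask in seq_len(2^n - 1)) {
      sel <- feas[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      num <- sum(lambda[sel] * traits$E[sel])
      den <- 1 + sum(lambda[sel] * H[sel])
      r <- num / den
      if (r > best_rate + 1e-12 * max(1, best_rate)) {
        best_rate <- r
        best_sets <- list(sel)
      } else if (abs(r - best_rate) <= 1e-12 * max(1, best_rate)) {
        best_sets <- c(best_sets, list(sel))
      }
    }
  }
  list(rate = best_rate, sets = best_sets)
}

# Intake rate of an arbitrary diet, from the definition.
oracle_rate <- function(traits, j, diet) {
  if (!length(diet)) return(0)
  H <- traits$H[diet, j]
  lambda <- traits$A[diet, j] * traits$N[diet]
  sum(lambda * traits$E[diet]) / (1 + sum(lambda * H))
}

# Naive TSS straight from the printed formula, from two plain matrices.
oracle_tss <- function(obs, pred) {
  TP <- sum(obs == 1 & pred == 1); TN <- sum(obs == 0 & pred == 0)
  FP <- sum(obs == 0 & pred == 1); FN <- sum(obs == 1 & pred == 0)
  (TP * TN - FP * FN) / ((TP + FN) * (FP + TN))
}

# Random binary web over a community (not degenerate unless forced).
random_web <- function(com, p = 0.3) {
  S <- length(com$node_ids)
  predation_matrix(com, matrix(as.integer(runif(S^2) < p), S, S))
}

toy_community <- function(S = 4, lo = -3, hi = 2, seed = 1) {
  generate_community(S, c(lo, hi), seed = seed)
}

# 3-species chain over a fixed community: a eaten by b, b eaten by c.
chain3 <- function() {
  com <- community(c("a", "b", "c"), c(1, 10, 100))
  links <- matrix(0L, 3, 3, dimnames = list(com$node_ids, com$node_ids))
  links["a", "b"] <- 1L
  links["b", "c"] <- 1L
  predation_matrix(com, links)
}

# 4-species directed cycle a->b->c->d->a (resource -> consumer).
cycle4 <- function() {
  com <- community(c("a", "b", "c", "d"), c(1, 2, 4, 8))
  links <- matrix(0L, 4, 4, dimnames = list(com$node_ids, com$node_ids))
  links["a", "b"] <- 1L
  links["b", "c"] <- 1L
  links["c", "d"] <- 1L
  links["d", "a"] <- 1L
  predation_matrix(com, links)
}

random_params <- function() {
  adbm_params(a = 10^runif(1, -6, 2), ai = runif(1, -1.5, 1.5),
              aj = runif(1, 0, 3), b = 10^runif(1, -2, 1))
}
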