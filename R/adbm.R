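#' ADBM parameters
#'
#' One point in the parameter space of the allometric diet breadth model.
#' Four parameters are free and estimated by ABC: the space-clearance
#' constant `a`, the prey- and predator-mass exponents of the space clearance
#' (attack) rate `ai` and `aj`, and the handling-time ratio threshold `b`,
#' above which a prey/predator mass ratio makes handling time infinite. The
#' remaining constants are fixed: only the product n*a*h affects which links
#' are predicted and the energy constant e has no effect on structure at all,
#' so `e = n = h = 1` and the density exponent `ni = -3/4` (metabolic scaling
#' of abundance with body mass).
#'
#' @param a space-clearance constant, > 0.
#' @param ai prey-mass exponent of the space clearance rate.
#' @param aj predator-mass exponent of the space clearance rate.
#' @param b handling-time threshold on the prey/predator mass ratio, > 0.
#' @param e energy constant (fixed, > 0).
#' @param n density constant (fixed, > 0).
#' @param ni density exponent (fixed).
#' @param h handling-time constant (fixed, > 0).
#' @return An object of class `adbm_params`.
#' @examples
#' adbm_params(a = 1e-3, ai = 0.5, aj = 0.5, b = 0.1)
#' @export
adbm_params <- function(a, ai, aj, b, e = 1, n = 1, ni = -0.75, h = 1) {
  vals <- c(a = a, ai = ai, aj = aj, b = b, e = e, n = n, ni = ni, h = h)
  if (any(!is.finite(vals))) stop("all ADBM parameters must be finite")
  pos <- c("a", "b", "e", "n", "h")
  bad <- pos[vals[pos] <= 0]
  if (length(bad)) stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  structure(as.list(vals), class = "adbm_params")
}

#' @export
print.adbm_params <- function(x, ...) {
  cat(sprintf("ADBM parameters: a = %.4g, ai = %.4g, aj = %.4g, b = %.4g",
              x$a, x$ai, x$aj, x$b),
      sprintf("(fixed: e = %g, n = %g, ni = %g, h = %g)\n", x$e, x$n, x$ni, x$h))
  invisible(x)
}

#' Allometric trait tables
#'
#' Builds the four allometric quantities the foraging model needs, from body
#' masses M (grams):
#' \itemize{
#'   \item prey energy content `E[i] = e * M[i]`
#'   \item prey density `N[i] = n * M[i]^ni`
#'   \item space clearance (attack) rate `A[i, j] = a * M[i]^ai * M[j]^aj`
#'   \item handling time `H[i, j] = h / (b - M[i]/M[j])` when
#'     `M[i]/M[j] < b`, and `+Inf` otherwise (the prey is too large relative
#'     to the consumer to ever be handled).
#' }
#' Rows index prey i and columns consumers j. Power terms are evaluated on
#' the log scale, so communities spanning ten or more orders of magnitude in
#' mass do not overflow; an entry that still overflows (parameter-driven)
#' raises an error naming the species.
#'
#' @param community an `adbm_community`.
#' @param params an `adbm_params`.
#' @return An object of class `adbm_traits`: list with vectors `E`, `N` and
#'   matrices `A`, `H`, plus the masses `M`.
#' @export
build_traits <- function(community, params) {
  stopifnot(inherits(community, "adbm_community"), inherits(params, "adbm_params"))
  M <- community$masses
  logM <- log(M)
  E <- params$e * M
  N <- exp(log(params$n) + params$ni * logM)
  logA <- log(params$a) + outer(params$ai * logM, params$aj * logM, `+`)
  A <- exp(logA)
  if (any(is.infinite(A))) {
    idx <- which(is.infinite(A), arr.ind = TRUE)[1, ]
    stop("attack rate overflow for prey ", community$node_ids[idx[1]],
         ", consumer ", community$node_ids[idx[2]],
         " (exponents ai = ", params$ai, ", aj = ", params$aj, ")")
  }
  if (any(!is.finite(N)) || any(N <= 0)) {
    stop("prey density overflow/underflow (exponent ni = ", params$ni, ")")
  }
  ratio <- exp(outer(logM, logM, `-`))  # M_i / M_j
  H <- params$h / (params$b - ratio)
  H[ratio >= params$b] <- Inf
  ids <- community$node_ids
  dimnames(A) <- dimnames(H) <- list(resource = ids, consumer = ids)
  structure(list(M = M, E = E, N = N, A = A, H = H),
            class = "adbm_traits")
}

# Core diet routine shared by optimal_diet() and predict_web(). Takes the
# per-consumer profitability and encounter quantities and applies the
# contingency rule: rank feasible prey by decreasing profitability
# P = E/H (ties: smaller prey first, i.e. lower index in the mass-sorted
# community), add prey while the next item's profitability strictly exceeds
# the intake rate R(D) = sum(lambda*E) / (1 + sum(lambda*H)) of the diet so
# far, stop at the first exclusion.
diet_for_consumer <- function(P, lambda, H) {
  feas <- which(is.finite(H) & P > 0)
  if (!length(feas)) return(integer(0))
  ord <- feas[order(-P[feas], feas)]
  lamE <- lambda[ord] * P[ord] * H[ord]  # lambda * E  (E = P * H, H finite)
  lamH <- lambda[ord] * H[ord]
  rate <- cumsum(lamE) / (1 + cumsum(lamH))
  r_prev <- c(0, rate[-length(rate)])
  keep <- P[ord] > r_prev
  first_drop <- which(!keep)
  k <- if (length(first_drop)) first_drop[1] - 1L else length(ord)
  if (k == 0L) integer(0) else as.integer(sort(unname(ord[seq_len(k)])))
}

#' Optimal diet of one consumer
#'
#' Applies the contingency model of optimal foraging: prey are ranked by
#' decreasing profitability `P[i, j] = E[i] / H[i, j]` (zero when handling is
#' infinite) and added in that order while the next item's profitability
#' strictly exceeds the energy intake rate of the current diet,
#' `R(D) = sum_i(lambda[i, j] * E[i]) / (1 + sum_i(lambda[i, j] * H[i, j]))`
#' with encounter rate `lambda[i, j] = A[i, j] * N[i]`. The first excluded
#' item stops the scan; the resulting set maximizes the intake rate. Ties in
#' profitability are broken towards the smaller prey, then label order, via
#' the community's canonical sorting.
#'
#' @param consumer_index integer column index of the consumer in the
#'   mass-sorted community.
#' @param traits an `adbm_traits` from [build_traits()].
#' @return Sorted integer vector of prey indices (possibly empty).
#' @export
optimal_diet <- function(consumer_index, traits) {
  stopifnot(inherits(traits, "adbm_traits"))
  j <- as.integer(consumer_index)
  stopifnot(j >= 1L, j <= length(traits$M))
  H <- traits$H[, j]
  P <- ifelse(is.finite(H), traits$E / H, 0)
  lambda <- traits$A[, j] * traits$N
  diet_for_consumer(P, lambda, H)
}

#' Predict a food web with the ADBM
#'
#' Column j of the predicted predation matrix is the indicator vector of the
#' optimal diet of consumer j. The model is purely deterministic: equal
#' inputs always give an identical matrix.
#'
#' @param community an `adbm_community`.
#' @param params an `adbm_params`.
#' @return A `predation_matrix`.
#' @examples
#' com <- community(paste0("s", 1:4), c(0.01, 0.1, 1, 10))
#' predict_web(com, adbm_params(a = 1, ai = 0.5, aj = 0.5, b = 0.5))
#' @export
predict_web <- function(community, params) {
  traits <- build_traits(community, params)
  S <- length(traits$M)
  links <- matrix(0L, S, S)
  lambda <- traits$A * traits$N  # N recycles down columns: lambda[i,j] = A[i,j]*N[i]
  P <- ifelse(is.finite(traits$H), traits$E / traits$H, 0)
  for (j in seq_len(S)) {
    d <- diet_for_consumer(P[, j], lambda[, j], traits$H[, j])
    if (length(d)) links[d, j] <- 1L
  }
  predation_matrix(community, links)
}

# Fast path used by the ABC loop: precomputes everything that depends only
# on the community, then predicts the link matrix (no classes, no dimnames)
# for many parameter points.
adbm_precompute <- function(community, ni = -0.75) {
  M <- community$masses
  logM <- log(M)
  list(
    S = length(M),
    logM = logM,
    E = M,                               # e = 1
    N = exp(ni * logM),                  # n = 1
    ratio = exp(outer(logM, logM, `-`)), # M_i / M_j
    ai_part = logM, aj_part = logM
  )
}

adbm_predict_links <- function(pre, a, ai, aj, b, h = 1) {
  S <- pre$S
  H <- h / (b - pre$ratio)
  H[pre$ratio >= b] <- Inf
  A <- exp(log(a) + outer(ai * pre$logM, aj * pre$logM, `+`))
  lambda <- A * pre$N
  P <- ifelse(is.finite(H), pre$E / H, 0)
  links <- matrix(0L, S, S)
  for (j in seq_len(S)) {
    d <- diet_for_consumer(P[, j], lambda[, j], H[, j])
    if (length(d)) links[d, j] <- 1L
  }
  links
}
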