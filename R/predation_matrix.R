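#' Create a predation matrix
#'
#' A predation matrix is the unit of observation and prediction: a binary
#' S x S matrix over a community, with rows as resources and columns as
#' consumers, so `links[i, j] == 1` means consumer j eats resource i. The
#' diagonal is permitted (cannibalism). Rows and columns follow the
#' community's canonical mass-sorted order.
#'
#' @param community an `adbm_community`.
#' @param links S x S matrix with entries in \{0, 1\}. Dimnames, if present,
#'   must match the community node ids (any order; the matrix is realigned).
#' @return An object of class `predation_matrix`: list with elements
#'   `community` and `links` (integer matrix with dimnames).
#' @export
predation_matrix <- function(community, links) {
  stopifnot(inherits(community, "adbm_community"))
  links <- as.matrix(links)
  S <- length(community$node_ids)
  if (nrow(links) != S || ncol(links) != S) {
    stop("links must be a square ", S, " x ", S, " matrix")
  }
  if (!all(links %in% c(0, 1))) {
    stop("links entries must be 0 or 1")
  }
  ids <- community$node_ids
  if (!is.null(rownames(links)) || !is.null(colnames(links))) {
    if (!setequal(rownames(links), ids) || !setequal(colnames(links), ids)) {
      stop("links dimnames do not match community node ids")
    }
    links <- links[ids, ids, drop = FALSE]
  }
  storage.mode(links) <- "integer"
  dimnames(links) <- list(resource = ids, consumer = ids)
  structure(list(community = community, links = links),
            class = "predation_matrix")
}

#' @export
print.predation_matrix <- function(x, ...) {
  S <- nrow(x$links)
  L <- sum(x$links)
  cat(sprintf("Predation matrix: S = %d, L = %d, connectance = %.4f\n",
              S, L, L / S^2))
  invisible(x)
}

#' Connectance of a predation matrix
#'
#' The number of realized trophic links divided by the number of potential
#' links, L / S^2. Potential links include self-links, i.e. every species can
#' in principle have a trophic link with every species including itself.
#'
#' @param web a `predation_matrix`.
#' @return Fraction in \[0, 1\].
#' @examples
#' com <- community(c("a", "b", "c"), c(1, 10, 100))
#' chain <- predation_matrix(com, rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
#' connectance(chain)  # 2/9
#' @export
connectance <- function(web) {
  stopifnot(inherits(web, "predation_matrix"))
  sum(web$links) / nrow(web$links)^2
}

#' Create a link-frequency matrix
#'
#' Aggregates how often each potential link was present across a set of
#' predicted webs (e.g. the posterior-predictive stack of accepted ABC
#' samples): `counts[i, j]` is the number of webs, out of `n_webs`, in which
#' consumer j ate resource i.
#'
#' @param community an `adbm_community`.
#' @param counts S x S matrix of non-negative integer counts.
#' @param n_webs number of webs aggregated; all counts must be `<= n_webs`.
#' @return An object of class `link_frequency`.
#' @export
link_frequency <- function(community, counts, n_webs) {
  stopifnot(inherits(community, "adbm_community"))
  counts <- as.matrix(counts)
  S <- length(community$node_ids)
  n_webs <- as.integer(n_webs)
  if (nrow(counts) != S || ncol(counts) != S) {
    stop("counts must be a square ", S, " x ", S, " matrix")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(counts > n_webs)) {
    stop("counts cannot exceed n_webs")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(resource = community$node_ids,
                           consumer = community$node_ids)
  structure(list(community = community, counts = counts, n_webs = n_webs),
            class = "link_frequency")
}

#' @export
print.link_frequency <- function(x, ...) {
  cat(sprintf("Link frequencies over %d webs (S = %d); never-predicted pairs: %d\n",
              x$n_webs, nrow(x$counts), sum(x$counts == 0L)))
  invisible(x)
}
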