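#' Create a community of species with body masses
#'
#' A community is the sole trait input to the allometric diet breadth model:
#' an ordered set of node labels with one body mass (grams) per node. On
#' construction the community is canonically sorted by non-decreasing body
#' mass (ties broken by label order), so that predation matrices built on it
#' display prey size increasing down the rows and predator size increasing
#' across the columns.
#'
#' @param node_ids character vector of unique node labels.
#' @param masses numeric vector of strictly positive, finite body masses in
#'   grams, same length and order as `node_ids`.
#' @return An object of class `adbm_community`: a list with elements
#'   `node_ids` and `masses` in canonical (mass-sorted) order, and an
#'   attribute `input_order` recording the order the nodes were supplied in.
#' @examples
#' community(c("A", "B"), c(1.0, 0.5))  # stored as B, A
#' @export
community <- function(node_ids, masses) {
  node_ids <- as.character(node_ids)
  masses <- as.numeric(masses)
  if (length(node_ids) != length(masses)) {
    stop("node_ids and masses must have the same length")
  }
  if (length(node_ids) < 2L) {
    stop("a community needs at least 2 nodes")
  }
  bad <- !is.finite(masses) | masses <= 0
  if (any(bad)) {
    stop("non-positive or non-finite body mass for node(s): ",
         paste(node_ids[bad], collapse = ", "))
  }
  dup <- duplicated(node_ids)
  if (any(dup)) {
    stop("duplicate node_id(s): ", paste(unique(node_ids[dup]), collapse = ", "))
  }
  ord <- order(masses, node_ids)
  out <- structure(
    list(node_ids = node_ids[ord], masses = masses[ord]),
    input_order = node_ids,
    class = "adbm_community"
  )
  out
}

#' @export
print.adbm_community <- function(x, ...) {
  cat(sprintf("Community of %d species; body mass range [%.3g, %.3g] g\n",
              length(x$node_ids), min(x$masses), max(x$masses)))
  invisible(x)
}

#' Number of species in a community or web
#'
#' @param x an `adbm_community` or `predation_matrix`.
#' @return Integer species count S.
#' @export
n_species <- function(x) {
  if (inherits(x, "predation_matrix")) x <- x$community
  length(x$node_ids)
}

same_community <- function(a, b) {
  identical(a$node_ids, b$node_ids) && isTRUE(all.equal(a$masses, b$masses))
}
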