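#' Structural properties of a food web
#'
#' Computes eleven structural metrics of a predation matrix. Definitions:
#' \itemize{
#'   \item Species are classified from their resource/consumer sets with
#'     self-links ignored: basal = no resources; top = at least one resource
#'     and no consumers; intermediate = both. The classification is
#'     exhaustive, so the three proportions sum to 1.
#'   \item `prop_herbivores`: proportion of species that consume at least one
#'     resource, all of whose resources are basal.
#'   \item `mean_omnivory`: trophic levels are shortest-path based (basal
#'     species have level 1; any other species has level 1 plus the length of
#'     its shortest directed path to a basal species along feeding links).
#'     A consumer's omnivory is the standard deviation of its resources'
#'     trophic levels (0 for a single resource); `mean_omnivory` averages
#'     over consumers whose resources all have defined levels. Undefined
#'     (`NA`) when the web has no basal species.
#'   \item `clustering_coefficient`: average local clustering on the
#'     undirected simple projection (self-links dropped); vertices with
#'     fewer than two neighbours contribute 0.
#'   \item `sd_generality`, `sd_vulnerability`: sample standard deviation of
#'     the normalized counts `g = G / (L/S)` and `v = V / (L/S)`, where `G`
#'     is a consumer's number of resources and `V` a resource's number of
#'     consumers, self-links included. 0 for an empty web.
#'   \item `diet_similarity`: mean Jaccard similarity of resource sets over
#'     unordered species pairs; two empty diets count as identical
#'     (similarity 1).
#'   \item `mean_path_length`: mean directed shortest-path length over
#'     ordered reachable pairs of distinct species (links directed resource
#'     to consumer); `NA` if no pair is reachable.
#'   \item `nestedness`: NODF over rows and columns of the binary matrix, on
#'     the 0--100 scale (computed with \code{vegan::nestednodf}); `NA` for an
#'     empty web.
#' }
#' Metrics that are undefined on an instance are returned as `NA`, never as
#' an arbitrary number.
#'
#' @param web a `predation_matrix`.
#' @return Named numeric vector of class `property_set` with elements
#'   `prop_basal`, `prop_intermediate`, `prop_top`, `prop_herbivores`,
#'   `mean_omnivory`, `clustering_coefficient`, `sd_generality`,
#'   `sd_vulnerability`, `diet_similarity`, `mean_path_length`, `nestedness`.
#' @export
structural_properties <- function(web) {
  stopifnot(inherits(web, "predation_matrix"))
  m <- web$links
  S <- nrow(m)
  L <- sum(m)
  m_noself <- m
  diag(m_noself) <- 0L

  n_res <- colSums(m_noself)   # resources per consumer, self ignored
  n_con <- rowSums(m_noself)   # consumers per resource, self ignored
  basal <- n_res == 0
  top <- n_res > 0 & n_con == 0
  intermediate <- n_res > 0 & n_con > 0

  herb <- vapply(seq_len(S), function(j) {
    res <- which(m_noself[, j] == 1L)
    length(res) > 0 && all(basal[res])
  }, logical(1))

  # shortest-path trophic levels: distance from each species to the nearest
  # basal species along "eats" edges (consumer -> resource)
  mean_omnivory <- NA_real_
  if (any(basal)) {
    g_down <- igraph::graph_from_adjacency_matrix(t(m_noself), mode = "directed")
    dmat <- igraph::distances(g_down, mode = "out")
    dbasal <- apply(dmat[, basal, drop = FALSE], 1, min)
    tl <- 1 + dbasal  # Inf when no path to a basal species
    omn <- vapply(seq_len(S), function(j) {
      res <- which(m_noself[, j] == 1L)
      if (!length(res)) return(NA_real_)
      levs <- tl[res]
      if (any(!is.finite(levs))) return(NA_real_)
      if (length(levs) == 1) 0 else stats::sd(levs)
    }, numeric(1))
    if (any(!is.na(omn))) mean_omnivory <- mean(omn, na.rm = TRUE)
  }

  adj_un <- (m_noself + t(m_noself)) > 0
  dimnames(adj_un) <- NULL
  g_un <- igraph::graph_from_adjacency_matrix(adj_un, mode = "undirected")
  clustering <- igraph::transitivity(g_un, type = "localaverage",
                                     isolates = "zero")
  if (is.nan(clustering)) clustering <- 0

  if (L == 0) {
    sd_gen <- 0
    sd_vul <- 0
  } else {
    norm <- L / S
    sd_gen <- stats::sd(colSums(m) / norm)
    sd_vul <- stats::sd(rowSums(m) / norm)
  }

  # mean Jaccard similarity of resource sets (columns), self-links included
  pairs <- utils::combn(S, 2)
  cross <- crossprod(m)  # cross[i, j] = |diet_i intersect diet_j|
  sizes <- colSums(m)
  jac <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    un <- sizes[i] + sizes[j] - cross[i, j]
    if (un == 0) 1 else cross[i, j] / un
  }, numeric(1))
  diet_similarity <- mean(jac)

  g_dir <- igraph::graph_from_adjacency_matrix(m_noself, mode = "directed")
  dd <- igraph::distances(g_dir, mode = "out")
  diag(dd) <- Inf
  reach <- is.finite(dd)
  mean_path_length <- if (any(reach)) mean(dd[reach]) else NA_real_

  nestedness <- NA_real_
  if (L > 0) {
    nodf <- vegan::nestednodf(m)
    nestedness <- unname(nodf$statistic["NODF"])
  }

  structure(c(
    prop_basal = mean(basal),
    prop_intermediate = mean(intermediate),
    prop_top = mean(top),
    prop_herbivores = mean(herb),
    mean_omnivory = mean_omnivory,
    clustering_coefficient = clustering,
    sd_generality = sd_gen,
    sd_vulnerability = sd_vul,
    diet_similarity = diet_similarity,
    mean_path_length = mean_path_length,
    nestedness = nestedness
  ), class = "property_set")
}

#' @export
print.property_set <- function(x, ...) {
  df <- data.frame(property = names(unclass(x)), value = as.numeric(x))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Standardized property errors of predicted webs
#'
#' For each structural property, the raw error of a predicted web is the
#' absolute difference between the observed and predicted value; the
#' standardized error divides it by the maximum raw error for that property
#' across the set of predicted webs, giving values in \[0, 1\] with the worst
#' web at 1. Properties undefined in the observation are dropped entirely;
#' a property undefined for a particular predicted web is excluded pairwise
#' (that cell is `NA` and does not enter that web's mean). If every raw error
#' for a property is zero, its standardized errors are all 0.
#'
#' @param observed_props a `property_set` for the observed web.
#' @param predicted_props a list of `property_set`s (or a matrix with
#'   properties in columns), one per predicted web.
#' @return An object of class `property_error_table`: list with matrices
#'   `raw` and `standardized` (webs x properties), `mean_by_web` (mean
#'   standardized error per predicted web), and `dropped_properties`.
#' @export
standardized_errors <- function(observed_props, predicted_props) {
  obs <- unclass(observed_props)
  if (is.list(predicted_props)) {
    P <- do.call(rbind, lapply(predicted_props, unclass))
  } else {
    P <- as.matrix(predicted_props)
  }
  if (!nrow(P)) stop("need at least one predicted property set")
  if (!all(names(obs) %in% colnames(P))) {
    stop("predicted property sets lack some observed properties")
  }
  P <- P[, names(obs), drop = FALSE]
  keep <- !is.na(obs)
  dropped <- names(obs)[!keep]
  raw <- abs(sweep(P[, keep, drop = FALSE], 2, obs[keep], `-`))
  std <- raw
  for (p in seq_len(ncol(raw))) {
    mx <- suppressWarnings(max(raw[, p], na.rm = TRUE))
    if (!is.finite(mx)) {            # all predictions undefined
      std[, p] <- NA_real_
    } else if (mx == 0) {
      std[!is.na(raw[, p]), p] <- 0
    } else {
      std[, p] <- raw[, p] / mx
    }
  }
  mean_by_web <- rowMeans(std, na.rm = TRUE)
  structure(list(raw = raw, standardized = std, mean_by_web = mean_by_web,
                 dropped_properties = dropped),
            class = "property_error_table")
}

#' @export
print.property_error_table <- function(x, ...) {
  cat(sprintf("Standardized property errors for %d predicted web(s), %d properties\n",
              nrow(x$standardized), ncol(x$standardized)))
  if (length(x$dropped_properties)) {
    cat("  dropped (undefined in observation):",
        paste(x$dropped_properties, collapse = ", "), "\n")
  }
  cat(sprintf("  mean standardized error: %.4f (range [%.4f, %.4f])\n",
              mean(x$mean_by_web), min(x$mean_by_web), max(x$mean_by_web)))
  invisible(x)
}
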