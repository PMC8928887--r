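# Delimited-text IO. Separator auto-detected from the file extension:
# ".csv" is comma-separated, anything else tab-separated. Output is UTF-8
# with Unix newlines.

io_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_table <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = io_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#", quote = "\"", ...)
}

write_delim_table <- function(x, path, row.names = FALSE) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(x, con, sep = io_sep(path), row.names = row.names,
                     col.names = if (row.names) NA else TRUE,
                     quote = FALSE, eol = "\n")
}

#' Read a community table
#'
#' Reads a delimited text file (comma-separated for `.csv`, otherwise
#' tab-separated) with header columns `node_id` and `body_mass` into a
#' mass-sorted [community()]. Masses spanning many orders of magnitude
#' (e.g. 1e-8 to 1e6 g) are preserved exactly as parsed.
#'
#' @param path file path.
#' @param mass_unit unit of the `body_mass` column; masses are converted to
#'   grams on input.
#' @return An `adbm_community`.
#' @export
read_community <- function(path, mass_unit = c("g", "mg", "kg")) {
  mass_unit <- match.arg(mass_unit)
  tab <- read_delim_table(path)
  need <- c("node_id", "body_mass")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("community file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  masses <- suppressWarnings(as.numeric(tab$body_mass))
  bad <- which(!is.finite(masses) | masses <= 0)
  if (length(bad)) {
    stop("non-positive or unparseable body_mass at row(s) ",
         paste(bad, collapse = ", "), " (node ",
         paste(tab$node_id[bad], collapse = ", "), ")")
  }
  scale <- c(g = 1, mg = 1e-3, kg = 1e3)[[mass_unit]]
  community(tab$node_id, masses * scale)
}

#' Write a community table
#'
#' Writes `node_id`/`body_mass` columns (grams) in the order the nodes were
#' originally supplied, so a read/write cycle round-trips the file layout.
#'
#' @param com an `adbm_community`.
#' @param path output path; `.csv` writes comma-separated, otherwise tabs.
#' @export
write_community <- function(com, path) {
  stopifnot(inherits(com, "adbm_community"))
  orig <- attr(com, "input_order")
  if (is.null(orig)) orig <- com$node_ids
  idx <- match(orig, com$node_ids)
  write_delim_table(
    data.frame(node_id = com$node_ids[idx], body_mass = com$masses[idx]),
    path
  )
}

#' Read an observed or predicted web
#'
#' Two dialects are supported. `matrix`: a square table with node labels on
#' the first row and first column and binary cells. `edgelist`: two columns
#' `resource` and `consumer`, one row per trophic link. Either way the result
#' is aligned to the community's canonical mass-sorted order, so file order
#' never matters.
#'
#' @param path file path (separator from extension, as in [read_community()]).
#' @param community the `adbm_community` the web is defined over.
#' @param dialect `"matrix"` or `"edgelist"`.
#' @return A `predation_matrix`.
#' @export
read_web <- function(path, community, dialect = c("matrix", "edgelist")) {
  dialect <- match.arg(dialect)
  ids <- community$node_ids
  if (dialect == "matrix") {
    tab <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                             check.names = FALSE, comment.char = "#",
                             row.names = 1)
    m <- as.matrix(tab)
    if (!setequal(rownames(m), colnames(m))) {
      stop("matrix web file ", path, " has asymmetric row/column label sets")
    }
    unknown <- setdiff(rownames(m), ids)
    if (length(unknown)) {
      stop("web file labels not in community: ", paste(unknown, collapse = ", "))
    }
    if (!setequal(rownames(m), ids)) {
      stop("web file is missing community node(s): ",
           paste(setdiff(ids, rownames(m)), collapse = ", "))
    }
    if (!all(m %in% c(0, 1))) {
      stop("non-binary cell(s) in web file ", path)
    }
    predation_matrix(community, m[ids, ids, drop = FALSE])
  } else {
    tab <- read_delim_table(path)
    need <- c("resource", "consumer")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop("edge list ", path, " is missing column(s): ",
           paste(miss, collapse = ", "))
    }
    labs <- c(as.character(tab$resource), as.character(tab$consumer))
    unknown <- setdiff(labs, ids)
    if (length(unknown)) {
      stop("edge list names unknown node(s): ", paste(unknown, collapse = ", "))
    }
    links <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    if (nrow(tab)) {
      links[cbind(as.character(tab$resource), as.character(tab$consumer))] <- 1L
    }
    predation_matrix(community, links)
  }
}

#' Write a web to delimited text
#'
#' Round-trips exactly through [read_web()] with the matching dialect.
#'
#' @param web a `predation_matrix`.
#' @param path output path.
#' @param dialect `"matrix"` (labelled binary table) or `"edgelist"`
#'   (`resource`, `consumer` columns, one row per link).
#' @export
write_web <- function(web, path, dialect = c("matrix", "edgelist")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(web, "predation_matrix"))
  if (dialect == "matrix") {
    m <- web$links
    dimnames(m) <- list(web$community$node_ids, web$community$node_ids)
    write_delim_table(as.data.frame(m, check.names = FALSE), path,
                      row.names = TRUE)
  } else {
    idx <- which(web$links == 1L, arr.ind = TRUE)
    ids <- web$community$node_ids
    write_delim_table(
      data.frame(resource = ids[idx[, 1]], consumer = ids[idx[, 2]]),
      path
    )
  }
}

#' Write / read a link-frequency matrix
#'
#' The file is a labelled count matrix preceded by a `# n_webs: <K>` comment
#' line carrying the number of aggregated webs.
#'
#' @param lf a `link_frequency`.
#' @param path file path.
#' @export
write_link_frequency <- function(lf, path) {
  stopifnot(inherits(lf, "link_frequency"))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# n_webs: ", lf$n_webs), con, sep = "\n")
  m <- lf$counts
  dimnames(m) <- list(lf$community$node_ids, lf$community$node_ids)
  utils::write.table(as.data.frame(m, check.names = FALSE), con,
                     sep = io_sep(path), row.names = TRUE, col.names = NA,
                     quote = FALSE, eol = "\n")
}

#' @rdname write_link_frequency
#' @param community the `adbm_community` the frequencies are defined over.
#' @export
read_link_frequency <- function(path, community) {
  first <- readLines(path, n = 1L)
  n_webs <- as.integer(sub("^#\\s*n_webs:\\s*", "", first))
  if (is.na(n_webs)) {
    stop("link-frequency file ", path, " lacks the '# n_webs:' header line")
  }
  tab <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                           check.names = FALSE, comment.char = "#",
                           row.names = 1)
  m <- as.matrix(tab)
  ids <- community$node_ids
  if (!setequal(rownames(m), ids) || !setequal(colnames(m), ids)) {
    stop("link-frequency labels do not match community")
  }
  link_frequency(community, m[ids, ids, drop = FALSE], n_webs)
}
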