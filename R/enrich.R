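# Hypergeometric metabolite-set over-representation and degree-based
# filtering of a metabolite interaction network.

#' Construct a pathway library
#'
#' @param pathways named list: `pathway_id -> list(name = display name,
#'   members = character vector of metabolite ids)`
#' @param source free-text provenance tag
#' @return an object of class `pathway_library`
#' @export
pathway_library <- function(pathways, source = "custom") {
  stop_if_not(length(pathways) > 0L, "empty pathway library")
  for (id in names(pathways)) {
    stop_if_not(length(pathways[[id]]$members) > 0L, "empty pathway: %s", id)
  }
  universe <- sort(unique(unlist(lapply(pathways, `[[`, "members"))))
  structure(list(pathways = pathways, universe = universe, source = source),
            class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("Pathway library (%s): %d pathways, %d metabolites in universe\n",
              x$source, length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Read a pathway library from a GMT-like file
#'
#' Tab-separated lines: `pathway_id <TAB> name <TAB> member1 <TAB> member2 ...`
#'
#' @param path input file
#' @param source provenance tag (defaults to the file stem)
#' @return a [pathway_library()]
#' @export
read_pathway_library <- function(path, source = NULL) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  pw <- list()
  for (l in lines) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    stop_if_not(length(parts) >= 3L, "malformed GMT line: %s", l)
    pw[[parts[1L]]] <- list(name = parts[2L], members = unique(parts[-(1:2)]))
  }
  pathway_library(pw, source)
}

#' Load a bundled pathway mini-library
#'
#' Curated static subsets of KEGG-style and SMPDB-style pathway memberships
#' restricted to commonly assayed urinary metabolites; shipped with the
#' package so enrichment needs no network access.
#'
#' @param source `"kegg"` or `"smpdb"`
#' @return a [pathway_library()]
#' @export
load_pathway_library <- function(source = c("kegg", "smpdb")) {
  source <- match.arg(source)
  path <- system.file("extdata", paste0(source, "_mini.gmt"),
                      package = "nmrbiomark", mustWork = TRUE)
  read_pathway_library(path, source)
}

#' Hypergeometric over-representation of a metabolite set
#'
#' For every pathway with at least `min_hits` query members, computes the
#' upper-tail (at-least-k) hypergeometric probability of drawing `k` of the
#' pathway's `K` members in a size-`n` query from the size-`N` universe.
#' Pathways below `min_hits` are excluded both from testing and from the
#' multiple-testing family; Bonferroni adjustment runs across the tested
#' pathways. Query members absent from the universe are reported and dropped
#' from `n`.
#'
#' @param query character vector of metabolite ids
#' @param lib a [pathway_library()]
#' @param min_hits minimum overlap for a pathway to be tested (default 2)
#' @return an object of class `enrichment_result`: a data.frame (`pathway_id`,
#'   `name`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, `hits`) sorted by `p_raw`,
#'   with unmapped query members in attribute `"unmapped"`
#' @export
enrich_hypergeometric <- function(query, lib, min_hits = 2) {
  stop_if_not(inherits(lib, "pathway_library"), "lib must be a pathway_library")
  query <- unique(query)
  mapped <- intersect(query, lib$universe)
  unmapped <- setdiff(query, lib$universe)
  stop_if_not(length(mapped) > 0L, "no query metabolite maps to the library universe")
  N <- length(lib$universe)
  n <- length(mapped)
  rows <- lapply(names(lib$pathways), function(id) {
    members <- lib$pathways[[id]]$members
    hits <- intersect(mapped, members)
    k <- length(hits)
    if (k < min_hits) return(NULL)
    K <- length(members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, name = lib$pathways[[id]]$name,
               k = k, K = K, n = n, N = N, p_raw = p,
               hits = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pathway_id = character(), name = character(), k = integer(),
               K = integer(), n = integer(), N = integer(),
               p_raw = numeric(), hits = character(), stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    out$p_adj <- adjust_bonferroni(out$p_raw)
    out <- out[order(out$p_raw), , drop = FALSE]
    rownames(out) <- NULL
    out <- out[, c("pathway_id", "name", "k", "K", "n", "N",
                   "p_raw", "p_adj", "hits")]
  } else {
    out$p_adj <- numeric()
  }
  attr(out, "unmapped") <- unmapped
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Construct a metabolite interaction network
#'
#' @param edges data.frame with columns `a`, `b` and optionally `score`;
#'   undirected, self-loops forbidden
#' @return an object of class `interaction_network` with `nodes` and `edges`
#' @export
interaction_network <- function(edges) {
  stop_if_not(all(c("a", "b") %in% names(edges)), "edges need columns 'a' and 'b'")
  stop_if_not(!any(edges$a == edges$b), "self-loops are not allowed")
  if (is.null(edges$score)) edges$score <- 1
  key <- apply(cbind(pmin(edges$a, edges$b), pmax(edges$a, edges$b)), 1L,
               paste, collapse = "|")
  edges <- edges[!duplicated(key), , drop = FALSE]
  structure(list(nodes = sort(unique(c(edges$a, edges$b))), edges = edges),
            class = "interaction_network")
}

#' Read an interaction network from a 3-column edge list
#'
#' Tab-separated `node_a <TAB> node_b <TAB> score` with an optional header.
#'
#' @param path input file
#' @return an [interaction_network()]
#' @export
read_interaction_network <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  names(df)[1:2] <- c("a", "b")
  if (ncol(df) >= 3L) names(df)[3L] <- "score"
  interaction_network(df)
}

#' Load the bundled synthetic interaction network
#'
#' A small synthetic stand-in for a chemical-interaction database extract,
#' covering the assayed urinary metabolites and their common neighbours.
#'
#' @return an [interaction_network()]
#' @export
load_interaction_network <- function() {
  read_interaction_network(system.file("extdata",
                                       "interactions_synthetic.tsv",
                                       package = "nmrbiomark",
                                       mustWork = TRUE))
}

#' Filter a network by node degree
#'
#' Keeps nodes whose degree in the input network is strictly greater than
#' `cutoff`, plus every protected query node regardless of degree, then keeps
#' the edges with both endpoints retained.
#'
#' @param net an [interaction_network()]
#' @param cutoff degree cutoff (strict; default 2)
#' @param protect node ids kept regardless of degree
#' @return the filtered [interaction_network()] (possibly empty)
#' @export
filter_network_by_degree <- function(net, cutoff = 2, protect = character()) {
  stop_if_not(inherits(net, "interaction_network"),
              "net must be an interaction_network")
  deg <- table(factor(c(net$edges$a, net$edges$b), levels = net$nodes))
  keep <- net$nodes[deg > cutoff | net$nodes %in% protect]
  edges <- net$edges[net$edges$a %in% keep & net$edges$b %in% keep, ,
                     drop = FALSE]
  structure(list(nodes = keep, edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
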