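# Interactome construction, hop-neighbourhood decomposition around a seed
# protein (e.g. beta1 integrin), and residue composition stratified by hop
# distance.

#' Build an annotated interaction graph
#'
#' Merges one or two undirected edge lists into a simple graph over
#' accessions and attaches per-node annotation: whether the protein was
#' detected, its phosphosite count, and its adhesome category. By default
#' the graph is restricted to detected proteins before any distance
#' computation, since neighbourhood summaries refer to identified proteins;
#' set `restrict = "full"` to keep the complete interactome.
#'
#' @param edges edge tibble (`from`, `to`)
#' @param extra_edges optional second edge tibble merged by union
#' @param detected character vector of detected accessions (`NULL` = all)
#' @param sites optional site tibble used to attach phosphosite counts
#' @param annotation optional adhesome tibble for node categories
#' @param restrict `"detected"` (default) or `"full"`
#' @return an [igraph::igraph] with node attributes `detected`, `n_sites`,
#'   `category`
#' @export
build_graph <- function(edges, extra_edges = NULL, detected = NULL,
                        sites = NULL, annotation = NULL,
                        restrict = c("detected", "full")) {
  restrict <- match.arg(restrict)
  all_edges <- clean_edges(dplyr::bind_rows(
    tibble::as_tibble(edges),
    if (!is.null(extra_edges)) tibble::as_tibble(extra_edges)
  ))
  g <- igraph::graph_from_data_frame(all_edges, directed = FALSE)
  g <- igraph::simplify(g)

  det <- if (is.null(detected)) igraph::V(g)$name else detected
  if (restrict == "detected" && !is.null(detected)) {
    g <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, detected))
  }
  nodes <- igraph::V(g)$name
  igraph::V(g)$detected <- nodes %in% det

  n_sites <- rep(0L, length(nodes))
  if (!is.null(sites)) {
    tab <- dplyr::count(tibble::as_tibble(sites), .data$accession)
    n_sites <- tab$n[match(nodes, tab$accession)]
    n_sites[is.na(n_sites)] <- 0L
  }
  igraph::V(g)$n_sites <- n_sites

  category <- rep("other", length(nodes))
  if (!is.null(annotation)) {
    ann <- tibble::as_tibble(annotation)
    hit <- match(nodes, ann$accession)
    category <- ifelse(is.na(hit), "other", ann$category[hit])
  }
  igraph::V(g)$category <- category
  g
}

#' Hop decomposition of a graph around a seed protein
#'
#' Breadth-first geodesic distance from the seed to every node. Unreachable
#' nodes get `hop = Inf` and are reported in a separate bucket, never
#' silently dropped.
#'
#' @param graph an igraph (from [build_graph()])
#' @param seed accession of the seed node
#' @return a `hop_decomposition` tibble (`accession`, `hop`) with the seed
#'   stored as an attribute
#' @export
hop_distances <- function(graph, seed) {
  if (!seed %in% igraph::V(graph)$name) {
    abort(paste0("Seed node '", seed, "' is not in the graph."))
  }
  d <- igraph::distances(graph, v = seed, weights = NA)[1, ]
  out <- tibble(accession = names(d), hop = unname(d))
  structure(out, class = c("hop_decomposition", class(tibble())), seed = seed)
}

#' Nodes within k hops of the seed (seed excluded)
#' @param decomp a `hop_decomposition`
#' @param k maximum hop distance
#' @return character vector of accessions with `0 < hop <= k`
#' @export
neighbourhood <- function(decomp, k) {
  decomp$accession[decomp$hop <= k & decomp$hop > 0]
}

#' @export
tidy.hop_decomposition <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "hop_decomposition")
  out
}

#' @export
glance.hop_decomposition <- function(x, ...) {
  tibble(
    seed = attr(x, "seed"),
    n_nodes = nrow(x) - 1L,
    n_hop1 = sum(x$hop == 1),
    n_hop2 = sum(x$hop == 2),
    n_within2 = sum(x$hop >= 1 & x$hop <= 2),
    n_unreachable = sum(is.infinite(x$hop))
  )
}

#' Residue composition stratified by hop distance
#'
#' For each k in 1..`max_hop`, the phospho-residue composition over sites on
#' proteins within k hops of the seed (cumulative bands, matching "within
#' one interaction / two interactions" summaries); exact-hop bands are also
#' emitted for diagnostics. The seed protein itself is never counted.
#'
#' @param decomp a `hop_decomposition`
#' @param sites site tibble with `accession` and `residue`
#' @param max_hop largest hop band (default 3)
#' @return tibble with one row per (band type, hop): site/protein counts and
#'   residue counts and percentages
#' @export
hop_composition <- function(decomp, sites, max_hop = 3) {
  sites <- tibble::as_tibble(sites)
  one_band <- function(acc, band, k) {
    comp <- residue_composition(sites, subset = acc)
    wide <- setNames(as.list(comp$n), paste0("n", comp$residue))
    pcts <- setNames(as.list(comp$pct), paste0("p", comp$residue))
    tibble(band = band, hop = k,
           n_proteins = length(acc),
           n_sites = attr(comp, "total"), !!!wide, !!!pcts)
  }
  purrr::map_dfr(seq_len(max_hop), function(k) {
    dplyr::bind_rows(
      one_band(neighbourhood(decomp, k), "cumulative", k),
      one_band(decomp$accession[decomp$hop == k], "exact", k)
    )
  })
}

#' Export an annotated graph to GraphML or SIF
#'
#' GraphML serializes all node attributes (hop distance included when a
#' decomposition is supplied) and re-imports losslessly via
#' [igraph::read_graph()]. SIF writes one `A pp B` line per edge.
#'
#' @param graph an igraph
#' @param path output path
#' @param format `"graphml"` or `"sif"`
#' @param decomp optional `hop_decomposition` whose distances are attached
#'   as a `hop` node attribute (-1 encodes unreachable)
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif"),
                         decomp = NULL) {
  format <- match.arg(format)
  if (!is.null(decomp)) {
    h <- decomp$hop[match(igraph::V(graph)$name, decomp$accession)]
    h[is.na(h) | is.infinite(h)] <- -1
    igraph::V(graph)$hop <- h
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    readr::write_lines(paste(el[, 1], "pp", el[, 2], sep = "\t"), path)
  }
  invisible(path)
}
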