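#' Build a per-bird syllable-transition network
#'
#' The bird's songs are concatenated in temporal order into one token string
#' and every adjacent ordered pair of syllable types contributes one count to
#' a directed edge. By default the breaks between songs are ignored, so pairs
#' straddling a song boundary are counted too (this avoids small disconnected
#' networks); set `respect_song_breaks = TRUE` to count only within-song
#' transitions, for sensitivity analysis. Self-transitions (trills) are kept
#' as directed self-loop counts for visualization; the metric calculations
#' use the undirected simple view with self-loops removed and direction
#' collapsed.
#'
#' @param songs List of song strings as returned by [song_strings()].
#' @param respect_song_breaks Count transitions across song boundaries?
#'   Default `FALSE` (boundaries ignored).
#' @return An object of class `syllable_network`: a list with `nodes`
#'   (character vector), `edges` (`data.frame` `from,to,count` of directed
#'   transitions), `node_usage` (named token counts), `graph_directed`
#'   (weighted igraph with loops), `graph_undirected` (simple undirected
#'   igraph, no loops), `n_tokens`.
#' @export
build_network <- function(songs, respect_song_breaks = FALSE) {
  .check_songs(songs)
  tok_by_song <- lapply(songs, `[[`, "tokens")
  all_tokens <- unlist(tok_by_song, use.names = FALSE)
  nodes <- sort(unique(all_tokens))
  if (respect_song_breaks) {
    pairs <- do.call(rbind, lapply(tok_by_song, function(tk) {
      if (length(tk) < 2L) return(NULL)
      cbind(tk[-length(tk)], tk[-1L])
    }))
  } else {
    tk <- all_tokens
    pairs <- if (length(tk) < 2L) NULL else cbind(tk[-length(tk)], tk[-1L])
  }
  if (is.null(pairs)) {
    edges <- data.frame(from = character(0), to = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(pairs[, 1L], pairs[, 2L], sep = "\x1f")
    cnt <- table(key)
    sp <- strsplit(names(cnt), "\x1f", fixed = TRUE)
    edges <- data.frame(from = vapply(sp, `[[`, character(1), 1L),
                        to = vapply(sp, `[[`, character(1), 2L),
                        count = as.integer(cnt), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  usage <- table(factor(all_tokens, levels = nodes))
  g_dir <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = data.frame(name = nodes))
  igraph::E(g_dir)$weight <- edges$count
  g_und <- igraph::simplify(igraph::as_undirected(g_dir, mode = "collapse"),
                            remove.loops = TRUE, remove.multiple = TRUE)
  # metrics are defined on edge presence, not transition counts
  if ("weight" %in% igraph::edge_attr_names(g_und))
    g_und <- igraph::delete_edge_attr(g_und, "weight")
  structure(list(nodes = nodes, edges = edges,
                 node_usage = stats::setNames(as.integer(usage), names(usage)),
                 graph_directed = g_dir, graph_undirected = g_und,
                 n_tokens = length(all_tokens)),
            class = "syllable_network")
}

#' @export
print.syllable_network <- function(x, ...) {
  cat(sprintf("<syllable_network> %d syllable types, %d directed transitions (%d tokens), %d undirected edges\n",
              length(x$nodes), nrow(x$edges), x$n_tokens,
              igraph::ecount(x$graph_undirected)))
  invisible(x)
}

#' Average minimum path length of a syllable network
#'
#' Mean breadth-first shortest-path length (in edges) over all unordered node
#' pairs of the undirected simple view, ignoring dead ends: pairs that are
#' not mutually reachable are omitted from both numerator and denominator.
#' Higher values indicate more fixed, linear syllable sequencing.
#'
#' @param net A [build_network()] result.
#' @return Mean path length, or `NA` if no pair of nodes is reachable.
#' @export
average_path_length <- function(net) {
  stopifnot(inherits(net, "syllable_network"))
  g <- net$graph_undirected
  if (igraph::vcount(g) < 2L || igraph::ecount(g) == 0L) return(NA_real_)
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(apl)) NA_real_ else apl
}

#' Density of a syllable network
#'
#' Observed undirected simple edges divided by the `n(n-1)/2` possible
#' transitions between distinct syllable types. Self-loops (trill
#' repetitions) are excluded from both numerator and denominator. Higher
#' values indicate more flexible syllable sequencing.
#'
#' @param net A [build_network()] result.
#' @return Density in `[0, 1]`, or `NA` when the network has fewer than two
#'   nodes.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "syllable_network"))
  n <- length(net$nodes)
  if (n < 2L) return(NA_real_)
  igraph::ecount(net$graph_undirected) / (n * (n - 1) / 2)
}

#' Network metrics with small-network exclusion
#'
#' Networks comprised of `small_threshold` (default 3) or fewer syllable
#' types are excluded from analysis to avoid bias from very small node
#' counts: their metrics are reported as `NA` and flagged.
#'
#' @param net A [build_network()] result.
#' @param small_threshold Maximum node count that still triggers exclusion.
#' @return One-row `data.frame` with `n_nodes`, `path_length`, `density`,
#'   `excluded`.
#' @export
network_metrics <- function(net, small_threshold = 3L) {
  stopifnot(inherits(net, "syllable_network"))
  excl <- length(net$nodes) <= small_threshold
  data.frame(n_nodes = length(net$nodes),
             path_length = if (excl) NA_real_ else average_path_length(net),
             density = if (excl) NA_real_ else network_density(net),
             excluded = excl)
}

#' Flag small networks across birds
#'
#' @param nets Named list of [build_network()] results (one per bird).
#' @param small_threshold Maximum node count that still triggers exclusion.
#' @return A list with `retained` and `excluded` (named sublists) plus an
#'   `exclusion_log` data.frame (`bird`, `n_nodes`, `excluded`).
#' @export
exclude_small <- function(nets, small_threshold = 3L) {
  n_nodes <- vapply(nets, function(nt) length(nt$nodes), integer(1))
  excl <- n_nodes <= small_threshold
  log <- data.frame(bird = if (is.null(names(nets))) as.character(seq_along(nets)) else names(nets),
                    n_nodes = n_nodes, excluded = excl, stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(retained = nets[!excl], excluded = nets[excl], exclusion_log = log)
}

#' Export a transition-network diagram and interoperable graph files
#'
#' Draws the directed weighted network with node area proportional to
#' syllable-type usage and edge darkness proportional to transition count
#' (self-loops included), and writes a GraphML file plus a `from,to,count`
#' edge-list CSV.
#'
#' @param net A [build_network()] result.
#' @param path Output image path; the device is chosen from the extension
#'   (`.svg`, `.png`, or `.pdf`).
#' @param graphml_path,edges_path Optional companion file paths; defaults
#'   replace the image extension.
#' @param seed Layout seed, so a given network always renders identically.
#' @param main Plot title.
#' @return Invisibly, the image path.
#' @export
export_diagram <- function(net, path, graphml_path = NULL, edges_path = NULL,
                           seed = 1L, main = NULL) {
  stopifnot(inherits(net, "syllable_network"))
  ext <- tolower(tools::file_ext(path))
  if (is.null(graphml_path)) graphml_path <- sub(sprintf("\\.%s$", ext), ".graphml", path)
  if (is.null(edges_path)) edges_path <- sub(sprintf("\\.%s$", ext), "_edges.csv", path)
  igraph::write_graph(net$graph_directed, graphml_path, format = "graphml")
  write.csv(net$edges, edges_path, row.names = FALSE, quote = FALSE)
  dev <- switch(ext,
                svg = function(p) grDevices::svg(p, width = 7, height = 7),
                png = function(p) grDevices::png(p, width = 700, height = 700),
                pdf = function(p) grDevices::pdf(p, width = 7, height = 7),
                stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE))
  dev(path)
  on.exit(grDevices::dev.off())
  g <- net$graph_directed
  usage <- net$node_usage[igraph::V(g)$name]
  size <- 12 * sqrt(usage / max(usage))
  w <- igraph::E(g)$weight
  shade <- grDevices::gray(1 - 0.15 - 0.85 * w / max(w))
  lay <- withr::with_seed(seed, igraph::layout_with_fr(g))
  graphics::plot(g, layout = lay, vertex.size = size + 6,
                 vertex.color = "lightsteelblue", vertex.label.color = "black",
                 edge.color = shade, edge.width = 1 + 2 * w / max(w),
                 edge.arrow.size = 0.4, edge.curved = 0.2, main = main)
  invisible(path)
}
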