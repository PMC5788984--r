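#' Build a minimum-spanning haplotype network
#'
#' Constructs the union of all minimum spanning trees of the haplotype
#' distance matrix (so equal-weight alternatives are retained, producing
#' reticulations), then expands every retained link of weight w > 1 into a
#' chain of w - 1 anonymous latent ("missing node") haplotypes so that every
#' edge spans exactly one mutation step. An optional connection limit drops
#' retained links longer than `limit` steps, possibly disconnecting clusters.
#'
#' The MST-union uses the cycle-property characterization: an edge of weight
#' w belongs to some minimum spanning tree iff its endpoints lie in different
#' connected components of the subgraph of strictly lighter edges.
#'
#' @param d Symmetric difference matrix ([pairwise_diff_matrix()]).
#' @param freqs Optional haplotype frequencies (named by the labels of `d`),
#'   or a haplotype table; defaults to frequency 1 each.
#' @param limit Optional integer step cutoff; retained links longer than this
#'   are dropped.
#' @return An object of class `hap_network`: a list with `graph` (igraph;
#'   vertex attributes `label`, `freq`, `latent`), and `links` (tibble of the
#'   retained inter-haplotype links with their original step counts).
#' @export
build_network <- function(d, freqs = NULL, limit = NULL) {
  n <- nrow(d)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("H", seq_len(n))
  if (is.data.frame(freqs) && "total" %in% names(freqs)) {
    freqs <- stats::setNames(freqs$total, freqs$label)
  }
  if (is.null(freqs)) freqs <- stats::setNames(rep(1, n), labs)
  freqs <- as.numeric(freqs[labs])
  if (!isSymmetric(unname(d))) abort("Difference matrix must be symmetric.")

  links <- msn_links(d)
  if (!is.null(limit)) links <- links[links$w <= limit, , drop = FALSE]

  # expand weight-w links into chains with w-1 latent nodes
  vertices <- tibble(name = labs, label = labs, freq = freqs, latent = FALSE)
  edges <- character(0)
  k <- 0
  if (nrow(links)) {
    for (r in seq_len(nrow(links))) {
      i <- links$from[r]; j <- links$to[r]; w <- links$w[r]
      path <- labs[i]
      if (w > 1) {
        mids <- paste0(".mv", k + seq_len(w - 1))
        k <- k + w - 1
        vertices <- dplyr::bind_rows(
          vertices, tibble(name = mids, label = NA_character_, freq = 0, latent = TRUE)
        )
        path <- c(path, mids)
      }
      path <- c(path, labs[j])
      edges <- c(edges, rbind(path[-length(path)], path[-1]))
    }
  }
  g <- igraph::graph_from_data_frame(
    d = if (length(edges)) as.data.frame(matrix(edges, ncol = 2, byrow = TRUE)) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = as.data.frame(vertices)
  )
  structure(
    list(
      graph = g,
      links = tibble(
        from = labs[links$from], to = labs[links$to], steps = links$w
      )
    ),
    class = "hap_network"
  )
}

# Retained links of the minimum-spanning network: for each weight class,
# an edge is kept iff its endpoints are in different components of the
# strictly-lighter subgraph.
msn_links <- function(d) {
  n <- nrow(d)
  if (n == 1) return(tibble(from = integer(0), to = integer(0), w = integer(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  keep_from <- integer(0); keep_to <- integer(0); keep_w <- integer(0)
  comp <- seq_len(n)  # union-find by relabel (n is small)
  for (wc in sort(unique(w))) {
    idx <- which(w == wc)
    sel <- comp[pairs[idx, 1]] != comp[pairs[idx, 2]]
    keep_from <- c(keep_from, pairs[idx[sel], 1])
    keep_to <- c(keep_to, pairs[idx[sel], 2])
    keep_w <- c(keep_w, rep(wc, sum(sel)))
    # merge components using all edges of this weight class
    for (e in idx) {
      c1 <- comp[pairs[e, 1]]; c2 <- comp[pairs[e, 2]]
      if (c1 != c2) comp[comp == c2] <- c1
    }
  }
  tibble(from = keep_from, to = keep_to, w = as.integer(keep_w))
}

#' @export
print.hap_network <- function(x, ...) {
  nh <- sum(!igraph::V(x$graph)$latent)
  nl <- sum(igraph::V(x$graph)$latent)
  cat(sprintf(
    "<hap_network> %d haplotypes, %d latent nodes, %d unit edges, %d links\n",
    nh, nl, igraph::ecount(x$graph), nrow(x$links)
  ))
  invisible(x)
}

#' Minimum mutation steps between two haplotype sets
#'
#' @param d Difference matrix.
#' @param setA,setB Disjoint non-empty sets of haplotype labels or indices.
#' @return Integer: min over a in A, b in B of `d[a, b]`.
#' @export
min_steps_between <- function(d, setA, setB) {
  if (is.character(setA)) setA <- match(setA, rownames(d))
  if (is.character(setB)) setB <- match(setB, rownames(d))
  if (anyNA(setA) || anyNA(setB)) abort("Unknown haplotype label(s).")
  if (length(setA) == 0 || length(setB) == 0) abort("Both sets must be non-empty.")
  if (length(intersect(setA, setB))) abort("Haplotype sets must be disjoint.")
  min(d[setA, setB, drop = FALSE])
}

#' Star-likeness of a network component
#'
#' The central node is the haplotype (non-latent) node of maximum degree,
#' ties broken by higher frequency then label order. The score is the
#' fraction of tip haplotype nodes (degree 1) lying exactly one mutation
#' step from the centre.
#'
#' @param net A connected [build_network()] result (or one component of it).
#' @return A list with `central` (label) and `score` in `[0, 1]`.
#' @export
star_score <- function(net) {
  g <- net$graph
  hap <- which(!igraph::V(g)$latent)
  if (length(hap) == 1) {
    return(list(central = igraph::V(g)$label[hap], score = 1))
  }
  deg <- igraph::degree(g)[hap]
  frq <- igraph::V(g)$freq[hap]
  lab <- igraph::V(g)$label[hap]
  ord <- order(-deg, -frq, lab)
  central <- hap[ord[1]]
  tips <- hap[igraph::degree(g)[hap] == 1 & hap != central]
  if (length(tips) == 0) return(list(central = igraph::V(g)$label[central], score = 0))
  dist <- igraph::distances(g, v = central, to = tips)
  list(
    central = igraph::V(g)$label[central],
    score = mean(dist == 1)
  )
}

#' Write a haplotype network to GraphML, GML or a TSV edge list
#'
#' @param net A [build_network()] result.
#' @param path Output path.
#' @param format `"graphml"`, `"gml"` or `"edges"` (TSV edge list).
#' @export
write_network <- function(net, path, format = c("graphml", "gml", "edges")) {
  format <- match.arg(format)
  g <- net$graph
  if (format == "edges") {
    el <- igraph::as_data_frame(g, what = "edges")
    readr::write_tsv(as_tibble(el), path)
  } else {
    # GraphML/GML cannot hold NA labels; blank out latent nodes
    igraph::V(g)$label <- ifelse(is.na(igraph::V(g)$label), "", igraph::V(g)$label)
    igraph::V(g)$latent <- as.integer(igraph::V(g)$latent)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Plot a haplotype network
#'
#' Haplotype nodes are drawn with area proportional to frequency; latent
#' nodes as small black points.
#'
#' @param net A [build_network()] result.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 1) {
  g <- net$graph
  xy <- with_seed_(seed, igraph::layout_with_fr(g))
  nodes <- tibble(
    x = xy[, 1], y = xy[, 2],
    label = igraph::V(g)$label,
    freq = igraph::V(g)$freq,
    latent = igraph::V(g)$latent
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  segs <- tibble(
    x = xy[el[, 1], 1], y = xy[el[, 1], 2],
    xend = xy[el[, 2], 1], yend = xy[el[, 2], 2]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes[nodes$latent, ],
      ggplot2::aes(.data$x, .data$y), size = 1, colour = "black"
    ) +
    ggplot2::geom_point(
      data = nodes[!nodes$latent, ],
      ggplot2::aes(.data$x, .data$y, size = .data$freq),
      colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_text(
      data = nodes[!nodes$latent, ],
      ggplot2::aes(.data$x, .data$y, label = .data$label), vjust = -1, size = 3
    ) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "frequency")
}
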