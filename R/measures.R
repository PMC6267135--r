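# Closeness, cohesion, removal-based betweenness, time-resolved rankings and
# geodesic baseline measures, all defined on top of the influence matrix.

# dense competition-free ranks: equal values share a rank, ranks are 1, 2, ...
.denseRank <- function(values) {
  match(values, sort(unique(values), decreasing = TRUE))
}

#' Closeness centrality from an influence matrix
#'
#' Out-closeness of node n is the row sum \eqn{C_{n,\cdot} = \sum_j C_{n,j}}
#' (including the diagonal self term, which keeps every centrality curve
#' starting from 1 at \eqn{T = 0} and keeps isolated nodes at the constant
#' value 1); in-closeness is the column sum.  Normalized values divide by N.
#'
#' @param im an [InfluenceMatrix-class], computed with diagonal 1
#' @param direction \code{"out"} (influence of n on the network, default) or
#'   \code{"in"} (influence of the network on n)
#' @return data.frame with columns \code{node}, \code{C} (un-normalized),
#'   \code{c} (normalized), \code{rank} (dense, ties share a rank), ordered
#'   by node label
#' @examples
#' net <- generateNetwork("chain", n = 3)
#' im <- influenceMatrix(net, spreadParams(poissonModel(1), 1, lMax = 2))
#' closenessCentrality(im)
#' @export
closenessCentrality <- function(im, direction = c("out", "in")) {
  direction <- match.arg(direction)
  m <- im@.Data
  C <- if (direction == "out") rowSums(m) else colSums(m)
  data.frame(node = rownames(m), C = unname(C), c = unname(C) / nrow(m),
             rank = .denseRank(unname(C)), stringsAsFactors = FALSE)
}

#' Network cohesion
#'
#' The grand mean of the influence matrix over source nodes:
#' \eqn{C = (1/N) \sum_{i,j} C_{i,j}}, i.e. the average over nodes of the
#' un-normalized closeness; the normalized version divides once more by N.
#' Cohesion is the reference denominator of the relative betweenness ratio.
#'
#' @param im an [InfluenceMatrix-class]
#' @param normalized if \code{TRUE} return \eqn{c = C / N}
#' @return a single number
#' @export
cohesion <- function(im, normalized = FALSE) {
  C <- sum(im@.Data) / nrow(im@.Data)
  if (normalized) C / nrow(im@.Data) else C
}

#' Removal-based betweenness
#'
#' For each node n the influence matrix is recomputed on the network with n
#' deleted; \eqn{B_n = (1/N) \sum_{i \ne n, j \ne n} C^{(-n)}_{i,j}} with the
#' normalization taken over the ORIGINAL node count N, so that the ratio
#' \eqn{R_n = B_n / C} against the full-network cohesion and the betweenness
#' centrality \eqn{b_n = 1 - R_n} both stay in [0, 1].  Deleting a node can
#' only remove influence (subgraph monotonicity), so high \eqn{b_n} marks
#' brokers whose removal severs much of the network's internal influence.
#'
#' @param net a [SpreadNetwork-class] with at least 2 nodes
#' @param params a [SpreadParams-class] (diagonal convention 1)
#' @param verbose log progress per removed node
#' @return data.frame with columns \code{node}, \code{B}, \code{R}, \code{b},
#'   \code{rank} (dense rank by \code{b} descending)
#' @examples
#' net <- generateNetwork("chain", n = 3)
#' betweennessCentrality(net, spreadParams(poissonModel(1), 1, lMax = 2))
#' @export
betweennessCentrality <- function(net, params, verbose = FALSE) {
  n <- numNodes(net)
  if (n < 2L) stop("betweenness needs at least 2 nodes")
  Cfull <- cohesion(influenceMatrix(net, params))
  B <- vapply(net@nodeLabels, function(lab) {
    if (verbose) message("removing node ", lab)
    sub <- .deleteNode(net, lab)
    sum(influenceMatrix(sub, params)@.Data) / n
  }, numeric(1))
  R <- B / Cfull
  b <- 1 - R
  data.frame(node = net@nodeLabels, B = unname(B), R = unname(R),
             b = unname(b), rank = .denseRank(unname(b)),
             stringsAsFactors = FALSE)
}

#' Time-resolved ranking table
#'
#' Turns per-time measure values into a long table with dense ranks per time
#' point.  Accepts either a long data.frame with columns \code{T},
#' \code{node}, \code{value}, or a named list (names = times) of data.frames
#' with columns \code{node} and a value column (\code{value}, \code{C} or
#' \code{b}).
#'
#' @param results long data.frame or named list, see above
#' @return data.frame (T, node, value, rank), ordered by T then node label;
#'   ties share a rank
#' @export
rankingsOverTime <- function(results) {
  if (is.data.frame(results)) {
    if (!all(c("T", "node", "value") %in% names(results)))
      stop("long input needs columns T, node, value")
    df <- results[c("T", "node", "value")]
  } else {
    if (!length(results) || is.null(names(results)))
      stop("need a named list of per-time results (names = time values)")
    df <- do.call(rbind, lapply(names(results), function(tt) {
      r <- results[[tt]]
      vcol <- intersect(c("value", "C", "b"), names(r))[1L]
      if (is.na(vcol)) stop("per-time results need a value column")
      data.frame(T = as.numeric(tt), node = r$node, value = r[[vcol]],
                 stringsAsFactors = FALSE)
    }))
  }
  df$node <- as.character(df$node)
  out <- do.call(rbind, lapply(split(df, df$T), function(d) {
    d <- d[order(match(d$node, .orderLabels(unique(d$node)))), , drop = FALSE]
    d$rank <- .denseRank(d$value)
    d
  }))
  rownames(out) <- NULL
  out[order(out$T), , drop = FALSE]
}

#' Geodesic baseline centrality and betweenness
#'
#' Classical shortest-path measures used as a structural baseline, computed
#' on the unweighted topology: reciprocal closeness
#' \eqn{C_C(i) = \sum_{j \ne i} g_{ij}^{-1} / (N-1)} and its gradient variant
#' \eqn{C_C^\delta} with exponent \eqn{\delta \ge 0} (unreachable pairs
#' contribute 0); shortest-path betweenness
#' \eqn{C_B(i) = \sum_{j<k} t_{jik} / t_{jk}} counting the fraction of
#' geodesics through i, and its gradient variant with the extra factor
#' \eqn{(g_{jk} - 1)^{-\delta}} (adjacent pairs, \eqn{g_{jk} = 1}, are
#' excluded from the weighted sum).
#'
#' @param net a [SpreadNetwork-class]; link weights are ignored
#' @param delta gradient parameter \eqn{\delta \ge 0}
#' @return data.frame with columns \code{node}, \code{CC}, \code{CCdelta},
#'   \code{CB}, \code{CBdelta}
#' @examples
#' geodesicBaselines(generateNetwork("chain", n = 3), delta = 1)
#' @export
geodesicBaselines <- function(net, delta = 1) {
  if (delta < 0) stop("delta must be >= 0")
  n <- numNodes(net)
  labs <- net@nodeLabels
  g <- asIgraph(net)
  d <- igraph::distances(g, weights = NA, mode = "out")
  d <- d[labs, labs, drop = FALSE]
  reach <- is.finite(d) & d > 0
  CC <- rowSums(ifelse(reach, 1 / d, 0)) / max(n - 1L, 1L)
  CCd <- rowSums(ifelse(reach, d^(-delta), 0)) / max(n - 1L, 1L)
  # geodesic counts: t_jk and, per interior node, t_jik
  tjk <- matrix(0, n, n)
  tji <- array(0, c(n, n, n))  # [j, k, i] = geodesics j->k through i
  for (j in seq_len(n)) {
    asp <- igraph::all_shortest_paths(g, from = labs[j], weights = NA)$vpaths
    for (pp in asp) {
      nodes <- match(igraph::as_ids(pp), labs)
      k <- nodes[length(nodes)]
      if (k == j) next
      tjk[j, k] <- tjk[j, k] + 1
      inner <- nodes[-c(1L, length(nodes))]
      if (length(inner)) tji[j, k, inner] <- tji[j, k, inner] + 1
    }
  }
  CB <- numeric(n); CBd <- numeric(n)
  for (j in seq_len(n - 1L)) for (k in seq((j + 1L), n)) {
    if (tjk[j, k] == 0) next
    frac <- tji[j, k, ] / tjk[j, k]
    CB <- CB + frac
    if (d[j, k] > 1) CBd <- CBd + frac * (d[j, k] - 1)^(-delta)
  }
  data.frame(node = labs, CC = unname(CC), CCdelta = unname(CCd),
             CB = unname(CB), CBdelta = unname(CBd),
             stringsAsFactors = FALSE)
}
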