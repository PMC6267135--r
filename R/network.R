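# Construction, accessors and I/O for SpreadNetwork objects.

#' Construct a SpreadNetwork from an edge table
#'
#' @param edges data.frame (or matrix) whose first two columns are source and
#'   target node labels and whose optional third column holds link weights in
#'   [0, 1] (missing weights default to 1).
#' @param nodes optional vector of additional node labels (e.g. isolated
#'   nodes that appear in no link).
#' @param activity node activity weights: a single scalar applied uniformly,
#'   or a named vector keyed by node label (unnamed nodes default to 1).
#' @param directed logical; if \code{FALSE} (default) the edge set is
#'   symmetrized, i.e. every link is mirrored with equal weight.
#' @return a [SpreadNetwork-class] object.
#' @examples
#' net <- newSpreadNetwork(data.frame(from = c(1, 2), to = c(2, 3)))
#' numNodes(net)
#' @export
newSpreadNetwork <- function(edges, nodes = NULL, activity = 1,
                             directed = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && ncol(edges) < 2L)
    stop("edge table needs at least two columns (source, target)")
  src <- as.character(edges[[1L]])
  dst <- if (nrow(edges)) as.character(edges[[2L]]) else character(0)
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, nrow(edges))
  if (anyNA(w)) stop("link weights must be numeric")
  if (nrow(edges) && (min(w) < 0 || max(w) > 1))
    stop("link weights must lie in [0, 1]")
  if (any(src == dst))
    stop("self-links are not allowed (offending node: ",
         src[src == dst][1L], ")")
  labels <- .orderLabels(unique(c(src, dst, as.character(nodes))))
  e <- data.frame(from = match(src, labels), to = match(dst, labels),
                  weight = w)
  if (!directed && nrow(e)) {
    e <- rbind(e, data.frame(from = e$to, to = e$from, weight = e$weight))
  }
  if (nrow(e)) {
    key <- paste(e$from, e$to)
    if (anyDuplicated(key)) {
      agg <- tapply(e$weight, key, function(x) diff(range(x)))
      if (any(agg > 1e-12))
        stop("conflicting weights for a duplicated link")
      e <- e[!duplicated(key), , drop = FALSE]
    }
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  }
  act <- rep(1, length(labels))
  if (length(activity) == 1L && is.null(names(activity))) {
    act[] <- as.numeric(activity)
  } else {
    if (is.null(names(activity)))
      stop("per-node activity must be a named vector")
    hit <- match(names(activity), labels)
    if (anyNA(hit))
      stop("activity given for unknown node(s): ",
           paste(names(activity)[is.na(hit)], collapse = ", "))
    act[hit] <- as.numeric(activity)
  }
  new("SpreadNetwork", nodeLabels = labels, nodeActivity = act,
      edges = e, directed = directed)
}

#' @describeIn newSpreadNetwork number of nodes
#' @param x a \code{SpreadNetwork}
#' @export
setMethod("numNodes", "SpreadNetwork", function(x) length(x@nodeLabels))

#' @describeIn newSpreadNetwork external node labels in internal order
#' @export
setMethod("nodeLabels", "SpreadNetwork", function(x) x@nodeLabels)

#' @describeIn newSpreadNetwork node activity weights (named by label)
#' @export
setMethod("nodeActivity", "SpreadNetwork",
          function(x) setNames(x@nodeActivity, x@nodeLabels))

#' @describeIn newSpreadNetwork set node activities; a bare scalar is applied
#'   to every node, a named vector updates the named nodes only
#' @param value replacement activity value(s)
#' @export
setMethod("nodeActivity<-", "SpreadNetwork", function(x, value) {
  if (is.null(names(value))) {
    if (length(value) == 1L) {
      x@nodeActivity[] <- as.numeric(value)
    } else if (length(value) == numNodes(x)) {
      x@nodeActivity <- as.numeric(value)
    } else stop("activity must be a scalar, a full vector, or named")
  } else {
    hit <- match(names(value), x@nodeLabels)
    if (anyNA(hit)) stop("unknown node(s): ",
                         paste(names(value)[is.na(hit)], collapse = ", "))
    x@nodeActivity[hit] <- as.numeric(value)
  }
  validObject(x)
  x
})

#' @describeIn newSpreadNetwork directed links as a data.frame of external
#'   labels (columns \code{from}, \code{to}, \code{weight})
#' @export
setMethod("linkTable", "SpreadNetwork", function(x) {
  data.frame(from = x@nodeLabels[x@edges$from],
             to = x@nodeLabels[x@edges$to],
             weight = x@edges$weight,
             stringsAsFactors = FALSE)
})

#' @describeIn newSpreadNetwork whether the network is directed
#' @export
setMethod("isDirected", "SpreadNetwork", function(x) x@directed)

setMethod("show", "SpreadNetwork", function(object) {
  e <- object@edges
  cat("SpreadNetwork with", numNodes(object), "nodes and",
      if (object@directed) nrow(e) else nrow(e) / 2L,
      if (object@directed) "directed links\n" else "undirected links\n")
  act <- unique(object@nodeActivity)
  if (length(act) == 1L) cat("  uniform node activity w_N =", act, "\n")
  else cat("  node activities in [", min(act), ",", max(act), "]\n")
})

#' Convert a SpreadNetwork to an igraph graph
#'
#' Edge weights are carried over as the \code{weight} edge attribute and node
#' activities as the \code{activity} vertex attribute.  Undirected networks
#' yield an undirected igraph with one edge per unordered pair.
#'
#' @param x a [SpreadNetwork-class]
#' @param ... unused
#' @return an \code{igraph} object
#' @export
setMethod("asIgraph", "SpreadNetwork", function(x, ...) {
  e <- x@edges
  if (!x@directed) e <- e[e$from < e$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = x@nodeLabels[e$from], to = x@nodeLabels[e$to],
               weight = e$weight),
    directed = x@directed,
    vertices = data.frame(name = x@nodeLabels, activity = x@nodeActivity))
  g
})

# ---------------------------------------------------------------------------
# internal helpers

.labelToIndex <- function(net, labels) {
  idx <- match(as.character(labels), net@nodeLabels)
  if (anyNA(idx))
    stop("unknown node(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

# adjacency list on internal indices, neighbors in ascending index order
.adjList <- function(net) {
  n <- numNodes(net)
  adj <- rep(list(integer(0)), n)
  e <- net@edges
  if (nrow(e)) {
    sp <- split(e$to, factor(e$from, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(v))
  }
  adj
}

# dense link-weight matrix (0 where there is no link)
.weightMatrix <- function(net) {
  n <- numNodes(net)
  W <- matrix(0, n, n)
  e <- net@edges
  if (nrow(e)) W[cbind(e$from, e$to)] <- e$weight
  W
}

.isolatedNodes <- function(net) {
  n <- numNodes(net)
  touched <- unique(c(net@edges$from, net@edges$to))
  net@nodeLabels[setdiff(seq_len(n), touched)]
}

# remove one node (by label) keeping everything else intact
.deleteNode <- function(net, label) {
  idx <- .labelToIndex(net, label)
  keep <- setdiff(seq_len(numNodes(net)), idx)
  e <- net@edges
  e <- e[e$from != idx & e$to != idx, , drop = FALSE]
  remap <- match(seq_len(numNodes(net)), keep)
  e$from <- remap[e$from]
  e$to <- remap[e$to]
  new("SpreadNetwork",
      nodeLabels = net@nodeLabels[keep],
      nodeActivity = net@nodeActivity[keep],
      edges = e, directed = net@directed)
}

# ---------------------------------------------------------------------------
# file I/O

#' Read a network from an edge-list file
#'
#' Expects two label columns \code{source, target} and an optional numeric
#' weight column.  Lines are validated individually so malformed input is
#' reported with its line number.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator; by default \code{"\t"} for \code{.tsv}
#'   files and \code{","} otherwise.
#' @param header logical; does the first line hold column names?
#' @param weightColumn index of the link-weight column, or \code{NA} to
#'   default all weights to 1 (a third column, if present, is used when
#'   \code{weightColumn} is missing).
#' @param directed logical; undirected input is symmetrized.
#' @param ... passed to [newSpreadNetwork()] (e.g. \code{activity},
#'   \code{nodes}).
#' @return a [SpreadNetwork-class]
#' @export
readEdgeList <- function(path, delimiter = NULL, header = FALSE,
                         weightColumn = NULL, directed = FALSE, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- if (header) 2L else 1L
  if (length(lines) < start) stop("no data rows in ", path)
  rows <- strsplit(lines[seq(start, length(lines))], delimiter, fixed = TRUE)
  nf <- lengths(rows)
  if (any(nf < 2L))
    stop("malformed row at line ",
         which(nf < 2L)[1L] + start - 1L, " of ", path,
         " (need at least 2 fields)")
  src <- trimws(vapply(rows, `[[`, "", 1L))
  dst <- trimws(vapply(rows, `[[`, "", 2L))
  wcol <- if (is.null(weightColumn)) {
    if (all(nf >= 3L)) 3L else NA_integer_
  } else as.integer(weightColumn)
  if (!is.na(wcol)) {
    bad <- which(nf < wcol)
    if (length(bad))
      stop("malformed row at line ", bad[1L] + start - 1L, " of ", path,
           " (missing weight column)")
    w <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", wcol)))
    if (anyNA(w)) {
      bad <- which(is.na(w))[1L]
      stop("non-numeric weight at line ", bad + start - 1L, " of ", path)
    }
    if (min(w) < 0 || max(w) > 1) {
      bad <- which(w < 0 | w > 1)[1L]
      stop("weight outside [0, 1] at line ", bad + start - 1L, " of ", path)
    }
  } else w <- rep(1, length(src))
  bad <- which(src == dst)
  if (length(bad))
    stop("self-link at line ", bad[1L] + start - 1L, " of ", path)
  newSpreadNetwork(data.frame(from = src, to = dst, weight = w),
                   directed = directed, ...)
}

#' Write a network as an edge list
#'
#' Writes \code{source,target,weight} rows (with header).  For undirected
#' networks each unordered pair is written once.
#'
#' @param net a [SpreadNetwork-class]
#' @param path output file path
#' @param delimiter field separator (default comma)
#' @return invisibly, the path
#' @export
writeEdgeList <- function(net, path, delimiter = ",") {
  e <- net@edges
  if (!net@directed) e <- e[e$from < e$to, , drop = FALSE]
  df <- data.frame(source = net@nodeLabels[e$from],
                   target = net@nodeLabels[e$to],
                   weight = e$weight)
  write.table(df, path, sep = delimiter, row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}

#' Read a network from a GraphML file
#'
#' Thin convenience wrapper over \code{igraph::read_graph}; a \code{weight}
#' edge attribute (if present) is used for link weights.
#'
#' @param path GraphML file
#' @param ... passed to [newSpreadNetwork()]
#' @return a [SpreadNetwork-class]
#' @export
readGraphML <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  labs <- igraph::vertex_attr(g, "name")
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(g)))
  edges <- data.frame(from = el$from, to = el$to)
  if (!is.null(el$weight)) edges$weight <- el$weight
  newSpreadNetwork(edges, nodes = labs,
                   directed = igraph::is_directed(g), ...)
}

#' Read a node-activity table
#'
#' Two-column CSV \code{node,weight}; returns a named numeric vector suitable
#' for the \code{activity} argument of the constructors or for
#' \code{nodeActivity<-}.
#'
#' @param path CSV file
#' @param header logical
#' @return named numeric vector of activities
#' @export
readNodeActivity <- function(path, header = FALSE) {
  df <- read.table(path, sep = ",", header = header,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("activity table needs columns node, weight")
  w <- as.numeric(df[[2L]])
  if (anyNA(w) || min(w) < 0 || max(w) > 1)
    stop("node activities must be numeric in [0, 1]")
  setNames(w, as.character(df[[1L]]))
}

# ---------------------------------------------------------------------------
# fixture and synthetic generators

#' Worked-example subgraph between two reference nodes
#'
#' Reconstructs the 9-node, 13-edge undirected subgraph spanned by the 14
#' self-avoiding paths from node 1 to node 4 used throughout the package's
#' worked example.  All node activities and link weights are 1.
#'
#' @return a [SpreadNetwork-class] on nodes
#'   {1, 3, 4, 6, 13, 15, 20, 27, 30}
#' @examples
#' net <- workedExampleNetwork()
#' numNodes(net)  # 9
#' @export
workedExampleNetwork <- function() {
  edges <- rbind(
    c(1, 3), c(3, 15), c(15, 6), c(6, 27), c(3, 27), c(27, 4), c(27, 20),
    c(27, 30), c(20, 4), c(20, 30), c(30, 4), c(30, 13), c(13, 4))
  newSpreadNetwork(data.frame(from = edges[, 1], to = edges[, 2]),
                   directed = FALSE)
}

#' Generate synthetic test networks
#'
#' Reproducible generators for the topologies used in tests and validation:
#' simple chains, random recursive trees, connected Erdos-Renyi graphs
#' (augmented with bridging links until connected), and planted two-block
#' partition graphs.
#'
#' @param kind one of \code{"chain"}, \code{"tree"},
#'   \code{"connected_random"}, \code{"planted_partition"}.
#' @param n number of nodes (chain, tree, connected_random).
#' @param p edge probability for \code{connected_random}.
#' @param sizes integer vector of block sizes for \code{planted_partition}.
#' @param pIn,pOut within- and between-block edge probabilities.
#' @param seed integer RNG seed; the same seed yields the identical network.
#' @param activity node activity passed through to the constructor.
#' @return an undirected [SpreadNetwork-class]
#' @examples
#' generateNetwork("chain", n = 3)
#' generateNetwork("planted_partition", sizes = c(5, 5), pIn = 1, pOut = 0,
#'                 seed = 1)
#' @export
generateNetwork <- function(kind = c("chain", "tree", "connected_random",
                                     "planted_partition"),
                            n = NULL, p = NULL, sizes = NULL,
                            pIn = NULL, pOut = NULL, seed = NULL,
                            activity = 1) {
  kind <- match.arg(kind)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  edges <- switch(kind,
    chain = {
      if (is.null(n) || n < 1L) stop("chain needs n >= 1")
      if (n == 1L) data.frame(from = integer(0), to = integer(0))
      else data.frame(from = seq_len(n - 1L), to = seq_len(n - 1L) + 1L)
    },
    tree = {
      if (is.null(n) || n < 1L) stop("tree needs n >= 1")
      if (n == 1L) data.frame(from = integer(0), to = integer(0))
      else {
        parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
        data.frame(from = parent, to = 2:n)
      }
    },
    connected_random = {
      if (is.null(n) || n < 1L) stop("connected_random needs n >= 1")
      if (is.null(p) || p < 0 || p > 1)
        stop("connected_random needs edge probability p in [0, 1]")
      pairs <- if (n >= 2L) t(combn(n, 2L)) else matrix(integer(0), 0, 2)
      pick <- runif(nrow(pairs)) < p
      e <- pairs[pick, , drop = FALSE]
      # augment with bridging links between components until connected
      comp <- .componentsOf(n, e)
      pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1
      while (length(unique(comp)) > 1L) {
        cs <- unique(comp)
        a <- pick1(which(comp == cs[1L]))
        b <- pick1(which(comp != cs[1L]))
        e <- rbind(e, c(min(a, b), max(a, b)))
        comp <- .componentsOf(n, e)
      }
      data.frame(from = e[, 1], to = e[, 2])
    },
    planted_partition = {
      if (is.null(sizes) || length(sizes) != 2L || any(sizes < 1L))
        stop("planted_partition needs two block sizes >= 1")
      if (is.null(pIn) || is.null(pOut) ||
          pIn < 0 || pIn > 1 || pOut < 0 || pOut > 1)
        stop("planted_partition needs pIn and pOut in [0, 1]")
      ntot <- sum(sizes)
      block <- rep(1:2, sizes)
      pairs <- t(combn(ntot, 2L))
      prob <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], pIn, pOut)
      pick <- runif(nrow(pairs)) < prob
      e <- pairs[pick, , drop = FALSE]
      n <- ntot
      data.frame(from = e[, 1], to = e[, 2])
    })
  newSpreadNetwork(edges, nodes = seq_len(n), directed = FALSE,
                   activity = activity)
}

# connected components from an undirected edge matrix (indices 1..n)
.componentsOf <- function(n, e) {
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  if (length(e)) for (k in seq_len(nrow(e))) {
    a <- find(e[k, 1]); b <- find(e[k, 2])
    if (a != b) comp[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}
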