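# Path enumeration and the prefix trie.
#
# Enumeration runs depth-first from one source simultaneously to every other
# node, pruned at lMax links.  Neighbor expansion is in ascending internal
# index order, so the enumeration (and everything downstream) is
# deterministic.  In self-avoiding mode no node may repeat; in walk mode node
# revisits are allowed but a path to target t is recorded only on the first
# arrival at t, so t never occurs as an intermediate node of its own paths.

# internal engine on indices; returns list (length n) of lists of int vectors
.enumeratePathsIdx <- function(adj, src, lMax, walks) {
  n <- length(adj)
  res <- rep(list(list()), n)
  cnt <- integer(n)
  path <- integer(lMax + 1L)
  path[1L] <- src
  visit <- integer(n)
  visit[src] <- 1L
  rec <- function(v, depth) {
    if (depth >= lMax) return(invisible(NULL))
    for (u in adj[[v]]) {
      if (walks) {
        path[depth + 2L] <<- u
        if (visit[u] == 0L) {
          cnt[u] <<- cnt[u] + 1L
          res[[u]][[cnt[u]]] <<- path[seq_len(depth + 2L)]
        }
        visit[u] <<- visit[u] + 1L
        rec(u, depth + 1L)
        visit[u] <<- visit[u] - 1L
      } else if (visit[u] == 0L) {
        path[depth + 2L] <<- u
        cnt[u] <<- cnt[u] + 1L
        res[[u]][[cnt[u]]] <<- path[seq_len(depth + 2L)]
        visit[u] <<- 1L
        rec(u, depth + 1L)
        visit[u] <<- 0L
      }
    }
    invisible(NULL)
  }
  rec(src, 0L)
  res
}

#' Enumerate paths from a source node
#'
#' Enumerates all self-avoiding paths (default) or loop-allowing bounded
#' walks of at most \code{lMax} links from \code{source} to every other node.
#' The result is a named list, one entry per reachable target, each a list of
#' paths given as character vectors of node labels from source to target.
#'
#' @param net a [SpreadNetwork-class]
#' @param source source node label
#' @param lMax maximum path length in links (\eqn{\ge 1})
#' @param mode \code{"self_avoiding"} or \code{"walks"}; in walk mode a walk
#'   may revisit nodes but terminates on first arrival at its target
#' @return named list of lists of paths (character vectors), in deterministic
#'   depth-first order
#' @examples
#' net <- workedExampleNetwork()
#' length(enumeratePaths(net, "1", lMax = 8)[["4"]])  # 14
#' @export
enumeratePaths <- function(net, source, lMax = 6L,
                           mode = c("self_avoiding", "walks")) {
  mode <- match.arg(mode)
  if (lMax < 1L) stop("lMax must be >= 1")
  src <- .labelToIndex(net, source)
  raw <- .enumeratePathsIdx(.adjList(net), src, as.integer(lMax),
                            mode == "walks")
  labs <- net@nodeLabels
  out <- list()
  for (t in seq_along(raw)) {
    if (length(raw[[t]]))
      out[[labs[t]]] <- lapply(raw[[t]], function(p) labs[p])
  }
  out
}

# ---------------------------------------------------------------------------
# prefix trie

# A trie node is list(node=<id>, depth=<links from source>, terminal=<flag>,
# children=<list of trie nodes>).  Terminal marks a complete path; in the
# enumerations above path sets are prefix-free, so terminal nodes have no
# children, but the structure tolerates both.

.buildTrieRec <- function(paths, depth, node) {
  lens <- vapply(paths, length, integer(1))
  terminal <- any(lens == depth + 1L)
  rest <- paths[lens > depth + 1L]
  children <- list()
  if (length(rest)) {
    nxt <- vapply(rest, function(p) p[[depth + 2L]], rest[[1L]][[1L]])
    for (key in unique(nxt)) {
      children[[length(children) + 1L]] <-
        .buildTrieRec(rest[nxt == key], depth + 1L, key)
    }
  }
  list(node = node, depth = depth, terminal = terminal, children = children)
}

#' Build the prefix trie of a target's path set
#'
#' Groups a set of paths sharing one source into a rooted prefix tree: each
#' trie node is a path prefix (its depth is the prefix link count, its graph
#' node the prefix endpoint) and each complete path is a root-to-leaf walk.
#' Branching reproduces longest-common-prefix grouping, the structure on
#' which dependent-path combination runs.
#'
#' @param paths list of paths (vectors of node labels or indices) that all
#'   start with the same source node
#' @return nested-list trie with fields \code{node}, \code{depth},
#'   \code{terminal}, \code{children}; \code{NULL} for an empty path set
#' @examples
#' net <- workedExampleNetwork()
#' trie <- buildPathTrie(enumeratePaths(net, "1", lMax = 8)[["4"]])
#' length(trie$children)  # 1: every path starts with the same first link
#' @export
buildPathTrie <- function(paths) {
  if (!length(paths)) return(NULL)
  first <- vapply(paths, function(p) p[[1L]], paths[[1L]][[1L]])
  if (length(unique(first)) != 1L)
    stop("all paths must share the same source node")
  .buildTrieRec(paths, 0L, first[[1L]])
}

#' Reconstruct the path set stored in a trie
#'
#' Inverse of [buildPathTrie()]: walks the trie and returns every
#' root-to-terminal path.
#'
#' @param trie a trie from [buildPathTrie()]
#' @return list of paths (vectors of node ids)
#' @export
triePaths <- function(trie) {
  if (is.null(trie)) return(list())
  out <- list()
  walk <- function(tn, prefix) {
    prefix <- c(prefix, tn$node)
    if (tn$terminal) out[[length(out) + 1L]] <<- prefix
    for (ch in tn$children) walk(ch, prefix)
  }
  walk(trie, if (is.character(trie$node)) character(0) else integer(0))
  out
}

#' Count complete paths stored in a trie
#' @param trie a trie from [buildPathTrie()]
#' @return integer number of terminal nodes
#' @export
trieLeafCount <- function(trie) {
  if (is.null(trie)) return(0L)
  sum(vapply(trie$children, trieLeafCount, integer(1))) +
    as.integer(isTRUE(trie$terminal))
}

#' Write a path dump
#'
#' One path per line, node labels hyphen-separated (the presentation used for
#' worked-example path listings).
#'
#' @param paths list of paths (character vectors of labels)
#' @param path output file
#' @return invisibly, the output path
#' @export
writePathDump <- function(paths, path) {
  writeLines(vapply(paths, paste, "", collapse = "-"), path)
  invisible(path)
}
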