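# The combination engine: from a path trie to C_{s,t}(T), and the N x N
# influence spreading matrix.
#
# Normative recursion (bottom-up over the trie): a terminal node has
# conditional value q = 1; an internal node at depth L with endpoint m and
# children c_i reached via link m -> m_i has
#
#   q = 1 - prod_i ( 1 - w_L(m, m_i) * w_N(m_i) * stepFactor(L, T) * q(c_i) )
#
# and C_{s,t}(T) = q(root).  The root-level product combines the independent
# first links out of the source; the two-child case reproduces the pairwise
# combination rule P_a + P_b - P_a P_b / P_prefix in its conditional form,
# which stays well defined at T = 0 and for non-unit intermediate node
# weights.  Multi-way combination 1 - prod(1 - r_i) is the associative
# closure of the iterated pairwise rule.

#' Probability of influence spreading over one path
#'
#' Evaluates \eqn{C = w_{N=t} \; W_L \; D_L(T)} for a single path of length
#' \eqn{L}, where \eqn{W_L} is the product of the link weights along the path
#' and the activities of all nodes after the source (the source initiates
#' with activity 1).
#'
#' @param path node labels from source to target (length L + 1)
#' @param net a [SpreadNetwork-class]
#' @param params a [SpreadParams-class]
#' @return probability in [0, 1]
#' @examples
#' net <- workedExampleNetwork()
#' p <- spreadParams(poissonModel(1), time = 1)
#' pathProbability(c("1", "3", "27", "4"), net, p)  # D_3(1)
#' @export
pathProbability <- function(path, net, params) {
  idx <- .labelToIndex(net, path)
  L <- length(idx) - 1L
  if (L < 1L) stop("a path needs at least two nodes")
  W <- .weightMatrix(net)
  wl <- W[cbind(idx[-length(idx)], idx[-1L])]
  if (any(wl == 0))
    stop("path uses a node pair that is not a link of the network")
  prod(wl) * prod(net@nodeActivity[idx[-1L]]) *
    spreadProb(params@model, L, params@time)
}

# internal trie evaluation on indices
.evalTrie <- function(trie, W, act, model, time) {
  if (is.null(trie)) return(0)
  q <- function(tn) {
    if (isTRUE(tn$terminal)) return(1)
    if (!length(tn$children)) return(0)
    sf <- stepFactor(model, tn$depth, time)
    if (sf == 0) return(0)
    keep <- 1
    for (ch in tn$children) {
      r <- W[tn$node, ch$node] * act[ch$node] * sf * q(ch)
      keep <- keep * (1 - r)
    }
    1 - keep
  }
  q(trie)
}

#' Combine a path trie into the influence probability C_st(T)
#'
#' Bottom-up evaluation of the prefix trie of all enumerated paths from one
#' source to one target: paths sharing their initial links are coupled
#' through the shared prefix (a single conditional hop factor per trie edge),
#' while branches are combined as independent contributions.  An empty trie
#' evaluates to 0.
#'
#' @param trie a trie from [buildPathTrie()] (node ids may be labels or
#'   internal indices)
#' @param net a [SpreadNetwork-class]
#' @param params a [SpreadParams-class]
#' @return the probability \eqn{C_{s,t}(T)} in [0, 1]
#' @examples
#' net <- workedExampleNetwork()
#' p <- spreadParams(poissonModel(1), time = 1, lMax = 8)
#' trie <- buildPathTrie(enumeratePaths(net, "1", lMax = 8)[["4"]])
#' evaluateTrie(trie, net, p)
#' @export
evaluateTrie <- function(trie, net, params) {
  if (is.null(trie)) return(0)
  if (is.character(trie$node)) trie <- .trieToIdx(trie, net)
  .evalTrie(trie, .weightMatrix(net), net@nodeActivity,
            params@model, params@time)
}

.trieToIdx <- function(tn, net) {
  tn$node <- .labelToIndex(net, tn$node)
  tn$children <- lapply(tn$children, .trieToIdx, net = net)
  tn
}

#' Compute the influence spreading matrix
#'
#' For every ordered pair (s, t) of distinct nodes: enumerate paths from s,
#' build the prefix trie for t, and evaluate it.  The diagonal is set to the
#' configured self value (1 by convention; 0 under the community-detection
#' convention), and unreachable pairs evaluate to 0.
#'
#' @param net a [SpreadNetwork-class]
#' @param params a [SpreadParams-class]
#' @param verbose if \code{TRUE}, log progress per source node
#' @return an [InfluenceMatrix-class] with node labels as dimnames
#' @examples
#' net <- generateNetwork("chain", n = 3)
#' influenceMatrix(net, spreadParams(poissonModel(1), time = 1, lMax = 2))
#' @export
influenceMatrix <- function(net, params, verbose = FALSE) {
  n <- numNodes(net)
  labs <- net@nodeLabels
  adj <- .adjList(net)
  W <- .weightMatrix(net)
  act <- net@nodeActivity
  walks <- params@mode == "walks"
  M <- matrix(0, n, n, dimnames = list(labs, labs))
  for (s in seq_len(n)) {
    if (verbose) message("source ", labs[s], " (", s, "/", n, ")")
    paths <- .enumeratePathsIdx(adj, s, params@lMax, walks)
    for (t in seq_len(n)) {
      if (t == s || !length(paths[[t]])) next
      trie <- .buildTrieRec(paths[[t]], 0L, s)
      M[s, t] <- .evalTrie(trie, W, act, params@model, params@time)
    }
  }
  diag(M) <- params@selfValue
  new("InfluenceMatrix", M, params = params)
}

setMethod("show", "InfluenceMatrix", function(object) {
  n <- nrow(object@.Data)
  cat("InfluenceMatrix ", n, " x ", n, " (T = ", object@params@time,
      ", lMax = ", object@params@lMax, ", mode = ", object@params@mode,
      ")\n", sep = "")
  off <- object@.Data[row(object@.Data) != col(object@.Data)]
  if (length(off))
    cat("  off-diagonal range: [", signif(min(off), 4), ", ",
        signif(max(off), 4), "]\n", sep = "")
})

#' @describeIn influenceMatrix number of nodes
#' @param x an \code{InfluenceMatrix}
#' @export
setMethod("numNodes", "InfluenceMatrix", function(x) nrow(x@.Data))

#' @describeIn influenceMatrix node labels
#' @export
setMethod("nodeLabels", "InfluenceMatrix", function(x) rownames(x@.Data))

#' Replace the diagonal convention of an influence matrix
#'
#' Returns a copy of the matrix with every diagonal entry set to
#' \code{value} and the stored parameters updated accordingly.  Community
#' detection uses the 0 convention, closeness and betweenness the 1
#' convention.
#'
#' @param im an [InfluenceMatrix-class]
#' @param value new diagonal value in [0, 1]
#' @return an [InfluenceMatrix-class]
#' @export
setDiagonal <- function(im, value) {
  m <- im@.Data
  diag(m) <- value
  p <- im@params
  p@selfValue <- as.numeric(value)
  new("InfluenceMatrix", m, params = p)
}

#' Write an influence matrix with its metadata sidecar
#'
#' The matrix goes to \code{path} as CSV with a label header row and column;
#' the parameters (T, lambda, lMax, mode, diagonal convention) go to
#' \code{<path>.meta.json}.
#'
#' @param im an [InfluenceMatrix-class]
#' @param path output CSV path
#' @return invisibly, the CSV path
#' @export
writeInfluenceMatrix <- function(im, path) {
  df <- as.data.frame(im@.Data)
  df <- cbind(node = rownames(im@.Data), df)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  p <- im@params
  meta <- list(time = p@time, lMax = p@lMax, mode = p@mode,
               selfValue = p@selfValue, family = p@model@family,
               lambda = p@model@lambda)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
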