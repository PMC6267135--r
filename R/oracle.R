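# Independent validation oracles for the combination engine.
#
# Two routes that never share code with evaluateTrie():
#  - pairwiseReference(): the literal pairwise combination algebra
#    P_a + P_b - P_a P_b / P_prefix on absolute path probabilities, processing
#    longest common prefixes first.  Exact only when every node activity is 1
#    (the division form double-counts the junction node's activity
#    otherwise), which is why it lives here as an oracle and not in the
#    engine.
#  - simulateSpread(): a Monte-Carlo first-passage simulation of the
#    spreading process itself.  On chains and trees (a unique path per node)
#    its estimate converges to the analytic value; on graphs with re-merging
#    paths the analytic model's prefix-only dependency treatment is an
#    approximation, so deviations there are reported, never asserted.

#' Pairwise-combination reference evaluator
#'
#' Combines absolute path probabilities two at a time with
#' \eqn{P_a + P_b - P_a P_b / P_{prefix}}, deepest shared prefixes first,
#' finishing with the independent top-level combination at the source.
#' Requires all node activities to be 1 (link weights may vary); outside
#' that regime the division form is not exact and the call errors.
#'
#' @param paths list of paths (label vectors) from one source to one target
#' @param net a [SpreadNetwork-class] with unit node activities
#' @param params a [SpreadParams-class]
#' @return the combined probability
#' @examples
#' net <- workedExampleNetwork()
#' p <- spreadParams(poissonModel(1), 1, lMax = 8)
#' paths <- enumeratePaths(net, "1", lMax = 8)[["4"]]
#' pairwiseReference(paths, net, p)  # equals evaluateTrie on the same input
#' @export
pairwiseReference <- function(paths, net, params) {
  if (any(net@nodeActivity != 1))
    stop("pairwiseReference is exact only for unit node activities")
  if (!length(paths)) return(0)
  W <- .weightMatrix(net)
  model <- params@model
  time <- params@time
  idxPaths <- lapply(paths, function(p) .labelToIndex(net, p))
  trie <- .buildTrieRec(idxPaths, 0L, idxPaths[[1L]][1L])
  # absolute probability of traversing a prefix: product of link weights
  # times D_depth
  combine <- function(tn, wprefix) {
    if (isTRUE(tn$terminal))
      return(wprefix * spreadProb(model, tn$depth, time))
    if (!length(tn$children)) return(0)
    pPrefix <- wprefix * spreadProb(model, tn$depth, time)
    vals <- vapply(tn$children, function(ch) {
      combine(ch, wprefix * W[tn$node, ch$node])
    }, numeric(1))
    acc <- vals[1L]
    if (length(vals) > 1L) for (vv in vals[-1L]) {
      acc <- if (pPrefix > 0) acc + vv - acc * vv / pPrefix else 0
    }
    acc
  }
  combine(trie, 1)
}

#' Monte-Carlo simulation of the spreading process
#'
#' Event simulation of the model semantics: the source is active at time 0;
#' each activated node forwards influence over each outgoing link after an
#' exponential(\eqn{\lambda}) delay, gated by an independent
#' Bernoulli(\eqn{w_N(next) \cdot w_L}) acceptance; a node's influence time
#' is its first arrival.  Implemented as a replicate-vectorized random
#' shortest-path (Bellman-Ford) computation, so an L-hop chain's arrival
#' time is Gamma(L, \eqn{\lambda}) distributed -- the unique delay model
#' whose first-passage probability equals the Poisson-tail spreading
#' distribution.
#'
#' @param net a [SpreadNetwork-class]
#' @param source source node label
#' @param time observation time \eqn{T}
#' @param lambda forwarding intensity (> 0)
#' @param reps number of replicates (\eqn{\ge 1})
#' @param seed optional RNG seed
#' @return data.frame with columns \code{node}, \code{fraction} (share of
#'   replicates influenced by \code{time}), and \code{se}, the binomial
#'   standard error \eqn{\sqrt{p(1-p)/reps}} at the estimated fraction;
#'   the replicate count is attached as attribute \code{reps}
#' @examples
#' net <- generateNetwork("chain", n = 3)
#' simulateSpread(net, "1", time = 1, lambda = 1, reps = 1000, seed = 1)
#' @export
simulateSpread <- function(net, source, time, lambda, reps = 10000L,
                           seed = NULL) {
  if (reps < 1L) stop("reps must be >= 1")
  if (lambda <= 0) stop("lambda must be positive")
  if (!is.null(seed)) set.seed(seed)
  src <- .labelToIndex(net, source)
  n <- numNodes(net)
  e <- net@edges
  nE <- nrow(e)
  arrive <- matrix(Inf, reps, n)
  arrive[, src] <- 0
  if (nE) {
    gateP <- net@nodeActivity[e$to] * e$weight
    # per replicate per link: forwarding delay if the gate opens, else never
    eff <- matrix(rexp(reps * nE, rate = lambda), reps, nE)
    open <- matrix(runif(reps * nE), reps, nE) <=
      matrix(gateP, reps, nE, byrow = TRUE)
    eff[!open] <- Inf
    for (iter in seq_len(max(n - 1L, 1L))) {
      changed <- FALSE
      for (k in seq_len(nE)) {
        cand <- arrive[, e$from[k]] + eff[, k]
        upd <- cand < arrive[, e$to[k]]
        if (any(upd)) {
          arrive[upd, e$to[k]] <- cand[upd]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  frac <- colMeans(arrive <= time)
  out <- data.frame(node = net@nodeLabels, fraction = unname(frac),
                    se = sqrt(unname(frac) * (1 - unname(frac)) / reps),
                    stringsAsFactors = FALSE)
  attr(out, "reps") <- reps
  out
}
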