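# S4 classes for the influence spreading model.
#
# Conventions used throughout:
#  - node labels are arbitrary strings; internally nodes are mapped to a dense
#    1-based index in a deterministic order (numeric order when every label is
#    an integer literal, radix/lexicographic order otherwise);
#  - links are stored as directed rows (from, to, weight) on internal indices;
#    an undirected network stores both directions with equal weights;
#  - all node activities and link weights live in [0, 1].

.orderLabels <- function(labels) {
  if (all(grepl("^-?[0-9]+$", labels))) {
    labels[order(as.numeric(labels))]
  } else {
    labels[order(labels, method = "radix")]
  }
}

#' Network with node activities and weighted directed links
#'
#' A \code{SpreadNetwork} holds the node set, per-node activity weights
#' \eqn{w_N \in [0,1]} (the probability that a node forwards an influence
#' event), and a set of directed links with weights \eqn{w_L \in [0,1]}.
#' Undirected networks are stored symmetrized: every link appears in both
#' directions with equal weight.  Self-links are rejected.
#'
#' @slot nodeLabels character vector of unique external node labels, in
#'   internal index order.
#' @slot nodeActivity numeric vector of activities aligned with
#'   \code{nodeLabels}.
#' @slot edges data.frame with integer columns \code{from}, \code{to}
#'   (internal indices) and numeric \code{weight}.
#' @slot directed logical flag; if \code{FALSE} the edge set is symmetric.
#'
#' @seealso [newSpreadNetwork()], [readEdgeList()], [generateNetwork()]
#' @export
setClass("SpreadNetwork",
  representation(
    nodeLabels   = "character",
    nodeActivity = "numeric",
    edges        = "data.frame",
    directed     = "logical"
  )
)

setValidity("SpreadNetwork", function(object) {
  n <- length(object@nodeLabels)
  e <- object@edges
  msgs <- character(0)
  if (anyDuplicated(object@nodeLabels))
    msgs <- c(msgs, "node labels must be unique")
  if (length(object@nodeActivity) != n)
    msgs <- c(msgs, "nodeActivity must have one entry per node")
  if (length(object@nodeActivity) &&
      (min(object@nodeActivity) < 0 || max(object@nodeActivity) > 1))
    msgs <- c(msgs, "node activities must lie in [0, 1]")
  if (!identical(sort(names(e)), sort(c("from", "to", "weight"))))
    msgs <- c(msgs, "edges must have columns from, to, weight")
  if (nrow(e)) {
    if (any(e$from < 1L | e$from > n | e$to < 1L | e$to > n))
      msgs <- c(msgs, "every link endpoint must be a declared node")
    if (any(e$from == e$to))
      msgs <- c(msgs, "self-links are not allowed")
    if (any(e$weight < 0 | e$weight > 1))
      msgs <- c(msgs, "link weights must lie in [0, 1]")
    if (anyDuplicated(e[, c("from", "to")]))
      msgs <- c(msgs, "duplicate links are not allowed")
    if (!object@directed) {
      key <- paste(e$from, e$to)
      rkey <- paste(e$to, e$from)
      if (!all(rkey %in% key))
        msgs <- c(msgs, "undirected network must contain both directions of every link")
      w <- e$weight[match(rkey, key)]
      if (any(abs(w - e$weight) > 1e-12))
        msgs <- c(msgs, "undirected link weights must be equal in both directions")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Temporal spreading distribution family
#'
#' Holds the temporal spreading distribution \eqn{D_L(T)}: the probability
#' that influence has advanced at least \eqn{L} hops along a chain by time
#' \eqn{T}.  The default family is Poisson with intensity \eqn{\lambda} per
#' unit time, for which \eqn{D_L(T) = P(K(T) \ge L)} with
#' \eqn{K(T) \sim Poisson(\lambda T)} and \eqn{D_0(T) = 1}.  An empirical
#' family interpolates a user-supplied table of \eqn{(L, T, D)} triples.
#'
#' @slot family either \code{"poisson"} or \code{"empirical"}.
#' @slot lambda Poisson intensity (> 0); \code{NA} for empirical models.
#' @slot table for empirical models, a list of per-L data.frames with columns
#'   \code{T} and \code{D}, sorted by \code{T}.
#'
#' @seealso [poissonModel()], [empiricalModel()], [spreadProb()]
#' @export
setClass("TemporalModel",
  representation(
    family = "character",
    lambda = "numeric",
    table  = "list"
  )
)

setValidity("TemporalModel", function(object) {
  if (!object@family %in% c("poisson", "empirical"))
    return("family must be 'poisson' or 'empirical'")
  if (object@family == "poisson" &&
      (length(object@lambda) != 1L || !is.finite(object@lambda) ||
       object@lambda <= 0))
    return("poisson intensity lambda must be a single positive number")
  TRUE
})

#' Parameters of an influence spreading computation
#'
#' Bundles everything needed to evaluate influence probabilities: the temporal
#' model, the evaluation time \eqn{T}, the maximum path length
#' \eqn{L_{max}}, the path mode (self-avoiding paths or loop-allowing bounded
#' walks), and the diagonal convention for \eqn{C_{n,n}}.  The source node's
#' own activity is always taken as 1: the source initiates the process at
#' \eqn{T = 0} with certainty.
#'
#' @slot model a [TemporalModel-class].
#' @slot time evaluation time \eqn{T \ge 0}.
#' @slot lMax maximum path length (number of links) \eqn{\ge 1}.
#' @slot mode \code{"self_avoiding"} or \code{"walks"}.
#' @slot selfValue diagonal value for \eqn{C_{n,n}}, in [0, 1]; 1 by default,
#'   0 under the community-detection convention.
#'
#' @seealso [spreadParams()], [influenceMatrix()]
#' @export
setClass("SpreadParams",
  representation(
    model     = "TemporalModel",
    time      = "numeric",
    lMax      = "integer",
    mode      = "character",
    selfValue = "numeric"
  )
)

setValidity("SpreadParams", function(object) {
  msgs <- character(0)
  if (length(object@time) != 1L || !is.finite(object@time) || object@time < 0)
    msgs <- c(msgs, "time T must be a single nonnegative number")
  if (length(object@lMax) != 1L || is.na(object@lMax) || object@lMax < 1L)
    msgs <- c(msgs, "lMax must be an integer >= 1")
  if (!object@mode %in% c("self_avoiding", "walks"))
    msgs <- c(msgs, "mode must be 'self_avoiding' or 'walks'")
  if (length(object@selfValue) != 1L || object@selfValue < 0 ||
      object@selfValue > 1)
    msgs <- c(msgs, "selfValue must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Influence spreading matrix
#'
#' An N x N matrix whose entry \eqn{(s, t)} is the probability
#' \eqn{C_{s,t}(T)} that a spreading process initiated at node \eqn{s} has
#' influenced node \eqn{t} by time \eqn{T}, together with the parameters that
#' produced it.  Row and column names carry the external node labels; the
#' diagonal equals the configured self value.
#'
#' @slot .Data numeric matrix of probabilities.
#' @slot params the [SpreadParams-class] used to compute the matrix.
#'
#' @seealso [influenceMatrix()], [closenessCentrality()], [cohesion()]
#' @export
setClass("InfluenceMatrix",
  contains = "matrix",
  representation(params = "SpreadParams")
)

setValidity("InfluenceMatrix", function(object) {
  m <- object@.Data
  msgs <- character(0)
  if (nrow(m) != ncol(m))
    msgs <- c(msgs, "influence matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msgs <- c(msgs, "influence matrix must carry node labels as dimnames")
  if (length(m) && (min(m) < -1e-12 || max(m) > 1 + 1e-12))
    msgs <- c(msgs, "all entries must lie in [0, 1]")
  if (nrow(m) && any(abs(diag(m) - object@params@selfValue) > 1e-12))
    msgs <- c(msgs, "diagonal must equal the configured self value")
  if (length(msgs)) msgs else TRUE
})

#' Two-faction division of a network
#'
#' A split of the node set into a faction \eqn{V} and its complement, scored
#' by the intra-faction influence objective
#' \eqn{P(V, \bar V) = \sum_{s,t \in V} C_{s,t} + \sum_{s,t \in \bar V} C_{s,t}}
#' (diagonal entries zeroed).  Reported faction sizes exclude isolated nodes.
#'
#' @slot faction character vector of node labels in \eqn{V}.
#' @slot complement character vector of node labels in \eqn{\bar V}.
#' @slot value the objective \eqn{P(V, \bar V)}.
#' @slot sizes integer of length 2: non-isolated node counts of the two
#'   factions.
#'
#' @seealso [divisionValue()], [localSearch()]
#' @export
setClass("Division",
  representation(
    faction    = "character",
    complement = "character",
    value      = "numeric",
    sizes      = "integer"
  )
)

setValidity("Division", function(object) {
  if (length(intersect(object@faction, object@complement)))
    return("faction and complement must be disjoint")
  if (length(object@sizes) != 2L)
    return("sizes must have length 2")
  TRUE
})

#' Catalog of detected community divisions
#'
#' The deduplicated set of two-faction divisions found as local maxima of the
#' intra-influence objective, ranked by objective value in descending order.
#' The rank serves as the community identifier.
#'
#' @slot divisions list of [Division-class] objects, best first.
#' @slot nodeLabels all node labels of the analysed network.
#' @slot isolated labels of isolated nodes (excluded from faction sizes).
#' @slot total the grand total \eqn{S_{total}} of the (diagonal-zeroed)
#'   influence matrix; \eqn{P \le S_{total}} for every division.
#'
#' @seealso [detectCommunities()], [refineWithIntersections()],
#'   [relationsReport()]
#' @export
setClass("CommunityCatalog",
  representation(
    divisions  = "list",
    nodeLabels = "character",
    isolated   = "character",
    total      = "numeric"
  )
)

setValidity("CommunityCatalog", function(object) {
  if (!all(vapply(object@divisions, is, logical(1), class2 = "Division")))
    return("divisions must be a list of Division objects")
  v <- vapply(object@divisions, function(d) d@value, numeric(1))
  if (is.unsorted(rev(v), strictly = FALSE))
    return("divisions must be ranked by decreasing objective value")
  TRUE
})
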