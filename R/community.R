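# Community detection by local maximisation of the two-faction
# intra-influence objective
#
#   P(V, Vbar) = sum_{s,t in V} C_{s,t} + sum_{s,t in Vbar} C_{s,t}
#
# on the influence matrix with its diagonal set to zero (the diagonal only
# shifts P by a constant and never changes the ranking of divisions).
# Strict-improvement sweeps in ascending node-index order; restart search
# with deduplication; optional intersection-driven refinement.

# coerce input to a plain zero-diagonal matrix with label dimnames
.communityMatrix <- function(m) {
  if (is(m, "InfluenceMatrix")) m <- m@.Data
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("need a square influence matrix")
  if (is.null(rownames(m)))
    dimnames(m) <- list(as.character(seq_len(nrow(m))),
                        as.character(seq_len(nrow(m))))
  diag(m) <- 0
  m
}

# membership logical vector -> canonical orientation (node 1 in faction V)
.canonical <- function(v) if (v[1L]) v else !v

.membershipValue <- function(m, v) {
  sum(m[v, v]) + sum(m[!v, !v])
}

.divisionFromMembership <- function(m, v) {
  v <- .canonical(v)
  labs <- rownames(m)
  S <- m + t(m)
  isolated <- rowSums(S) == 0
  new("Division",
      faction = labs[v], complement = labs[!v],
      value = .membershipValue(m, v),
      sizes = c(sum(v & !isolated), sum(!v & !isolated)))
}

#' Value of a two-faction division
#'
#' Evaluates the intra-influence objective \eqn{P(V, \bar V)}: the sum of
#' influence matrix entries over ordered within-faction pairs of both
#' factions, with the diagonal zeroed.  \eqn{P \le S_{total}} (the total
#' off-diagonal influence), with equality exactly when no influence crosses
#' the faction boundary.
#'
#' @param m an [InfluenceMatrix-class] or plain square matrix; the diagonal
#'   is zeroed internally
#' @param faction node labels of \eqn{V} (the complement is implied)
#' @return the objective value \eqn{P}
#' @examples
#' m <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' divisionValue(m, "a")  # 0: all influence crosses the split
#' @export
divisionValue <- function(m, faction) {
  m <- .communityMatrix(m)
  labs <- rownames(m)
  faction <- as.character(faction)
  if (!all(faction %in% labs))
    stop("faction contains unknown node(s): ",
         paste(setdiff(faction, labs), collapse = ", "))
  v <- labs %in% faction
  .membershipValue(m, v)
}

#' Strict-improvement local search for one division
#'
#' Starting from an initial faction assignment, repeatedly sweeps the nodes
#' in ascending index order, moving a node to the other faction if and only
#' if the move strictly increases \eqn{P}; terminates when a full sweep makes
#' no move.  The returned division is a certified local maximum: no
#' single-node move improves the objective.
#'
#' @param m an [InfluenceMatrix-class] or plain matrix (diagonal zeroed)
#' @param init initial faction: node labels, or a logical membership vector
#'   in internal node order
#' @return a [Division-class]
#' @export
localSearch <- function(m, init) {
  m <- .communityMatrix(m)
  n <- nrow(m)
  labs <- rownames(m)
  if (is.logical(init)) {
    if (length(init) != n) stop("logical init must have one entry per node")
    v <- init
  } else {
    init <- as.character(init)
    if (!all(init %in% labs)) stop("init contains unknown node(s)")
    v <- labs %in% init
  }
  S <- m + t(m)  # S[k, j]: objective weight tied to the unordered pair {k, j}
  repeat {
    moved <- FALSE
    for (k in seq_len(n)) {
      same <- sum(S[k, v == v[k]])       # S[k, k] = 0
      cross <- sum(S[k, v != v[k]])
      if (cross - same > 0) {            # strict improvement only
        v[k] <- !v[k]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  .divisionFromMembership(m, v)
}

#' Post-hoc local-maximum certificate
#'
#' Re-verifies that no single-node move strictly increases the objective of
#' a division.
#'
#' @param m an [InfluenceMatrix-class] or plain matrix
#' @param division a [Division-class]
#' @return \code{TRUE} if the division is a local maximum
#' @export
isLocalMaximum <- function(m, division) {
  m <- .communityMatrix(m)
  labs <- rownames(m)
  v <- labs %in% division@faction
  S <- m + t(m)
  for (k in seq_len(nrow(m))) {
    if (sum(S[k, v != v[k]]) - sum(S[k, v == v[k]]) > 1e-12) return(FALSE)
  }
  TRUE
}

.divisionKey <- function(d, labs) {
  v <- .canonical(labs %in% d@faction)
  paste(as.integer(v), collapse = "")
}

# deduplicate + rank a list of divisions; distinct compositions whose P
# values coincide within `tol` are treated as duplicates (keeps the catalog
# from exploding when the objective is degenerate, e.g. edgeless networks).
# A division with an empty faction is the whole network itself (P = S_total,
# the global optimum by construction) -- it is the reference row, never a
# catalog entry.
.rankDivisions <- function(divs, labs, tol = 1e-9) {
  if (!length(divs)) return(divs)
  divs <- divs[vapply(divs, function(d)
    length(d@faction) > 0L && length(d@complement) > 0L, logical(1))]
  if (!length(divs)) return(divs)
  keys <- vapply(divs, .divisionKey, "", labs = labs)
  divs <- divs[!duplicated(keys)]
  vals <- vapply(divs, function(d) d@value, numeric(1))
  keys <- vapply(divs, .divisionKey, "", labs = labs)
  ord <- order(-vals, keys)
  divs <- divs[ord]; vals <- vals[ord]
  keep <- logical(length(divs))
  kept <- numeric(0)
  for (i in seq_along(divs)) {
    if (!length(kept) || all(abs(kept - vals[i]) > tol)) {
      keep[i] <- TRUE
      kept <- c(kept, vals[i])
    }
  }
  divs[keep]
}

#' Detect communities by restart local search
#'
#' Runs [localSearch()] from random initial divisions, deduplicates the
#' local maxima found, and returns them ranked by objective value (the rank
#' is the community identifier).  The search stops after \code{restarts}
#' initialisations, when \code{maxCommunities} distinct divisions have been
#' found, or when \code{noNewWindow} consecutive restarts produce no new
#' composition.
#'
#' @param m an [InfluenceMatrix-class] or plain matrix; diagonal zeroed
#' @param restarts number of random restarts (\eqn{\ge 1})
#' @param seed optional RNG seed for reproducible catalogs
#' @param maxCommunities stop once this many distinct divisions are found
#' @param noNewWindow stop after this many consecutive restarts without a
#'   new composition (default: never)
#' @param refine if \code{TRUE}, run [refineWithIntersections()] on the
#'   result
#' @return a [CommunityCatalog-class]
#' @examples
#' net <- generateNetwork("planted_partition", sizes = c(5, 5), pIn = 1,
#'                        pOut = 0, seed = 1)
#' im <- influenceMatrix(net, spreadParams(poissonModel(0.5), 1, lMax = 4,
#'                                         selfValue = 0))
#' detectCommunities(im, restarts = 10, seed = 7)
#' @export
detectCommunities <- function(m, restarts = 20L, seed = NULL,
                              maxCommunities = Inf, noNewWindow = Inf,
                              refine = FALSE) {
  mm <- .communityMatrix(m)
  if (restarts < 1L) stop("restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mm)
  labs <- rownames(mm)
  found <- list()
  keys <- character(0)
  sinceNew <- 0L
  for (r in seq_len(restarts)) {
    v0 <- runif(n) > 0.5
    d <- localSearch(mm, v0)
    key <- .divisionKey(d, labs)
    if (!key %in% keys) {
      found[[length(found) + 1L]] <- d
      keys <- c(keys, key)
      sinceNew <- 0L
    } else sinceNew <- sinceNew + 1L
    if (length(found) >= maxCommunities || sinceNew >= noNewWindow) break
  }
  S <- mm + t(mm)
  catalog <- new("CommunityCatalog",
                 divisions = .rankDivisions(found, labs),
                 nodeLabels = labs,
                 isolated = labs[rowSums(S) == 0],
                 total = sum(mm))
  if (refine) catalog <- refineWithIntersections(catalog, mm)
  catalog
}

#' @describeIn detectCommunities ranked list of [Division-class] objects
#' @param x a \code{CommunityCatalog}
#' @export
setMethod("divisions", "CommunityCatalog", function(x) x@divisions)

setMethod("show", "CommunityCatalog", function(object) {
  k <- length(object@divisions)
  cat("CommunityCatalog with", k, "division(s) of",
      length(object@nodeLabels), "nodes")
  if (length(object@isolated))
    cat(" (", length(object@isolated), " isolated excluded from sizes)",
        sep = "")
  cat("\n")
  if (k) {
    df <- data.frame(
      rank = seq_len(k),
      P = vapply(object@divisions, function(d) d@value, numeric(1)),
      sizes = vapply(object@divisions,
                     function(d) paste(d@sizes, collapse = " + "), ""))
    print(head(df, 10L), row.names = FALSE)
    if (k > 10L) cat("  ... and", k - 10L, "more\n")
  }
})

# the community set reported for a division: its smaller faction
# (ties broken toward the faction holding the smallest node label)
.smallerFaction <- function(d, labs) {
  a <- d@faction; b <- d@complement
  if (length(a) < length(b)) return(a)
  if (length(b) < length(a)) return(b)
  if (match(TRUE, labs %in% a) < match(TRUE, labs %in% b)) a else b
}

#' Refine a catalog with set differences and intersections
#'
#' Detected factions that nest or overlap suggest further sub-communities:
#' for nested faction pairs \eqn{F_j \subset F_i} the set difference
#' \eqn{F_i - F_j}, and for overlapping pairs the intersection, are used to
#' seed new local searches.  Newly found local maxima are merged into the
#' catalog; the procedure iterates until no new composition appears, so
#' re-running the refinement leaves the catalog unchanged.
#'
#' @param catalog a [CommunityCatalog-class]
#' @param m the influence matrix the catalog was computed from
#' @param maxIter safety cap on refinement rounds
#' @return a [CommunityCatalog-class]
#' @export
refineWithIntersections <- function(catalog, m, maxIter = 10L) {
  mm <- .communityMatrix(m)
  labs <- catalog@nodeLabels
  divs <- catalog@divisions
  if (!length(divs)) return(catalog)
  keys <- vapply(divs, .divisionKey, "", labs = labs)
  for (iter in seq_len(maxIter)) {
    sets <- unique(c(lapply(divs, function(d) d@faction),
                     lapply(divs, function(d) d@complement)))
    seeds <- list()
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i == j) next
      Fi <- sets[[i]]; Fj <- sets[[j]]
      common <- intersect(Fi, Fj)
      if (!length(common)) next
      if (all(Fj %in% Fi) && length(Fj) < length(Fi)) {
        seeds[[length(seeds) + 1L]] <- setdiff(Fi, Fj)
      } else if (!all(Fj %in% Fi) && !all(Fi %in% Fj) && i < j) {
        seeds[[length(seeds) + 1L]] <- common
      }
    }
    seeds <- unique(seeds[lengths(seeds) > 0L])
    new <- FALSE
    for (sd in seeds) {
      d <- localSearch(mm, sd)
      key <- .divisionKey(d, labs)
      if (!key %in% keys) {
        divs[[length(divs) + 1L]] <- d
        keys <- c(keys, key)
        new <- TRUE
      }
    }
    if (!new) break
  }
  new("CommunityCatalog",
      divisions = .rankDivisions(divs, labs),
      nodeLabels = labs, isolated = catalog@isolated,
      total = catalog@total)
}

#' Report relations among detected communities
#'
#' Compares the reported community sets (the smaller faction of each ranked
#' division) pairwise and lists subset (nested) relations, exact union and
#' intersection identities, and genuine overlaps (a nonempty intersection
#' with no containment either way).
#'
#' @param catalog a [CommunityCatalog-class]
#' @return data.frame with columns \code{relation} (\code{"nested"},
#'   \code{"union"}, \code{"intersection"}, \code{"overlap"}), \code{lhs},
#'   \code{rhs} (community ranks involved) and \code{detail}; zero rows when
#'   no relations exist
#' @export
relationsReport <- function(catalog) {
  labs <- catalog@nodeLabels
  sets <- lapply(catalog@divisions, .smallerFaction, labs = labs)
  k <- length(sets)
  out <- data.frame(relation = character(0), lhs = character(0),
                    rhs = character(0), detail = character(0),
                    stringsAsFactors = FALSE)
  add <- function(rel, lhs, rhs, detail) {
    out[nrow(out) + 1L, ] <<- list(rel, lhs, rhs, detail)
  }
  setEq <- function(a, b) length(a) == length(b) && all(a %in% b)
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    A <- sets[[i]]; B <- sets[[j]]
    common <- intersect(A, B)
    if (setEq(A, B)) next
    if (all(B %in% A)) add("nested", as.character(j), as.character(i),
                           paste0("C", j, " subset of C", i))
    else if (all(A %in% B)) add("nested", as.character(i), as.character(j),
                                paste0("C", i, " subset of C", j))
    else if (length(common)) add("overlap", as.character(i), as.character(j),
                                 paste0(length(common), " shared node(s)"))
  }
  if (k >= 3L) for (kk in seq_len(k)) {
    for (ij in combn(setdiff(seq_len(k), kk), 2L, simplify = FALSE)) {
      A <- sets[[ij[1L]]]; B <- sets[[ij[2L]]]
      if (setEq(sets[[kk]], union(A, B)) && !setEq(A, B) &&
          !all(A %in% B) && !all(B %in% A))
        add("union", as.character(kk), paste(ij, collapse = "+"),
            paste0("C", kk, " = C", ij[1L], " U C", ij[2L]))
      common <- intersect(A, B)
      if (length(common) && setEq(sets[[kk]], common) &&
          !all(A %in% B) && !all(B %in% A))
        add("intersection", as.character(kk), paste(ij, collapse = "^"),
            paste0("C", kk, " = C", ij[1L], " n C", ij[2L]))
    }
  }
  out
}

#' Write a community catalog as JSON and CSV
#'
#' The JSON file holds, per division: rank id, objective value \code{P},
#' faction sizes (isolated nodes excluded), and member labels of both
#' factions, plus the relations table and the diagonal convention.  The CSV
#' summary mirrors the ranked table layout.
#'
#' @param catalog a [CommunityCatalog-class]
#' @param jsonPath output JSON path (or \code{NULL} to skip)
#' @param csvPath output CSV path (or \code{NULL} to skip)
#' @return invisibly, the catalog
#' @export
writeCommunityCatalog <- function(catalog, jsonPath = NULL, csvPath = NULL) {
  divs <- catalog@divisions
  if (!is.null(jsonPath)) {
    payload <- list(
      diagonal_convention = 0,
      isolated_nodes = catalog@isolated,
      total_influence = catalog@total,
      divisions = lapply(seq_along(divs), function(i) {
        d <- divs[[i]]
        list(id = i, P = d@value, sizes = as.integer(d@sizes),
             faction = d@faction, complement = d@complement)
      }),
      relations = relationsReport(catalog))
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csvPath)) {
    df <- data.frame(
      rank = seq_along(divs),
      P = vapply(divs, function(d) d@value, numeric(1)),
      size1 = vapply(divs, function(d) d@sizes[1L], integer(1)),
      size2 = vapply(divs, function(d) d@sizes[2L], integer(1)),
      faction = vapply(divs, function(d) paste(d@faction, collapse = " "),
                       ""))
    write.table(df, csvPath, sep = ",", row.names = FALSE, quote = TRUE)
  }
  invisible(catalog)
}

setMethod("show", "Division", function(object) {
  cat("Division P =", object@value, "| sizes", object@sizes[1L], "+",
      object@sizes[2L], "\n")
  cat("  faction: ", paste(object@faction, collapse = " "), "\n")
})
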