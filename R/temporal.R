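# Temporal spreading distributions D_L(T) and their per-hop factors.
#
# D_L(T) is the probability that influence has advanced at least L hops along
# a chain by time T.  For the Poisson family with intensity lambda,
#   D_L(T) = P(K(T) >= L) = 1 - sum_{z=0}^{L-1} exp(-lambda T) (lambda T)^z / z!
# with D_0(T) = 1 for all T.  Equivalently D_L(T) = P(Gamma(L, lambda) <= T):
# the L-hop first-passage time is the sum of L exponential forwarding delays.

#' Poisson temporal spreading model
#'
#' @param lambda intensity of forwarding events per unit time (> 0).
#' @return a [TemporalModel-class] of the Poisson family
#' @examples
#' m <- poissonModel(0.5)
#' spreadProb(m, 1, 1)  # 1 - exp(-0.5)
#' @export
poissonModel <- function(lambda) {
  new("TemporalModel", family = "poisson", lambda = as.numeric(lambda),
      table = list())
}

#' Empirical temporal spreading model
#'
#' Builds a \code{TemporalModel} from a table of \eqn{(L, T, D)} triples,
#' interpolating linearly in \eqn{T} within each hop count \eqn{L}.  Outside
#' the tabulated range, \eqn{D} is interpolated from \eqn{(0, 0)} on the left
#' and held constant on the right; hop counts beyond the largest tabulated
#' \eqn{L} evaluate to 0.  The defining invariants are validated strictly:
#' \eqn{D} must be nondecreasing in \eqn{T}, nonincreasing in \eqn{L} at
#' shared times, and within [0, 1].
#'
#' @param x a data.frame with columns \code{L}, \code{T}, \code{D}, or the
#'   path of a CSV file with those columns.
#' @return a [TemporalModel-class] of the empirical family
#' @export
empiricalModel <- function(x) {
  if (is.character(x)) x <- read.table(x, sep = ",", header = TRUE)
  df <- as.data.frame(x)
  need <- c("L", "T", "D")
  if (!all(need %in% names(df)))
    stop("empirical table needs columns L, T, D")
  if (any(df$D < -1e-12 | df$D > 1 + 1e-12))
    stop("empirical D values must lie in [0, 1]")
  if (any(df$L < 1L)) stop("empirical table rows must have L >= 1 (D_0 = 1 is implied)")
  if (any(df$T < 0)) stop("empirical table times must be nonnegative")
  tabs <- lapply(split(df[c("T", "D")], df$L), function(d) {
    d <- d[order(d$T), , drop = FALSE]
    if (anyDuplicated(d$T)) stop("duplicate (L, T) entries in empirical table")
    if (is.unsorted(d$D)) stop("empirical D must be nondecreasing in T")
    d
  })
  Ls <- as.integer(names(tabs))
  # anti-monotonicity in L wherever two consecutive L share a time point
  for (i in seq_along(Ls)[-1L]) {
    a <- tabs[[i - 1L]]; b <- tabs[[i]]
    shared <- intersect(a$T, b$T)
    if (length(shared) &&
        any(b$D[match(shared, b$T)] > a$D[match(shared, a$T)] + 1e-12))
      stop("empirical D must be nonincreasing in L at shared times")
  }
  names(tabs) <- Ls
  new("TemporalModel", family = "empirical", lambda = NA_real_, table = tabs)
}

.empiricalD <- function(model, L, time) {
  tab <- model@table[[as.character(L)]]
  if (is.null(tab)) return(0)
  Ts <- c(0, tab$T[tab$T > 0])
  Ds <- c(0, tab$D[tab$T > 0])
  if (tab$T[1L] == 0) Ds[1L] <- tab$D[1L]
  if (time >= Ts[length(Ts)]) return(Ds[length(Ds)])
  stats::approx(Ts, Ds, xout = time, method = "linear", ties = "ordered")$y
}

#' Temporal spreading probability D_L(T)
#'
#' @param model a [TemporalModel-class]
#' @param L hop count, integer \eqn{\ge 0} (vectorized)
#' @param time evaluation time \eqn{T \ge 0}
#' @return probability that influence has advanced at least \code{L} hops by
#'   \code{time}; always 1 at \code{L = 0}, and 0 at \code{time = 0} for
#'   \code{L >= 1}
#' @export
setMethod("spreadProb", "TemporalModel", function(model, L, time) {
  if (any(L < 0) || any(L != floor(L)))
    stop("hop count L must be a nonnegative integer")
  if (any(time < 0)) stop("time T must be nonnegative")
  if (model@family == "poisson") {
    out <- ppois(L - 1, model@lambda * time, lower.tail = FALSE)
    out[L == 0] <- 1
    out
  } else {
    out <- mapply(function(l, tt) {
      if (l == 0) 1 else .empiricalD(model, l, tt)
    }, L, rep_len(time, length(L)))
    as.numeric(out)
  }
})

#' Conditional one-hop step factor D_{L+1}(T) / D_L(T)
#'
#' The probability that influence advances one further hop by time \code{T},
#' given that it has already advanced \code{L} hops.  The product of step
#' factors for prefixes 0, ..., L-1 telescopes to \eqn{D_L(T)}.  At the
#' degenerate point where \eqn{D_L(T) = 0} (i.e. \eqn{T = 0}, \eqn{L \ge 1})
#' the factor is defined as 0: no spreading happens in zero time.
#'
#' @param model a [TemporalModel-class]
#' @param L completed prefix length, integer \eqn{\ge 0} (vectorized)
#' @param time evaluation time \eqn{T \ge 0}
#' @return conditional probability in [0, 1]
#' @export
setMethod("stepFactor", "TemporalModel", function(model, L, time) {
  num <- spreadProb(model, L + 1, time)
  den <- spreadProb(model, L, time)
  out <- ifelse(den > 0, num / den, 0)
  pmin(pmax(out, 0), 1)
})

setMethod("show", "TemporalModel", function(object) {
  if (object@family == "poisson")
    cat("Poisson temporal spreading model, lambda =", object@lambda, "\n")
  else
    cat("Empirical temporal spreading model for L in {",
        paste(names(object@table), collapse = ", "), "}\n")
})

#' Bundle influence spreading parameters
#'
#' Called on a [TemporalModel-class], constructs a parameter bundle; called
#' on an [InfluenceMatrix-class], returns the bundle that produced it.
#'
#' @param x a [TemporalModel-class] (e.g. [poissonModel()]) or an
#'   [InfluenceMatrix-class]
#' @param time evaluation time \eqn{T \ge 0}
#' @param lMax maximum path length in links (default 6; typical useful values
#'   lie between 4 and 10, and contributions beyond ~20 hops are negligible
#'   for ordinary temporal models)
#' @param mode \code{"self_avoiding"} (default) or \code{"walks"}
#' @param selfValue diagonal convention for \eqn{C_{n,n}} (default 1)
#' @param ... unused
#' @return a [SpreadParams-class]
#' @examples
#' spreadParams(poissonModel(1), time = 1, lMax = 8)
#' @export
setMethod("spreadParams", "TemporalModel",
          function(x, time, lMax = 6L, mode = c("self_avoiding", "walks"),
                   selfValue = 1, ...) {
  mode <- match.arg(mode)
  new("SpreadParams", model = x, time = as.numeric(time),
      lMax = as.integer(lMax), mode = mode, selfValue = as.numeric(selfValue))
})

setMethod("show", "SpreadParams", function(object) {
  cat("SpreadParams: T =", object@time, "| lMax =", object@lMax,
      "| mode =", object@mode, "| diagonal =", object@selfValue, "\n")
  show(object@model)
})

#' @rdname spreadParams-TemporalModel-method
#' @export
setMethod("spreadParams", "InfluenceMatrix", function(x, ...) x@params)
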