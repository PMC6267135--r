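# Shared fixture builders.  All randomness is seeded so the suite is
# reproducible end to end.

chainNet <- function(n) generateNetwork("chain", n = n)

# complete graph on the given labels, unit weights
completeNet <- function(labels) {
  pr <- t(combn(labels, 2L))
  newSpreadNetwork(data.frame(from = pr[, 1L], to = pr[, 2L]))
}

# diamond with a stem: s - a, then a - b - t and a - c - t
diamondStemNet <- function() {
  newSpreadNetwork(data.frame(
    from = c("s", "a", "a", "b", "c"),
    to   = c("a", "b", "c", "t", "t")))
}

# chain 1..7 plus a two-route tail to node 8 (7-8 direct, 7-9-8), giving a
# pair of paths of lengths 7 and 8 with a common prefix of 6 links
forkedChainNet <- function() {
  newSpreadNetwork(data.frame(
    from = c(1, 2, 3, 4, 5, 6, 7, 7, 9),
    to   = c(2, 3, 4, 5, 6, 7, 8, 9, 8)))
}

# random connected graph convenience
randomConnected <- function(n, p, seed) {
  generateNetwork("connected_random", n = n, p = p, seed = seed)
}

# monotone empirical spreading table with D_6 = .5, D_7 = .4, D_8 = .3 at T=1
empiricalTable468 <- function() {
  data.frame(L = 1:8, T = 1, D = c(.95, .9, .8, .7, .6, .5, .4, .3))
}

poisParams <- function(lambda, time, lMax = 6L, ...) {
  spreadParams(poissonModel(lambda), time, lMax = lMax, ...)
}
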