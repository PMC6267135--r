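communityFixture <- function(sizes = c(8, 8), pIn = 1, pOut = 0.05,
                             seed = 1, lMax = 4) {
  net <- generateNetwork("planted_partition", sizes = sizes, pIn = pIn,
                         pOut = pOut, seed = seed)
  influenceMatrix(net, spreadParams(poissonModel(0.5), 1, lMax = lMax,
                                    selfValue = 0))
}

test_that("division values satisfy the partition identity", {
  im <- communityFixture()
  m <- unclass(im@.Data)
  labs <- rownames(m)
  S <- sum(m)
  # V = all nodes reproduces the grand total
  expect_equal(divisionValue(im, labs), S, tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:10) {
    V <- sample(labs, sample(1:15, 1))
    cross <- sum(m[V, setdiff(labs, V)]) + sum(m[setdiff(labs, V), V])
    expect_equal(divisionValue(im, V), S - cross, tolerance = 1e-9)
    expect_lte(divisionValue(im, V), S + 1e-12)
  }
  # disconnected components: separating them loses nothing
  im0 <- communityFixture(pOut = 0)
  expect_equal(divisionValue(im0, as.character(1:8)), sum(unclass(im0@.Data)),
               tolerance = 1e-12)
  expect_error(divisionValue(im, "nope"), "unknown node")
})

test_that("local search terminates at certified local maxima", {
  im <- communityFixture()
  # the planted split is already a local maximum: returned unchanged
  d <- localSearch(im, as.character(1:8))
  expect_setequal(d@faction, as.character(1:8))
  expect_true(isLocalMaximum(im, d))
  # random starts always end at certified local maxima
  set.seed(3)
  for (rep in 1:10) {
    d <- localSearch(im, runif(16) > 0.5)
    expect_true(isLocalMaximum(im, d))
  }
  # 1-node network: trivial division with P = 0
  one <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(localSearch(one, "a")@value, 0)
})

test_that("restart detection recovers planted blocks and matches brute force", {
  im0 <- communityFixture(pOut = 0)
  catalog <- detectCommunities(im0, restarts = 20, seed = 42)
  d1 <- divisions(catalog)[[1]]
  expect_true(setequal(d1@faction, as.character(1:8)) ||
              setequal(d1@complement, as.character(1:8)))
  # exhaustive check over all nontrivial splits of the 16 nodes
  m <- unclass(im0@.Data)
  best <- -Inf
  bestSplit <- NULL
  for (bits in seq_len(2^15 - 1)) {
    v <- c(as.logical(bitwAnd(bits, 2^(0:14))), FALSE)
    P <- sum(m[v, v]) + sum(m[!v, !v])
    if (P > best) { best <- P; bestSplit <- v }
  }
  expect_equal(d1@value, best, tolerance = 1e-9)
  expect_true(setequal(rownames(m)[bestSplit], d1@faction) ||
              setequal(rownames(m)[bestSplit], d1@complement))
  # faction sizes exclude nothing here (no isolates)
  expect_equal(sort(d1@sizes), c(8L, 8L))
})

test_that("catalogs are deterministic and collapse degenerate ties", {
  im <- communityFixture()
  a <- detectCommunities(im, restarts = 15, seed = 7)
  b <- detectCommunities(im, restarts = 15, seed = 7)
  expect_equal(lapply(divisions(a), function(d) d@faction),
               lapply(divisions(b), function(d) d@faction))
  # edgeless network: all splits tie at P = 0, one entry survives
  m0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  cat0 <- detectCommunities(m0, restarts = 10, seed = 1)
  expect_length(divisions(cat0), 1L)
  expect_equal(divisions(cat0)[[1L]]@value, 0)
  # every node is isolated there, so reported sizes are 0 + 0
  expect_equal(divisions(cat0)[[1L]]@sizes, c(0L, 0L))
})

test_that("isolated nodes are excluded from reported faction sizes", {
  net <- generateNetwork("planted_partition", sizes = c(5, 5), pIn = 1,
                         pOut = 0, seed = 2)
  lt <- linkTable(net)
  aug <- newSpreadNetwork(lt[lt$from < lt$to, ], nodes = c("iso1", "iso2"))
  im <- influenceMatrix(aug, spreadParams(poissonModel(0.5), 1, lMax = 4,
                                          selfValue = 0))
  catalog <- detectCommunities(im, restarts = 20, seed = 5)
  expect_setequal(catalog@isolated, c("iso1", "iso2"))
  sizes <- vapply(divisions(catalog), function(d) sum(d@sizes), integer(1))
  expect_true(all(sizes <= 10L))
})

test_that("intersection refinement finds the middle block and is idempotent", {
  # three blocks on 12 nodes; weak inter-block links make values distinct
  set.seed(14)
  blocks <- list(1:3, 4:7, 8:12)
  within <- do.call(rbind, lapply(blocks, function(b) t(combn(b, 2))))
  between <- rbind(c(3, 4), c(7, 8))   # a weak chain A - B - C
  lt <- data.frame(from = c(within[, 1], between[, 1]),
                   to = c(within[, 2], between[, 2]),
                   weight = c(rep(1, nrow(within)), rep(0.3, 2)))
  net <- newSpreadNetwork(lt)
  im <- influenceMatrix(net, spreadParams(poissonModel(0.5), 1, lMax = 4,
                                          selfValue = 0))
  A <- as.character(1:3); B <- as.character(4:7); C <- as.character(8:12)
  # phase 1 seeded with the outer splits only
  seedDivs <- list(localSearch(im, A), localSearch(im, C))
  catalog <- new("CommunityCatalog",
                 divisions = spreadnet:::.rankDivisions(
                   seedDivs, rownames(unclass(im@.Data))),
                 nodeLabels = rownames(unclass(im@.Data)),
                 isolated = character(0), total = sum(unclass(im@.Data)))
  hasB <- function(cat) any(vapply(divisions(cat), function(d)
    setequal(d@faction, B) || setequal(d@complement, B), logical(1)))
  expect_false(hasB(catalog))
  refined <- refineWithIntersections(catalog, im)
  expect_true(hasB(refined))
  # idempotence on the final catalog
  again <- refineWithIntersections(refined, im)
  expect_equal(lapply(divisions(again), function(d) d@faction),
               lapply(divisions(refined), function(d) d@faction))
  # no nested or overlapping pairs: nothing to do
  disjoint <- detectCommunities(communityFixture(pOut = 0), restarts = 10,
                                seed = 2)
  expect_equal(length(divisions(refineWithIntersections(
    disjoint, communityFixture(pOut = 0)))), length(divisions(disjoint)))
})

test_that("relations reports recognise nesting, unions and overlaps", {
  mk <- function(faction, all) new("Division", faction = faction,
                                   complement = setdiff(all, faction),
                                   value = as.numeric(length(faction)),
                                   sizes = c(1L, 1L))
  all <- as.character(1:10)
  cat1 <- new("CommunityCatalog",
              divisions = list(mk(c("1", "2", "3", "4"), all),
                               mk(c("1", "2"), all)),
              nodeLabels = all, isolated = character(0), total = 0)
  r <- relationsReport(cat1)
  expect_true(any(r$relation == "nested"))
  # union identity X, Y, X U Y
  cat2 <- new("CommunityCatalog",
              divisions = list(mk(c("1", "2", "3", "4"), all),
                               mk(c("1", "2"), all),
                               mk(c("3", "4"), all)),
              nodeLabels = all, isolated = character(0), total = 0)
  r2 <- relationsReport(cat2)
  expect_true(any(r2$relation == "union"))
  # disjoint factions: no relations at all
  cat3 <- new("CommunityCatalog",
              divisions = list(mk(c("1", "2"), all), mk(c("3", "4"), all)),
              nodeLabels = all, isolated = character(0), total = 0)
  expect_equal(nrow(relationsReport(cat3)), 0L)
  # overlap
  cat4 <- new("CommunityCatalog",
              divisions = list(mk(c("1", "2", "3"), all),
                               mk(c("3", "4", "5"), all)),
              nodeLabels = all, isolated = character(0), total = 0)
  expect_true(any(relationsReport(cat4)$relation == "overlap"))
})

test_that("catalogs are invariant under node relabeling", {
  net <- generateNetwork("planted_partition", sizes = c(6, 6), pIn = 1,
                         pOut = 0, seed = 9)
  im <- influenceMatrix(net, spreadParams(poissonModel(0.5), 1, lMax = 4,
                                          selfValue = 0))
  # permute the labels
  perm <- setNames(sprintf("n%02d", c(7, 3, 11, 1, 12, 5, 9, 2, 10, 4, 8, 6)),
                   nodeLabels(net))
  lt <- linkTable(net)
  lt$from <- unname(perm[lt$from]); lt$to <- unname(perm[lt$to])
  net2 <- newSpreadNetwork(lt[!duplicated(t(apply(cbind(lt$from, lt$to), 1,
                                                  sort))), ])
  im2 <- influenceMatrix(net2, spreadParams(poissonModel(0.5), 1, lMax = 4,
                                            selfValue = 0))
  c1 <- detectCommunities(im, restarts = 25, seed = 3)
  c2 <- detectCommunities(im2, restarts = 25, seed = 3)
  sets1 <- lapply(divisions(c1), function(d) sort(unname(perm[d@faction])))
  sets2 <- lapply(divisions(c2), function(d) sort(d@faction))
  canon <- function(s, all) {
    comp <- sort(setdiff(all, s))
    if (paste(s, collapse = ",") < paste(comp, collapse = ",")) s else comp
  }
  all2 <- sort(unname(perm))
  expect_setequal(vapply(sets1, function(s) paste(canon(s, all2), collapse = ","), ""),
                  vapply(sets2, function(s) paste(canon(s, all2), collapse = ","), ""))
})

test_that("catalog JSON and CSV outputs carry the ranked structure", {
  im <- communityFixture(pOut = 0)
  catalog <- detectCommunities(im, restarts = 20, seed = 4)
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  writeCommunityCatalog(catalog, jf, cf)
  js <- jsonlite::read_json(jf)
  expect_equal(js$diagonal_convention, 0)
  expect_equal(js$divisions[[1L]]$id, 1L)
  expect_equal(length(js$divisions), length(divisions(catalog)))
  df <- read.csv(cf)
  expect_equal(df$P[1L], divisions(catalog)[[1L]]@value, tolerance = 1e-9)
})
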