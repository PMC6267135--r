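test_that("single-path probabilities follow the weighted hop formula", {
  net <- workedExampleNetwork()
  p <- poisParams(1, 1, lMax = 8)
  # unit weights: the path probability is D_L(T)
  expect_equal(pathProbability(c("1", "3", "27", "4"), net, p),
               spreadProb(poissonModel(1), 3, 1), tolerance = 1e-12)
  expect_equal(pathProbability(c("1", "3", "27", "4"), net, p),
               0.0803014, tolerance = 1e-6)
  # one hop, target activity 0.5, large time: tends to the activity
  ch <- chainNet(2)
  nodeActivity(ch) <- c("2" = 0.5)
  expect_equal(pathProbability(c("1", "2"), ch, poisParams(1, 500, 1)), 0.5,
               tolerance = 1e-9)
  expect_error(pathProbability(c("1", "4"), net, p), "not a link")
})

test_that("trie evaluation reproduces the two-branch prefix algebra", {
  # branches of 1 and 2 links after a 6-link prefix; with an empirical
  # model pinning D_6 = .5, D_7 = .4, D_8 = .3 the combined probability is
  # D_7 + D_8 - D_7 D_8 / D_6 = 0.46
  net <- forkedChainNet()
  em <- empiricalModel(empiricalTable468())
  pp <- spreadParams(em, 1, lMax = 8)
  paths <- enumeratePaths(net, "1", lMax = 8)[["8"]]
  expect_length(paths, 2L)
  expect_equal(evaluateTrie(buildPathTrie(paths), net, pp), 0.46,
               tolerance = 1e-12)
  # same identity with genuine Poisson tails over several (lambda, T);
  # compared on the absolute scale (the values are probabilities)
  for (lam in c(0.5, 1, 2)) for (tt in c(0.5, 1, 3)) {
    m <- poissonModel(lam)
    got <- evaluateTrie(buildPathTrie(paths), net, spreadParams(m, tt, lMax = 8))
    D <- function(L) spreadProb(m, L, tt)
    expect_lt(abs(got - (D(7) + D(8) - D(7) * D(8) / D(6))), 1e-12)
  }
})

test_that("trie evaluation agrees with the pairwise reference everywhere", {
  p <- poisParams(1, 1, lMax = 8)
  net <- workedExampleNetwork()
  paths <- enumeratePaths(net, "1", lMax = 8)[["4"]]
  expect_lt(abs(evaluateTrie(buildPathTrie(paths), net, p) -
                pairwiseReference(paths, net, p)), 1e-12)
  # randomized instances, unit node weights, random link weights
  set.seed(71)
  for (rep in 1:20) {
    net <- randomConnected(6, 0.4, seed = rep)
    lt <- linkTable(net)
    keep <- lt$from < lt$to
    lt$weight[keep] <- round(runif(sum(keep), 0.3, 1), 3)
    lt$weight[!keep] <- lt$weight[match(paste(lt$to, lt$from)[!keep],
                                        paste(lt$from, lt$to))]
    net <- newSpreadNetwork(lt[keep, ], directed = FALSE)
    pl <- enumeratePaths(net, "1", lMax = 5)
    for (target in names(pl)) {
      if (length(pl[[target]]) > 25L) next
      expect_lt(abs(evaluateTrie(buildPathTrie(pl[[target]]), net, p) -
                    pairwiseReference(pl[[target]], net, p)), 1e-12)
    }
  }
})

test_that("certainty and degenerate limits behave", {
  ch <- chainNet(2)
  # connected pair, all weights 1, huge time: influence is certain
  expect_equal(evaluateTrie(
    buildPathTrie(enumeratePaths(ch, "1", lMax = 1)[["2"]]),
    ch, poisParams(1, 1e4, 1)), 1, tolerance = 1e-9)
  expect_equal(evaluateTrie(NULL, ch, poisParams(1, 1, 1)), 0)
})

test_that("the influence matrix honors diagonal and reachability conventions", {
  net <- workedExampleNetwork()
  im0 <- influenceMatrix(net, poisParams(1, 0, lMax = 8))
  expect_equal(unname(diag(im0@.Data)), rep(1, 9))
  expect_true(all(im0@.Data[row(im0@.Data) != col(im0@.Data)] == 0))

  # isolated node: zero row and column off-diagonal at any time
  withIso <- newSpreadNetwork(data.frame(from = c(1, 2), to = c(2, 3)),
                              nodes = "iso")
  for (tt in c(0.5, 5)) {
    im <- influenceMatrix(withIso, poisParams(0.5, tt, lMax = 3))
    off <- setdiff(nodeLabels(withIso), "iso")
    expect_true(all(im["iso", off] == 0))
    expect_true(all(im[off, "iso"] == 0))
    expect_equal(unname(im["iso", "iso"]), 1)
  }

  # community convention flips the diagonal only
  imz <- setDiagonal(im0, 0)
  expect_equal(unname(diag(imz@.Data)), rep(0, 9))
  expect_equal(spreadParams(imz)@selfValue, 0)
})

test_that("influence is monotone in time, weights, lMax and subgraphs", {
  net <- randomConnected(7, 0.3, seed = 12)
  lam <- 0.8
  # time monotonicity, entrywise
  ims <- lapply(c(0.5, 1, 2, 4), function(tt)
    influenceMatrix(net, poisParams(lam, tt, lMax = 6))@.Data)
  for (k in seq_along(ims)[-1L])
    expect_true(all(ims[[k]] >= ims[[k - 1L]] - 1e-12))
  # activity monotonicity
  lo <- net; nodeActivity(lo) <- 0.4
  hi <- net; nodeActivity(hi) <- 0.9
  expect_true(all(influenceMatrix(hi, poisParams(lam, 1, 6))@.Data >=
                  influenceMatrix(lo, poisParams(lam, 1, 6))@.Data - 1e-12))
  # lMax monotonicity
  for (l in 2:5)
    expect_true(all(influenceMatrix(net, poisParams(lam, 1, l + 1L))@.Data >=
                    influenceMatrix(net, poisParams(lam, 1, l))@.Data - 1e-12))
  # deleting any link never increases any entry
  full <- influenceMatrix(net, poisParams(lam, 1, 6))@.Data
  lt <- linkTable(net)
  lt <- lt[lt$from < lt$to, ]
  for (k in seq_len(nrow(lt))) {
    sub <- newSpreadNetwork(lt[-k, ], nodes = nodeLabels(net))
    expect_true(all(influenceMatrix(sub, poisParams(lam, 1, 6))@.Data <=
                    full + 1e-12))
  }
  # probabilities stay inside [0, 1] throughout
  expect_true(all(full >= 0 & full <= 1))
})

test_that("chain influence is exactly the unique path probability", {
  ch <- chainNet(5)
  p <- poisParams(1.2, 1.5, lMax = 4)
  im <- influenceMatrix(ch, p)
  for (t in 2:5) {
    expect_equal(unname(im["1", as.character(t)]),
                 pathProbability(as.character(1:t), ch, p),
                 tolerance = 1e-12)
  }
})

test_that("matrix CSV output round-trips with its metadata sidecar", {
  net <- chainNet(3)
  p <- poisParams(0.5, 2, lMax = 2)
  im <- influenceMatrix(net, p)
  f <- withr::local_tempfile(fileext = ".csv")
  writeInfluenceMatrix(im, f)
  back <- read.csv(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(im@.Data), ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(meta$time, 2)
  expect_equal(meta$lambda, 0.5)
  expect_equal(meta$mode, "self_avoiding")
})
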