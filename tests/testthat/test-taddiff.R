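test_that("hypergeometric upper tail matches enumeration and edge cases", {
  expect_equal(tadHypergeomTest(10, 5, 4, 0), 1)
  expect_equal(tadHypergeomTest(10, 5, 4, 4), 5 / 210)
  expect_equal(tadHypergeomTest(10, 5, 10, 5), 1)   # whole universe drawn
  expect_error(tadHypergeomTest(10, 11, 4, 0), "inconsistent")
  expect_error(tadHypergeomTest(10, 5, 4, 5), "inconsistent")
  set.seed(88)
  for (i in 1:200) {
    N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(tadHypergeomTest(N, K, n, k), hyperUpperEnum(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("the hypergeometric tail is non-increasing in k", {
  for (N in c(10, 37)) for (K in c(3, N %/% 2)) for (n in c(5, N %/% 2)) {
    ks <- 0:min(K, n)
    p <- vapply(ks, function(k) tadHypergeomTest(N, K, n, k), 0)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("activation averages |logFC| over expression events only", {
  expect_equal(tadActivation(-3, "count"), 3)
  expect_equal(tadActivation(c(2, -4, 50), c("count", "count", "freq")), 3)
  expect_equal(tadActivation(c(5, 8), c("freq", "freq")), 0)
  expect_equal(tadActivation(numeric(), character()), 0)
})

test_that("with no significant events every TAD has p = 1 and no calls", {
  set.seed(99)
  m <- 200
  x <- matrix(rnorm(m * 20, 50, 5), m)
  x <- pmin(pmax(x, 0), 100)
  agg <- makeAgg(x, tad_id = rep(sprintf("T%02d", 1:20), each = 10))
  meta <- data.frame(group = rep(c(0, 1), each = 10),
                     row.names = colnames(agg))
  ev <- eventDiffRun(agg, meta, "group")
  ev$significant[] <- FALSE             # force the empty-K case
  td <- tadDiffRun(agg, ev, "group")
  expect_true(all(td$hyper_p == 1))
  expect_equal(sum(td$significant), 0L)
  ## partition conservation: TAD event counts sum to assigned events
  expect_equal(sum(td$n_events), sum(!is.na(tadIds(agg)) & ev$included))
})

test_that("a fully shifted TAD is the top-ranked hypergeometric hit", {
  set.seed(111)
  nT <- 30; per <- 10
  x <- matrix(rnorm(nT * per * 24, 50, 5), nT * per)
  tad <- rep(sprintf("T%02d", 1:nT), each = per)
  x[tad == "T07", 13:24] <- x[tad == "T07", 13:24] + 30
  x <- pmin(pmax(x, 0), 100)
  kind <- rep(c("freq", "count"), length.out = nrow(x))
  agg <- makeAgg(x, tad_id = tad, kind = kind,
                 source = ifelse(kind == "freq", "meth.txt", "expr.txt"))
  meta <- data.frame(group = rep(c(0, 1), each = 12),
                     row.names = colnames(agg))
  ev <- eventDiffRun(agg, meta, "group")
  td <- tadDiffRun(agg, ev, "group")
  expect_equal(td$tad_id[1], "T07")
  expect_true(td$significant[td$tad_id == "T07"])
  expect_lte(sum(td$significant), 2)
})

test_that("per-TAD sample means match a naive loop", {
  x <- matrix(c(10, 20, 30, 40, 5, 6, 7, 8), 4, 2, byrow = TRUE,
              dimnames = list(paste0("e", 1:4), c("S1", "S2")))
  agg <- makeAgg(x, tad_id = c("T1", "T1", "T2", NA))
  tm <- tadSampleMeans(agg)
  expect_equal(tm["T1", ], c(S1 = 20, S2 = 30))
  expect_equal(tm["T2", ], c(S1 = 5, S2 = 6))   # single-event TAD
  ## random instance vs loop oracle, with NAs
  set.seed(123)
  y <- matrix(runif(300, 0, 100), 30, 10,
              dimnames = list(sprintf("r%02d", 1:30), sprintf("S%02d", 1:10)))
  y[sample(300, 25)] <- NA
  tads <- sample(c("A", "B", "C", NA), 30, replace = TRUE)
  agg2 <- makeAgg(y, tad_id = tads)
  tm2 <- tadSampleMeans(agg2)
  for (td in c("A", "B", "C"))
    for (s in colnames(y))
      expect_equal(tm2[td, s], mean(y[which(tads == td), s], na.rm = TRUE))
})

test_that("per-TAD mean absolute group difference matches a loop oracle", {
  set.seed(321)
  y <- matrix(runif(200, 0, 100), 20, 10,
              dimnames = list(sprintf("r%02d", 1:20),
                              sprintf("S%02d", 1:10)))
  tads <- rep(c("A", "B"), each = 10)
  agg <- makeAgg(y, tad_id = tads)
  g <- setNames(rep(c(0, 1), each = 5), colnames(y))
  got <- tadAbsDiffMeans(agg, g)
  for (td in c("A", "B")) {
    rows <- which(tads == td)
    ref <- mean(vapply(rows, function(i)
      abs(mean(y[i, 6:10]) - mean(y[i, 1:5])), 0))
    expect_equal(unname(got[td]), ref)
  }
  ## identical groups give zero
  y2 <- y; y2[, 6:10] <- y2[, 1:5]
  agg2 <- makeAgg(y2, tad_id = tads)
  expect_equal(unname(tadAbsDiffMeans(agg2, g)), c(0, 0))
})

test_that("tadDiffRun writes the TADiff file suite", {
  dir <- withr::local_tempdir()
  b <- generateBundle(file.path(dir, "b"), nTads = 15, eventsPerTad = 12,
                      nPlantedTads = 2, effect = 30, seed = 14)
  res <- runPipeline(b, outDir = file.path(dir, "out"))
  path <- file.path(dir, "out", "group_TADiff.txt")
  expect_true(file.exists(path))
  sm <- read.delim(file.path(dir, "out", "Summary_TADiff.txt"))
  expect_equal(sm$n_TADs_tested, nrow(res$tads))
  expect_equal(sm$n_significant, sum(res$tads$significant))
  head <- read.delim(path, nrows = nrow(res$tads))
  expect_equal(head$tad_id, res$tads$tad_id)
})
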