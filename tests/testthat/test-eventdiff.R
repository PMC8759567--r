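test_that("two-group fit matches the hand-computed pooled variance", {
  x <- matrix(c(10, 12, 20, 22), 1, 4,
              dimnames = list("e1", c("a1", "a2", "b1", "b2")))
  g <- c(a1 = 0, a2 = 0, b1 = 1, b2 = 1)
  fit <- fitTwoGroup(x, g)
  expect_equal(fit$logFC, 10)
  expect_equal(fit$AveExpr, 16)
  expect_equal(fit$s2, 2)       # ((12-11)^2+(10-11)^2+(22-21)^2+(20-21)^2)/2
  expect_equal(fit$df, 2L)
})

test_that("the fit is antisymmetric in group labels and null on identical groups", {
  set.seed(11)
  x <- matrix(runif(40, 0, 100), 4, 10,
              dimnames = list(paste0("e", 1:4), paste0("S", 1:10)))
  g <- setNames(rep(c(0, 1), each = 5), colnames(x))
  fit <- fitTwoGroup(x, g)
  swap <- fitTwoGroup(x, setNames(1 - g, names(g)))
  expect_equal(swap$logFC, -fit$logFC)
  expect_equal(swap$s2, fit$s2)
  same <- matrix(rep(x[, 1:5], 2), 4, 10,
                 dimnames = dimnames(x))
  expect_equal(fitTwoGroup(same, g)$logFC, rep(0, 4))
})

test_that("NA cells are excluded pairwise and short events are flagged", {
  x <- matrix(runif(20, 0, 100), 2, 10,
              dimnames = list(c("e1", "e2"), paste0("S", 1:10)))
  x["e2", 1:4] <- NA                    # leaves 1 usable group-0 sample
  g <- setNames(rep(c(0, 1), each = 5), colnames(x))
  fit <- fitTwoGroup(x, g)
  expect_true(fit["e1", "included"])
  expect_false(fit["e2", "included"])
  expect_true(is.na(fit["e2", "logFC"]))
  ## whole-contrast failure is a hard error
  expect_error(fitTwoGroup(x[, 1:3], setNames(c(0, 0, 1), paste0("S", 1:3))),
               ">= 2 samples")
})

test_that("identical variances give an infinite prior; tiny inputs error", {
  p <- estimateModeration(rep(2.5, 50), rep(10, 50))
  expect_equal(p$d0, Inf)
  expect_equal(p$s0_2, 2.5, tolerance = 1e-6)
  expect_error(estimateModeration(c(1, 2), c(4, 4)), ">= 10 events")
  expect_error(estimateModeration(rep(0, 20), rep(4, 20)), "zero")
})

test_that("the moment estimator recovers a planted variance prior", {
  set.seed(2024)
  d0 <- 4; s02 <- 2; G <- 5000; df <- 10
  sigma2 <- d0 * s02 / rchisq(G, d0)          # scaled inverse chi-square
  s2 <- sigma2 * rchisq(G, df) / df
  p <- estimateModeration(s2, rep(df, G))
  expect_lt(abs(p$d0 - d0) / d0, 0.25)
  expect_lt(abs(p$s0_2 - s02) / s02, 0.10)
})

test_that("moderated t reduces to the ordinary t as the prior vanishes", {
  set.seed(33)
  x <- matrix(runif(200, 0, 100), 20, 10,
              dimnames = list(paste0("e", 1:20), paste0("S", 1:10)))
  g <- setNames(rep(c(0, 1), each = 5), colnames(x))
  fit <- fitTwoGroup(x, g)
  mod <- moderateStats(fit, list(d0 = 1e-12, s0_2 = 1))
  ref <- pooledTLoop(x, paste0("S", 1:5), paste0("S", 6:10))
  expect_equal(mod$t, unname(ref[, "t"]), tolerance = 1e-9)
})

test_that("zero-variance events get finite moderated t under a finite prior", {
  x <- matrix(c(rep(10, 5), rep(20, 5)), 1, 10,
              dimnames = list("e1", paste0("S", 1:10)))
  g <- setNames(rep(c(0, 1), each = 5), colnames(x))
  fit <- fitTwoGroup(x, g)
  expect_equal(fit$s2, 0)
  mod <- moderateStats(fit, list(d0 = 4, s0_2 = 2))
  expect_true(is.finite(mod$t))
  expect_gt(mod$s2_post, 0)
})

test_that("moderated statistics match an independently coded evaluation", {
  set.seed(44)
  n0 <- 6; n1 <- 8
  sd <- sqrt(rchisq(100, 6) / 6) * 8      # heterogeneous event variances
  x <- matrix(rnorm(100 * (n0 + n1), 50, rep(sd, n0 + n1)), 100,
              dimnames = list(paste0("e", 1:100),
                              paste0("S", 1:(n0 + n1))))
  g <- setNames(rep(c(0, 1), c(n0, n1)), colnames(x))
  fit <- fitTwoGroup(x, g)
  params <- estimateModeration(fit$s2, fit$df)
  mod <- moderateStats(fit, params)
  ## brute re-evaluation of the same formulas, scalar loop
  for (i in sample(100, 20)) {
    a <- x[i, 1:n0]; b <- x[i, n0 + 1:n1]
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n0 + n1 - 2)
    st <- (params$d0 * params$s0_2 + (n0 + n1 - 2) * s2) /
      (params$d0 + n0 + n1 - 2)
    tt <- (mean(b) - mean(a)) / sqrt(st * (1 / n0 + 1 / n1))
    expect_equal(mod$t[i], tt, tolerance = 1e-10)
    expect_equal(mod$P.Value[i],
                 2 * pt(-abs(tt), params$d0 + n0 + n1 - 2),
                 tolerance = 1e-10)
  }
  ## shift invariance: adding a constant to one event changes nothing
  x2 <- x; x2[7, ] <- x2[7, ] + 13.5
  fit2 <- fitTwoGroup(x2, g)
  mod2 <- moderateStats(fit2, params)
  expect_equal(mod2$t[7], mod$t[7], tolerance = 1e-9)
})

test_that("moderation agrees with the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(55)
  n0 <- 7; n1 <- 9
  x <- matrix(rnorm(500 * (n0 + n1), 50, 6) *
                rep(sqrt(rchisq(500, 8) / 8), n0 + n1),
              500, dimnames = list(paste0("e", 1:500),
                                   paste0("S", 1:(n0 + n1))))
  g <- setNames(rep(c(0, 1), c(n0, n1)), colnames(x))
  fit <- fitTwoGroup(x, g)
  params <- estimateModeration(fit$s2, fit$df)
  mod <- moderateStats(fit, params)
  design <- cbind(1, rep(c(0, 1), c(n0, n1)))
  lfit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(params$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(params$s0_2, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mod$logFC, unname(lfit$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(mod$t, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(mod$P.Value, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0,1\\]")
  p <- c(0.2, NA, 0.01)
  adj <- bhAdjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bhOracle(p[c(1, 3)]))
})

test_that("BH adjustment equals the sort/cummin/unsort oracle on random vectors", {
  set.seed(66)
  for (i in 1:300) {
    p <- runif(sample(1:60, 1))^sample(c(0.5, 1, 3), 1)
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("eventDiffRun writes its file suite and is deterministic", {
  dir <- withr::local_tempdir()
  b <- generateBundle(file.path(dir, "b"), nTads = 20, eventsPerTad = 10,
                      nPlantedTads = 2, effect = 25, seed = 9)
  res <- runPipeline(b, outDir = file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out", "group_evenDiff.txt")))
  sm <- read.delim(file.path(dir, "out", "Summary_evenDiff.txt"))
  expect_equal(sm$n_events_tested, sum(res$events$included))
  expect_equal(sm$n_significant, sum(res$events$significant))
  ## duplicate rows get identical statistics
  ev <- res$events
  expect_true(all(ev$adj.P.Val >= ev$P.Value - 1e-12, na.rm = TRUE))
  res2 <- runPipeline(b)
  expect_identical(res2$events$t, res$events$t)
})

test_that("a planted mean shift is recovered in nearly all planted events", {
  set.seed(77)
  m <- 500; nPlanted <- 50; n <- 20
  x <- matrix(rnorm(m * 2 * n, 50, 6), m,
              dimnames = list(sprintf("e%03d", 1:m),
                              sprintf("S%03d", 1:(2 * n))))
  x[1:nPlanted, n + 1:n] <- x[1:nPlanted, n + 1:n] + 30
  x <- pmin(pmax(x, 0), 100)
  agg <- makeAgg(x, tad_id = rep("T1", m))
  meta <- data.frame(group = rep(c(0, 1), each = n),
                     row.names = colnames(x))
  ev <- eventDiffRun(agg, meta, "group")
  expect_gte(sum(ev$significant[1:nPlanted]), 45)
  ## and essentially nothing among the nulls
  expect_lte(sum(ev$significant[-(1:nPlanted)]), 2)
})
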