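test_that("pairCovariance reproduces the classical twin structure", {
  sg <- pairCovariance(list(c(1, 0, 0)), zygosity = "MZ")
  expect_equal(sg[1, 2], 1)
  sg <- pairCovariance(list(c(0, 0, 1)), zygosity = "MZ")
  expect_equal(sg[1, 2], 0)
  sg <- pairCovariance(list(c(0.6, 0.2, 0.2)), zygosity = "DZ")
  expect_equal(sg[1, 2], 0.5 * 0.6 + 0.2)

  ## two traits, E-only: twins independent (block diagonal)
  sg4 <- pairCovariance(list(c(0, 0, 1), c(0, 0, 1)), zygosity = "MZ")
  expect_equal(sg4[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(diag(sg4), rep(1, 4))

  expect_error(pairCovariance(list(c(0.5, 0.6, 0.2)), zygosity = "MZ"), "sum to 1")
  expect_error(pairCovariance(list(c(.5, 0, .5), c(.5, 0, .5)),
                              cross = list(iCud = 2, iMdd = 0.5),
                              zygosity = "MZ"), "singular")
})

test_that("causal pair covariance matches a brute-force structural simulation", {
  iCud <- 0.5
  aceM <- c(0.5, 0.1, 0.4)
  aceC <- c(0.7, 0, 0.3)
  sg <- pairCovariance(list(aceM, aceC), cross = list(iCud = iCud), zygosity = "DZ")
  ## within-person cross-trait covariance = iCud / sd(MDD total)
  expect_equal(sg[1, 2], iCud / sqrt(1 + iCud^2), tolerance = 1e-10)

  ## Monte-Carlo oracle: simulate the structural equations directly
  set.seed(21)
  n <- 1e6
  mkTrait <- function(ace) {
    a0 <- rnorm(n)
    A <- sqrt(.5) * a0 + sqrt(.5) * cbind(rnorm(n), rnorm(n))
    C <- rnorm(n)
    sqrt(ace[1]) * A + sqrt(ace[2]) * C + sqrt(ace[3]) * cbind(rnorm(n), rnorm(n))
  }
  eM <- mkTrait(aceM)
  eC <- mkTrait(aceC)
  M <- (eM + iCud * eC) / sqrt(1 + iCud^2)  # standardised total MDD liability
  X <- cbind(M[, 1], eC[, 1], M[, 2], eC[, 2])
  expect_equal(cov(X), sg, tolerance = 6e-3)
})

test_that("band probabilities match closed forms", {
  ## four independent liabilities, all cut at 0: every orthant 1/16
  sg4 <- pairCovariance(list(c(0, 0, 1), c(0, 0, 1)), zygosity = "MZ")
  p <- mvnBandProbs(sg4, cuts = list(0, 0))
  expect_equal(as.vector(p), rep(1 / 16, 16), tolerance = 1e-9)

  ## bivariate, r = 0.5, cuts 0: P(both above) = 1/4 + asin(.5)/(2 pi) = 1/3
  sg2 <- pairCovariance(list(c(0.5, 0, 0.5)), zygosity = "MZ")
  p2 <- mvnBandProbs(sg2, cuts = 0)
  expect_equal(p2[2, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(sum(p2), 1, tolerance = 1e-12)

  ## orthant identity on a grid of correlations
  for (r in c(-0.9, -0.4, 0.2, 0.7, 0.95)) {
    ace <- if (r >= 0) list(c(r, 0, 1 - r)) else NULL
    sgr <- matrix(c(1, r, r, 1), 2)
    pr <- mvnBandProbs(sgr, cuts = 0)
    expect_equal(pr[2, 2], 1 / 4 + asin(r) / (2 * pi), tolerance = 1e-12)
  }
})

test_that("4-dim band probabilities agree with a Monte-Carlo oracle", {
  ace <- list(c(0.5, 0.1, 0.4), c(0.7, 0.05, 0.25))
  sg <- pairCovariance(ace, cross = list(rA = 0.5, rC = 0.3, rE = 0.2),
                       zygosity = "DZ")
  cuts <- list(0.66, 0.99)
  p <- mvnBandProbs(sg, cuts)
  expect_equal(sum(p), 1, tolerance = 1e-8)

  set.seed(31)
  n <- 1e6
  e <- eigen(sg, symmetric = TRUE)
  X <- matrix(rnorm(4 * n), n) %*% t(e$vectors %*% diag(sqrt(pmax(e$values, 0))))
  for (b1 in 1:2) for (b2 in 1:2) for (b3 in 1:2) for (b4 in 1:2) {
    inb <- function(x, cut, b) if (b == 1) x <= cut else x > cut
    emp <- mean(inb(X[, 1], 0.66, b1) & inb(X[, 2], 0.99, b2) &
                  inb(X[, 3], 0.66, b3) & inb(X[, 4], 0.99, b4))
    se <- sqrt(max(p[b1, b2, b3, b4] * (1 - p[b1, b2, b3, b4]), 1e-12) / n)
    expect_lt(abs(emp - p[b1, b2, b3, b4]), 3 * se + 1e-5)
  }
})

test_that("band probabilities sum to 1 across random model draws", {
  set.seed(41)
  for (rep in 1:20) {
    a2 <- runif(2, 0, 0.95)
    c2 <- runif(2, 0, 1 - a2)
    ace <- list(c(a2[1], c2[1], 1 - a2[1] - c2[1]),
                c(a2[2], c2[2], 1 - a2[2] - c2[2]))
    r3 <- runif(3, -0.6, 0.9)
    z <- sample(c("MZ", "DZ"), 1)
    sg <- pairCovariance(ace, cross = list(rA = r3[1], rC = r3[2], rE = r3[3]),
                         zygosity = z)
    p <- mvnBandProbs(sg, cuts = list(runif(1, -1, 1.5), runif(1, -1, 1.5)))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("band probabilities respect twin exchange symmetry", {
  ace <- list(c(0.45, 0.1, 0.45), c(0.75, 0, 0.25))
  sg <- pairCovariance(ace, cross = list(rA = 0.4, rC = 0, rE = 0.2),
                       zygosity = "DZ")
  p <- mvnBandProbs(sg, cuts = list(0.5, 1.1))
  expect_equal(p, aperm(p, c(3, 4, 1, 2)), tolerance = 1e-9)
})

test_that("MZ probabilities depend on a2 + c2 only; DZ separate the two", {
  mk <- function(a2, c2, z) {
    sg <- pairCovariance(list(c(a2, c2, 1 - a2 - c2)), zygosity = z)
    mvnBandProbs(sg, cuts = 0.7)
  }
  expect_equal(mk(0.6, 0.2, "MZ"), mk(0.3, 0.5, "MZ"), tolerance = 1e-12)
  expect_gt(max(abs(mk(0.6, 0.2, "DZ") - mk(0.3, 0.5, "DZ"))), 1e-3)
})

test_that("concordance probability is monotone in the cross-twin correlation", {
  probBoth <- function(r) {
    p <- mvnBandProbs(matrix(c(1, r, r, 1), 2), cuts = 0.8)
    p[2, 2]
  }
  vals <- vapply(seq(0, 0.95, by = 0.05), probBoth, numeric(1))
  expect_true(all(diff(vals) > 0))
})
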