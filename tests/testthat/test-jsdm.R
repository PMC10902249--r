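# simulate directly from the latent-factor probit model
simulateJsdmData <- function(n, Lambda, beta, seed) {
  set.seed(seed)
  J <- nrow(Lambda); q <- ncol(Lambda); p <- nrow(beta)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  U <- matrix(rnorm(n * q), n, q)
  Z <- X %*% beta + U %*% t(Lambda) + matrix(rnorm(n * J), n, J)
  list(Y = (Z > 0) * 1L, X = X,
       species = paste0("sp", seq_len(J)))
}

trueResidualCorrelation <- function(Lambda) {
  stats::cov2cor(tcrossprod(Lambda) + diag(nrow(Lambda)))
}

test_that("site matrix standardizes covariates and aligns habitats", {
  s <- defaultStack()
  hsi1 <- hsiFromMatrix(nicheSuitability(s, nicheSpec(c(sst = 2), c(sst = 2))),
                        s@grid)
  hsi2 <- hsiFromMatrix(nicheSuitability(s, nicheSpec(c(sst = 0), c(sst = 2))),
                        s@grid)
  habs <- list(a = binarizeTop5(hsi1), b = binarizeTop5(hsi2))
  m <- buildSiteMatrix(habs, s, subsample = 500, seed = 1)
  expect_equal(nrow(m$Y), 500L)
  expect_equal(colnames(m$X)[1], "intercept")
  for (k in 2:ncol(m$X)) {
    expect_lt(abs(mean(m$X[, k])), 1e-9)
    expect_lt(abs(stats::sd(m$X[, k]) - 1), 1e-9)
  }
  # subsample = NULL keeps every complete ocean cell
  mAll <- buildSiteMatrix(habs, s, subsample = NULL)
  expect_equal(nrow(mAll$Y), sum(oceanMask(s)))
  expect_error(buildSiteMatrix(list(a = habs$a, b = NULL), s),
               "missing a habitat map")
})

test_that("zero latent factors reduce to independent probits with identity R", {
  d <- simulateJsdmData(150, matrix(0, 3, 1), matrix(c(0, 1, 0, -1, 0.5, 0.2),
                                                     2, 3), seed = 2)
  post <- fitJsdm(list(Y = d$Y, X = d$X, species = d$species), q = 0,
                  nIter = 300, burn = 100, thin = 2, seed = 3)
  R <- residualCorrelation(post)
  expect_equal(associationCorrelation(R), diag(3), ignore_attr = TRUE)
  expect_false(any(associationSignificant(R)))
})

test_that("residual correlation closed forms and matrix validity", {
  # lambda_j = lambda_k = (1, 0) -> R_jk = 1/2
  post <- structure(list(
    Lambda = array(rep(c(1, 1, 0, 0, 0, 0), each = 1), c(1, 3, 2)),
    beta = array(0, c(1, 1, 3)), species = c("a", "b", "c"), q = 2),
    class = "jsdmPosterior")
  post$Lambda[1, , ] <- cbind(c(1, 1, 0), c(0, 0, 0))
  R <- associationCorrelation(residualCorrelation(post))
  expect_equal(R[1, 2], 0.5)
  expect_equal(R[1, 3], 0)
  expect_equal(diag(R), rep(1, 3))
  expect_equal(R, t(R))
  expect_true(min(eigen(R, symmetric = TRUE)$values) > -1e-8)
})

test_that("the Gibbs sampler is deterministic given a seed", {
  d <- simulateJsdmData(100, cbind(c(1, -1, 0.5)), matrix(0, 1, 3), seed = 4)
  m <- list(Y = d$Y, X = d$X, species = d$species)
  a <- fitJsdm(m, q = 1, nIter = 200, burn = 50, thin = 1, seed = 9)
  b <- fitJsdm(m, q = 1, nIter = 200, burn = 50, thin = 1, seed = 9)
  expect_identical(a$Lambda, b$Lambda)
  expect_identical(a$beta, b$beta)
  c <- fitJsdm(m, q = 1, nIter = 200, burn = 50, thin = 1, seed = 10)
  expect_false(identical(a$Lambda, c$Lambda))
})

test_that("shared and opposed latent loadings recover signed associations", {
  Lambda <- cbind(c(1.2, 1.1, -1.1, 0.1), c(0, 0.2, 0.3, 1.0))
  beta <- matrix(c(0, 0.8, 0, -0.6, 0, 0.4, 0, 0.2), 2, 4)
  d <- simulateJsdmData(400, Lambda, beta, seed = 5)
  post <- fitJsdm(list(Y = d$Y, X = d$X, species = d$species), q = 2,
                  nIter = 1500, burn = 500, thin = 2, seed = 6)
  R <- associationCorrelation(residualCorrelation(post))
  truth <- trueResidualCorrelation(Lambda)
  # species 1-2 share a factor (positive), 1-3 oppose (negative)
  expect_gt(truth[1, 2], 0.4)
  expect_lt(truth[1, 3], -0.4)
  expect_gt(R[1, 2], 0.2)
  expect_lt(R[1, 3], -0.2)
})

test_that("association averaging pools draws and checks species order", {
  Rt <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  mk <- function(R, draws) {
    structure(new("AssociationMatrix", correlation = R,
                  significant = matrix(FALSE, 2, 2), species = c("a", "b")),
              draws = draws)
  }
  d1 <- array(0, c(50, 2, 2)); d1[, 1, 2] <- d1[, 2, 1] <- 0.5
  d1[, 1, 1] <- d1[, 2, 2] <- 1
  a1 <- mk(Rt, d1)
  R2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  d2 <- d1; d2[, 1, 2] <- d2[, 2, 1] <- 0.3
  a2 <- mk(R2, d2)
  avg <- averageAssociations(list(a1, a2))
  expect_equal(associationCorrelation(avg)[1, 2], 0.4)
  expect_true(associationSignificant(avg)[1, 2])  # pooled draws all positive
  expect_equal(associationCorrelation(avg), t(associationCorrelation(avg)))
  # identical matrices average to themselves
  same <- averageAssociations(list(a1, a1))
  expect_equal(associationCorrelation(same), Rt)

  bad <- new("AssociationMatrix", correlation = Rt,
             significant = matrix(FALSE, 2, 2), species = c("b", "a"))
  expect_error(averageAssociations(list(a1, bad)), "species order")
})

test_that("chain and model-shape guards fire", {
  d <- simulateJsdmData(50, cbind(c(1, -1)), matrix(0, 1, 2), seed = 7)
  m <- list(Y = d$Y, X = d$X, species = d$species)
  expect_error(fitJsdm(m, q = 2), "q must be smaller")
  expect_error(fitJsdm(m, q = 1, nIter = 100, burn = 100), "exceed burn-in")
  mBad <- m; mBad$Y[1, 1] <- 2
  expect_error(fitJsdm(mBad, q = 1, nIter = 100, burn = 10), "binary")
})
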