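#' Build the site x species matrix for the joint model
#'
#' Rows are (optionally subsampled) ocean cells; the response column for
#' each species comes from its binary habitat map, and the covariate matrix
#' holds the six dynamic environmental variables standardized to mean 0,
#' SD 1 (plus an intercept column). Bathymetry-static depth is included as a
#' covariate too since it shapes shelf species.
#'
#' @param binaryHabitats named list of [BinaryHabitat-class], one per
#'   species, sharing a grid.
#' @param stack the [EnvStack-class] the habitats were derived from.
#' @param subsample number of ocean cells to keep (NULL = all), sampled
#'   without replacement.
#' @param seed integer seed for the subsample.
#' @return list(Y = sites x J binary matrix, X = sites x (p+1) design with
#'   intercept, cells = linear cell indices, species).
#' @export
buildSiteMatrix <- function(binaryHabitats, stack, subsample = 1000, seed = 1) {
  if (is.null(names(binaryHabitats)) || any(names(binaryHabitats) == ""))
    stopf("binaryHabitats must be a named list (species names)")
  g <- stack@grid
  for (sp in names(binaryHabitats)) {
    b <- binaryHabitats[[sp]]
    if (is.null(b)) stopf("species '%s' is missing a habitat map", sp)
    if (!identical(b@grid, g)) stopf("habitat grid mismatch for '%s'", sp)
  }
  ocean <- which(oceanMask(stack))
  # keep only cells valid in every habitat map and covariate
  covDf <- as.data.frame(lapply(stats::setNames(ENV_VARS, ENV_VARS),
                                function(v) stack@fields[[v]][ocean]))
  ok <- stats::complete.cases(covDf)
  for (b in binaryHabitats) ok <- ok & !is.na(b@suitable[ocean])
  cells <- ocean[ok]
  if (!is.null(subsample) && subsample < length(cells)) {
    set.seed(childSeed(seed, "site-subsample"))
    cells <- sort(sample(cells, subsample))
  }
  Y <- vapply(binaryHabitats, function(b) as.integer(b@suitable[cells]),
              integer(length(cells)))
  X <- vapply(stats::setNames(ENV_VARS, ENV_VARS),
              function(v) stack@fields[[v]][cells], numeric(length(cells)))
  Xs <- scale(X)
  keep <- apply(is.finite(Xs), 2, all)  # drop constant covariates
  Xs <- cbind(intercept = 1, Xs[, keep, drop = FALSE])
  list(Y = Y, X = Xs, cells = cells, species = names(binaryHabitats))
}

# Vectorized truncated-normal draws: z ~ N(mu, 1) truncated to z > 0 where
# positive, z <= 0 otherwise. Inverse-CDF with clamped tail probabilities.
rtruncProbit <- function(mu, positive) {
  p0 <- stats::pnorm(-mu)            # P(z <= 0)
  u <- stats::runif(length(mu))
  p <- ifelse(positive, p0 + u * (1 - p0), u * p0)
  p <- clip(p, 1e-12, 1 - 1e-12)
  mu + stats::qnorm(p)
}

#' Fit the latent-factor probit joint species distribution model
#'
#' Gibbs sampler for y_ij ~ Bernoulli(Phi(x_i' beta_j + lambda_j' z_i)) with
#' site scores z_i ~ N(0, I_q): truncated-normal data augmentation for the
#' probit likelihood, conjugate normal updates for species coefficients
#' (prior N(0, 10^2)), factor loadings (prior N(0, 1), upper triangle fixed
#' at zero) and site scores. The loading matrix is kept lower-triangular
#' with positive diagonal by deterministic column sign flips after each
#' draw; residual correlations are invariant to those flips. With q = 0 the
#' model reduces to J independent probit regressions.
#'
#' @param m a site matrix from [buildSiteMatrix()] (list with Y, X, species).
#' @param q number of latent factors (default 2; must be < J).
#' @param nIter total Gibbs iterations (default 5000).
#' @param burn burn-in iterations discarded (default 1000).
#' @param thin keep every thin-th post-burn-in draw (default 5).
#' @param seed integer seed; same seed gives identical draw sequences.
#' @param betaPriorSd prior SD of the regression coefficients (default 10).
#' @return object of class \code{jsdmPosterior}: list with Lambda draws
#'   (array draws x J x q), beta draws (array draws x p x J), species, and
#'   the chain settings.
#' @export
fitJsdm <- function(m, q = 2, nIter = 5000, burn = 1000, thin = 5, seed = 1,
                    betaPriorSd = 10) {
  Y <- m$Y; X <- m$X
  J <- ncol(Y); n <- nrow(Y); p <- ncol(X)
  if (J < 2) stopf("need at least 2 species")
  if (q >= J) stopf("q must be smaller than the number of species")
  if (!all(Y %in% c(0, 1))) stopf("response matrix must be binary")
  if (nIter <= burn) stopf("chain length must exceed burn-in")
  set.seed(childSeed(seed, "jsdm"))

  XtX <- crossprod(X)
  priorPrec <- diag(1 / betaPriorSd^2, p)
  betaPrecChol <- chol(XtX + priorPrec)
  pos <- Y == 1

  beta <- matrix(0, p, J)
  Lambda <- matrix(0, J, max(q, 1))
  U <- matrix(0, n, max(q, 1))
  if (q == 0) { Lambda <- matrix(0, J, 0); U <- matrix(0, n, 0) }

  nKeep <- floor((nIter - burn) / thin)
  LambdaDraws <- array(NA_real_, c(nKeep, J, q))
  betaDraws <- array(NA_real_, c(nKeep, p, J))
  kept <- 0

  for (it in seq_len(nIter)) {
    eta <- X %*% beta + (if (q > 0) U %*% t(Lambda) else 0)
    Z <- matrix(rtruncProbit(as.numeric(eta), as.logical(pos)), n, J)

    resid <- Z - (if (q > 0) U %*% t(Lambda) else 0)
    # beta_j | . : N(A^-1 X'r_j, A^-1), A = X'X + prior
    meanB <- backsolve(betaPrecChol,
                       forwardsolve(t(betaPrecChol), crossprod(X, resid)))
    beta <- meanB + backsolve(betaPrecChol, matrix(stats::rnorm(p * J), p, J))

    if (q > 0) {
      E <- Z - X %*% beta
      # site scores u_i | . : N(V L' e_i, V), V = (I + L'L)^-1
      V <- solve(diag(q) + crossprod(Lambda))
      U <- E %*% Lambda %*% V +
        matrix(stats::rnorm(n * q), n, q) %*% chol(V)
      # loadings row j: free elements 1..min(j, q), prior N(0, 1)
      for (j in seq_len(J)) {
        mj <- min(j, q)
        Um <- U[, seq_len(mj), drop = FALSE]
        Aj <- crossprod(Um) + diag(mj)
        cholA <- chol(Aj)
        mu <- backsolve(cholA, forwardsolve(t(cholA), crossprod(Um, E[, j])))
        lam <- mu + backsolve(cholA, stats::rnorm(mj))
        Lambda[j, ] <- 0
        Lambda[j, seq_len(mj)] <- lam
      }
      # identification: positive diagonal via column sign flips
      for (k in seq_len(q)) if (Lambda[k, k] < 0) {
        Lambda[, k] <- -Lambda[, k]
        U[, k] <- -U[, k]
      }
    }

    if (it > burn && (it - burn) %% thin == 0) {
      kept <- kept + 1
      if (q > 0) LambdaDraws[kept, , ] <- Lambda
      betaDraws[kept, , ] <- beta
    }
  }
  structure(list(Lambda = LambdaDraws, beta = betaDraws, species = m$species,
                 q = q, nIter = nIter, burn = burn, thin = thin, seed = seed),
            class = "jsdmPosterior")
}

#' Residual correlation matrix from a fitted joint model
#'
#' Per posterior draw the residual covariance is Sigma = Lambda Lambda' + I
#' and the correlation R_jk = Sigma_jk / sqrt(Sigma_jj Sigma_kk); the point
#' estimate is the posterior mean of R and significance is whether the
#' HPD interval of each pairwise draw sequence excludes zero.
#'
#' @param post a \code{jsdmPosterior} from [fitJsdm()].
#' @param mass HPD mass for the significance mask (default 0.99).
#' @return an [AssociationMatrix-class]; the per-pair draws are attached as
#'   attribute \code{draws} (array draws x J x J) for cross-ESM pooling.
#' @export
residualCorrelation <- function(post, mass = 0.99) {
  J <- length(post$species)
  nd <- dim(post$beta)[1]
  if (is.null(nd) || nd < 1) stopf("posterior holds no draws")
  draws <- array(NA_real_, c(nd, J, J))
  for (d in seq_len(nd)) {
    L <- if (post$q > 0) matrix(post$Lambda[d, , ], J, post$q)
    else matrix(0, J, 0)
    S <- tcrossprod(L) + diag(J)
    draws[d, , ] <- stats::cov2cor(S)
  }
  Rbar <- apply(draws, c(2, 3), mean)
  Rbar <- (Rbar + t(Rbar)) / 2
  diag(Rbar) <- 1
  sig <- matrix(FALSE, J, J)
  for (j in seq_len(J)) for (k in seq_len(J)) if (j != k)
    sig[j, k] <- hpdInterval(draws[, j, k], mass)$significant
  structure(new("AssociationMatrix", correlation = Rbar, significant = sig,
                species = post$species),
            draws = draws)
}

#' Average association matrices across ESMs
#'
#' Entrywise mean of per-ESM residual-correlation matrices. Significance of
#' the averaged matrix is assessed by pooling the per-ESM posterior R draws
#' (carried on each matrix as attribute \code{draws}) and applying one HPD
#' interval to the pooled sample; if any input lacks draws, the fallback
#' mask marks pairs significant in all inputs.
#'
#' @param perEsm list of [AssociationMatrix-class] with identical species.
#' @param mass HPD mass (default 0.99).
#' @return an [AssociationMatrix-class].
#' @export
averageAssociations <- function(perEsm, mass = 0.99) {
  stopifnot(length(perEsm) >= 1)
  sp <- perEsm[[1]]@species
  for (a in perEsm) if (!identical(a@species, sp))
    stopf("species order mismatch between association matrices")
  Rbar <- Reduce(`+`, lapply(perEsm, function(a) a@correlation)) /
    length(perEsm)
  Rbar <- (Rbar + t(Rbar)) / 2
  diag(Rbar) <- 1
  J <- length(sp)
  drawsList <- lapply(perEsm, function(a) attr(a, "draws"))
  sig <- matrix(FALSE, J, J)
  if (!any(vapply(drawsList, is.null, logical(1)))) {
    pooled <- do.call(abind1, drawsList)
    for (j in seq_len(J)) for (k in seq_len(J)) if (j != k)
      sig[j, k] <- hpdInterval(pooled[, j, k], mass)$significant
  } else {
    sig[] <- TRUE
    for (a in perEsm) sig <- sig & a@significant
    diag(sig) <- FALSE
  }
  new("AssociationMatrix", correlation = Rbar, significant = sig, species = sp)
}

# bind arrays along the first dimension (avoids an abind dependency)
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], numeric(1))),
                           d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
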