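# Gaussian linear mixed model engine.
#
# Model: y = X beta + sum_b Z_b u_b + e,  e ~ N(0, I sigma2),
#   u_b ~ N(0, G_b):  iid blocks G_b = I sigma2_b;  a kinship block
#   G = K sigma2_g (handled by multiplying the genotype incidence design
#   with a covariance root L, L L' = K, so the block becomes iid on Z L);
#   and correlated intercept-trend blocks G = I_units (x) Sigma (2x2
#   unstructured).
#
# Estimation maximizes the profiled (restricted) likelihood over
# variance ratios lambda_b = sigma2_b / sigma2 on the log scale
# (correlation via tanh), with beta and sigma2 profiled out by GLS.  All
# per-iteration work happens on q x q cross-products (q = total number of
# random-effect columns), never on n x n covariance matrices; the exact
# dense-covariance likelihood is available separately as directLogLik()
# and serves as the engine's verification oracle.

LOG_LAMBDA_FLOOR <- log(1e-10)
LOG_LAMBDA_CEIL <- log(1e8)

#' Random-effect block constructors
#'
#' \code{iidBlock}: independent effects with a common variance.
#' \code{kinshipBlock}: genotype effects with covariance K sigma2_g,
#' embedded by multiplying the incidence design with [covarianceRoot()] of
#' K. \code{us2Block}: per-unit correlated random intercept and slope with
#' an unstructured 2x2 covariance.
#'
#' @param Z incidence matrix (n x units), e.g. from [stats::model.matrix()].
#' @param label block label; variance components are reported under it.
#' @param K kinship matrix ([KinshipMatrix-class] or plain PSD matrix)
#'   whose rows match the columns of \code{Z}.
#' @param Zint,Ztrend n x units incidence designs for the random intercept
#'   and the random slope (same unit columns, in the same order).
#' @return a block object for [lmmSpec()].
#' @export
iidBlock <- function(Z, label) {
  Z <- as.matrix(Z)
  list(label = label, type = "iid", Z = Z, q = ncol(Z))
}

#' @rdname iidBlock
#' @export
kinshipBlock <- function(Z, K, label = "genotype") {
  Z <- as.matrix(Z)
  Km <- if (methods::is(K, "KinshipMatrix")) kinship(K) else K
  if (!is.null(colnames(Z)) && !is.null(rownames(Km))) {
    if (!all(colnames(Z) %in% rownames(Km)))
      stop("genotypes missing from K: ",
           paste(setdiff(colnames(Z), rownames(Km)), collapse = ", "))
    Km <- Km[colnames(Z), colnames(Z)]
  }
  L <- covarianceRoot(Km)
  list(label = label, type = "kinship", Z = Z %*% L, q = ncol(Z),
       Zraw = Z, K = Km, L = L)
}

#' @rdname iidBlock
#' @export
us2Block <- function(Zint, Ztrend, label) {
  Zint <- as.matrix(Zint); Ztrend <- as.matrix(Ztrend)
  stopifnot(identical(dim(Zint), dim(Ztrend)))
  u <- ncol(Zint)
  Z <- matrix(0, nrow(Zint), 2L * u)
  Z[, seq(1L, 2L * u, 2L)] <- Zint
  Z[, seq(2L, 2L * u, 2L)] <- Ztrend   # unit-major (int, trend) pairs
  list(label = label, type = "us2", Z = Z, q = 2L * u, units = u)
}

#' Model specification for the mixed-model engine
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix with column names; must have full
#'   column rank (prune with [dropAliased()] first if needed).
#' @param blocks list of random-effect blocks ([iidBlock()],
#'   [us2Block()], [kinshipBlock()]); at most one kinship block.
#' @return object of class \code{"lmmSpec"}.
#' @export
lmmSpec <- function(y, X, blocks = list()) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  for (b in blocks) stopifnot(nrow(b$Z) == length(y))
  if (sum(vapply(blocks, function(b) b$type == "kinship", logical(1))) > 1L)
    stop("at most one kinship block is allowed")
  if (anyDuplicated(vapply(blocks, `[[`, "", "label")))
    stop("duplicated block labels")
  structure(list(y = as.numeric(y), X = X, blocks = blocks),
            class = "lmmSpec")
}

#' Drop aliased (collinear) columns from a design matrix
#'
#' @param X design matrix.
#' @param protect column names never dropped (an error if aliased).
#' @return X restricted to a full-rank column set; dropped names in
#'   \code{attr(, "dropped")}.
#' @export
dropAliased <- function(X, protect = character()) {
  qrX <- qr(X)
  if (qrX$rank == ncol(X)) {
    attr(X, "dropped") <- character()
    return(X)
  }
  keep <- qrX$pivot[seq_len(qrX$rank)]
  dropped <- colnames(X)[-keep]
  if (any(dropped %in% protect))
    stop("protected column(s) aliased: ",
         paste(intersect(dropped, protect), collapse = ", "))
  out <- X[, sort(keep), drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

# --- parameter layout ------------------------------------------------------

thetaLayout <- function(blocks) {
  out <- list(); pos <- 1L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    np <- if (b$type == "us2") 3L else 1L
    out[[i]] <- list(label = b$label, type = b$type,
                     idx = seq(pos, length.out = np))
    pos <- pos + np
  }
  attr(out, "nparam") <- pos - 1L
  out
}

# T factor (lower triangular) of Sigma2/sigma2 from (log l1, log l2, atanh rho)
us2Tfactor <- function(th) {
  l1 <- exp(th[1L]); l2 <- exp(th[2L]); rho <- tanh(th[3L])
  c(t11 = sqrt(l1), t21 = rho * sqrt(l2), t22 = sqrt(l2 * (1 - rho^2)))
}

# Column-scale M by Lambda (M %*% Lambda), blockwise.
scaleColsLambda <- function(M, blocks, layout, theta) {
  pos <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; cols <- seq(pos + 1L, pos + b$q); pos <- pos + b$q
    th <- theta[layout[[i]]$idx]
    if (b$type == "us2") {
      tf <- us2Tfactor(th)
      o <- cols[seq(1L, b$q, 2L)]; e <- cols[seq(2L, b$q, 2L)]
      Mo <- M[, o, drop = FALSE]; Me <- M[, e, drop = FALSE]
      M[, o] <- tf["t11"] * Mo + tf["t21"] * Me
      M[, e] <- tf["t22"] * Me
    } else {
      M[, cols] <- M[, cols, drop = FALSE] * exp(th / 2)
    }
  }
  M
}

# Row-scale M by Lambda' (Lambda' %*% M), blockwise.
scaleRowsLambda <- function(M, blocks, layout, theta) {
  pos <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; rows <- seq(pos + 1L, pos + b$q); pos <- pos + b$q
    th <- theta[layout[[i]]$idx]
    if (b$type == "us2") {
      tf <- us2Tfactor(th)
      o <- rows[seq(1L, b$q, 2L)]; e <- rows[seq(2L, b$q, 2L)]
      Mo <- M[o, , drop = FALSE]; Me <- M[e, , drop = FALSE]
      M[o, ] <- tf["t11"] * Mo + tf["t21"] * Me
      M[e, ] <- tf["t22"] * Me
    } else {
      M[rows, ] <- M[rows, , drop = FALSE] * exp(th / 2)
    }
  }
  M
}

# --- engine ---------------------------------------------------------------

# Precompute the cross-products the profiled likelihood needs.  Reused
# across refits that share y and the random design (e.g. a marker scan,
# via engineAddColumns()).
makeEngine <- function(spec) {
  y <- spec$y; X <- spec$X; blocks <- spec$blocks
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(attr(dropAliased(X), "dropped"), collapse = ", "),
         " (remove them with dropAliased())")
  if (n <= p) stop("need n > rank(X)")
  Z <- if (length(blocks)) do.call(cbind, lapply(blocks, `[[`, "Z")) else
    matrix(0, n, 0L)
  list(n = n, p = p, q = ncol(Z), blocks = blocks,
       layout = thetaLayout(blocks), xnames = colnames(X), y = y,
       X = X, Z = Z,
       ZtZ = crossprod(Z), ZtX = crossprod(Z, X), Zty = crossprod(Z, y)[, 1L],
       XtX = crossprod(X), Xty = crossprod(X, y)[, 1L], yty = sum(y * y))
}

# Extend an engine with one additional fixed-effect column without
# recomputing the (expensive) random-design cross-products.  The column
# must be fully observed on the engine's rows.
engineWithColumn <- function(eng, x, name) {
  stopifnot(length(x) == eng$n, !anyNA(x))
  ztx <- if (eng$q > 0L) crossprod(eng$Z, x)[, 1L] else numeric(0)
  Xtx <- crossprod(eng$X, x)[, 1L]
  eng$ZtX <- cbind(eng$ZtX, ztx)
  eng$XtX <- rbind(cbind(eng$XtX, Xtx), c(Xtx, sum(x * x)))
  eng$Xty <- c(eng$Xty, sum(x * eng$y))
  eng$X <- cbind(eng$X, x)
  colnames(eng$X)[ncol(eng$X)] <- name
  eng$xnames <- c(eng$xnames, name)
  dimnames(eng$XtX) <- list(eng$xnames, eng$xnames)
  eng$p <- eng$p + 1L
  eng
}

# Lambda = D + S representation for the compiled congruence kernels:
# d holds per-column scale factors, (o, e, t) the intercept-trend
# couplings (0-based column indices for C++).
lambdaParts <- function(blocks, layout, theta) {
  q <- sum(vapply(blocks, `[[`, 0L, "q"))
  d <- numeric(q); o <- integer(0); e <- integer(0); tt <- numeric(0)
  pos <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; cols <- seq(pos + 1L, pos + b$q); pos <- pos + b$q
    th <- theta[layout[[i]]$idx]
    if (b$type == "us2") {
      tf <- us2Tfactor(th)
      oc <- cols[seq(1L, b$q, 2L)]; ec <- cols[seq(2L, b$q, 2L)]
      d[oc] <- tf["t11"]; d[ec] <- tf["t22"]
      o <- c(o, oc - 1L); e <- c(e, ec - 1L)
      tt <- c(tt, rep(tf["t21"], length(oc)))
    } else d[cols] <- exp(th / 2)
  }
  list(d = d, o = o, e = e, t = tt)
}

# Shared core of the profiled deviance (-2 log lik) at theta: factors and
# GLS quantities reused by the objective, the gradient and the reporting
# step.  Returns NULL on numerical failure (treated as +Inf).
devCore <- function(eng, theta, method) {
  n <- eng$n; p <- eng$p
  nstar <- if (method == "REML") n - p else n
  lp <- NULL
  if (eng$q > 0L) {
    lp <- lambdaParts(eng$blocks, eng$layout, theta)
    B <- .lambdaCongruence(eng$ZtZ, lp$d, lp$o, lp$e, lp$t, 1.0)
    R <- tryCatch(chol(B), error = function(err) NULL)
    if (is.null(R)) return(NULL)
    W <- .lambdaLeft(cbind(eng$ZtX, eng$Zty), lp$d, lp$o, lp$e, lp$t)
    M <- backsolve(R, W, transpose = TRUE)
    Mx <- M[, seq_len(p), drop = FALSE]
    my <- M[, p + 1L]
    S <- eng$XtX - crossprod(Mx)
    r <- eng$Xty - crossprod(Mx, my)[, 1L]
    ldC <- 2 * sum(log(diag(R)))
    qy2 <- sum(my^2)
  } else {
    R <- NULL; Mx <- NULL; my <- numeric(0)
    S <- eng$XtX; r <- eng$Xty; ldC <- 0; qy2 <- 0
  }
  Rs <- tryCatch(chol(S), error = function(err) NULL)
  if (is.null(Rs)) return(NULL)
  u <- backsolve(Rs, r, transpose = TRUE)
  Q <- eng$yty - qy2 - sum(u^2)
  if (!is.finite(Q) || Q <= 0) return(NULL)
  ldS <- 2 * sum(log(diag(Rs)))
  dev <- if (method == "REML")
    nstar * (log(2 * pi) + log(Q / nstar) + 1) + ldC + ldS
  else
    n * (log(2 * pi) + log(Q / n) + 1) + ldC
  list(deviance = dev, R = R, Mx = Mx, my = my, Rs = Rs, r = r, u = u,
       Q = Q, logdetC = ldC, logdetS = ldS, lp = lp, nstar = nstar)
}

profiledDeviance <- function(eng, theta, method, details = FALSE) {
  core <- devCore(eng, theta, method)
  if (is.null(core)) return(Inf)
  if (!details) return(core$deviance)
  p <- eng$p
  beta <- as.numeric(backsolve(core$Rs, core$u))
  sigma2 <- core$Q / core$nstar
  covb <- chol2inv(core$Rs) * sigma2
  list(deviance = core$deviance, beta = stats::setNames(beta, eng$xnames),
       se = stats::setNames(sqrt(diag(covb)), eng$xnames),
       sigma2 = sigma2, Q = core$Q, logdetC = core$logdetC,
       logdetS = core$logdetS)
}

# Analytic gradient of the profiled deviance with respect to theta.
# With Vs = I + Z G Z' (G = Lambda Lambda', relative covariance) and
# P = Vs^-1 - Vs^-1 X S^-1 X' Vs^-1:
#   REML: d/dtheta_k = tr(P Z Gdot_k Z') - (nu/Q) y'P Z Gdot_k Z' P y
#   ML:   d/dtheta_k = tr(Vs^-1 Z Gdot_k Z') - (n/Q) y'P Z Gdot_k Z' P y
# Gdot_k is nonzero only in block k, so only the blockwise diagonal (and,
# for intercept-trend blocks, the per-unit cross terms) of Z'PZ is needed.
profiledGradient <- function(eng, theta, method, core = NULL) {
  n <- eng$n; p <- eng$p
  blocks <- eng$blocks; layout <- eng$layout
  if (is.null(core)) core <- devCore(eng, theta, method)
  if (is.null(core)) return(rep(0, attr(layout, "nparam")))
  nstar <- if (method == "REML") n - p else n
  R <- core$R; Mx <- core$Mx; my <- core$my; Rs <- core$Rs
  u <- core$u; Q <- core$Q; lp <- core$lp
  LtZtZ <- .lambdaLeft(eng$ZtZ, lp$d, lp$o, lp$e, lp$t)   # Lambda' Z'Z

  U <- backsolve(R, LtZtZ, transpose = TRUE)       # R^-T Lambda' Z'Z
  dV <- diag(eng$ZtZ) - colSums(U * U)             # diag(Z' Vs^-1 Z)
  ZvX <- eng$ZtX - crossprod(U, Mx)                # Z' Vs^-1 X
  Zvy <- eng$Zty - crossprod(U, my)[, 1L]          # Z' Vs^-1 y
  E <- t(backsolve(Rs, t(ZvX), transpose = TRUE))  # (Z'Vs^-1X) Rs^-1
  w <- Zvy - E %*% u                               # Z' P y
  w <- w[, 1L]
  dAdj <- rowSums(E * E)                           # diag of REML adjustment
  dP <- dV - dAdj                                  # diag(Z' P Z)
  dTr <- if (method == "REML") dP else dV

  grad <- numeric(attr(layout, "nparam"))
  pos <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; idx <- seq(pos + 1L, pos + b$q); pos <- pos + b$q
    th <- theta[layout[[i]]$idx]
    if (b$type == "us2") {
      o <- idx[seq(1L, b$q, 2L)]; e <- idx[seq(2L, b$q, 2L)]
      # per-unit aggregates of Z'PZ (or Z'Vs^-1 Z) entries
      Soo <- sum(dTr[o]); See <- sum(dTr[e])
      crossV <- diag(eng$ZtZ[o, e, drop = FALSE]) -
        colSums(U[, o, drop = FALSE] * U[, e, drop = FALSE])
      if (method == "REML")
        crossV <- crossV - rowSums(E[o, , drop = FALSE] * E[e, , drop = FALSE])
      Soe <- sum(crossV)
      qoo <- sum(w[o]^2); qee <- sum(w[e]^2); qoe <- sum(w[o] * w[e])
      l1 <- exp(th[1L]); l2 <- exp(th[2L]); rho <- tanh(th[3L])
      cc <- rho * sqrt(l1 * l2)
      dSig <- list(c(l1, cc / 2, 0), c(0, cc / 2, l2),
                   c(0, (1 - rho^2) * sqrt(l1 * l2), 0))   # (d11, d12, d22)
      for (k in 1:3) {
        ds <- dSig[[k]]
        grad[layout[[i]]$idx[k]] <-
          (ds[1L] * Soo + 2 * ds[2L] * Soe + ds[3L] * See) -
          (nstar / Q) * (ds[1L] * qoo + 2 * ds[2L] * qoe + ds[3L] * qee)
      }
    } else {
      lam <- exp(th)
      grad[layout[[i]]$idx] <- lam * sum(dTr[idx]) -
        (nstar / Q) * lam * sum(w[idx]^2)
    }
  }
  grad
}

defaultStarts <- function(layout) {
  np <- attr(layout, "nparam")
  mk <- function(lam) {
    th <- numeric(np)
    for (li in layout) {
      th[li$idx] <- if (li$type == "us2") c(log(lam), log(lam), 0) else log(lam)
    }
    th
  }
  list(mk(0.5), mk(0.02), mk(8))
}

#' Fit a Gaussian linear mixed model
#'
#' Maximizes the profiled (restricted) log-likelihood over variance ratios
#' on the log scale (correlations via tanh) with the PORT quasi-Newton
#' optimizer, from several deterministic spread starting points (best kept).
#' Fixed effects and the residual variance are profiled out by generalized
#' least squares.  Variance ratios reaching the internal floor (1e-10) are
#' reported as 0 with a boundary flag.
#'
#' @param spec an [lmmSpec()].
#' @param method \code{"REML"} (default) or \code{"ML"}.
#' @param start optional warm-start parameter vector (log variance ratios,
#'   atanh correlations) in block order; used as the first start.
#' @param nStarts number of deterministic starts (default 3; a supplied
#'   \code{start} counts as the first).
#' @param pReference reference distribution for Wald P values:
#'   \code{"normal"} (default; the engine reports t statistics without
#'   denominator degrees of freedom) or \code{"tresid"} (Student t with
#'   n - p df).
#' @return [LMMFit-class]
#' @export
fitLMM <- function(spec, method = c("REML", "ML"), start = NULL,
                   nStarts = 3L, pReference = c("normal", "tresid")) {
  method <- match.arg(method)
  pReference <- match.arg(pReference)
  eng <- makeEngine(spec)
  fitEngine(eng, method, start = start, nStarts = nStarts,
            pReference = pReference)
}

fitEngine <- function(eng, method, start = NULL, nStarts = 3L,
                      pReference = "normal") {
  layout <- eng$layout
  np <- attr(layout, "nparam")
  if (np == 0L) {
    det <- profiledDeviance(eng, numeric(0), method, details = TRUE)
    theta <- numeric(0)
    opt <- list(iterations = 0L, convergence = 0L, message = "closed form")
  } else {
    cache <- new.env(parent = emptyenv())
    getCore <- function(th) {
      if (!is.null(cache$theta) && identical(cache$theta, th))
        return(cache$core)
      cache$theta <- th
      cache$core <- devCore(eng, th, method)
      cache$core
    }
    obj <- function(th) {
      core <- getCore(th)
      if (is.null(core)) Inf else core$deviance
    }
    gr <- function(th) profiledGradient(eng, th, method, core = getCore(th))
    lower <- rep(LOG_LAMBDA_FLOOR, np); upper <- rep(LOG_LAMBDA_CEIL, np)
    for (li in layout) if (li$type == "us2") {
      lower[li$idx[3L]] <- -6; upper[li$idx[3L]] <- 6
    }
    starts <- defaultStarts(layout)
    if (!is.null(start)) {
      stopifnot(length(start) == np)
      starts <- c(list(pmin(pmax(start, lower), upper)), starts)
    }
    starts <- starts[seq_len(min(length(starts), max(1L, nStarts)))]
    # warm single-start refits polish an already-converged optimum and use
    # a slightly looser relative tolerance than cold multi-start fits
    relTol <- if (!is.null(start) && length(starts) == 1L) 1e-8 else 1e-9
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        stats::nlminb(s, obj, gradient = gr, lower = lower, upper = upper,
                      control = list(iter.max = 500L, eval.max = 1000L,
                                     rel.tol = relTol)),
        error = function(e) NULL)
      if (is.null(o) || !is.finite(o$objective)) next
      if (is.null(best) || o$objective < best$objective - 1e-10) best <- o
    }
    if (is.null(best))
      stop("mixed-model fit failed to converge from all starting points")
    theta <- best$par
    opt <- list(iterations = best$iterations, convergence = best$convergence,
                message = best$message)
    det <- profiledDeviance(eng, theta, method, details = TRUE)
  }
  sigma2 <- det$sigma2
  vc <- c(); boundary <- logical(0)
  for (li in layout) {
    th <- theta[li$idx]
    if (li$type == "us2") {
      l1 <- exp(th[1L]); l2 <- exp(th[2L]); rho <- tanh(th[3L])
      atFloor <- th[1:2] <= LOG_LAMBDA_FLOOR + 1e-6
      v <- c(ifelse(atFloor[1L], 0, l1 * sigma2),
             ifelse(atFloor[2L], 0, l2 * sigma2), rho)
      names(v) <- paste0(li$label, c(".intercept", ".trend", ".cor"))
      vc <- c(vc, v)
      boundary <- c(boundary, stats::setNames(any(atFloor), li$label))
    } else {
      atFloor <- th <= LOG_LAMBDA_FLOOR + 1e-6
      vc <- c(vc, stats::setNames(if (atFloor) 0 else exp(th) * sigma2,
                                  li$label))
      boundary <- c(boundary, stats::setNames(atFloor, li$label))
    }
  }
  vc <- c(vc, residual = sigma2)
  tstat <- det$beta / det$se
  pval <- if (pReference == "normal") 2 * stats::pnorm(-abs(tstat))
          else 2 * stats::pt(-abs(tstat), df = eng$n - eng$p)
  methods::new("LMMFit", method = method, varcomp = vc, beta = det$beta,
               se = det$se, tstat = tstat, pval = pval,
               loglik = -det$deviance / 2, n = eng$n, p = eng$p,
               y = eng$y, xnames = eng$xnames,
               diagnostics = c(opt, list(theta = theta, boundary = boundary,
                                         deviance = det$deviance,
                                         pReference = pReference)))
}

#' Exact dense-covariance log-likelihood (verification oracle)
#'
#' Forms the full n x n marginal covariance V = sum_b Z_b G_b Z_b' +
#' I sigma2 explicitly and evaluates the exact (restricted) Gaussian
#' log-likelihood at the given variance values, with fixed effects
#' profiled by GLS.  Deliberately independent of the engine's q-space
#' computations; guarded to small n.
#'
#' @param spec an [lmmSpec()].
#' @param varcomp named list/vector of variance values: \code{residual},
#'   one value per iid/kinship block label, and for a correlated
#'   intercept-trend block a length-3 vector \code{c(intercept, trend,
#'   cor)} under the block label.
#' @param method \code{"REML"} or \code{"ML"}.
#' @param kinshipAs \code{"root"} builds the kinship block covariance as
#'   Z L L' Z' sigma2_g from the stored covariance root; \code{"direct"}
#'   uses Z K Z' sigma2_g with K itself.
#' @param maxN guard on the number of observations (default 500).
#' @return log-likelihood (numeric scalar).
#' @export
directLogLik <- function(spec, varcomp, method = c("REML", "ML"),
                         kinshipAs = c("root", "direct"), maxN = 500L) {
  method <- match.arg(method)
  kinshipAs <- match.arg(kinshipAs)
  n <- length(spec$y)
  if (n > maxN) stop("directLogLik is an oracle for small problems (n <= ",
                     maxN, ")")
  varcomp <- as.list(varcomp)
  if (is.null(varcomp$residual)) stop("varcomp$residual is required")
  V <- diag(as.numeric(varcomp$residual), n)
  for (b in spec$blocks) {
    v <- varcomp[[b$label]]
    if (is.null(v)) stop("no variance given for block ", b$label)
    V <- V + switch(b$type,
      iid = as.numeric(v) * tcrossprod(b$Z),
      kinship = if (kinshipAs == "root") as.numeric(v) * tcrossprod(b$Z)
                else as.numeric(v) * b$Zraw %*% b$K %*% t(b$Zraw),
      us2 = {
        stopifnot(length(v) == 3L)
        Sig <- matrix(c(v[1L], v[3L] * sqrt(v[1L] * v[2L]),
                        v[3L] * sqrt(v[1L] * v[2L]), v[2L]), 2L)
        u <- b$q / 2L
        G <- kronecker(diag(u), Sig)
        b$Z %*% G %*% t(b$Z)
      })
  }
  R <- tryCatch(chol(V), error = function(e)
    stop("singular covariance matrix in directLogLik"))
  X <- spec$X; y <- spec$y; p <- ncol(X)
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  XtVX <- crossprod(Xw)
  beta <- solve(XtVX, crossprod(Xw, yw))
  resid <- yw - Xw %*% beta
  quad <- sum(resid^2)
  ldV <- 2 * sum(log(diag(R)))
  if (method == "ML")
    -0.5 * (n * log(2 * pi) + ldV + quad)
  else
    -0.5 * ((n - p) * log(2 * pi) + ldV +
              determinant(XtVX, logarithm = TRUE)$modulus[1L] + quad)
}

# Engine-side (q-space) log-likelihood at given absolute variance values;
# used to cross-check that the optimizer's internal objective agrees with
# the dense oracle at arbitrary points.
engineLogLik <- function(spec, varcomp, method = c("REML", "ML")) {
  method <- match.arg(method)
  eng <- makeEngine(spec)
  varcomp <- as.list(varcomp)
  sigma2 <- as.numeric(varcomp$residual)
  theta <- numeric(attr(eng$layout, "nparam"))
  for (li in eng$layout) {
    v <- varcomp[[li$label]]
    if (li$type == "us2") {
      theta[li$idx] <- c(log(v[1L] / sigma2), log(v[2L] / sigma2), atanh(v[3L]))
    } else theta[li$idx] <- log(as.numeric(v) / sigma2)
  }
  n <- eng$n; p <- eng$p
  det <- profiledDeviance(eng, theta, method, details = TRUE)
  if (method == "ML")
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + det$logdetC + det$Q / sigma2)
  else
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) + det$logdetC +
              det$logdetS + det$Q / sigma2)
}

#' Wald test of one fixed-effect coefficient
#'
#' @param fit [LMMFit-class].
#' @param coefficient coefficient label.
#' @param pReference \code{"normal"} (default) or \code{"tresid"}
#'   (Student t, n - p df).
#' @return list with \code{estimate}, \code{se}, \code{t} and two-sided
#'   \code{p}.
#' @export
waldTest <- function(fit, coefficient, pReference = c("normal", "tresid")) {
  pReference <- match.arg(pReference)
  if (!coefficient %in% names(fit@beta))
    stop("coefficient not estimable / not in the model: ", coefficient)
  est <- fit@beta[[coefficient]]; se <- fit@se[[coefficient]]
  t <- est / se
  p <- if (pReference == "normal") 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = fit@n - fit@p)
  list(estimate = est, se = se, t = t, p = p)
}

#' Likelihood-ratio test between nested fits
#'
#' The statistic 2 (logLik_full - logLik_reduced), floored at zero, is
#' referred to a chi-square with \code{df} degrees of freedom.  For
#' variance-component tests this reference is deliberately conservative
#' (the true asymptotic null is a chi-square mixture).  Comparing models
#' with different fixed effects requires ML fits; REML likelihoods are not
#' comparable across fixed-effect sets and raise an error.
#'
#' @param fitFull,fitReduced [LMMFit-class] objects fitted to the same
#'   response by the same method.
#' @param df degrees of freedom; defaults to the difference in the number
#'   of fixed-effect columns when positive.
#' @return list with \code{statistic}, \code{df} and \code{p}.
#' @export
lrt <- function(fitFull, fitReduced, df = NULL) {
  if (fitFull@method != fitReduced@method)
    stop("both fits must use the same estimation method")
  if (!isTRUE(all.equal(fitFull@y, fitReduced@y, tolerance = 1e-12)))
    stop("fits are not nested: responses differ")
  sameX <- identical(sort(fitFull@xnames), sort(fitReduced@xnames))
  if (fitFull@method == "REML" && !sameX)
    stop("REML likelihoods are not comparable across fixed-effect sets; refit with ML")
  if (is.null(df)) {
    df <- fitFull@p - fitReduced@p
    if (df <= 0L)
      stop("supply df explicitly for variance-component comparisons")
  }
  stat <- max(0, 2 * (fitFull@loglik - fitReduced@loglik))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Percent genetic variance explained by a model term
#'
#' 100 (sigma2_g,reduced - sigma2_g,with) / sigma2_g,reduced, where
#' sigma2_g is the kinship-structured genotype variance component in the
#' model without and with the tested term.  Negative values are truncated
#' to zero (the ad-hoc measure can increase under additional adjustment);
#' a reduced-model genotype variance of zero yields 0 with attribute
#' \code{undefined = TRUE}.
#'
#' @param fitReduced,fitWith [LMMFit-class] objects sharing the response,
#'   method and genotype block.
#' @return percent in [0, 100].
#' @export
varianceExplained <- function(fitReduced, fitWith) {
  if (!isTRUE(all.equal(fitReduced@y, fitWith@y, tolerance = 1e-12)))
    stop("fits do not share the response")
  if (fitReduced@method != fitWith@method)
    stop("fits do not share the estimation method")
  if (!all(c("genotype") %in% names(fitReduced@varcomp)) ||
      !all(c("genotype") %in% names(fitWith@varcomp)))
    stop("both fits need a 'genotype' variance component")
  s2r <- fitReduced@varcomp[["genotype"]]
  s2w <- fitWith@varcomp[["genotype"]]
  if (s2r <= 0) return(structure(0, undefined = TRUE))
  max(0, 100 * (s2r - s2w) / s2r)
}
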