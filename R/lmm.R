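# EMMA-style linear mixed model for association:
#   y = X b + g + e,  g ~ N(0, sg^2 K),  e ~ N(0, se^2 I).
# A single eigendecomposition K = U D U' rotates the problem so that for
# any variance ratio lambda = sg^2 / se^2 the covariance is diagonal with
# weights 1 / (lambda d_i + 1); the restricted likelihood is then profiled
# over lambda by one-dimensional optimization on a log scale.

eigen_grm <- function(K) {
  if (inherits(K, "grm")) K <- K$matrix
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-8) stop_invalid("GRM is not symmetric")
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values), 1))
    stop_invalid("GRM is not positive semidefinite (min eigenvalue %.3g)",
                 min(ev$values))
  ev$values <- pmax(ev$values, 0)
  ev
}

# restricted log-likelihood at a given variance ratio, for rotated data
reml_loglik <- function(lambda, d, Xt, yt, XtX_logdet) {
  n <- length(yt); p <- ncol(Xt)
  w <- 1 / (lambda * d + 1)
  Xw <- Xt * w
  A <- crossprod(Xt, Xw)
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(list(ll = -Inf))
  b <- backsolve(cA, forwardsolve(t(cA), crossprod(Xw, yt)))
  r <- yt - Xt %*% b
  rss <- sum(w * r * r)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(lambda * d + 1)) +
                  2 * sum(log(diag(cA))) - XtX_logdet)
  list(ll = ll, beta = b, s2 = s2, chol_A = cA)
}

fit_lambda <- function(d, Xt, yt, lower = 1e-5, upper = 1e5, tol = 1e-6) {
  XtX_logdet <- 2 * sum(log(diag(chol(crossprod(Xt)))))
  obj <- function(loglam)
    -reml_loglik(10^loglam, d, Xt, yt, XtX_logdet)$ll
  opt <- optimize(obj, c(log10(lower), log10(upper)), tol = tol)
  cand <- c(10^opt$minimum, lower, upper)
  lls <- vapply(cand, function(l)
    reml_loglik(l, d, Xt, yt, XtX_logdet)$ll, numeric(1))
  best <- which.max(lls)
  lambda <- cand[best]
  # treat a boundary solution at the lower end as effectively zero genetic
  # variance for reporting, while keeping the likelihood value
  fit <- reml_loglik(lambda, d, Xt, yt, XtX_logdet)
  list(lambda = lambda, ll = fit$ll, fit = fit, XtX_logdet = XtX_logdet)
}

#' Fit the null linear mixed model (REML)
#'
#' Estimates the genetic-to-residual variance ratio by restricted maximum
#' likelihood via one eigendecomposition of the GRM and one-dimensional
#' optimization of the ratio on a log scale over [1e-5, 1e5].
#'
#' @param y numeric trait (or 0/1 status) vector, no missing values.
#' @param covars optional covariate matrix; an intercept is always added.
#' @param K a [compute_grm()] result or plain n x n PSD matrix.
#' @param eig optional precomputed `eigen()` of K (see [eigen_grm()]).
#' @return List of class `lmm_fit`: `variance_ratio`, `log_likelihood`,
#'   `beta` (fixed effects), `se`, `sigma2_e`, `n`.
#' @export
lmm_fit_null <- function(y, covars = NULL, K, eig = NULL) {
  X <- cbind(`(Intercept)` = rep(1, length(y)),
             if (!is.null(covars)) as.matrix(covars))
  if (anyNA(y) || anyNA(X))
    stop_invalid("lmm_fit_null requires complete y and covariates")
  ev <- eig %||% eigen_grm(K)
  if (length(y) != length(ev$values)) stop_invalid("dimension mismatch")
  yt <- crossprod(ev$vectors, y)
  Xt <- crossprod(ev$vectors, X)
  res <- fit_lambda(ev$values, Xt, yt)
  cov_b <- res$fit$s2 * chol2inv(res$fit$chol_A)
  structure(list(variance_ratio = res$lambda,
                 log_likelihood = res$ll,
                 beta = setNames(as.vector(res$fit$beta), colnames(X)),
                 se = sqrt(diag(cov_b)),
                 sigma2_e = res$fit$s2, n = length(y)),
            class = "lmm_fit")
}

#' Mixed-model association test for one SNP
#'
#' Wald test of the genotype coefficient with the variance ratio profiled
#' (re-optimized) for the tested SNP; at the optimum the estimate equals
#' the generalized-least-squares fit. Fixing `variance_ratio = 0` reduces
#' the model to ordinary least squares. Missing values are excluded
#' case-wise (the GRM is subset accordingly).
#'
#' @param y trait or 0/1 status vector.
#' @param x encoded genotype regressor (see [encode_genotype()]).
#' @param covars optional covariate matrix.
#' @param K GRM (or `eig`, its precomputed eigendecomposition, when there
#'   are no missing values).
#' @param eig optional precomputed eigendecomposition of K.
#' @param variance_ratio optional fixed ratio (skips profiling; 0 gives
#'   OLS; `"null"` plugs in the null-model REML estimate).
#' @param snp_id,model labels carried into the result.
#' @return One-row `AssociationResult` data frame (`beta`, `se`,
#'   `p_value` from a t reference with n - p df, counts).
#' @export
lmm_assoc <- function(y, x, covars = NULL, K = NULL, eig = NULL,
                      variance_ratio = NULL, snp_id = NA,
                      model = "recessive") {
  X0 <- cbind(if (!is.null(covars)) as.matrix(covars))
  cc <- !is.na(y) & !is.na(x)
  if (!is.null(X0)) cc <- cc & complete.cases(X0)
  n_all <- length(y)
  if (!all(cc)) {
    if (is.null(K)) stop_invalid("K is required when data contain missing values")
    Km <- if (inherits(K, "grm")) K$matrix else as.matrix(K)
    eig <- eigen_grm(Km[cc, cc, drop = FALSE])
  } else if (is.null(eig)) {
    eig <- eigen_grm(K)
  }
  y <- y[cc]; x <- x[cc]
  if (!is.null(X0)) X0 <- X0[cc, , drop = FALSE]
  hom_level <- if (identical(model, "recessive")) 1 else 2
  n_hom <- sum(x == hom_level)
  if (length(unique(x)) < 2)
    return(assoc_result(snp_id, model, n_used = length(y),
                        n_homozygous = n_hom, estimable = FALSE))
  X <- cbind(`(Intercept)` = rep(1, length(y)), x = x, X0)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  if (identical(variance_ratio, "null")) {
    nullfit <- lmm_fit_null(y, X0, eig = eig, K = NULL)
    variance_ratio <- nullfit$variance_ratio
  }
  if (is.null(variance_ratio)) {
    res <- fit_lambda(eig$values, Xt, yt)
    fit <- res$fit
  } else {
    XtX_logdet <- 2 * sum(log(diag(chol(crossprod(Xt)))))
    fit <- reml_loglik(max(variance_ratio, 0), eig$values, Xt, yt,
                       XtX_logdet)
  }
  cov_b <- fit$s2 * chol2inv(fit$chol_A)
  b <- as.vector(fit$beta)[2]
  se <- sqrt(diag(cov_b))[2]
  df <- length(y) - ncol(X)
  p <- 2 * pt(-abs(b / se), df = df)
  assoc_result(snp_id, model, beta = b, se = se, p_value = p,
               n_used = length(y), n_homozygous = n_hom, estimable = TRUE)
}

#' Mixed-model association scan over all SNPs
#'
#' Batch driver: one eigendecomposition and one rotation of the genotype
#' matrix, then a profiled (or plugged-in) variance ratio per SNP. Missing
#' dosages are mean-imputed for the scan (single-SNP [lmm_assoc()] does
#' exact case-wise exclusion instead).
#'
#' @param G a [genotype_matrix()] or dosage matrix.
#' @param y complete trait / status vector.
#' @param covars optional covariate matrix (complete).
#' @param K GRM; computed from `G` when missing.
#' @param model genetic model for the coding.
#' @param ratio `"profile"` (exact per-SNP re-optimization) or `"null"`
#'   (faster plug-in of the null-model estimate).
#' @return `AssociationResult` data frame, one row per SNP.
#' @export
lmm_scan <- function(G, y, covars = NULL, K = NULL,
                     model = c("recessive", "additive"),
                     ratio = c("profile", "null")) {
  model <- match.arg(model)
  ratio <- match.arg(ratio)
  dos <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  ids <- if (inherits(G, "genotype_matrix")) G$snp_ids
         else colnames(dos) %||% paste0("snp", seq_len(ncol(dos)))
  if (anyNA(y)) stop_invalid("lmm_scan requires a complete outcome")
  K <- K %||% compute_grm(dos)
  ev <- eigen_grm(K)
  X0 <- cbind(`(Intercept)` = rep(1, length(y)),
              if (!is.null(covars)) as.matrix(covars))
  yt <- crossprod(ev$vectors, y)
  X0t <- crossprod(ev$vectors, X0)
  E <- apply(dos, 2, encode_genotype, model = model)
  mu <- colMeans(E, na.rm = TRUE)
  miss <- is.na(E)
  if (any(miss)) E[miss] <- rep(mu, each = nrow(E))[miss]
  Et <- crossprod(ev$vectors, E)
  lambda_null <- if (ratio == "null")
    lmm_fit_null(y, covars, eig = ev, K = NULL)$variance_ratio else NULL
  hom_level <- if (model == "recessive") 1 else 2
  out <- vector("list", ncol(dos))
  for (j in seq_len(ncol(dos))) {
    n_hom <- sum(E[, j] == hom_level)
    if (var(E[, j]) == 0) {
      out[[j]] <- assoc_result(ids[j], model, n_used = length(y),
                               n_homozygous = n_hom, estimable = FALSE)
      next
    }
    Xt <- cbind(X0t[, 1, drop = FALSE], x = Et[, j],
                if (ncol(X0t) > 1) X0t[, -1, drop = FALSE])
    if (is.null(lambda_null)) {
      res <- fit_lambda(ev$values, Xt, yt)
      fit <- res$fit
    } else {
      XtX_logdet <- 2 * sum(log(diag(chol(crossprod(Xt)))))
      fit <- reml_loglik(lambda_null, ev$values, Xt, yt, XtX_logdet)
    }
    cov_b <- fit$s2 * chol2inv(fit$chol_A)
    b <- as.vector(fit$beta)[2]
    se <- sqrt(diag(cov_b))[2]
    df <- length(y) - ncol(Xt)
    out[[j]] <- assoc_result(ids[j], model, beta = b, se = se,
                             p_value = 2 * pt(-abs(b / se), df = df),
                             n_used = length(y), n_homozygous = n_hom,
                             estimable = TRUE)
  }
  do.call(rbind, out)
}

#' Full association scan: mixed-model p values plus logistic odds ratios
#'
#' Mirrors the discovery design: relatedness-aware p values from the
#' linear mixed model applied to the 0/1 status (or a quantitative trait),
#' and, for case-control outcomes, odds ratios from covariate-adjusted
#' logistic regression with principal components.
#'
#' @param G a [genotype_matrix()].
#' @param outcome 0/1 status or quantitative trait (complete).
#' @param binary whether `outcome` is case-control.
#' @param covars covariate matrix for both fits (e.g. sex, age, cohort
#'   dummies).
#' @param n_pcs number of genotype PCs added to the logistic fit.
#' @param model genetic model(s): `"recessive"`, `"additive"` or
#'   `"both"`.
#' @param K optional precomputed GRM.
#' @param ratio variance-ratio handling for the scan (see [lmm_scan()]).
#' @return `AssociationResult` data frame; for binary outcomes the
#'   logistic OR and its p value are appended as `odds_ratio`,
#'   `p_logistic`.
#' @export
assoc_scan <- function(G, outcome, binary = TRUE, covars = NULL,
                       n_pcs = 10, model = "both", K = NULL,
                       ratio = c("profile", "null")) {
  ratio <- match.arg(ratio)
  models <- if (model == "both") c("additive", "recessive") else model
  K <- K %||% compute_grm(G)
  pcs <- if (binary && n_pcs > 0) compute_pcs(G, n_pcs) else NULL
  res <- lapply(models, function(mo) {
    r <- lmm_scan(G, outcome, covars = covars, K = K, model = mo,
                  ratio = ratio)
    if (binary) {
      lg <- lapply(seq_len(ncol(G$dosages)), function(j) {
        x <- encode_genotype(G$dosages[, j], mo)
        logistic_assoc(outcome, x, covars = cbind(covars, pcs),
                       snp_id = G$snp_ids[j], model = mo)
      })
      lg <- do.call(rbind, lg)
      r$odds_ratio <- lg$odds_ratio
      r$p_logistic <- lg$p_value
    }
    r
  })
  do.call(rbind, res)
}
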