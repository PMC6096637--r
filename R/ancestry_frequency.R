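# Two-step ancestry-component allele-frequency estimation:
#   step 1 - admixture proportions Q from the binomial admixture
#            likelihood (EM, optionally supervised by anchor individuals),
#   step 2 - per-SNP maximum-likelihood ancestral frequencies with Q
#            fixed, with bootstrap-over-individuals confidence intervals.

#' Estimate admixture proportions and ancestral frequencies by EM
#'
#' Local maximum of the binomial admixture likelihood
#' L = prod_ij Binom(g_ij | 2, sum_k Q_ik F_jk) by alternating
#' multiplicative EM updates of Q and F. The log-likelihood is
#' non-decreasing across iterations; convergence is declared when the gain
#' drops below `tol`. Supervised mode clamps the Q rows of anchor
#' individuals with known ancestry (e.g. unadmixed European reference
#' samples), which also fixes the component labelling.
#'
#' @param G a [genotype_matrix()] or dosage matrix; no SNP may be
#'   entirely missing.
#' @param K number of ancestral populations (>= 2; K = 1 degenerates to
#'   per-SNP sample frequencies).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the last
#'   iterate with `converged = FALSE` and a warning.
#' @param seed seed for the random initialisation of Q.
#' @param anchors optional list with `rows` (individual indices) and `Q`
#'   (matrix of their known ancestry proportions) for supervised mode.
#' @return List of class `ancestry_model`: `Q` (n x K), `F_mat` (m x K),
#'   `loglik`, `loglik_trace`, `iterations`, `converged`.
#' @export
admixture_em <- function(G, K = 2, tol = 1e-4, max_iter = 2000, seed = 1,
                         anchors = NULL) {
  dos <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  n <- nrow(dos); m <- ncol(dos)
  if (any(colSums(!is.na(dos)) == 0))
    stop_invalid("some SNPs are entirely missing")
  if (K < 1) stop_invalid("K must be >= 1")
  if (K == 1) {
    f <- colMeans(dos, na.rm = TRUE) / 2
    return(structure(list(Q = matrix(1, n, 1),
                          F_mat = matrix(f, ncol = 1),
                          loglik = NA_real_, iterations = 0L,
                          converged = TRUE), class = "ancestry_model"))
  }
  set.seed(seed)
  Q0 <- rdirichlet_mat(n, rep(1, K))
  p <- colMeans(dos, na.rm = TRUE) / 2
  p <- pmin(pmax(p, 0.01), 0.99)
  F0 <- vapply(seq_len(K), function(k)
    pmin(pmax(p + runif(m, -0.05, 0.05), 0.01), 0.99), numeric(m))
  anchored <- rep(FALSE, n)
  if (!is.null(anchors)) {
    stopifnot(is.list(anchors), !is.null(anchors$rows), !is.null(anchors$Q))
    anchored[anchors$rows] <- TRUE
    Q0[anchors$rows, ] <- anchors$Q
  }
  Gi <- dos
  Gi[is.na(Gi)] <- -1L
  storage.mode(Gi) <- "integer"
  res <- .em_admixture(Gi, Q0, F0, anchored, tol = tol,
                       max_iter = max_iter)
  if (!res$converged)
    warning(sprintf("admixture EM did not converge in %d iterations",
                    max_iter))
  structure(list(Q = res$Q, F_mat = res$F, loglik = res$loglik,
                 loglik_trace = res$loglik_trace,
                 iterations = res$iterations, converged = res$converged),
            class = "ancestry_model")
}

#' Align EM component labels to a reference
#'
#' EM component order is arbitrary; this relabels components so component
#' 1 is the one with the highest mean ancestry among the designated
#' reference individuals.
#'
#' @param model an `ancestry_model`.
#' @param reference_rows individual indices expected to be predominantly
#'   component-1 ancestry.
#' @export
align_components <- function(model, reference_rows) {
  ord <- order(colMeans(model$Q[reference_rows, , drop = FALSE]),
               decreasing = TRUE)
  model$Q <- model$Q[, ord, drop = FALSE]
  model$F_mat <- model$F_mat[, ord, drop = FALSE]
  model
}

#' Maximum-likelihood ancestral frequencies with Q fixed
#'
#' Maximizes sum_i log Binom(g_i | 2, sum_k Q_ik f_k) over f in [0,1]^K
#' by EM on f, to a log-likelihood tolerance of 1e-8. Missing dosages are
#' skipped. A component whose total ancestry mass among non-missing
#' individuals (sum_i Q_ik) is below one individual-equivalent is
#' unidentifiable and returned as NA with its name in the
#' `non_identifiable` attribute.
#'
#' @param dosages_at_snp 0/1/2/NA dosage vector for one SNP.
#' @param Q n x K ancestry-proportion matrix (rows on the simplex).
#' @param tol,max_iter EM controls.
#' @return Length-K frequency vector with attributes `loglik`,
#'   `converged`, `non_identifiable`.
#' @export
fixed_q_mle <- function(dosages_at_snp, Q, tol = 1e-8, max_iter = 10000) {
  Q <- as.matrix(Q)
  g <- as.numeric(dosages_at_snp)
  if (length(g) != nrow(Q)) stop_invalid("dosages and Q lengths differ")
  if (all(is.na(g))) stop_invalid("all dosages missing at this SNP")
  if (max(abs(rowSums(Q) - 1)) > 1e-8)
    stop_invalid("rows of Q must sum to 1")
  ok <- !is.na(g)
  mass <- colSums(Q[ok, , drop = FALSE])
  res <- .em_fixed_q(g, Q, tol = tol, max_iter = max_iter)
  f <- res$f
  nonid <- mass < 1
  f[nonid] <- NA_real_
  structure(f, loglik = res$loglik, converged = res$converged,
            non_identifiable = which(nonid))
}

#' Bootstrap confidence intervals for ancestral frequencies
#'
#' Resamples individuals (dosage and Q row jointly) with replacement B
#' times, re-estimates f by [fixed_q_mle()]'s EM on each resample, and
#' takes empirical quantiles per component. Replicates in which a
#' component is unidentifiable (ancestry mass < 1) are excluded from that
#' component's quantiles and counted.
#'
#' @param dosages_at_snp 0/1/2/NA dosages for one SNP.
#' @param Q ancestry proportions.
#' @param B bootstrap replicates (default 1000).
#' @param quantiles CI quantile pair, default c(0.025, 0.975).
#' @param seed integer seed.
#' @param snp_id label.
#' @return List of class `ancestral_freq_estimate`: `snp_id`, `f_hat`,
#'   `ci_low`, `ci_high` (K-vectors), `B`, `n_boot_valid` (per
#'   component), `boot` (B x K matrix of replicate estimates).
#' @export
bootstrap_ci <- function(dosages_at_snp, Q, B = 1000,
                         quantiles = c(0.025, 0.975), seed = 1,
                         snp_id = NA) {
  if (B < 1) stop_invalid("B must be >= 1")
  if (length(quantiles) != 2 || any(quantiles <= 0) ||
      any(quantiles >= 1) || quantiles[1] >= quantiles[2])
    stop_invalid("quantiles must satisfy 0 < lo < hi < 1")
  Q <- as.matrix(Q)
  n <- nrow(Q)
  f_hat <- fixed_q_mle(dosages_at_snp, Q)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  f_start <- as.numeric(f_hat)
  f_start[is.na(f_start)] <- 0.5
  boot <- .bootstrap_fixed_q(as.numeric(dosages_at_snp), Q, idx,
                             f_start, mass_min = 1)
  ci <- apply(boot, 2, function(col)
    quantile(col, probs = quantiles, na.rm = TRUE, names = FALSE))
  structure(list(snp_id = snp_id,
                 f_hat = as.numeric(f_hat),
                 ci_low = ci[1, ], ci_high = ci[2, ], B = B,
                 n_boot_valid = colSums(!is.na(boot)),
                 non_identifiable = attr(f_hat, "non_identifiable"),
                 boot = boot),
            class = "ancestral_freq_estimate")
}

#' Table of pooled and ancestry-component allele frequencies
#'
#' Per SNP: the pooled sample effect-allele frequency with a binomial
#' (Wald, on 2n alleles) confidence interval, plus each component's
#' fixed-Q maximum-likelihood estimate with bootstrap quantile CIs.
#'
#' @param G a [genotype_matrix()].
#' @param Q ancestry proportions for the same individuals.
#' @param snp_ids SNPs to estimate (default: all).
#' @param B bootstrap replicates.
#' @param ci_level CI level, default 0.95.
#' @param seed integer seed (per-SNP seeds derive from it).
#' @return Data frame: snp_id, eaf_all, ci_all_lo, ci_all_hi, then per
#'   component f_k, ci_k_lo, ci_k_hi, n_boot_valid_k.
#' @export
estimate_component_eaf_table <- function(G, Q, snp_ids = NULL, B = 1000,
                                         ci_level = 0.95, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  Q <- as.matrix(Q)
  snp_ids <- snp_ids %||% G$snp_ids
  miss <- setdiff(snp_ids, G$snp_ids)
  if (length(miss)) stop_invalid("unknown snp_id(s): %s",
                                 paste(miss, collapse = ", "))
  qs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  K <- ncol(Q)
  rows <- lapply(seq_along(snp_ids), function(t) {
    j <- match(snp_ids[t], G$snp_ids)
    g <- G$dosages[, j]
    ok <- !is.na(g)
    n_alleles <- 2 * sum(ok)
    eaf <- sum(g[ok]) / n_alleles
    half <- qnorm(0.975) * sqrt(eaf * (1 - eaf) / n_alleles)
    est <- bootstrap_ci(g, Q, B = B, quantiles = qs,
                        seed = (seed * 100003 + t) %% 2147483629 + 1,
                        snp_id = snp_ids[t])
    row <- data.frame(snp_id = snp_ids[t], eaf_all = eaf,
                      ci_all_lo = max(0, eaf - half),
                      ci_all_hi = min(1, eaf + half))
    for (k in seq_len(K)) {
      row[[paste0("f_", k)]] <- est$f_hat[k]
      row[[paste0("ci_", k, "_lo")]] <- est$ci_low[k]
      row[[paste0("ci_", k, "_hi")]] <- est$ci_high[k]
      row[[paste0("n_boot_valid_", k)]] <- est$n_boot_valid[k]
    }
    row
  })
  do.call(rbind, rows)
}
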