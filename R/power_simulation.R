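# Additive-vs-recessive case-control power simulation over an (EAF, OR)
# grid. Genotypes are drawn Binomial(2, EAF) (Hardy-Weinberg), disease
# status from the recessive odds-multiplication model, and each replicate
# is tested by logistic regression under both genotype codings; power is
# the fraction of replicates whose Wald p value falls below the study-wide
# threshold.

#' Power-grid specification
#'
#' Defaults reproduce the study design: EAFs 0.05-0.30, ORs 1.1-10.0 in
#' steps of 0.1 (540 cells), n = 2948 individuals, baseline risk 0.1,
#' 20,000 replicates per cell and the study-wide significance threshold
#' 4.3e-7 (Bonferroni for 115,182 SNPs).
#'
#' @param eafs effect allele frequencies.
#' @param ors odds ratios; default built by integer indexing
#'   (1.1 + 0.1 k, k = 0..89) so the 10.0 endpoint is included exactly.
#' @param n cohort size per replicate.
#' @param baseline_risk non-homozygote disease probability.
#' @param reps replicates per cell (>= 1).
#' @param alpha significance threshold in (0, 1).
#' @param seed integer master seed; per-cell seeds derive from it.
#' @return A `power_grid_spec` list.
#' @export
power_grid_spec <- function(eafs = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
                            ors = 1.1 + 0.1 * (0:89),
                            n = 2948, baseline_risk = 0.1, reps = 20000,
                            alpha = 4.3e-7, seed = 1) {
  if (length(eafs) < 1 || length(ors) < 1)
    stop_invalid("eafs and ors must be non-empty")
  if (alpha <= 0 || alpha >= 1) stop_invalid("alpha must lie in (0, 1)")
  if (reps < 1) stop_invalid("reps must be >= 1")
  structure(list(eafs = eafs, ors = ors, n = as.integer(n),
                 baseline_risk = baseline_risk, reps = as.integer(reps),
                 alpha = alpha, seed = as.integer(seed)),
            class = "power_grid_spec")
}

#' Enumerate the (EAF, OR) cells of a power grid
#'
#' Cartesian product in deterministic order: EAF-major, OR ascending.
#' @param spec a [power_grid_spec()].
#' @return Data frame with columns `cell`, `eaf`, `or`.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "power_grid_spec"))
  g <- expand.grid(or = spec$ors, eaf = spec$eafs,
                   KEEP.OUT.ATTRS = FALSE)[, c("eaf", "or")]
  g <- g[order(match(g$eaf, spec$eafs), g$or), ]
  rownames(g) <- NULL
  data.frame(cell = seq_len(nrow(g)), g)
}

# deterministic per-cell seed below 2^31, derived from the master seed
cell_seed <- function(seed, cell) {
  (as.double(seed) * 1000003 + as.double(cell) * 7919) %% 2147483629 + 1
}

# fast Wald p for logistic regression with design cbind(1, x);
# returns p = 1 for inestimable fits (constant x, non-convergence,
# separation) so degenerate replicates count conservatively against power.
logistic_wald_p <- function(x, y) {
  if (length(unique(x)) < 2L) return(c(p = 1, degenerate = 1))
  X <- cbind(1, x)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  b <- unname(fit$coefficients[2])
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  # closed-form 2x2 inverse of X' W X
  s11 <- sum(w); s12 <- sum(w * x); s22 <- sum(w * x * x)
  det <- s11 * s22 - s12 * s12
  if (!fit$converged || !is.finite(b) || det <= 0 || abs(b) > 15)
    return(c(p = 1, degenerate = 1))
  se <- sqrt(s11 / det)
  z <- b / se
  c(p = 2 * pnorm(-abs(z)), degenerate = 0)
}

#' Run one power-simulation replicate
#'
#' Simulates genotypes Binomial(2, eaf) for n individuals, disease status
#' under the recessive odds-multiplication model, and returns the Wald p
#' values of the additive (0/1/2 dosage) and recessive (homozygote
#' indicator) logistic regressions. Inestimable models (e.g. zero
#' homozygotes) yield p = 1 and are flagged.
#'
#' @param eaf effect allele frequency.
#' @param or_effect homozygote odds ratio.
#' @param n cohort size.
#' @param baseline_risk non-homozygote disease probability.
#' @param seed integer seed; the replicate is deterministic given it.
#' @return Named vector: `p_additive`, `p_recessive`,
#'   `degenerate_additive`, `degenerate_recessive`.
#' @export
run_replicate <- function(eaf, or_effect, n = 2948, baseline_risk = 0.1,
                          seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2L, eaf)
  pi_hom <- homozygote_risk(baseline_risk, or_effect)
  y <- rbinom(n, 1L, ifelse(g == 2L, pi_hom, baseline_risk))
  add <- logistic_wald_p(g, y)
  rec <- logistic_wald_p(as.numeric(g == 2L), y)
  c(p_additive = unname(add["p"]), p_recessive = unname(rec["p"]),
    degenerate_additive = unname(add["degenerate"]),
    degenerate_recessive = unname(rec["degenerate"]))
}

#' Estimate power for one grid cell
#'
#' Power = proportion of replicates with p < alpha, per genetic model,
#' with Monte-Carlo standard error sqrt(p(1-p)/reps). Replicate seeds are
#' derived deterministically from `spec$seed` and the cell's position in
#' [build_grid()], so cells are independently reproducible.
#'
#' @param spec a [power_grid_spec()].
#' @param eaf,or_effect the cell.
#' @param reps optional override of `spec$reps`.
#' @return One-row data frame per model (long format): columns `eaf`,
#'   `or`, `model`, `power`, `mc_se`, `n_degenerate`, `reps`.
#' @export
estimate_power <- function(spec, eaf, or_effect, reps = spec$reps) {
  stopifnot(inherits(spec, "power_grid_spec"))
  if (reps < 1) stop_invalid("reps must be >= 1")
  grid <- build_grid(spec)
  hit <- which(abs(grid$eaf - eaf) < 1e-12 & abs(grid$or - or_effect) < 1e-12)
  cell <- if (length(hit)) grid$cell[hit[1]] else 0L
  base <- cell_seed(spec$seed, cell)
  pa <- pr <- logical(reps); da <- dr <- 0L
  for (r in seq_len(reps)) {
    res <- run_replicate(eaf, or_effect, spec$n, spec$baseline_risk,
                         seed = (base + r) %% 2147483629 + 1)
    pa[r] <- res["p_additive"] < spec$alpha
    pr[r] <- res["p_recessive"] < spec$alpha
    da <- da + res["degenerate_additive"]
    dr <- dr + res["degenerate_recessive"]
  }
  pow <- c(mean(pa), mean(pr))
  data.frame(eaf = eaf, or = or_effect,
             model = c("additive", "recessive"),
             power = pow, mc_se = sqrt(pow * (1 - pow) / reps),
             n_degenerate = c(da, dr), reps = reps, row.names = NULL)
}

#' Run the full power grid
#'
#' @param spec a [power_grid_spec()].
#' @param cells optional subset of rows of [build_grid()] to run.
#' @return Long-format data frame, two rows (models) per cell.
#' @export
run_power_grid <- function(spec, cells = NULL) {
  grid <- build_grid(spec)
  if (!is.null(cells)) grid <- grid[grid$cell %in% cells, ]
  out <- lapply(seq_len(nrow(grid)), function(i)
    estimate_power(spec, grid$eaf[i], grid$or[i]))
  do.call(rbind, out)
}
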