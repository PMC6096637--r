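# Synthetic admixed cohort generation.
#
# The generator emulates the statistical structure of a two-way admixed
# Arctic cohort: per-individual ancestry proportions on the simplex,
# ancestral allele frequencies diverged Balding-Nichols style around shared
# base frequencies, binomial genotypes given p_ij = sum_k Q_ik F_jk, a
# recessive-effect disease model on top of a fixed baseline risk, and OGTT
# measurements consistent with disease status.

rdirichlet_mat <- function(n, alpha) {
  # zero entries in alpha pin that component to mass 0 (degenerate draw)
  K <- length(alpha)
  g <- vapply(alpha, function(a) {
    if (a <= 0) rep(0, n) else rgamma(n, shape = a, rate = 1)
  }, numeric(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  g / rowSums(g)
}

#' Sample per-individual ancestry proportions
#'
#' Draws rows of the admixture-proportion matrix Q from a Dirichlet
#' distribution. The default concentration (3, 1) gives a mean ancestry
#' split of 75%/25%, emulating the predominantly Inuit ancestry of the
#' Greenlandic cohorts; a zero concentration entry pins that component out
#' (unadmixed individuals).
#'
#' @param n number of individuals (>= 1).
#' @param K number of ancestral populations (>= 2).
#' @param mix_params length-K non-negative Dirichlet concentration; at
#'   least one entry must be positive.
#' @param seed integer seed; the draw is deterministic given it.
#' @return n x K matrix with rows on the simplex.
#' @export
sample_ancestry <- function(n, K = 2, mix_params = c(3, 1), seed = 1) {
  if (length(n) != 1 || n < 1) stop_invalid("n must be a positive count")
  if (length(K) != 1 || K < 2) stop_invalid("K must be >= 2")
  if (length(mix_params) != K)
    stop_invalid("mix_params must have length K = %d", K)
  if (any(mix_params < 0) || sum(mix_params) <= 0)
    stop_invalid("mix_params must be non-negative with a positive sum")
  set.seed(seed)
  Q <- rdirichlet_mat(n, mix_params)
  colnames(Q) <- paste0("q", seq_len(K))
  Q
}

#' Sample ancestral allele frequencies
#'
#' Balding-Nichols-style divergence: for base frequency p and divergence d
#' (an F_ST-like parameter), each component's frequency is drawn from
#' Beta(p(1-d)/d, (1-p)(1-d)/d), which has mean p and variance d p (1-p).
#'
#' @param m number of SNPs.
#' @param divergence divergence parameter in (0, 1); scalar or length K.
#' @param base_freqs base frequencies: scalar, length-m vector, or a
#'   function of m; default draws Uniform(0.05, 0.95).
#' @param K number of ancestral components.
#' @param seed integer seed.
#' @return m x K matrix of frequencies clamped to [1e-6, 1 - 1e-6].
#' @export
sample_ancestral_frequencies <- function(m, divergence = 0.15,
                                         base_freqs = NULL, K = 2,
                                         seed = 1) {
  if (any(divergence <= 0) || any(divergence >= 1))
    stop_invalid("divergence must lie in (0, 1)")
  divergence <- rep_len(divergence, K)
  set.seed(seed)
  p <- if (is.null(base_freqs)) runif(m, 0.05, 0.95)
       else if (is.function(base_freqs)) base_freqs(m)
       else rep_len(base_freqs, m)
  if (any(p <= 0) || any(p >= 1))
    stop_invalid("base frequencies must lie in (0, 1)")
  FF <- vapply(seq_len(K), function(k) {
    d <- divergence[k]
    rbeta(m, shape1 = p * (1 - d) / d, shape2 = (1 - p) * (1 - d) / d)
  }, numeric(m))
  if (m == 1) FF <- matrix(FF, nrow = 1)
  FF <- pmin(pmax(FF, 1e-6), 1 - 1e-6)
  colnames(FF) <- paste0("f", seq_len(K))
  FF
}

#' Sample genotypes under the admixture model
#'
#' Dosage of individual i at SNP j is Binomial(2, p_ij) with
#' p_ij = sum_k Q_ik F_jk (the binomial admixture likelihood's genotype
#' model). Missingness is applied completely at random.
#'
#' @param Q n x K ancestry proportions (rows on the simplex).
#' @param F_mat m x K ancestral effect-allele frequencies.
#' @param missing_rate fraction of entries set missing, in [0, 1).
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
sample_genotypes <- function(Q, F_mat, missing_rate = 0, seed = 1) {
  Q <- as.matrix(Q); F_mat <- as.matrix(F_mat)
  if (ncol(Q) != ncol(F_mat))
    stop_invalid("Q has %d components but F has %d", ncol(Q), ncol(F_mat))
  if (max(abs(rowSums(Q) - 1)) > 1e-8)
    stop_invalid("rows of Q must sum to 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_invalid("missing_rate must lie in [0, 1)")
  n <- nrow(Q); m <- nrow(F_mat)
  set.seed(seed)
  P <- Q %*% t(F_mat)                       # n x m
  dos <- matrix(rbinom(n * m, 2L, as.vector(P)), nrow = n)
  if (missing_rate > 0) {
    drop <- runif(n * m) < missing_rate
    dos[drop] <- NA_integer_
  }
  genotype_matrix(dos)
}

#' Disease-simulation specification
#'
#' Parameters of the recessive-effect disease model: non-homozygotes are
#' diseased with probability `baseline_risk`; homozygous effect-allele
#' carriers with the probability whose odds are `or_effect` times the
#' baseline odds.
#'
#' @param eaf effect allele frequency in (0, 1).
#' @param or_effect odds ratio for homozygous carriers (> 0).
#' @param baseline_risk disease probability for non-homozygotes, in (0, 1).
#' @param n cohort size (>= 1).
#' @param model inheritance mode of the simulated effect; only
#'   `"recessive"` is defined.
#' @return A `disease_spec` list.
#' @export
disease_spec <- function(eaf, or_effect, baseline_risk = 0.1, n = 2948,
                         model = "recessive") {
  if (eaf <= 0 || eaf >= 1) stop_invalid("eaf must lie in (0, 1)")
  if (or_effect <= 0) stop_invalid("or_effect must be positive")
  if (baseline_risk <= 0 || baseline_risk >= 1)
    stop_invalid("baseline_risk must lie in (0, 1)")
  if (n < 1) stop_invalid("n must be >= 1")
  model <- match.arg(model, "recessive")
  structure(list(eaf = eaf, or_effect = or_effect,
                 baseline_risk = baseline_risk, n = as.integer(n),
                 model = model), class = "disease_spec")
}

#' Homozygote disease probability under odds multiplication
#'
#' pi such that odds(pi) = OR * odds(baseline): with b the baseline risk,
#' pi = OR b / (1 - b) / (1 + OR b / (1 - b)). A relative-risk
#' interpretation (pi = OR * b) is deliberately NOT used; the odds ratio is
#' the reported effect measure.
#'
#' @param baseline_risk baseline probability in (0, 1).
#' @param or_effect odds ratio (> 0).
#' @export
homozygote_risk <- function(baseline_risk, or_effect) {
  odds <- or_effect * baseline_risk / (1 - baseline_risk)
  odds / (1 + odds)
}

#' Simulate disease status from causal-SNP dosages
#'
#' @param dosages_at_causal integer vector of 0/1/2 dosages (no missing:
#'   callers must simulate the causal SNP without missingness).
#' @param spec a [disease_spec()].
#' @param seed integer seed.
#' @return Integer 0/1 status vector.
#' @export
simulate_disease_status <- function(dosages_at_causal, spec, seed = 1) {
  stopifnot(inherits(spec, "disease_spec"))
  if (anyNA(dosages_at_causal))
    stop_invalid("missing dosage at the causal SNP is not allowed")
  if (!all(dosages_at_causal %in% 0:2))
    stop_invalid("causal dosages must be 0, 1 or 2")
  set.seed(seed)
  pi_hom <- homozygote_risk(spec$baseline_risk, spec$or_effect)
  p <- ifelse(dosages_at_causal == 2L, pi_hom, spec$baseline_risk)
  rbinom(length(p), 1L, p)
}

#' Simulate a quantitative trait with a recessive effect
#'
#' trait = beta_rec * 1[dosage == 2] + polygenic + noise, where the
#' polygenic component has covariance `grm_background` * GRM (the realized
#' genetic similarity matrix of `G`) and the noise variance is
#' 1 - `grm_background`, so total background variance is 1.
#'
#' @param G a [genotype_matrix()].
#' @param causal_index column index of the causal SNP.
#' @param beta_rec recessive effect in SD units.
#' @param grm_background polygenic variance fraction in [0, 1).
#' @param seed integer seed.
#' @return Numeric trait vector of length n.
#' @export
simulate_quantitative_trait <- function(G, causal_index, beta_rec = 0,
                                        grm_background = 0, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosages); n <- nrow(G$dosages)
  if (causal_index < 1 || causal_index > m)
    stop_invalid("causal_index %d out of range 1..%d", causal_index, m)
  if (!is.finite(beta_rec)) stop_invalid("beta_rec must be finite")
  if (grm_background < 0 || grm_background >= 1)
    stop_invalid("grm_background must lie in [0, 1)")
  set.seed(seed)
  y <- rnorm(n, sd = sqrt(1 - grm_background))
  if (grm_background > 0) {
    K <- compute_grm(G)$matrix
    # scale so the polygenic component contributes grm_background on average
    K <- K / mean(diag(K))
    ev <- eigen(K, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    y <- y + ev$vectors %*% (sqrt(grm_background * lam) * rnorm(n))
    y <- as.vector(y)
  }
  hom <- !is.na(G$dosages[, causal_index]) & G$dosages[, causal_index] == 2L
  y + beta_rec * as.numeric(hom)
}

# OGTT measurements given disease status; distributions respect the
# diagnostic thresholds (cases mostly >7 fasting or >11.1 at 2 h; controls
# mostly below 6.1/7.8).
simulate_ogtt <- function(status) {
  n <- length(status)
  case <- status == 1L
  fpg <- ifelse(case, rnorm(n, 8.2, 1.4), rnorm(n, 5.35, 0.40))
  glu2h <- ifelse(case, rnorm(n, 12.6, 2.4), rnorm(n, 5.9, 0.95))
  fpg <- pmax(fpg, 3.0); glu2h <- pmax(glu2h, 2.5)
  fins <- exp(rnorm(n, log(40) + 0.45 * case, 0.5))
  ins2h <- exp(rnorm(n, log(230) + 0.40 * case, 0.6))
  weight <- pmax(rnorm(n, 72, 14), 40)
  selfreport <- case & runif(n) < 0.45
  data.frame(fpg_mmol_l = round(fpg, 2), glu2h_mmol_l = round(glu2h, 2),
             fins_pmol_l = round(fins, 1), ins2h_pmol_l = round(ins2h, 1),
             weight_kg = round(weight, 1), selfreport_dm = selfreport)
}

#' Simulate a complete admixed case-control cohort
#'
#' End-to-end generator: ancestry proportions, ancestral frequencies,
#' genotypes, a recessive-effect causal SNP (simulated without
#' missingness, with both components' frequency set so the pooled EAF
#' matches `spec$eaf`, unless `causal_F` overrides it), disease status and
#' OGTT phenotypes.
#'
#' @param n individuals; `m` SNPs.
#' @param m SNP count.
#' @param spec a [disease_spec()] for the causal variant.
#' @param K ancestral components.
#' @param mix_params Dirichlet concentration (see [sample_ancestry()]).
#' @param divergence Balding-Nichols divergence.
#' @param missing_rate MCAR missingness for non-causal SNPs.
#' @param causal_F optional length-K ancestral frequencies of the causal
#'   SNP (e.g. `c(0.31, 0.03)` for an Inuit-enriched variant).
#' @param seed integer seed.
#' @return List with `pheno` (phenotype data frame incl. `status`),
#'   `G` (genotype matrix), `Q`, `F_mat`, `causal_index`.
#' @export
simulate_cohort <- function(n = 1000, m = 500,
                            spec = disease_spec(eaf = 0.25, or_effect = 3,
                                                n = n),
                            K = 2, mix_params = c(3, 1), divergence = 0.15,
                            missing_rate = 0, causal_F = NULL, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, 6)
  Q <- sample_ancestry(n, K, mix_params, seed = seeds[1])
  F_mat <- sample_ancestral_frequencies(m, divergence, K = K,
                                        seed = seeds[2])
  causal_index <- max(1L, m %/% 2L)
  F_mat[causal_index, ] <- causal_F %||% rep(spec$eaf, K)
  G <- sample_genotypes(Q, F_mat, missing_rate = 0, seed = seeds[3])
  if (missing_rate > 0) {
    set.seed(seeds[4])
    drop <- matrix(runif(n * m) < missing_rate, n, m)
    drop[, causal_index] <- FALSE
    G$dosages[drop] <- NA_integer_
    G$missing_rate <- colMeans(is.na(G$dosages))
  }
  status <- simulate_disease_status(G$dosages[, causal_index], spec,
                                    seed = seeds[5])
  set.seed(seeds[6])
  ogtt <- simulate_ogtt(status)
  pheno <- data.frame(
    iid = G$iids,
    sex = sample(1:2, n, replace = TRUE, prob = c(0.45, 0.55)),
    age = round(runif(n, 35, 75)),
    cohort = sample(c("B99", "IHIT", "BBH"), n, replace = TRUE,
                    prob = c(0.30, 0.55, 0.15)),
    ogtt,
    status = status
  )
  list(pheno = pheno, G = G, Q = Q, F_mat = F_mat,
       causal_index = causal_index)
}

#' Write a simulated cohort to disk
#'
#' PLINK bed/bim/fam plus the phenotype TSV (schema of
#' [read_phenotypes()]).
#'
#' @param cohort result of [simulate_cohort()].
#' @param prefix output prefix.
#' @export
write_cohort <- function(cohort, prefix) {
  write_plink(cohort$G, prefix, sex = cohort$pheno$sex)
  write_phenotypes(cohort$pheno, paste0(prefix, ".pheno.tsv"))
  invisible(prefix)
}
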