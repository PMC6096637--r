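# OGTT phenotype derivation: glucose-tolerance classification, HOMA-IR,
# Gutt's ISI(0,120), and within-stratum rank-based inverse normal
# transformation.

#' Classify glucose tolerance from OGTT measurements
#'
#' Case (T2D) if self-reported diabetes, fasting plasma glucose > 7 mmol/l,
#' or 2 h plasma glucose > 11.1 mmol/l. Control (NGT) if fasting < 6.1 and
#' 2 h < 7.8 mmol/l and no self-report. Everything else (including records
#' where a missing value prevents confirming NGT) is INDETERMINATE.
#' Boundary equalities (exactly 7.0 / 11.1 / 6.1 / 7.8) follow the strict
#' inequalities: 7.0 fasting is not a case, 6.1 fasting is not a control.
#' Self-report overrides measured values: a self-reporter with a normal
#' OGTT is classified T2D (treated glycaemia is expected to normalise).
#'
#' @param fpg fasting plasma glucose, mmol/l (NA allowed).
#' @param glu2h 2 h plasma glucose, mmol/l (NA allowed).
#' @param selfreport_dm logical self-reported diabetes (NA treated FALSE).
#' @return Character vector with levels T2D / NGT / INDETERMINATE.
#' @export
classify_glucose_tolerance <- function(fpg, glu2h, selfreport_dm = FALSE) {
  nr <- max(length(fpg), length(glu2h), length(selfreport_dm))
  fpg <- rep_len(fpg, nr); glu2h <- rep_len(glu2h, nr)
  sr <- rep_len(as.logical(selfreport_dm), nr)
  if (any(is.na(fpg) & is.na(glu2h) & is.na(sr)))
    stop_invalid("record(s) with fasting glucose, 2 h glucose and self-report all missing")
  sr[is.na(sr)] <- FALSE
  case <- sr | (!is.na(fpg) & fpg > 7) | (!is.na(glu2h) & glu2h > 11.1)
  ctrl <- !sr & !is.na(fpg) & fpg < 6.1 & !is.na(glu2h) & glu2h < 7.8
  ifelse(case, "T2D", ifelse(ctrl, "NGT", "INDETERMINATE"))
}

#' HOMA-IR insulin-resistance index
#'
#' fasting glucose (mmol/l) x fasting insulin (pmol/l converted to uU/ml
#' by /6.945), divided by 22.5.
#'
#' @param fpg fasting plasma glucose, mmol/l (> 0).
#' @param fins fasting serum insulin, pmol/l (> 0).
#' @return Unitless index; NA in gives NA out.
#' @export
homa_ir <- function(fpg, fins) {
  ok <- !is.na(fpg) & !is.na(fins)
  if (any(ok & (fpg <= 0 | fins <= 0)))
    stop_invalid("HOMA-IR requires positive glucose and insulin")
  fpg * (fins / 6.945) / 22.5
}

#' Gutt's insulin sensitivity index ISI(0,120)
#'
#' Glucose disposal rate m = (75000 + (G0 - G120) x 18 x 0.19 x weight)/120
#' (G in mmol/l, the x18 converting to mg/dl; 75,000 mg is the oral load),
#' divided by mean glucose (mmol/l) and by the natural log of mean insulin
#' in uU/ml (pmol/l / 6.945).
#'
#' @param fpg,glu2h fasting and 2 h plasma glucose, mmol/l.
#' @param fins,ins2h fasting and 2 h serum insulin, pmol/l.
#' @param weight body weight, kg.
#' @return Index vector; records whose mean insulin is <= 1 uU/ml (log
#'   argument <= 1, a non-positive denominator) are returned NA and counted
#'   in the `n_flagged` attribute rather than failing the batch.
#' @export
isi_0_120 <- function(fpg, glu2h, fins, ins2h, weight) {
  ok <- !(is.na(fpg) | is.na(glu2h) | is.na(fins) | is.na(ins2h) |
            is.na(weight))
  if (any(ok & (fpg <= 0 | glu2h <= 0 | fins <= 0 | ins2h <= 0 |
                  weight <= 0)))
    stop_invalid("ISI(0,120) requires positive inputs")
  m <- (75000 + (fpg - glu2h) * 18 * 0.19 * weight) / 120
  mean_glu <- (fpg + glu2h) / 2
  mean_ins_uU <- ((fins + ins2h) / 2) / 6.945
  bad <- ok & mean_ins_uU <= 1
  out <- m / mean_glu / log(mean_ins_uU)
  out[bad] <- NA_real_
  out[!ok] <- NA_real_
  attr(out, "n_flagged") <- sum(bad)
  out
}

#' Friedewald LDL-cholesterol (mmol/l)
#'
#' LDL = total cholesterol - HDL - triacylglycerol / 2.2, all mmol/l.
#' @param tc,hdl,tg total, HDL cholesterol and triacylglycerol, mmol/l.
#' @export
friedewald_ldl <- function(tc, hdl, tg) tc - hdl - tg / 2.2

#' Within-stratum rank-based inverse normal transformation
#'
#' Within each stratum, non-missing values are ranked (average ranks for
#' ties) and mapped to standard-normal quantiles via
#' qnorm((r - 0.5) / n_stratum); missing values stay missing; the
#' within-stratum rank order is preserved.
#'
#' @param values numeric trait vector (NA allowed).
#' @param strata vector/factor of stratum labels (e.g. interaction of sex
#'   and cohort), or a data frame whose columns are crossed.
#' @return z-score vector aligned with `values`.
#' @export
quantile_transform <- function(values, strata) {
  if (is.data.frame(strata))
    strata <- interaction(strata, drop = TRUE, sep = ":")
  strata <- as.factor(strata)
  if (length(strata) != length(values))
    stop_invalid("strata and values lengths differ")
  out <- rep(NA_real_, length(values))
  for (lev in levels(strata)) {
    idx <- which(strata == lev & !is.na(values))
    if (length(which(strata == lev)) > 0 && length(idx) < 2)
      stop_invalid("stratum '%s' has fewer than 2 non-missing values", lev)
    r <- rank(values[idx], ties.method = "average")
    out[idx] <- qnorm((r - 0.5) / length(idx))
  }
  out
}

#' Derive the analysis phenotypes for a cohort table
#'
#' Adds `gt_class` (glucose-tolerance class), `homa_ir`, `isi_0_120` and a
#' `z_<trait>` column per requested trait, quantile-transformed within
#' sex-by-cohort strata (the transformation the association analyses use).
#'
#' @param pheno phenotype data frame (schema of [read_phenotypes()]).
#' @param traits character vector of trait columns to transform; defaults
#'   to the derived indices plus the raw OGTT measurements.
#' @param strata character vector of stratification columns.
#' @return `pheno` with derived columns appended.
#' @export
derive_traits <- function(pheno,
                          traits = c("fpg_mmol_l", "glu2h_mmol_l",
                                     "fins_pmol_l", "ins2h_pmol_l",
                                     "homa_ir", "isi_0_120"),
                          strata = c("sex", "cohort")) {
  stopifnot(all(strata %in% names(pheno)))
  pheno$gt_class <- classify_glucose_tolerance(pheno$fpg_mmol_l,
                                               pheno$glu2h_mmol_l,
                                               pheno$selfreport_dm)
  pheno$homa_ir <- homa_ir(pheno$fpg_mmol_l, pheno$fins_pmol_l)
  isi <- isi_0_120(pheno$fpg_mmol_l, pheno$glu2h_mmol_l,
                   pheno$fins_pmol_l, pheno$ins2h_pmol_l,
                   pheno$weight_kg)
  pheno$isi_0_120 <- as.numeric(isi)
  sdef <- pheno[, strata, drop = FALSE]
  for (tr in traits) {
    if (!tr %in% names(pheno))
      stop_invalid("trait column '%s' not present", tr)
    pheno[[paste0("z_", tr)]] <- quantile_transform(pheno[[tr]], sdef)
  }
  pheno
}
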