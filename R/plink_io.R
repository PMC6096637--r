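# PLINK bed/bim/fam and VCF genotype I/O.
#
# The bed codec is implemented here directly: 2-bit SNP-major encoding,
# magic bytes 0x6c 0x1b, mode byte 0x01. Effect allele is stored as PLINK
# allele 1, so the dosage kept in memory is the count of allele 1.

#' Construct a genotype matrix object
#'
#' The common carrier of genotypes for every pipeline stage: an
#' individuals-by-SNPs integer dosage matrix (count of the effect allele,
#' 0/1/2, `NA` for missing) plus per-SNP metadata.
#'
#' @param dosages integer matrix, n individuals x m SNPs, entries 0/1/2/NA.
#' @param snp_ids character vector of m SNP identifiers.
#' @param effect_alleles character vector of m effect-allele labels
#'   (counted allele).
#' @param other_alleles character vector of m non-effect alleles.
#' @param chrom integer/character vector of m chromosome labels.
#' @param pos integer vector of m 1-based base-pair positions.
#' @param iids character vector of n individual identifiers.
#' @return An object of class `genotype_matrix`: a list with the validated
#'   fields above plus `missing_rate`, the per-SNP missingness fraction.
#' @export
genotype_matrix <- function(dosages, snp_ids = NULL, effect_alleles = NULL,
                            other_alleles = NULL, chrom = NULL, pos = NULL,
                            iids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  n <- nrow(dosages)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad))
    stop_invalid("dosages must be 0, 1, 2 or NA; %d other entries found",
                 sum(bad))
  storage.mode(dosages) <- "integer"
  snp_ids <- snp_ids %||% paste0("snp", seq_len(m))
  obj <- structure(list(
    dosages       = dosages,
    snp_ids       = as.character(snp_ids),
    effect_alleles = as.character(effect_alleles %||% rep("A", m)),
    other_alleles = as.character(other_alleles %||% rep("G", m)),
    chrom         = chrom %||% rep(1L, m),
    pos           = as.integer(pos %||% seq_len(m)),
    iids          = as.character(iids %||% paste0("id", seq_len(n))),
    missing_rate  = colMeans(is.na(dosages))
  ), class = "genotype_matrix")
  stopifnot(length(obj$snp_ids) == m, length(obj$effect_alleles) == m,
            length(obj$pos) == m, length(obj$iids) == n)
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(x$missing_rate)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# byte -> 4 dosages lookup for the 2-bit codes
# 00 = hom allele1 (dosage 2), 01 = missing, 10 = het, 11 = hom allele2
.bed_decode_table <- function() {
  codes <- c(2L, NA_integer_, 1L, 0L)
  tab <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    v <- b
    for (s in 1:4) {
      tab[b + 1, s] <- codes[(v %% 4) + 1]
      v <- v %/% 4
    }
  }
  tab
}

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @param sex optional integer vector (1 = male, 2 = female, 0 = unknown)
#'   for the fam file.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix, sex = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- nrow(G$dosages); m <- ncol(G$dosages)
  bim <- data.frame(chrom = G$chrom, id = G$snp_ids, cm = 0L, pos = G$pos,
                    a1 = G$effect_alleles, a2 = G$other_alleles)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$iids, iid = G$iids, pat = 0L, mat = 0L,
                    sex = sex %||% rep(0L, n), pheno = -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code (indexing by dosage + 1; NA handled separately)
  code_of <- c(3L, 2L, 0L)   # dosage 0 -> 11, 1 -> 10, 2 -> 00
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- (4L - n %% 4L) %% 4L
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    g <- G$dosages[, j]
    code <- ifelse(is.na(g), 1L, code_of[g + 1L])
    if (pad > 0L) code <- c(code, rep(3L, pad))  # pad with hom-a2 bits
    bytes <- colSums(matrix(code * mult, nrow = 4L))
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK or VCF
#'
#' @param path for PLINK, the file prefix (no extension) or the `.bed` path;
#'   for VCF, the file path (plain or bgzipped).
#' @param format `"plink"` or `"vcf"`. VCF dosages count ALT alleles;
#'   multi-allelic VCF records are skipped and counted in the
#'   `n_multiallelic_skipped` attribute.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") read_plink(path) else read_vcf_genotypes(path)
}

#' @rdname read_genotypes
#' @export
read_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed_path <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop_invalid("missing PLINK file: %s", f)
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE,
                    colClasses = "character")
  m <- nrow(bim); n <- nrow(fam)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_invalid("%s: bad PLINK bed magic bytes at offset 0", bed_path)
  if (raw[3] != as.raw(0x01))
    stop_invalid("%s: only SNP-major bed (mode byte 0x01) supported", bed_path)
  bpr <- ceiling(n / 4)
  if (length(raw) != 3 + bpr * m)
    stop_invalid("%s: expected %d data bytes for %d x %d, found %d",
                 bed_path, bpr * m, n, m, length(raw) - 3)
  tab <- .bed_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpr)
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    g <- as.vector(t(tab[body[, j] + 1L, , drop = FALSE]))
    dos[, j] <- g[seq_len(n)]
  }
  genotype_matrix(dos, snp_ids = bim[[2]], effect_alleles = bim[[5]],
                  other_alleles = bim[[6]], chrom = bim[[1]],
                  pos = bim[[4]], iids = fam[[2]])
}

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  dos_alt <- function(g) {
    # count ALT alleles from "0/1"-style calls, phased or unphased
    out <- rep(NA_integer_, length(g))
    ok <- !is.na(g) & !grepl("\\.", g)
    parts <- strsplit(g[ok], "[/|]")
    out[ok] <- vapply(parts, function(p) sum(p != "0"), integer(1))
    out
  }
  dos <- vapply(keep, function(j) dos_alt(gt[j, ]),
                integer(ncol(gt)))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  G <- genotype_matrix(dos,
                       snp_ids = fix[keep, "ID"],
                       effect_alleles = fix[keep, "ALT"],
                       other_alleles = fix[keep, "REF"],
                       chrom = fix[keep, "CHROM"],
                       pos = as.integer(fix[keep, "POS"]),
                       iids = colnames(gt))
  attr(G, "n_multiallelic_skipped") <- sum(multi)
  G
}

#' Read / write the cohort phenotype table
#'
#' Tab-separated, `.` for missing. Columns: iid, sex, age, cohort,
#' fpg_mmol_l, glu2h_mmol_l, fins_pmol_l, ins2h_pmol_l, weight_kg,
#' selfreport_dm, status, plus any derived columns.
#'
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  if (!"iid" %in% names(df))
    stop_invalid("%s: phenotype table must contain an 'iid' column", path)
  if ("selfreport_dm" %in% names(df))
    df$selfreport_dm <- as.logical(df$selfreport_dm)
  df
}

#' @rdname read_phenotypes
#' @param df phenotype data frame.
#' @export
write_phenotypes <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}
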