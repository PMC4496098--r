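#' Construct a marker map
#'
#' A marker map describes the SNPs of a genotype matrix: autosome label,
#' physical position (1-based inclusive base pairs) and SNP identifier.
#' Positions must be strictly increasing within a chromosome and SNP ids
#' unique; chromosomes are ordered numerically where the labels are numeric.
#'
#' @param chrom character or integer vector of autosome labels.
#' @param pos integer vector of base-pair positions (>= 1).
#' @param snp_id character vector of unique SNP identifiers.
#' @return A `data.frame` of class `marker_map` with columns
#'   `chrom`, `pos`, `snp_id`, sorted by (chromosome, position).
#' @export
marker_map <- function(chrom, pos, snp_id) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(snp_id))
  map <- data.frame(chrom = as.character(chrom),
                    pos = as.integer(pos),
                    snp_id = as.character(snp_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_ids in marker map: ",
         paste(utils::head(map$snp_id[duplicated(map$snp_id)], 3), collapse = ", "))
  if (any(map$pos < 1L)) stop("marker positions must be >= 1 (1-based bp)")
  map <- map[order(chrom_order(map$chrom), map$pos), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

# numeric sort key for chromosome labels ("2" before "10"); non-numeric
# labels sort after numeric ones, alphabetically
chrom_order <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(n), Inf, n)
  rank(key, ties.method = "min") * 1e6 + as.integer(factor(chrom))
}

#' Construct a genotype matrix
#'
#' Genotypes are coded 0/2 for the two homozygotes, 1 for the heterozygote
#' and `NA` for missing, with columns aligned to a [marker_map()].
#'
#' @param geno integer matrix, individuals in rows, SNPs in columns.
#' @param ids character vector of individual identifiers (one per row).
#' @param map a [marker_map()] with one row per column of `geno`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `ids`, `map`.
#' @export
genotype_matrix <- function(geno, ids, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(ids))
    stop("number of rows (", nrow(geno), ") != number of ids (", length(ids), ")")
  if (ncol(geno) != nrow(map))
    stop("number of columns (", ncol(geno), ") != map length (", nrow(map), ")")
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be in {0,1,2,NA}")
  rownames(geno) <- as.character(ids)
  colnames(geno) <- map$snp_id
  structure(list(geno = geno, ids = as.character(ids), map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chrom)), "chromosomes;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Read PLINK-style text PED/MAP files
#'
#' The PED file is whitespace-delimited with six leading columns
#' (family, individual, sire, dam, sex, phenotype) followed by two allele
#' columns per SNP over \{A,C,G,T\}, with "0" for a missing allele.  The MAP
#' file has four columns (chromosome, snp id, cM, bp).  Biallelic coding is
#' fixed by the first observed allele at each SNP: that allele is the
#' reference, and the genotype code is the count of the other allele.
#' "0 0" becomes missing.  Columns are returned in (chromosome, position)
#' order regardless of MAP file order.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  mp <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(mp) != 4L) stop("MAP file must have 4 columns, found ", ncol(mp))
  map <- marker_map(mp[[1]], as.integer(mp[[4]]), mp[[2]])
  perm <- match(map$snp_id, mp[[2]])  # MAP-file column -> sorted order

  pd <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                          fill = TRUE, data.table = FALSE)
  m <- nrow(map)
  want <- 6L + 2L * m
  if (ncol(pd) != want) {
    # fread pads short rows with NA; locate first offending line for message
    raw <- readLines(ped_path)
    lens <- vapply(strsplit(trimws(raw), "[ \t]+"), length, integer(1))
    bad <- which(lens != want)[1]
    stop("PED row length mismatch at line ", ifelse(is.na(bad), 1L, bad),
         ": expected ", want, " fields")
  }
  ids <- pd[[2]]
  a1 <- as.matrix(pd[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(pd[, 6L + 2L * seq_len(m), drop = FALSE])
  geno <- matrix(NA_integer_, nrow(pd), m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    labs <- unique(as.vector(rbind(x1[!miss], x2[!miss])))  # observation order
    if (length(labs) > 2L)
      stop("SNP ", mp[[2]][j], " has more than two alleles: ",
           paste(labs, collapse = ","))
    if (length(labs) == 0L) next  # all-missing SNP stays NA
    ref <- labs[1L]
    geno[!miss, j] <- (x1[!miss] != ref) + (x2[!miss] != ref)
  }
  genotype_matrix(geno[, perm, drop = FALSE], ids, map)
}

#' Write PLINK-style text PED/MAP files
#'
#' Code 0 homozygotes are written as "A A", heterozygotes as "A G", code 2
#' homozygotes as "G G"; missing genotypes as "0 0".  Reading the files back
#' with [read_ped_map()] recovers the codes up to the reference/alternate
#' relabelling implied by the first-observed-allele rule.
#'
#' @param g a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  map <- g$map
  data.table::fwrite(data.frame(map$chrom, map$snp_id, 0, map$pos),
                     map_path, sep = " ", col.names = FALSE, quote = FALSE)
  code <- g$geno
  lookup <- c("A A", "A G", "G G")
  txt <- matrix("0 0", nrow(code), ncol(code))
  ok <- !is.na(code)
  txt[ok] <- lookup[code[ok] + 1L]
  lead <- data.frame(g$ids, g$ids, 0, 0, 0, -9)
  data.table::fwrite(cbind(lead, as.data.frame(txt)), ped_path, sep = " ",
                     col.names = FALSE, quote = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read or write a pedigree table
#'
#' Four whitespace/tab-delimited columns: animal, sire, dam, birth year.
#' "0", "NA" or an empty field marks an unknown parent.
#'
#' @param path file path.
#' @return `read_pedigree`: a `data.frame` with columns `animal`, `sire`,
#'   `dam`, `birth_year`; unknown parents are `NA`.
#' @export
read_pedigree <- function(path) {
  pd <- data.table::fread(path, header = TRUE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(pd) < 3L) stop("pedigree file needs >= 3 columns")
  unk <- function(x) { x[x %in% c("0", "", "NA")] <- NA; x }
  data.frame(animal = pd[[1]],
             sire = unk(pd[[2]]),
             dam = unk(pd[[3]]),
             birth_year = if (ncol(pd) >= 4L) as.integer(pd[[4]]) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' @rdname read_pedigree
#' @param ped pedigree `data.frame` as returned by [read_pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("animal", "sire", "dam", "birth_year")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read or write a per-animal trait table
#'
#' Headered TSV with columns `animal`, `dpr_pta`, `scs_pta`, `birth_year`
#' (trait columns optional; missing values allowed).
#'
#' @param path file path.
#' @export
read_traits <- function(path) {
  tr <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!"animal" %in% names(tr)) names(tr)[1] <- "animal"
  tr$animal <- as.character(tr$animal)
  tr
}

#' @rdname read_traits
#' @param traits trait `data.frame`.
#' @export
write_traits <- function(traits, path) {
  data.table::fwrite(traits, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the allele counts
#' (the test PLINK applies by default): the p-value is the total probability
#' of heterozygote counts no more probable than the observed one under the
#' hypergeometric-type HWE distribution.  A 1-df chi-square alternative is
#' available behind `method = "chisq"`.
#'
#' @param hom0,het,hom2 genotype counts for the two homozygotes and the
#'   heterozygote.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in (0, 1]; `NA` if all counts are zero.
#' @export
hwe_test <- function(hom0, het, hom2, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(hom0 >= 0, het >= 0, hom2 >= 0)
  n <- hom0 + het + hom2
  if (n < 1L) return(NA_real_)
  if (method == "chisq") {
    p <- (2 * hom0 + het) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    if (any(e == 0)) return(1)
    x2 <- sum((c(hom0, het, hom2) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  n_a <- 2L * hom0 + het
  rare <- min(n_a, 2L * n - n_a)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het) up to a constant: n!/(n0! nh! n2!) 2^nh with n0=(na-nh)/2 etc.
  lp <- vapply(hets, function(h) {
    h0 <- (rare - h) / 2
    h2 <- n - h0 - h
    -lfactorial(h0) - lfactorial(h) - lfactorial(h2) + h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(het, hets)]
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Apply SNP-array quality control
#'
#' Filters are applied in a fixed, logged order: (1) individuals whose
#' missing-genotype fraction is at or above `ind_missing_max`; (2) SNPs with
#' call rate at or below `snp_callrate_min`; (3) SNPs with minor allele
#' frequency at or below `maf_min` (computed on non-missing calls); (4) SNPs
#' whose exact HWE test reaches `-log10 p >= hwe_neglogp_max`.  Defaults
#' correspond to the usual array screens MAF > 0.01, call rate > 0.8,
#' HWE -log10 p < 3, individual missingness < 20%.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min,hwe_neglogp_max,snp_callrate_min,ind_missing_max thresholds.
#' @param hwe_method passed to [hwe_test()].
#' @return A list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (a `qc_report`).
#' @export
apply_qc <- function(g, maf_min = 0.01, hwe_neglogp_max = 3,
                     snp_callrate_min = 0.8, ind_missing_max = 0.2,
                     hwe_method = "exact") {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$geno) == 0L || ncol(g$geno) == 0L) stop("empty genotype matrix")
  n_ind_in <- nrow(g$geno); n_snp_in <- ncol(g$geno)

  miss_frac <- rowMeans(is.na(g$geno))
  keep_ind <- miss_frac < ind_missing_max
  n_rm_ind <- sum(!keep_ind)
  geno <- g$geno[keep_ind, , drop = FALSE]
  ids <- g$ids[keep_ind]
  if (nrow(geno) == 0L) stop("empty dataset after QC: all individuals removed")

  callrate <- colMeans(!is.na(geno))
  keep_cr <- callrate > snp_callrate_min
  n_rm_cr <- sum(!keep_cr)

  nn <- colSums(!is.na(geno))
  p <- colSums(geno, na.rm = TRUE) / (2 * pmax(nn, 1L))
  maf <- pmin(p, 1 - p)
  keep_maf <- keep_cr & maf > maf_min
  n_rm_maf <- sum(keep_cr & !keep_maf)

  keep_hwe <- keep_maf
  idx <- which(keep_maf)
  if (length(idx)) {
    hwe_p <- vapply(idx, function(j) {
      x <- geno[, j]
      hwe_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
               sum(x == 2L, na.rm = TRUE), method = hwe_method)
    }, numeric(1))
    keep_hwe[idx] <- !is.na(hwe_p) & -log10(hwe_p) < hwe_neglogp_max
  }
  n_rm_hwe <- sum(keep_maf & !keep_hwe)

  if (!any(keep_hwe)) stop("empty dataset after QC: all SNPs removed")
  out <- genotype_matrix(geno[, keep_hwe, drop = FALSE], ids,
                         marker_map(g$map$chrom[keep_hwe], g$map$pos[keep_hwe],
                                    g$map$snp_id[keep_hwe]))
  report <- structure(list(
    n_ind_in = n_ind_in, n_ind_out = nrow(out$geno),
    n_snps_in = n_snp_in, n_snps_out = ncol(out$geno),
    removed = c(ind_missingness = n_rm_ind, snp_callrate = n_rm_cr,
                maf = n_rm_maf, hwe = n_rm_hwe),
    thresholds = c(maf_min = maf_min, hwe_neglogp_max = hwe_neglogp_max,
                   snp_callrate_min = snp_callrate_min,
                   ind_missing_max = ind_missing_max)),
    class = "qc_report")
  stopifnot(report$n_snps_in - sum(report$removed[-1]) == report$n_snps_out,
            report$n_ind_in - report$removed[["ind_missingness"]] == report$n_ind_out)
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  individuals: %d in, %d removed (missingness >= %.2f), %d out\n",
              x$n_ind_in, x$removed[["ind_missingness"]],
              x$thresholds[["ind_missing_max"]], x$n_ind_out))
  cat(sprintf("  SNPs: %d in -> callrate -%d, MAF -%d, HWE -%d -> %d out\n",
              x$n_snps_in, x$removed[["snp_callrate"]], x$removed[["maf"]],
              x$removed[["hwe"]], x$n_snps_out))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    key = c("n_ind_in", "n_ind_out", "n_snps_in", "n_snps_out",
            paste0("removed_", names(report$removed)),
            paste0("threshold_", names(report$thresholds))),
    value = c(report$n_ind_in, report$n_ind_out, report$n_snps_in,
              report$n_snps_out, unname(report$removed),
              unname(report$thresholds)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
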