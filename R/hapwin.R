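#' Construct a phased haplotype matrix
#'
#' Phased alleles coded 0/1, two rows per individual: rows 2i-1 and 2i hold
#' the two haplotypes of individual i.  Collapsing row pairs by addition
#' must reproduce the unphased genotype codes at non-missing sites.
#'
#' @param alleles integer matrix (2 x individuals) x SNPs of 0/1.
#' @param ids individual identifiers (half the number of rows).
#' @param map a [marker_map()] aligned to columns.
#' @return object of class `haplotype_matrix`: list with `alleles`, `ids`,
#'   `map`.
#' @export
haplotype_matrix <- function(alleles, ids, map) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) != 2L * length(ids))
    stop("haplotype matrix must have two rows per individual")
  if (ncol(alleles) != nrow(map)) stop("haplotypes and map are not aligned")
  if (!all(alleles %in% 0:1)) stop("phased alleles must be 0/1 with no missing")
  structure(list(alleles = alleles, ids = as.character(ids), map = map),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", length(x$ids), "individuals x", ncol(x$alleles),
      "phased SNPs\n")
  invisible(x)
}

#' Collapse phased haplotypes to unphased genotypes
#'
#' @param hap a [haplotype_matrix()].
#' @return a [genotype_matrix()] with codes 0/1/2.
#' @export
collapse_haplotypes <- function(hap) {
  n <- length(hap$ids)
  g <- hap$alleles[2L * seq_len(n) - 1L, , drop = FALSE] +
       hap$alleles[2L * seq_len(n), , drop = FALSE]
  genotype_matrix(g, hap$ids, hap$map)
}

#' Read/write a two-rows-per-individual phased haplotype text file
#'
#' Whitespace-delimited, no header: columns are individual id, haplotype
#' copy (1 or 2), then one 0/1 allele per SNP.  An adapter for transposed
#' layouts (SNPs in rows) is provided via `transposed = TRUE`.
#'
#' @param path file path.
#' @param map a [marker_map()] describing the SNP columns.
#' @param transposed logical; the file holds SNPs in rows, haplotypes in
#'   columns (first column = snp id).
#' @return a [haplotype_matrix()].
#' @export
read_haplotypes <- function(path, map, transposed = FALSE) {
  d <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (transposed) {
    snp_ids <- as.character(d[[1]])
    a <- t(as.matrix(d[, -1, drop = FALSE]))
    a <- a[, match(map$snp_id, snp_ids), drop = FALSE]
    n2 <- nrow(a)
    ids <- paste0("ind", seq_len(n2 / 2))
    return(haplotype_matrix(a, ids, map))
  }
  ids <- unique(as.character(d[[1]]))
  ord <- order(match(as.character(d[[1]]), ids), d[[2]])
  a <- as.matrix(d[ord, -(1:2), drop = FALSE])
  haplotype_matrix(a, ids, map)
}

#' @rdname read_haplotypes
#' @param hap a [haplotype_matrix()].
#' @export
write_haplotypes <- function(hap, path) {
  n <- length(hap$ids)
  lead <- data.frame(id = rep(hap$ids, each = 2L), copy = rep(1:2, n))
  data.table::fwrite(cbind(lead, as.data.frame(hap$alleles)), path,
                     sep = " ", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build sliding windows over a marker map
#'
#' Windows of exactly `window_snps` SNPs at step `step_snps`, per
#' chromosome; a trailing remainder shorter than the window is dropped, and
#' windows never span chromosomes.
#'
#' @param map a [marker_map()].
#' @param window_snps SNPs per window (default 50).
#' @param step_snps step between window starts (default = `window_snps`,
#'   i.e. non-overlapping; use 1 for fine mapping).
#' @return `data.frame`: `window`, `chrom`, `start_index`, `end_index`
#'   (global column indices), `start_bp`, `end_bp`, `span_bp`, `mid_bp`.
#' @export
make_windows <- function(map, window_snps = 50L, step_snps = window_snps) {
  stopifnot(window_snps >= 1L, step_snps >= 1L)
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < window_snps) {
      warning("chromosome ", ch, " has fewer SNPs than one window; skipped")
      next
    }
    starts <- seq.int(1L, length(idx) - window_snps + 1L, by = step_snps)
    gs <- idx[starts]
    ge <- idx[starts + window_snps - 1L]
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start_index = gs, end_index = ge,
      start_bp = map$pos[gs], end_bp = map$pos[ge],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(window = integer(0), chrom = character(0),
                      start_index = integer(0), end_index = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      span_bp = integer(0), mid_bp = numeric(0)))
  w <- do.call(rbind, out)
  w$span_bp <- w$end_bp - w$start_bp
  w$mid_bp <- (w$start_bp + w$end_bp) / 2
  w <- cbind(window = seq_len(nrow(w)), w)
  rownames(w) <- NULL
  w
}

# haplotype allele strings for one window; returns list(strings per
# haplotype row, per-individual pair indices)
.window_strings <- function(hap, start_index, end_index) {
  sub <- hap$alleles[, start_index:end_index, drop = FALSE]
  do.call(paste0, as.data.frame(sub))
}

#' Summarise one haplotype window
#'
#' Catalogues the distinct haplotype alleles (exact 0/1 strings over the
#' window), ranked by descending frequency with ties broken by first
#' genomic occurrence.  Expected homozygosity per allele is its squared
#' frequency; observed homozygosity is the fraction of individuals whose
#' two haplotypes both equal that allele.  The most-frequent-allele dosage
#' (0/1/2 copies) per individual is returned for association models.
#'
#' @param hap a [haplotype_matrix()].
#' @param window one row of [make_windows()] output (or a list with
#'   `start_index`, `end_index`).
#' @return list of class `window_summary`: `n_alleles`, `freq` (named,
#'   descending), `expected_hh`, `observed_hh`, `dosage` (named by
#'   individual), `obs_hh_total`, `span_bp`.
#' @export
window_summary <- function(hap, window) {
  s <- .window_strings(hap, window$start_index, window$end_index)
  first <- !duplicated(s)
  alleles <- s[first]                      # first-occurrence order
  counts <- as.vector(table(factor(s, levels = alleles)))
  ord <- order(-counts, seq_along(alleles))
  alleles <- alleles[ord]; counts <- counts[ord]
  freq <- counts / length(s)
  n <- length(hap$ids)
  h1 <- s[2L * seq_len(n) - 1L]
  h2 <- s[2L * seq_len(n)]
  homoz <- h1 == h2
  obs <- vapply(alleles, function(a) sum(homoz & h1 == a), numeric(1)) / n
  mf <- alleles[1L]
  dosage <- (h1 == mf) + (h2 == mf)
  names(dosage) <- hap$ids
  structure(list(
    n_alleles = length(alleles),
    freq = stats::setNames(freq, alleles),
    expected_hh = stats::setNames(freq^2, alleles),
    observed_hh = stats::setNames(unname(obs), alleles),
    dosage = dosage,
    obs_hh_total = mean(homoz),
    span_bp = if (!is.null(window$span_bp)) window$span_bp else NA_real_),
    class = "window_summary")
}

#' Expected haplotype homozygosity of an allele
#'
#' Under random union of haplotypes an allele at frequency q yields
#' homozygotes at rate q^2.
#'
#' @param freq allele frequency (or vector of frequencies).
#' @return `freq^2`.
#' @export
expected_hh <- function(freq) freq^2

#' Tabulate window summaries across the genome
#'
#' @param hap a [haplotype_matrix()].
#' @param windows output of [make_windows()].
#' @param top_k how many top-ranked alleles to report per window.
#' @return `data.frame`, one row per window: window coordinates,
#'   `n_alleles`, `freq1..freqK`, `exp_hh1..K`, `obs_hh1..K`,
#'   `exp_hh_total` (sum of squared frequencies), `obs_hh_total`,
#'   `top_share` (share of total observed HH carried by the top K alleles).
#' @export
window_table <- function(hap, windows, top_k = 5L) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    ws <- window_summary(hap, windows[i, ])
    pad <- function(x) { length(x) <- top_k; x }
    fr <- pad(unname(ws$freq)[seq_len(min(top_k, ws$n_alleles))])
    eh <- pad(unname(ws$expected_hh)[seq_len(min(top_k, ws$n_alleles))])
    oh <- pad(unname(ws$observed_hh)[seq_len(min(top_k, ws$n_alleles))])
    tot <- ws$obs_hh_total
    c(n_alleles = ws$n_alleles, stats::setNames(fr, paste0("freq", 1:top_k)),
      stats::setNames(eh, paste0("exp_hh", 1:top_k)),
      stats::setNames(oh, paste0("obs_hh", 1:top_k)),
      exp_hh_total = sum(ws$expected_hh), obs_hh_total = tot,
      top_share = if (tot > 0) sum(oh, na.rm = TRUE) / tot else NA_real_)
  })
  cbind(windows, as.data.frame(do.call(rbind, rows)))
}

#' Most-frequent-haplotype dosage matrix
#'
#' @param hap a [haplotype_matrix()].
#' @param windows output of [make_windows()].
#' @return individuals x windows integer matrix of copies (0/1/2) of each
#'   window's most frequent allele.
#' @export
window_dosage <- function(hap, windows) {
  n <- length(hap$ids)
  D <- matrix(0L, n, nrow(windows),
              dimnames = list(hap$ids, paste0("win", windows$window)))
  for (i in seq_len(nrow(windows)))
    D[, i] <- window_summary(hap, windows[i, ])$dosage
  D
}

#' Correlation of window-mean ROH with haplotype homozygosity
#'
#' For each window the mean of the ROH state matrix over the window's SNPs
#' and all individuals is compared with the total observed haplotype
#' homozygosity (fraction of individuals carrying two identical window
#' haplotypes); the Pearson correlation over windows is returned.
#'
#' @param H ROH state matrix from [roh_state_matrix()] (same map as `hap`).
#' @param hap a [haplotype_matrix()].
#' @param windows output of [make_windows()].
#' @return list with `r` (Pearson correlation), `roh_mean` and `hh` per
#'   window.  `r` is `NA` with a warning when fewer than 2 windows or a
#'   degenerate (zero-variance) side.
#' @export
hh_vs_roh_correlation <- function(H, hap, windows) {
  if (nrow(windows) < 2L) {
    warning("fewer than 2 windows; correlation undefined")
    return(list(r = NA_real_, roh_mean = numeric(0), hh = numeric(0)))
  }
  roh_mean <- vapply(seq_len(nrow(windows)), function(i)
    mean(H[, windows$start_index[i]:windows$end_index[i]]), numeric(1))
  hh <- vapply(seq_len(nrow(windows)), function(i)
    window_summary(hap, windows[i, ])$obs_hh_total, numeric(1))
  if (stats::sd(roh_mean) == 0 || stats::sd(hh) == 0) {
    warning("zero variance across windows; correlation undefined")
    return(list(r = NA_real_, roh_mean = roh_mean, hh = hh))
  }
  list(r = stats::cor(roh_mean, hh), roh_mean = roh_mean, hh = hh)
}

#' Additive or recessive association of the most frequent haplotype
#'
#' Per window, the trait is regressed on the number of copies of the most
#' frequent haplotype allele (additive model, G = 0/1/2) or on the
#' homozygote indicator (recessive model, G = 1 iff two copies), using the
#' same OLS/t machinery as the SNP-level scans.
#'
#' @param hap a [haplotype_matrix()].
#' @param windows output of [make_windows()].
#' @param trait named numeric vector per individual (names matched to
#'   haplotype ids when present).
#' @param model `"additive"` or `"recessive"`.
#' @param covariates optional covariate matrix aligned to individuals.
#' @return an `assoc_profile` over windows (`snp_id` = window label,
#'   `pos` = window midpoint).
#' @export
haplotype_trait_association <- function(hap, windows, trait,
                                        model = c("additive", "recessive"),
                                        covariates = NULL) {
  model <- match.arg(model)
  if (!is.null(names(trait))) trait <- trait[hap$ids]
  D <- window_dosage(hap, windows)
  G <- if (model == "additive") D else (D == 2L) + 0L
  prof <- genome_scan(trait, G,
                      map = NULL, covariates = covariates,
                      response_name = "trait", model = model)
  prof$snp_id <- paste0("win", windows$window)
  prof$chrom <- windows$chrom
  prof$pos <- windows$mid_bp
  prof
}
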