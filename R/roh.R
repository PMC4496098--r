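#' Define a run-of-homozygosity calling rule
#'
#' Exactly one of the two modes is active: by SNP count (a run qualifies
#' when it contains at least `min_snps` consecutive homozygous calls; the
#' default 50 corresponds to roughly 2-3 Mb on a 50K bovine array) or by
#' physical length (`min_bp`, e.g. 3 or 5 Mb).  Heterozygous calls always
#' break a run; missing calls break a run unless a per-run allowance
#' `max_missing_in_run` > 0 is granted.
#'
#' @param min_snps minimum number of SNPs in a run (count mode).
#' @param min_bp minimum physical span in bp (length mode); supplying this
#'   switches to length mode.
#' @param max_missing_in_run missing calls tolerated inside a run.
#' @return A list of class `roh_definition`.
#' @export
roh_definition <- function(min_snps = 50L, min_bp = NULL,
                           max_missing_in_run = 0L) {
  if (!is.null(min_bp)) {
    stopifnot(min_bp > 0)
    mode <- "by-length"
  } else {
    stopifnot(min_snps > 0)
    mode <- "by-count"
  }
  structure(list(mode = mode, min_snps = as.integer(min_snps),
                 min_bp = if (is.null(min_bp)) NULL else as.numeric(min_bp),
                 max_missing_in_run = as.integer(max_missing_in_run)),
            class = "roh_definition")
}

# maximal qualifying runs for one chromosome of one individual.
# hom/miss are logical vectors; returns matrix of (start, end) local indices.
runs_one_chrom <- function(hom, miss, max_missing) {
  if (max_missing == 0L) {
    ok <- hom & !miss
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
  } else {
    # greedy left-to-right scan: a run accumulates homozygous calls and up
    # to max_missing missing calls, is broken by a heterozygote or by the
    # allowance being exceeded, and is trimmed to homozygous endpoints
    n <- length(hom)
    out <- NULL
    j <- 1L
    while (j <= n) {
      if (!miss[j] && hom[j]) {
        start <- j; nmiss <- 0L; lasthom <- j
        k <- j + 1L
        while (k <= n) {
          if (miss[k]) {
            if (nmiss + 1L > max_missing) break
            nmiss <- nmiss + 1L
          } else if (hom[k]) {
            lasthom <- k
          } else break
          k <- k + 1L
        }
        out <- rbind(out, c(start, lasthom))
        j <- k
      } else j <- j + 1L
    }
    if (is.null(out)) out <- matrix(integer(0), 0, 2)
    colnames(out) <- c("start", "end")
    out
  }
}

#' Detect runs of homozygosity
#'
#' Scans every individual chromosome by chromosome for maximal runs of
#' consecutive homozygous genotypes and keeps those meeting the calling
#' rule.  Runs never span chromosomes; physical gap size between adjacent
#' SNPs does not break a run (the logic is SNP-count based).
#'
#' @param g a [genotype_matrix()] (QC'd, map sorted).
#' @param defn a [roh_definition()].
#' @return A `data.frame` of segments: `individual`, `chrom`,
#'   `start_index`/`end_index` (global column indices, inclusive),
#'   `start_bp`/`end_bp` (1-based inclusive), `n_snps`, `length_bp`.
#' @export
detect_roh <- function(g, defn = roh_definition()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(defn, "roh_definition"))
  map <- g$map
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(chrom_idx) <- chroms
  res <- vector("list", nrow(g$geno) * length(chroms))
  k <- 0L
  for (i in seq_len(nrow(g$geno))) {
    x <- g$geno[i, ]
    hom_all <- !is.na(x) & x != 1L
    miss_all <- is.na(x)
    for (ch in chroms) {
      idx <- chrom_idx[[ch]]
      rr <- runs_one_chrom(hom_all[idx], miss_all[idx],
                           defn$max_missing_in_run)
      if (!nrow(rr)) next
      gs <- idx[rr[, "start"]]
      ge <- idx[rr[, "end"]]
      n_snps <- ge - gs + 1L
      len <- map$pos[ge] - map$pos[gs]
      keep <- if (defn$mode == "by-count") n_snps >= defn$min_snps
              else len >= defn$min_bp
      if (!any(keep)) next
      k <- k + 1L
      res[[k]] <- data.frame(
        individual = g$ids[i], chrom = ch,
        start_index = gs[keep], end_index = ge[keep],
        start_bp = map$pos[gs[keep]], end_bp = map$pos[ge[keep]],
        n_snps = n_snps[keep], length_bp = len[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(individual = character(0), chrom = character(0),
                      start_index = integer(0), end_index = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_bp = integer(0)))
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Per-locus ROH state matrix
#'
#' Binary individuals x SNPs matrix H with H\[i, j\] = 1 iff SNP j lies
#' inside some ROH segment of individual i.  Column means of H are the
#' locus-level autozygosity F_L; row means are FROH.
#'
#' @param segments segment `data.frame` from [detect_roh()].
#' @param g the [genotype_matrix()] the segments were called on.
#' @return integer matrix with individual ids as rownames and SNP ids as
#'   colnames.
#' @export
roh_state_matrix <- function(segments, g) {
  H <- matrix(0L, nrow(g$geno), ncol(g$geno),
              dimnames = list(g$ids, g$map$snp_id))
  if (nrow(segments)) {
    ri <- match(segments$individual, g$ids)
    if (anyNA(ri))
      stop("segment references unknown individual: ",
           segments$individual[which(is.na(ri))[1]])
    for (s in seq_len(nrow(segments)))
      H[ri[s], segments$start_index[s]:segments$end_index[s]] <- 1L
  }
  H
}

#' Genomic inbreeding coefficient FROH
#'
#' Fraction of genotyped SNPs lying inside an ROH, per individual (the row
#' mean of the ROH state matrix).
#'
#' @param H matrix from [roh_state_matrix()].
#' @return named numeric vector in `[0, 1]`.
#' @export
froh <- function(H) {
  if (ncol(H) == 0L) stop("FROH undefined with zero SNPs")
  rowMeans(H)
}

#' Length-based genomic inbreeding
#'
#' Alternative FROH: total base pairs covered by ROH segments divided by
#' the physical map span (sum over chromosomes of last minus first SNP
#' position).  Useful for comparisons across by-length calling rules.
#'
#' @param segments segment `data.frame` from [detect_roh()].
#' @param g the source [genotype_matrix()].
#' @return named numeric vector, one entry per individual of `g`.
#' @export
froh_length <- function(segments, g) {
  span <- sum(tapply(g$map$pos, g$map$chrom, function(p) max(p) - min(p)))
  tot <- rep(0, length(g$ids)); names(tot) <- g$ids
  if (nrow(segments)) {
    agg <- tapply(segments$length_bp, segments$individual, sum)
    tot[names(agg)] <- agg
  }
  tot / span
}

#' Locus-level autozygosity F_L
#'
#' Column mean of the ROH state matrix: the fraction of individuals whose
#' ROH covers each SNP.
#'
#' @param H matrix from [roh_state_matrix()].
#' @return named numeric vector in `[0, 1]`, one entry per SNP.
#' @export
locus_autozygosity <- function(H) colMeans(H)

#' Expected autozygous-segment length from an ancestor g generations back
#'
#' A segment inherited identical by descent from a common ancestor `g`
#' generations in the past has expected length 100 / (2 g) centimorgan;
#' with the 1 cM ~ 1 Mb rule of thumb for cattle this is also the expected
#' physical length in Mb (5 Mb at g = 10).
#'
#' @param generations generations back to the common ancestor.
#' @return expected segment length in cM (= Mb at 1 cM/Mb).
#' @export
expected_ibd_segment_length_mb <- function(generations) {
  stopifnot(all(generations > 0))
  100 / (2 * generations)
}

#' Write ROH segments as BED-like TSV
#'
#' Columns: chrom, start_bp, end_bp, individual, n_snps.  Coordinates are
#' 1-based inclusive (stated in a header comment line).
#'
#' @param segments from [detect_roh()].
#' @param path output path.
#' @export
write_roh_segments <- function(segments, path) {
  con <- file(path, "w")
  writeLines("# coordinates are 1-based inclusive base pairs", con)
  close(con)
  data.table::fwrite(segments[, c("chrom", "start_bp", "end_bp",
                                  "individual", "n_snps")],
                     path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
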