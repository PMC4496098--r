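# Shared OLS engine.
#
# All single-locus models in the package are ordinary least squares of a
# response on one predictor column plus optional covariates, with a
# two-sided t test on the predictor slope at n - p - 2 residual degrees of
# freedom (p = number of covariates).  The engine residualises the response
# and the predictor columns on [1 | covariates] (Frisch-Waugh) so a whole
# matrix of predictors is handled with two crossproducts.

NEGLOG10P_CAP <- 300

# y: numeric vector (no NA); X: numeric matrix (no NA), columns = predictors;
# covariates: numeric matrix or NULL.  Returns list(slope, neglog10p, df).
.ols_scan <- function(y, X, covariates = NULL) {
  n <- length(y)
  W <- cbind(rep(1, n), covariates)
  qw <- qr(W)
  ey <- qr.resid(qw, y)
  EX <- qr.resid(qw, X)
  sxx <- colSums(EX^2)
  df <- n - qw$rank - 1L
  slope <- rep(NA_real_, ncol(X))
  nlp <- rep(NA_real_, ncol(X))
  eps <- sqrt(.Machine$double.eps) * n
  ok <- sxx > eps & df > 0L
  if (any(ok)) {
    sxy <- as.vector(crossprod(EX[, ok, drop = FALSE], ey))
    b <- sxy / sxx[ok]
    syy <- sum(ey^2)
    rss <- pmax(syy - b^2 * sxx[ok], 0)
    sigma2 <- rss / df
    tt <- ifelse(sigma2 > 0, b / sqrt(sigma2 / sxx[ok]), Inf * sign(b))
    # -log10 p computed on the log scale so tiny p-values stay accurate
    lp <- (log(2) + stats::pt(-abs(tt), df, log.p = TRUE)) / log(10)
    nlp_ok <- pmin(-lp, NEGLOG10P_CAP)
    nlp_ok[!is.finite(tt)] <- NEGLOG10P_CAP
    slope[ok] <- b
    nlp[ok] <- nlp_ok
  }
  list(slope = slope, neglog10p = nlp, df = df, n = n)
}

#' Single-locus linear regression
#'
#' Ordinary least squares of a response on one locus state (binary ROH
#' state or allele dosage) with optional covariate adjustment:
#' y = b0 + b1 h + (covariates) + e, with a two-sided t test on b1.
#' Complete-case analysis; a locus that is constant among the complete
#' cases yields an undefined (NA) result rather than an error.
#'
#' @param y numeric response per individual.
#' @param h numeric locus state per individual (0/1 or dosage 0/1/2).
#' @param covariates optional numeric matrix of covariates (e.g. PC scores).
#' @return list with `slope`, `neglog10_p` (capped at 300), `n` complete
#'   cases used.
#' @export
locus_regression <- function(y, h, covariates = NULL) {
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  cc <- stats::complete.cases(y, h, if (is.null(covariates)) rep(TRUE, length(y)) else covariates)
  n <- sum(cc)
  if (n < 3L) return(list(slope = NA_real_, neglog10_p = NA_real_, n = n))
  r <- .ols_scan(y[cc], matrix(h[cc], ncol = 1L),
                 if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE])
  list(slope = r$slope[1L], neglog10_p = r$neglog10p[1L], n = n)
}

#' Genome scan: locus regression applied to every SNP
#'
#' Applies [locus_regression()] column-wise to a locus state matrix (the
#' ROH state matrix H, or a dosage matrix).  Individuals with a missing
#' response or covariate are dropped once; columns containing missing
#' values fall back to per-column complete-case fits.
#'
#' @param response numeric vector per individual (FPED, birth year, PTA...).
#' @param X individuals x loci numeric matrix, rows aligned to `response`.
#' @param map optional [marker_map()] aligned to the columns of `X`.
#' @param covariates optional numeric covariate matrix (rows as `response`).
#' @param response_name,model labels stored on the profile.
#' @return A `data.frame` of class `assoc_profile` with columns `snp_id`,
#'   `chrom`, `pos`, `slope`, `neglog10p`, `n`; attributes `response_name`
#'   and `model`.
#' @export
genome_scan <- function(response, X, map = NULL, covariates = NULL,
                        response_name = "response",
                        model = if (is.null(covariates)) "raw" else
                          paste0("pc_adjusted(", ncol(as.matrix(covariates)), ")")) {
  X <- as.matrix(X)
  if (length(response) != nrow(X)) stop("response and X are not aligned")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(X)) stop("covariates and X are not aligned")
  }
  cc <- stats::complete.cases(response,
                              if (is.null(covariates)) rep(TRUE, length(response)) else covariates)
  y <- response[cc]
  Xc <- X[cc, , drop = FALSE]
  cv <- if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE]
  m <- ncol(X)
  slope <- rep(NA_real_, m); nlp <- rep(NA_real_, m); nn <- rep(sum(cc), m)
  has_na <- colSums(is.na(Xc)) > 0L
  if (any(!has_na) && sum(cc) >= 3L) {
    r <- .ols_scan(y, Xc[, !has_na, drop = FALSE], cv)
    slope[!has_na] <- r$slope
    nlp[!has_na] <- r$neglog10p
  }
  for (j in which(has_na)) {
    r <- locus_regression(y, Xc[, j], cv)
    slope[j] <- r$slope; nlp[j] <- r$neglog10_p; nn[j] <- r$n
  }
  prof <- data.frame(
    snp_id = if (!is.null(map)) map$snp_id else
      (colnames(X) %||% paste0("snp", seq_len(m))),
    chrom = if (!is.null(map)) map$chrom else NA_character_,
    pos = if (!is.null(map)) map$pos else NA_integer_,
    slope = slope, neglog10p = nlp, n = nn,
    stringsAsFactors = FALSE)
  attr(prof, "response_name") <- response_name
  attr(prof, "model") <- model
  class(prof) <- c("assoc_profile", "data.frame")
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation genome-wide significance thresholds
#'
#' The response is shuffled across individuals `n_perm` times while
#' covariates stay attached to their individuals; for each permutation the
#' genome scan is rerun and the maximum defined -log10 p is recorded.  The
#' genome-wide suggestive (5%) and significant (1%) thresholds are the 95th
#' and 99th percentiles of that maximum-statistic distribution.
#'
#' @param response,X,covariates as in [genome_scan()]; `X` must be free of
#'   missing values.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed making the thresholds reproducible.
#' @return list of class `perm_thresholds`: `suggestive_neglog10p`,
#'   `significant_neglog10p`, `n_permutations`, `seed`, `max_stats`.
#' @export
permutation_thresholds <- function(response, X, covariates = NULL,
                                   n_perm = 1000L, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X))
    stop("X must not contain missing values for permutation thresholds")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (n_perm < 100L)
    warning("fewer than 100 permutations: tail percentiles are unstable")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  cc <- stats::complete.cases(response,
                              if (is.null(covariates)) rep(TRUE, length(response)) else covariates)
  y <- response[cc]
  Xc <- X[cc, , drop = FALSE]
  cv <- if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE]
  n <- length(y)
  W <- cbind(rep(1, n), cv)
  qw <- qr(W)
  EX <- qr.resid(qw, Xc)
  sxx <- colSums(EX^2)
  df <- n - qw$rank - 1L
  eps <- sqrt(.Machine$double.eps) * n
  ok <- sxx > eps & df > 0L
  if (!any(ok)) stop("no defined locus statistic; cannot permute")
  EXo <- EX[, ok, drop = FALSE]
  sxxo <- sxx[ok]
  set.seed(seed)
  maxes <- vapply(seq_len(n_perm), function(p) {
    yp <- y[sample.int(n)]
    ey <- qr.resid(qw, yp)
    sxy <- as.vector(crossprod(EXo, ey))
    b <- sxy / sxxo
    rss <- pmax(sum(ey^2) - b^2 * sxxo, 0)
    tt <- ifelse(rss > 0, b / sqrt(rss / df / sxxo), Inf)
    lp <- (log(2) + stats::pt(-abs(tt), df, log.p = TRUE)) / log(10)
    min(max(pmin(-lp, NEGLOG10P_CAP)), NEGLOG10P_CAP)
  }, numeric(1))
  structure(list(
    suggestive_neglog10p = unname(stats::quantile(maxes, 0.95)),
    significant_neglog10p = unname(stats::quantile(maxes, 0.99)),
    n_permutations = as.integer(n_perm), seed = as.integer(seed),
    max_stats = maxes), class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf(
    "permutation thresholds (%d permutations, seed %d):\n  suggestive (5%%) -log10 p = %.3f\n  significant (1%%) -log10 p = %.3f\n",
    x$n_permutations, x$seed, x$suggestive_neglog10p, x$significant_neglog10p))
  invisible(x)
}

#' Call significant regions from an association profile
#'
#' SNPs exceeding the chosen threshold are grouped per chromosome; adjacent
#' groups separated by at most `merge_gap_bp` are merged, and regions
#' spanning less than `min_span_bp` are dropped.  The peak is the SNP with
#' the largest -log10 p (ties broken by smallest position).
#'
#' @param profile an `assoc_profile` from [genome_scan()] (needs map info).
#' @param thresholds a `perm_thresholds`, or a single numeric -log10 p cut.
#' @param level `"suggestive"` or `"significant"` (when `thresholds` is a
#'   `perm_thresholds`).
#' @param merge_gap_bp merge groups closer than this (default 1 Mb).
#' @param min_span_bp minimum first-to-last SNP span (default 1 Mb).
#' @param f_l optional per-SNP locus autozygosity, aligned to the profile;
#'   reported at the peak.
#' @param companion optional second `assoc_profile` on the same SNPs (e.g.
#'   the ROH-FPED scan); its -log10 p at the peak is reported.
#' @return `data.frame` of regions: `chrom`, `start_bp`, `end_bp`,
#'   `span_bp`, `n_snps`, `peak_pos`, `peak_neglog10p`, `peak_slope`,
#'   `peak_f_l`, `companion_neglog10p`.
#' @export
call_regions <- function(profile, thresholds, level = "suggestive",
                         merge_gap_bp = 1e6, min_span_bp = 1e6,
                         f_l = NULL, companion = NULL) {
  cut <- if (inherits(thresholds, "perm_thresholds")) {
    if (level == "significant") thresholds$significant_neglog10p
    else thresholds$suggestive_neglog10p
  } else as.numeric(thresholds)
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), span_bp = numeric(0),
                      n_snps = integer(0), peak_pos = numeric(0),
                      peak_neglog10p = numeric(0), peak_slope = numeric(0),
                      peak_f_l = numeric(0), companion_neglog10p = numeric(0))
  hit <- !is.na(profile$neglog10p) & profile$neglog10p >= cut
  if (!any(hit)) return(empty)
  out <- list()
  for (ch in unique(profile$chrom[hit])) {
    sub <- profile[hit & profile$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$pos) > merge_gap_bp))
    for (gi in unique(grp)) {
      blk <- sub[grp == gi, , drop = FALSE]
      span <- max(blk$pos) - min(blk$pos)
      if (span < min_span_bp) next
      pk <- blk[order(-blk$neglog10p, blk$pos), ][1L, ]
      rowi <- match(pk$snp_id, profile$snp_id)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = min(blk$pos), end_bp = max(blk$pos),
        span_bp = span, n_snps = nrow(blk), peak_pos = pk$pos,
        peak_neglog10p = pk$neglog10p, peak_slope = pk$slope,
        peak_f_l = if (is.null(f_l)) NA_real_ else f_l[rowi],
        companion_neglog10p = if (is.null(companion)) NA_real_ else
          companion$neglog10p[match(pk$snp_id, companion$snp_id)],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genome-wide correlation of two association effect profiles
#'
#' Pearson correlation of the per-SNP slopes of two profiles over the SNPs
#' defined in both (used to compare, e.g., ROH-FPED with ROH-trait scans).
#'
#' @param a,b `assoc_profile` objects sharing a SNP set.
#' @return Pearson r, or `NA` if fewer than 2 common defined SNPs.
#' @export
effect_profile_correlation <- function(a, b) {
  i <- match(a$snp_id, b$snp_id)
  ok <- !is.na(i) & !is.na(a$slope) & !is.na(b$slope[i])
  if (sum(ok) < 2L) return(NA_real_)
  stats::cor(a$slope[ok], b$slope[i[ok]])
}

#' Write an association profile as TSV
#' @param profile an `assoc_profile`.
#' @param path output path.
#' @export
write_assoc_profile <- function(profile, path) {
  data.table::fwrite(as.data.frame(profile), path, sep = "\t", quote = FALSE)
  invisible(path)
}
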