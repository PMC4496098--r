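#' Principal components for stratification covariates
#'
#' PCA of an individuals x SNPs matrix (ROH states or genotype dosages).
#' Columns are mean-centred but, by default, not variance-scaled: for
#' binary ROH states scaling would inflate the influence of rarely
#' autozygous loci.  Missing entries are mean-imputed per column before
#' centring (genotype matrices; ROH state matrices have none).  Scores are
#' the projections onto the top-k right singular directions; the sign of
#' each component is fixed by making its largest-magnitude loading
#' positive, so score files are reproducible.
#'
#' @param x numeric matrix (individuals x SNPs), or a [genotype_matrix()].
#' @param k number of components to keep (default 5).
#' @param scale logical; also divide columns by their standard deviation.
#' @param source label recorded in the result (`"roh-states"`,
#'   `"genotypes"`, ...).
#' @return An object of class `autozyg_pca`: list with `scores`
#'   (individuals x k), `explained` (fraction of total variance per kept
#'   component), `sdev`, `source`, `k`.
#' @export
structure_pca <- function(x, k = 5L, scale = FALSE, source = "matrix") {
  if (inherits(x, "genotype_matrix")) {
    source <- "genotypes"
    x <- x$geno
  }
  x <- as.matrix(x) * 1.0
  n <- nrow(x); m <- ncol(x)
  k <- as.integer(k)
  if (k > min(n, m)) stop("k exceeds matrix dimensions")
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0L)) {
      x[is.na(x[, j]), j] <- mu[j]
    }
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  if (scale) {
    sdv <- apply(xc, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xc <- sweep(xc, 2L, sdv, "/")
  }
  total_ss <- sum(xc^2)
  if (n <= m) {
    e <- eigen(tcrossprod(xc), symmetric = TRUE)
    d2 <- pmax(e$values, 0)
    u <- e$vectors[, seq_len(k), drop = FALSE]
    d <- sqrt(d2[seq_len(k)])
    scores <- u * rep(d, each = n)
    # loadings v_j = X' u_j / d_j; used only for the sign convention
    for (j in seq_len(k)) {
      if (d[j] < sqrt(.Machine$double.eps) * sqrt(total_ss + 1)) {
        scores[, j] <- 0
        warning("component ", j, " has zero variance (k exceeds rank)")
        next
      }
      v <- crossprod(xc, u[, j]) / d[j]
      if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
  } else {
    sv <- svd(xc, nu = k, nv = k)
    d2 <- sv$d^2
    d <- sv$d[seq_len(k)]
    scores <- sv$u * rep(d, each = n)
    for (j in seq_len(k)) {
      if (d[j] < sqrt(.Machine$double.eps) * sqrt(total_ss + 1)) {
        scores[, j] <- 0
        warning("component ", j, " has zero variance (k exceeds rank)")
        next
      }
      v <- sv$v[, j]
      if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
    }
  }
  explained <- if (total_ss > 0) d2[seq_len(k)] / sum(d2) else rep(0, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, explained = pmax(explained, 0),
                 sdev = d / sqrt(max(n - 1L, 1L)), source = source, k = k),
            class = "autozyg_pca")
}

#' @export
print.autozyg_pca <- function(x, ...) {
  cat("PCA of", x$source, "-", nrow(x$scores), "individuals, k =", x$k, "\n")
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Correlation of principal components with an inbreeding coefficient
#'
#' Pearson correlation of each PC score with F.  Component signs are
#' arbitrary, so the first component's correlation is sign-normalised to be
#' non-negative; later components are reported as computed.
#'
#' @param pc an `autozyg_pca` from [structure_pca()].
#' @param f named numeric vector of inbreeding coefficients; matched to the
#'   score rownames when named, otherwise taken row-aligned.
#' @return numeric vector of correlations, one per component (`NA` where a
#'   PC or `f` has zero variance).
#' @export
pc_f_correlation <- function(pc, f) {
  scores <- pc$scores
  if (!is.null(names(f)) && !is.null(rownames(scores))) {
    common <- intersect(rownames(scores), names(f))
    scores <- scores[common, , drop = FALSE]
    f <- f[common]
  }
  if (stats::sd(f) == 0) {
    warning("inbreeding coefficient has zero variance; correlations undefined")
    return(rep(NA_real_, ncol(scores)))
  }
  r <- apply(scores, 2L, function(s) {
    if (stats::sd(s) == 0) NA_real_ else stats::cor(s, f)
  })
  if (!is.na(r[1L])) r[1L] <- abs(r[1L])
  r
}

#' Bin inbreeding coefficients into plotting strata
#'
#' Convenience binning of F into low / intermediate / high strata
#' (breaks 0.03 and 0.10 by default), for colouring PCA scatter plots.
#'
#' @param f numeric vector of inbreeding coefficients.
#' @param breaks two interior break points.
#' @return factor with levels `"low"`, `"mid"`, `"high"`.
#' @export
f_strata <- function(f, breaks = c(0.03, 0.10)) {
  cut(f, breaks = c(-Inf, breaks, Inf), labels = c("low", "mid", "high"))
}

#' Write PCA scores and explained variance as TSV
#' @param pc an `autozyg_pca`.
#' @param scores_path,explained_path output paths.
#' @export
write_pca <- function(pc, scores_path, explained_path) {
  df <- data.frame(individual = rownames(pc$scores), pc$scores,
                   check.names = FALSE)
  data.table::fwrite(df, scores_path, sep = "\t", quote = FALSE)
  data.table::fwrite(data.frame(component = colnames(pc$scores),
                                explained = pc$explained),
                     explained_path, sep = "\t", quote = FALSE)
  invisible(c(scores_path, explained_path))
}
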