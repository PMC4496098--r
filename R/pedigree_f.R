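#' Topologically order a pedigree
#'
#' Parents are placed before their offspring.  A cycle (an animal that is
#' its own ancestor) is an error; one offending cycle is reported.
#'
#' @param ped pedigree `data.frame` with columns `animal`, `sire`, `dam`
#'   (`NA` = unknown parent).
#' @return integer permutation of `seq_len(nrow(ped))`.
#' @export
pedigree_order <- function(ped) {
  n <- nrow(ped)
  id <- ped$animal
  if (anyDuplicated(id)) stop("duplicate animal ids in pedigree")
  si <- match(ped$sire, id)  # NA for unknown or unlisted (founder) parents
  di <- match(ped$dam, id)
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (!is.na(p))
      children[[p]] <- c(children[[p]], i)
  }
  ord <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    left <- setdiff(seq_len(n), ord)
    # walk parent links inside the leftover set to exhibit one cycle
    v <- left[1L]; seen <- integer(0)
    while (!(v %in% seen)) {
      seen <- c(seen, v)
      v <- if (!is.na(si[v]) && si[v] %in% left) si[v] else di[v]
    }
    cyc <- seen[which(seen == v):length(seen)]
    stop("pedigree contains a cycle: ",
         paste(id[c(cyc, cyc[1L])], collapse = " -> "))
  }
  ord
}

#' Kinship matrix from a pedigree (tabular method)
#'
#' Computes the full kinship (coancestry) matrix by the tabular rule:
#' processing animals parents-first, phi(x, y) = (phi(sire_x, y) +
#' phi(dam_x, y)) / 2 for y preceding x, phi(x, x) = (1 + phi(sire_x,
#' dam_x)) / 2, with an unknown parent contributing zero and founder
#' self-kinship 1/2.  Parents named in the sire/dam columns but absent from
#' the animal column are treated as unrelated founders.
#'
#' @param ped pedigree `data.frame` (`animal`, `sire`, `dam`, ...).
#' @return symmetric numeric matrix with animal ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  # promote named-but-unlisted parents to founder rows
  extra <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  ped <- ped[, c("animal", "sire", "dam")]
  if (length(extra))
    ped <- rbind(data.frame(animal = extra, sire = NA_character_,
                            dam = NA_character_, stringsAsFactors = FALSE),
                 ped)
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    row <- numeric(n)
    if (!is.na(si[i])) row <- row + A[si[i], ] / 2
    if (!is.na(di[i])) row <- row + A[di[i], ] / 2
    fi <- if (!is.na(si[i]) && !is.na(di[i])) A[si[i], di[i]] else 0
    if (i > 1L) {
      A[i, seq_len(i - 1L)] <- row[seq_len(i - 1L)]
      A[seq_len(i - 1L), i] <- row[seq_len(i - 1L)]
    }
    A[i, i] <- (1 + fi) / 2
  }
  A
}

#' Kinship coefficient between two animals
#'
#' @param ped pedigree `data.frame`.
#' @param a,b animal ids.
#' @return phi(a, b); phi(x, x) = (1 + F_x) / 2.
#' @export
kinship <- function(ped, a, b) {
  A <- kinship_matrix(ped)
  for (x in c(a, b)) if (!x %in% rownames(A)) stop("unknown animal id: ", x)
  A[a, b]
}

#' Wright's pedigree inbreeding coefficient
#'
#' F of an animal is the kinship of its parents.  Animals with one or both
#' parents unknown (or unrecorded) receive F = 0, the usual convention when
#' founders are assumed unrelated and non-inbred.
#'
#' @param ped pedigree `data.frame` with columns `animal`, `sire`, `dam`.
#' @return named numeric vector of F in `[0, 1)`, one entry per animal in
#'   input order.
#' @export
compute_fped <- function(ped) {
  A <- kinship_matrix(ped)
  f <- vapply(seq_len(nrow(ped)), function(i) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) || is.na(d)) 0 else A[s, d]
  }, numeric(1))
  names(f) <- ped$animal
  f
}

#' Write an inbreeding-coefficient vector as two-column TSV
#' @param f named numeric vector from [compute_fped()].
#' @param path output path.
#' @export
write_fped <- function(f, path) {
  data.table::fwrite(data.frame(animal = names(f), fped = unname(f)),
                     path, sep = "\t", quote = FALSE)
  invisible(path)
}
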