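# Fixture builders and independent oracles shared across the test files.

# -- small genotype fixtures -------------------------------------------------

toy_map <- function(m, chrom = "1", spacing = 68000L) {
  marker_map(rep(chrom, m), seq_len(m) * spacing,
             paste0("c", chrom, "_s", seq_len(m)))
}

random_genotypes <- function(n, m, p_het = 0.3, p_missing = 0,
                             chrom = "1") {
  g <- matrix(sample(0:2, n * m, replace = TRUE,
                     prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2)),
              n, m)
  if (p_missing > 0) g[runif(n * m) < p_missing] <- NA_integer_
  genotype_matrix(g, paste0("ind", seq_len(n)), toy_map(m, chrom))
}

# -- independent HWE oracle: closed-form conditional probability of the
#    heterozygote count, enumerated directly ---------------------------------

hwe_oracle <- function(hom0, het, hom2) {
  n <- hom0 + het + hom2
  na <- 2 * hom0 + het
  nb <- 2 * n - na
  hets <- seq.int(min(na, nb) %% 2, min(na, nb), by = 2)
  lp <- vapply(hets, function(h) {
    h0 <- (na - h) / 2
    h2 <- (nb - h) / 2
    lfactorial(n) - lfactorial(h0) - lfactorial(h) - lfactorial(h2) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  obs <- pr[hets == het]
  sum(pr[pr <= obs * (1 + 1e-10)])
}

# -- path-counting oracle for Wright's F -------------------------------------

# all ancestor paths (vectors of animal indices) starting at `from`
all_ancestor_paths <- function(si, di, from) {
  paths <- list(from)
  out <- list(from)
  while (length(paths)) {
    nxt <- list()
    for (p in paths) {
      tip <- p[length(p)]
      for (par in c(si[tip], di[tip])) {
        if (!is.na(par)) {
          q <- c(p, par)
          out[[length(out) + 1L]] <- q
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    paths <- nxt
  }
  out
}

# F by explicit enumeration of common-ancestor path pairs:
# F(x) = sum over path pairs meeting only at the ancestor of
#        (1/2)^(n1+n2+1) * (1 + F_ancestor)
fped_path_oracle <- function(ped) {
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  memo <- rep(NA_real_, length(id))
  f_of <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    s <- si[i]; d <- di[i]
    if (is.na(s) || is.na(d)) { memo[i] <<- 0; return(0) }
    ps <- all_ancestor_paths(si, di, s)
    pd <- all_ancestor_paths(si, di, d)
    tot <- 0
    for (p1 in ps) for (p2 in pd) {
      a <- p1[length(p1)]
      if (p2[length(p2)] != a) next
      if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
      tot <- tot + 0.5^(length(p1) - 1 + length(p2) - 1 + 1) * (1 + f_of(a))
    }
    memo[i] <<- tot
    tot
  }
  vapply(seq_along(id), f_of, numeric(1))
}

# random acyclic pedigree of n animals; parents drawn among earlier animals
random_pedigree <- function(n, p_founder = 0.3) {
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && runif(1) > p_founder) {
      pars <- sample(i - 1L, 2L)
      sire[i] <- paste0("P", pars[1])
      dam[i] <- paste0("P", pars[2])
    }
  }
  data.frame(animal = paste0("P", seq_len(n)), sire = sire, dam = dam,
             birth_year = 2000L + seq_len(n), stringsAsFactors = FALSE)
}

# single-locus Monte-Carlo gene-drop estimate of kinship(a, b)
kinship_mc_oracle <- function(ped, a, b, n_drops = 10000L) {
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  ord <- autozyg::pedigree_order(ped)
  n <- length(id)
  al1 <- matrix(0L, n_drops, n)
  al2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(si[i])) { lab <- lab + 1L; al1[, i] <- lab }
    else {
      pick <- runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick, al1[, si[i]], al2[, si[i]])
    }
    if (is.na(di[i])) { lab <- lab + 1L; al2[, i] <- lab }
    else {
      pick <- runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick, al1[, di[i]], al2[, di[i]])
    }
  }
  ia <- match(a, id); ib <- match(b, id)
  mean((al1[, ia] == al1[, ib]) + (al1[, ia] == al2[, ib]) +
         (al2[, ia] == al1[, ib]) + (al2[, ia] == al2[, ib])) / 4
}

# -- brute-force ROH oracle: all maximal homozygous runs by direct scan ------

roh_brute_force <- function(x, min_snps) {
  hom <- !is.na(x) & x != 1L
  runs <- NULL
  i <- 1L
  while (i <= length(x)) {
    if (hom[i] && (i == 1L || !hom[i - 1L])) {
      j <- i
      while (j < length(x) && hom[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_snps) runs <- rbind(runs, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# -- brute-force haplotype-window counting oracle ----------------------------

window_count_oracle <- function(alleles_sub) {
  rows <- nrow(alleles_sub)
  key <- apply(alleles_sub, 1L, paste0, collapse = "")
  uniq <- unique(key)
  counts <- vapply(uniq, function(u) sum(key == u), numeric(1))
  n_ind <- rows / 2
  hom <- vapply(uniq, function(u) {
    sum(vapply(seq_len(n_ind), function(i)
      key[2 * i - 1] == u && key[2 * i] == u, logical(1)))
  }, numeric(1))
  ord <- order(-counts, match(uniq, key))
  list(alleles = uniq[ord], freq = counts[ord] / rows,
       obs_hh = hom[ord] / n_ind)
}

# default-scale cohort shared by the acceptance-style tests; simulated once
# per session (seed fixed) and memoised together with its derived summaries
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    sim <- simulate_cohort(sim_config(), seed = seed)
    fped <- compute_fped(sim$pedigree)
    seg <- detect_roh(sim$genotypes, roh_definition(min_snps = 50))
    H <- roh_state_matrix(seg, sim$genotypes)
    nonfounder <- sim$pedigree$animal[!(is.na(sim$pedigree$sire) &
                                          is.na(sim$pedigree$dam))]
    .cohort_cache[[key]] <- list(sim = sim, fped = fped, segments = seg,
                                 H = H, froh = froh(H),
                                 nonfounder = nonfounder)
  }
  .cohort_cache[[key]]
}

# small simulated cohort shared by slower tests
small_sim_config <- function(...) {
  sim_config(n_founders = 30L, n_generations = 6L,
             sires_per_generation = 3L, offspring_per_generation = 30L,
             founder_dams_per_generation = 6L,
             n_chromosomes = 2L, snps_per_chromosome = 400L,
             chromosome_length_mb = 50,
             dpr_recessive = data.frame(chrom = "1", pos_bp = 25e6,
                                        effect = -0.4),
             dpr_additive = data.frame(chrom = "2", pos_bp = 10e6,
                                       effect = 0.15),
             scs_recessive = data.frame(chrom = "2", pos_bp = 30e6,
                                        effect = 0.3),
             ...)
}
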