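#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator.  The defaults describe a
#' desk-scale dairy-cattle-like design: a 10-generation overlapping
#' pedigree in which a handful of AI sires father each crop of calves,
#' fresh unrelated dams enter every generation (the wider unrecorded cow
#' population), and a fraction of matings is deliberately drawn toward the
#' dam most related to the sire, producing a long right tail of inbreeding
#' on top of background drift.  The genome is 10 chromosomes of 100 Mb
#' carrying 1,500 evenly spaced SNPs each (15 SNPs/Mb, about the marker
#' density of a bovine 50K array after QC), recombining at 1 cM/Mb under
#' the Haldane (no-interference) model.  Founder haplotype alleles are
#' drawn independently per SNP from a uniform MAF spectrum on
#' \[0.05, 0.5\], so chance homozygosity exists even without inbreeding.
#'
#' Traits mimic transmitting abilities: a fertility-like trait (DPR)
#' carries a negative recessive effect expressed when the locus is truly
#' autozygous plus small additive effects, an udder-health-like trait
#' (SCS) carries a positive recessive effect, and both add Gaussian noise.
#'
#' @param n_founders founding animals (generation 0).
#' @param n_generations generations bred after the founders.
#' @param sires_per_generation males in AI service per generation.
#' @param offspring_per_generation calves born per generation.
#' @param founder_dams_per_generation unrelated females entering the
#'   breeding pool each generation.
#' @param relative_mating probability that a mating picks the candidate
#'   dam with the highest kinship to the sire instead of a random dam.
#' @param selection `"none"` or `"truncation"` (sires picked from the top
#'   `selection_proportion` of candidate males by an infinitesimal-model
#'   breeding value).
#' @param selection_proportion proportion retained under truncation.
#' @param n_chromosomes,chromosome_length_mb,snps_per_chromosome genome
#'   layout.
#' @param cm_per_mb genetic map density (Haldane crossovers; 0 disables
#'   recombination).
#' @param maf_range founder allele-frequency spectrum (uniform bounds).
#' @param base_year,years_per_generation birth-year bookkeeping.
#' @param dpr_recessive,dpr_additive,scs_recessive trait architectures:
#'   data.frames with columns `chrom`, `pos_bp`, `effect`.
#' @param trait_sd residual standard deviation of both traits.
#' @param seed default seed used by [simulate_cohort()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 60L,
                       n_generations = 10L,
                       sires_per_generation = 4L,
                       offspring_per_generation = 60L,
                       founder_dams_per_generation = 12L,
                       relative_mating = 0.15,
                       selection = c("none", "truncation"),
                       selection_proportion = 0.5,
                       n_chromosomes = 10L,
                       chromosome_length_mb = 100,
                       snps_per_chromosome = 1500L,
                       cm_per_mb = 1,
                       maf_range = c(0.05, 0.5),
                       base_year = 1960L,
                       years_per_generation = 5L,
                       dpr_recessive = data.frame(chrom = "3", pos_bp = 40e6,
                                                  effect = -0.4),
                       dpr_additive = data.frame(chrom = c("1", "7"),
                                                 pos_bp = c(50e6, 25e6),
                                                 effect = c(0.15, -0.15)),
                       scs_recessive = data.frame(chrom = "4", pos_bp = 10e6,
                                                  effect = 0.3),
                       trait_sd = 0.25,
                       seed = 1L) {
  selection <- match.arg(selection)
  # trait architectures may arrive as plain lists (e.g. from YAML configs)
  as_loci <- function(x) {
    if (is.null(x)) return(data.frame(chrom = character(0),
                                      pos_bp = numeric(0),
                                      effect = numeric(0)))
    x <- as.data.frame(x)
    x$chrom <- as.character(x$chrom)
    x
  }
  dpr_recessive <- as_loci(dpr_recessive)
  dpr_additive <- as_loci(dpr_additive)
  scs_recessive <- as_loci(scs_recessive)
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              sires_per_generation = as.integer(sires_per_generation),
              offspring_per_generation = as.integer(offspring_per_generation),
              founder_dams_per_generation = as.integer(founder_dams_per_generation),
              relative_mating = relative_mating,
              selection = selection,
              selection_proportion = selection_proportion,
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_mb = chromosome_length_mb,
              snps_per_chromosome = as.integer(snps_per_chromosome),
              cm_per_mb = cm_per_mb,
              maf_range = maf_range,
              base_year = as.integer(base_year),
              years_per_generation = as.integer(years_per_generation),
              dpr_recessive = dpr_recessive,
              dpr_additive = dpr_additive,
              scs_recessive = scs_recessive,
              trait_sd = trait_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_founders > 1L, cfg$n_generations >= 1L,
            cfg$sires_per_generation >= 1L,
            cfg$offspring_per_generation >= 1L,
            cfg$relative_mating >= 0, cfg$relative_mating <= 1,
            cfg$selection_proportion > 0, cfg$selection_proportion <= 1,
            cfg$n_chromosomes >= 1L, cfg$snps_per_chromosome >= 1L,
            cfg$cm_per_mb >= 0, length(cfg$maf_range) == 2L,
            cfg$trait_sd >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Marker map implied by a simulation configuration
#'
#' SNPs are evenly spaced along each chromosome (deterministic given the
#' configuration).
#'
#' @param cfg a [sim_config()].
#' @return a [marker_map()].
#' @export
sim_map <- function(cfg) {
  len_bp <- cfg$chromosome_length_mb * 1e6
  m <- cfg$snps_per_chromosome
  pos1 <- round(seq(from = len_bp / (m + 1), by = len_bp / (m + 1),
                    length.out = m))
  marker_map(chrom = rep(as.character(seq_len(cfg$n_chromosomes)), each = m),
             pos = rep(pos1, cfg$n_chromosomes),
             snp_id = paste0("chr", rep(seq_len(cfg$n_chromosomes), each = m),
                             "_snp", rep(seq_len(m), cfg$n_chromosomes)))
}

#' Simulate a sire-limited, overlapping-generation pedigree
#'
#' Generation 0 holds `n_founders` unrelated animals (half male).  Each
#' later generation: a small team of sires is drawn from the males of the
#' two preceding generations (at random, or by truncation on an
#' infinitesimal breeding value), the dam pool is the females of the two
#' preceding generations plus a crop of fresh unrelated founder dams, and
#' each calf picks a random sire and - with probability `relative_mating` -
#' the available dam most akin to that sire (otherwise a random dam).
#' Parents are always strictly older, so the pedigree is acyclic by
#' construction.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return pedigree `data.frame`: `animal`, `sire`, `dam`, `birth_year`,
#'   `sex` ("M"/"F"), `generation`.
#' @export
simulate_pedigree <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  n_total_guess <- cfg$n_founders +
    cfg$n_generations * (cfg$offspring_per_generation +
                           cfg$founder_dams_per_generation)
  id <- character(n_total_guess)
  sire <- rep(NA_character_, n_total_guess)
  dam <- rep(NA_character_, n_total_guess)
  sex <- character(n_total_guess)
  gen <- integer(n_total_guess)
  bv <- numeric(n_total_guess)
  # incremental kinship matrix, phi[i, j]
  phi <- matrix(0, n_total_guess, n_total_guess)
  n <- 0L
  add_animal <- function(a_sire, a_dam, a_sex, a_gen) {
    n <<- n + 1L
    i <- n
    id[i] <<- sprintf("A%05d", i)
    sire[i] <<- a_sire; dam[i] <<- a_dam
    sex[i] <<- a_sex; gen[i] <<- a_gen
    si <- if (is.na(a_sire)) NA_integer_ else match(a_sire, id[seq_len(i - 1L)])
    di <- if (is.na(a_dam)) NA_integer_ else match(a_dam, id[seq_len(i - 1L)])
    row <- numeric(i - 1L)
    if (!is.na(si)) row <- row + phi[si, seq_len(i - 1L)] / 2
    if (!is.na(di)) row <- row + phi[di, seq_len(i - 1L)] / 2
    fi <- if (!is.na(si) && !is.na(di)) phi[si, di] else 0
    if (i > 1L) { phi[i, seq_len(i - 1L)] <<- row; phi[seq_len(i - 1L), i] <<- row }
    phi[i, i] <<- (1 + fi) / 2
    bv[i] <<- if (is.na(si) && is.na(di)) stats::rnorm(1) else
      mean(c(if (is.na(si)) stats::rnorm(1) else bv[si],
             if (is.na(di)) stats::rnorm(1) else bv[di])) +
        stats::rnorm(1, sd = sqrt(0.5))
    i
  }
  for (i in seq_len(cfg$n_founders))
    add_animal(NA_character_, NA_character_,
               if (i <= cfg$n_founders / 2) "M" else "F", 0L)
  for (g in seq_len(cfg$n_generations)) {
    recent <- which(gen[seq_len(n)] %in% c(g - 1L, g - 2L))
    males <- recent[sex[recent] == "M"]
    if (!length(males)) stop("infeasible config: no candidate sires at generation ", g)
    if (cfg$selection == "truncation") {
      keep <- max(1L, ceiling(length(males) * cfg$selection_proportion))
      males <- males[order(-bv[males])][seq_len(keep)]
    }
    sires <- if (length(males) <= cfg$sires_per_generation) males else
      sample(males, cfg$sires_per_generation)
    # fresh unrelated dams entering this generation's pool
    for (k in seq_len(cfg$founder_dams_per_generation))
      add_animal(NA_character_, NA_character_, "F", g - 1L)
    recent <- which(gen[seq_len(n)] %in% c(g - 1L, g - 2L))
    dams <- recent[sex[recent] == "F"]
    if (!length(dams)) stop("infeasible config: no candidate dams at generation ", g)
    for (k in seq_len(cfg$offspring_per_generation)) {
      s <- if (length(sires) == 1L) sires else sample(sires, 1L)
      d <- if (stats::runif(1) < cfg$relative_mating) {
        # deliberately mate toward kin: dam drawn with weight = kinship
        kin <- phi[s, dams]
        if (sum(kin) == 0 || length(dams) == 1L) {
          if (length(dams) == 1L) dams else sample(dams, 1L)
        } else sample(dams, 1L, prob = kin)
      } else if (length(dams) == 1L) dams else sample(dams, 1L)
      add_animal(id[s], id[d], if (stats::runif(1) < 0.5) "M" else "F", g)
    }
  }
  out <- data.frame(animal = id[seq_len(n)], sire = sire[seq_len(n)],
                    dam = dam[seq_len(n)],
                    birth_year = cfg$base_year +
                      gen[seq_len(n)] * cfg$years_per_generation,
                    sex = sex[seq_len(n)], generation = gen[seq_len(n)],
                    stringsAsFactors = FALSE)
  out
}

# one recombinant gamete: given the parent's two haplotype rows over one
# chromosome, returns the indices (1/2) of the transmitted strand per SNP
.gamete_strand <- function(pos_mb, len_mb, cm_per_mb) {
  nx <- stats::rpois(1L, len_mb * cm_per_mb / 100)
  start <- sample.int(2L, 1L)
  if (nx == 0L) return(rep.int(start, length(pos_mb)))
  xo <- sort(stats::runif(nx, 0, len_mb))
  crossings <- findInterval(pos_mb, xo)
  1L + (start - 1L + crossings) %% 2L
}

#' Gene-drop haplotypes through a pedigree
#'
#' Every founder receives two uniquely labelled haplotypes with alleles
#' drawn per SNP from the configured founder frequency spectrum.  Each
#' transmission recombines the parental haplotypes with Haldane-model
#' crossovers at `cm_per_mb`; founder-origin labels travel with the
#' alleles, so true autozygosity (both alleles descending from the same
#' founder allele copy) is known exactly at every SNP.
#'
#' @param ped pedigree as from [simulate_pedigree()] (only `animal`,
#'   `sire`, `dam` are used; parents must precede usage topologically,
#'   which [pedigree_order()] enforces internally).
#' @param cfg a [sim_config()] (genome layout and founder spectrum).
#' @param seed integer seed (defaults to `cfg$seed + 1`).
#' @return list of class `sim_output`: `pedigree`, `map`,
#'   `haplotypes` (a [haplotype_matrix()]), `origins` (2n x SNPs integer
#'   label matrix), `genotypes` (a [genotype_matrix()]),
#'   `true_autozygosity` (n x SNPs 0/1 matrix), `founder_freq`.
#' @export
gene_drop <- function(ped, cfg = sim_config(), seed = cfg$seed + 1L) {
  set.seed(seed)
  map <- sim_map(cfg)
  m <- nrow(map)
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  id <- ped$animal
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  founder_freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  hap <- matrix(0L, 2L * n, m)
  org <- matrix(0L, 2L * n, m)
  chrom_idx <- split(seq_len(m), map$chrom)[unique(map$chrom)]
  pos_mb <- map$pos / 1e6
  len_mb <- cfg$chromosome_length_mb
  next_label <- 1L
  for (i in ord) {
    r1 <- 2L * i - 1L; r2 <- 2L * i
    for (which_par in 1:2) {
      p <- if (which_par == 1L) si[i] else di[i]
      row <- if (which_par == 1L) r1 else r2
      if (is.na(p)) {
        # founder gamete: fresh labelled haplotype
        hap[row, ] <- stats::rbinom(m, 1L, founder_freq)
        org[row, ] <- next_label
        next_label <- next_label + 1L
      } else {
        pr1 <- 2L * p - 1L; pr2 <- 2L * p
        for (idx in chrom_idx) {
          strand <- .gamete_strand(pos_mb[idx], len_mb, cfg$cm_per_mb)
          from1 <- strand == 1L
          hap[row, idx] <- ifelse(from1, hap[pr1, idx], hap[pr2, idx])
          org[row, idx] <- ifelse(from1, org[pr1, idx], org[pr2, idx])
        }
      }
    }
  }
  # interleave so rows 2i-1, 2i belong to individual i in pedigree order
  hm <- haplotype_matrix(hap, id, map)
  auto <- (org[2L * seq_len(n) - 1L, , drop = FALSE] ==
             org[2L * seq_len(n), , drop = FALSE]) + 0L
  rownames(auto) <- id
  colnames(auto) <- map$snp_id
  structure(list(pedigree = ped, map = map, haplotypes = hm, origins = org,
                 genotypes = collapse_haplotypes(hm),
                 true_autozygosity = auto, founder_freq = founder_freq,
                 config = cfg, seed = seed),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output:", nrow(x$pedigree), "animals,", nrow(x$map), "SNPs on",
      x$config$n_chromosomes, "chromosomes; mean true autozygosity",
      sprintf("%.3f\n", mean(x$true_autozygosity)))
  invisible(x)
}

# map a (chrom, pos_bp) locus to the nearest SNP column index
.locus_column <- function(map, chrom, pos_bp) {
  idx <- which(map$chrom == as.character(chrom))
  if (!length(idx)) stop("trait locus chromosome ", chrom, " not on map")
  idx[which.min(abs(map$pos[idx] - pos_bp))]
}

#' Simulate transmitting-ability-like traits
#'
#' Trait value = sum of additive effects times allele dosage at each
#' additive locus + sum of recessive effects times the true-autozygosity
#' indicator at each recessive locus + Gaussian noise.  The fertility-like
#' trait (DPR) uses the configured negative recessive effects, the
#' udder-health-like trait (SCS) positive ones.  Birth years come from the
#' pedigree.
#'
#' @param sim a `sim_output` from [gene_drop()].
#' @param cfg a [sim_config()] (trait architecture; defaults to the one in
#'   `sim`).
#' @param seed integer seed (defaults to `cfg$seed + 2`).
#' @return trait `data.frame`: `animal`, `dpr_pta`, `scs_pta`,
#'   `birth_year`.
#' @export
simulate_traits <- function(sim, cfg = sim$config, seed = cfg$seed + 2L) {
  set.seed(seed)
  n <- nrow(sim$pedigree)
  geno <- sim$genotypes$geno
  auto <- sim$true_autozygosity
  map <- sim$map
  one_trait <- function(additive, recessive) {
    v <- stats::rnorm(n, 0, cfg$trait_sd)
    if (!is.null(additive) && nrow(additive))
      for (k in seq_len(nrow(additive))) {
        j <- .locus_column(map, additive$chrom[k], additive$pos_bp[k])
        v <- v + additive$effect[k] * geno[, j]
      }
    if (!is.null(recessive) && nrow(recessive))
      for (k in seq_len(nrow(recessive))) {
        j <- .locus_column(map, recessive$chrom[k], recessive$pos_bp[k])
        v <- v + recessive$effect[k] * auto[, j]
      }
    v
  }
  data.frame(animal = sim$pedigree$animal,
             dpr_pta = one_trait(cfg$dpr_additive, cfg$dpr_recessive),
             scs_pta = one_trait(NULL, cfg$scs_recessive),
             birth_year = sim$pedigree$birth_year,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_pedigree()], [gene_drop()] and
#' [simulate_traits()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; the three stages use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return a `sim_output` with an additional `traits` element.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = cfg$seed) {
  ped <- simulate_pedigree(cfg, seed = seed)
  sim <- gene_drop(ped, cfg, seed = seed + 1L)
  sim$traits <- simulate_traits(sim, cfg, seed = seed + 2L)
  sim
}

#' Inject missing genotypes at random
#'
#' Sets a given fraction of genotype calls to missing; used to exercise QC
#' and missing-data paths on otherwise complete simulated data.
#'
#' @param g a [genotype_matrix()].
#' @param rate fraction of calls to blank out.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with `NA`s.
#' @export
inject_missingness <- function(g, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  geno <- g$geno
  k <- round(rate * length(geno))
  if (k > 0) geno[sample.int(length(geno), k)] <- NA_integer_
  genotype_matrix(geno, g$ids, g$map)
}

#' Write the simulated cohort's files
#'
#' Emits PED/MAP genotypes, pedigree TSV, phased haplotype text, true
#' autozygosity TSV and trait TSV into a directory, plus a `sim_config.yaml`
#' echoing the configuration and seed.
#'
#' @param sim a `sim_output` (ideally from [simulate_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ped = file.path(dir, "genotypes.ped"),
             map = file.path(dir, "genotypes.map"),
             pedigree = file.path(dir, "pedigree.tsv"),
             haplotypes = file.path(dir, "haplotypes.txt"),
             autozygosity = file.path(dir, "true_autozygosity.tsv"),
             traits = file.path(dir, "traits.tsv"),
             config = file.path(dir, "sim_config.yaml"))
  write_ped_map(sim$genotypes, paths["ped"], paths["map"])
  write_pedigree(sim$pedigree, paths["pedigree"])
  write_haplotypes(sim$haplotypes, paths["haplotypes"])
  data.table::fwrite(data.frame(animal = rownames(sim$true_autozygosity),
                                sim$true_autozygosity, check.names = FALSE),
                     paths["autozygosity"], sep = "\t", quote = FALSE)
  if (!is.null(sim$traits)) write_traits(sim$traits, paths["traits"])
  cfg <- sim$config
  cfg$dpr_recessive <- as.list(cfg$dpr_recessive)
  cfg$dpr_additive <- as.list(cfg$dpr_additive)
  cfg$scs_recessive <- as.list(cfg$scs_recessive)
  cfg$gene_drop_seed <- sim$seed
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
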