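test_that("a single sire produces only half- and full-sib offspring", {
  cfg <- sim_config(n_founders = 10L, n_generations = 3L,
                    sires_per_generation = 1L,
                    offspring_per_generation = 10L,
                    founder_dams_per_generation = 2L,
                    relative_mating = 0)
  ped <- simulate_pedigree(cfg, seed = 2)
  g3 <- ped[ped$generation == 3L, ]
  expect_equal(length(unique(g3$sire)), 1L)
})

test_that("random mating in a large founder pool leaves F near zero", {
  cfg <- sim_config(n_founders = 200L, n_generations = 3L,
                    sires_per_generation = 40L,
                    offspring_per_generation = 60L,
                    founder_dams_per_generation = 40L,
                    relative_mating = 0)
  ped <- simulate_pedigree(cfg, seed = 4)
  f <- compute_fped(ped)
  last <- ped$animal[ped$generation == max(ped$generation)]
  expect_lt(mean(f[last]), 0.02)
})

test_that("default pedigree reaches the emulated inbreeding spread", {
  ped <- simulate_pedigree(sim_config(), seed = 1)
  f <- compute_fped(ped)
  nf <- ped$animal[!(is.na(ped$sire) & is.na(ped$dam))]
  expect_lte(min(f[nf]), 0.02)
  expect_gte(max(f[nf]), 0.25)
  expect_gte(mean(f[nf]), 0.03)
  expect_lte(mean(f[nf]), 0.10)
  # parents strictly older: acyclic by construction
  expect_silent(pedigree_order(ped))
})

test_that("gene drop collapses to genotypes and tracks founder labels", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 3)
  n <- nrow(sim$pedigree)
  a <- sim$haplotypes$alleles
  expect_equal(sim$genotypes$geno,
               a[2 * (1:n) - 1, ] + a[2 * (1:n), ], ignore_attr = TRUE)
  # autozygous implies homozygous
  expect_true(all(sim$genotypes$geno[sim$true_autozygosity == 1L] != 1L))
  # founders carry two distinct labels everywhere
  founders <- which(is.na(sim$pedigree$sire) & is.na(sim$pedigree$dam))
  expect_true(all(sim$true_autozygosity[founders, ] == 0L))
})

test_that("zero recombination transmits whole parental chromosomes", {
  cfg <- sim_config(n_founders = 2L, n_generations = 1L,
                    sires_per_generation = 1L,
                    offspring_per_generation = 40L,
                    founder_dams_per_generation = 0L,
                    relative_mating = 0, cm_per_mb = 0,
                    n_chromosomes = 2L, snps_per_chromosome = 100L)
  sim <- gene_drop(simulate_pedigree(cfg, seed = 6), cfg, seed = 7)
  org <- sim$origins
  map <- sim$map
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    # each transmitted chromosome carries exactly one founder label
    expect_true(all(apply(org[, idx], 1, function(r) length(unique(r))) == 1L))
  }
})

test_that("crossover count averages ~1 per 100 Mb at 1 cM/Mb", {
  set.seed(31)
  counts <- replicate(3000, {
    strand <- autozyg:::.gamete_strand(seq(0.5, 99.5, by = 1), 100, 1)
    sum(diff(strand) != 0)
  })
  # observed switches undercount crossovers slightly (double crossovers
  # between adjacent SNPs cancel); Haldane expectation at 1 Mb spacing:
  # sum over intervals of P(odd # crossovers) = 99 * 0.5(1-exp(-0.02))
  expected <- 99 * 0.5 * (1 - exp(-2 * 0.01))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.02)
})

test_that("full-sib offspring average 25% true autozygosity", {
  # many independent families (founder couple -> two full sibs -> five
  # offspring); within-family fractions share the realised parental
  # gametes, so the standard error is taken over family means
  n_fam <- 400L; per_fam <- 5L
  fam <- seq_len(n_fam)
  ped <- rbind(
    data.frame(animal = c(paste0("A", fam), paste0("B", fam)),
               sire = NA_character_, dam = NA_character_),
    data.frame(animal = c(paste0("C", fam), paste0("D", fam)),
               sire = rep(paste0("A", fam), 2),
               dam = rep(paste0("B", fam), 2)),
    data.frame(animal = paste0("O", rep(fam, each = per_fam), "_",
                               rep(seq_len(per_fam), n_fam)),
               sire = rep(paste0("C", fam), each = per_fam),
               dam = rep(paste0("D", fam), each = per_fam)))
  ped$birth_year <- 2000L
  cfg <- sim_config(n_chromosomes = 10L, snps_per_chromosome = 150L)
  sim <- gene_drop(ped, cfg, seed = 8)
  off <- grep("^O", ped$animal, value = TRUE)
  expect_gte(length(off), 2000L)
  frac <- rowMeans(sim$true_autozygosity[off, ])
  fam_mean <- tapply(frac, sub("_.*", "", sub("^O", "", off)), mean)
  se <- sd(fam_mean) / sqrt(length(fam_mean))
  expect_lt(abs(mean(fam_mean) - 0.25), 3 * se)
})

test_that("expected true autozygosity equals pedigree F across designs", {
  # replicate gene drops over a fixed pedigree: E[autozygous fraction] = F
  cfg <- sim_config(n_chromosomes = 4L, snps_per_chromosome = 100L)
  designs <- list(
    # parent-offspring mating: F = 0.25
    data.frame(animal = c("A", "B", "C", "X"), sire = c(NA, NA, "A", "A"),
               dam = c(NA, NA, "B", "C"), stringsAsFactors = FALSE),
    # half-sib mating: F = 0.125
    data.frame(animal = c("A", "B", "B2", "C", "D", "X"),
               sire = c(NA, NA, NA, "A", "A", "C"),
               dam = c(NA, NA, NA, "B", "B2", "D"), stringsAsFactors = FALSE),
    # first-cousin mating: F = 0.0625
    data.frame(animal = c("GA", "GB", "P1", "P2", "M1", "M2", "C1", "C2", "X"),
               sire = c(NA, NA, "GA", "GA", NA, NA, "P1", "P2", "C1"),
               dam = c(NA, NA, "GB", "GB", NA, NA, "M1", "M2", "C2"),
               stringsAsFactors = FALSE))
  for (ped in designs) {
    f_x <- compute_fped(ped)[["X"]]
    fracs <- vapply(1:60, function(s) {
      sim <- gene_drop(ped, cfg, seed = 1000 + s)
      mean(sim$true_autozygosity["X", ])
    }, numeric(1))
    se <- sd(fracs) / sqrt(length(fracs))
    expect_lt(abs(mean(fracs) - f_x), 3 * se + 0.005)
  }
})

test_that("detected ROH cover long true autozygous tracts", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 5)
  seg <- detect_roh(sim$genotypes, roh_definition(min_snps = 50))
  H <- roh_state_matrix(seg, sim$genotypes)
  auto <- sim$true_autozygosity
  # every true autozygous tract of >= 50 SNPs lies inside a called run
  # (chance homozygosity can only extend runs, never truncate them)
  for (i in seq_len(nrow(auto))) {
    r <- rle(auto[i, ] == 1L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths >= 50L)
    for (k in long)
      expect_true(all(H[i, starts[k]:ends[k]] == 1L))
  }
})

test_that("traits carry the planted architecture", {
  cfg <- small_sim_config(trait_sd = 0)
  cfg$dpr_additive <- cfg$dpr_additive[0, ]
  cfg$dpr_recessive <- data.frame(chrom = "1", pos_bp = 25e6, effect = -0.4)
  sim <- simulate_cohort(cfg, seed = 12)
  tr <- sim$traits
  j <- autozyg:::.locus_column(sim$map, "1", 25e6)
  # single recessive locus, no noise: exactly two trait values
  expect_equal(sort(unique(tr$dpr_pta)), c(-0.4, 0))
  expect_equal(tr$dpr_pta, -0.4 * sim$true_autozygosity[, j],
               ignore_attr = TRUE)
  # zero effects, noise sd 1 -> variance ~ 1
  cfg2 <- small_sim_config(trait_sd = 1)
  cfg2$dpr_additive <- cfg2$dpr_additive[0, ]
  cfg2$dpr_recessive <- cfg2$dpr_recessive[0, ]
  sim2 <- simulate_cohort(cfg2, seed = 13)
  expect_lt(abs(var(sim2$traits$dpr_pta) - 1), 0.25)
  # birth years follow generations
  expect_equal(tr$birth_year,
               cfg$base_year + sim$pedigree$generation * cfg$years_per_generation)
})

test_that("missingness injection hits the requested rate and QC path runs", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg, seed = 21)
  gm <- inject_missingness(sim$genotypes, 0.05, seed = 2)
  expect_equal(mean(is.na(gm$geno)), 0.05, tolerance = 0.002)
  res <- apply_qc(gm)
  expect_gt(ncol(res$genotypes$geno), 0)
})

test_that("simulation output files round trip", {
  cfg <- sim_config(n_founders = 8L, n_generations = 2L,
                    sires_per_generation = 2L, offspring_per_generation = 8L,
                    founder_dams_per_generation = 2L,
                    n_chromosomes = 2L, snps_per_chromosome = 60L,
                    dpr_recessive = data.frame(chrom = "1", pos_bp = 25e6,
                                               effect = -0.4),
                    dpr_additive = NULL,
                    scs_recessive = data.frame(chrom = "2", pos_bp = 30e6,
                                               effect = 0.3))
  sim <- simulate_cohort(cfg, seed = 30)
  dir <- withr::local_tempdir()
  paths <- write_sim_output(sim, dir)
  expect_true(all(file.exists(paths)))
  ped2 <- read_pedigree(paths["pedigree"])
  expect_equal(ped2$animal, sim$pedigree$animal)
  expect_equal(is.na(ped2$sire), is.na(sim$pedigree$sire))
  hap2 <- read_haplotypes(paths["haplotypes"], sim$map)
  expect_equal(hap2$alleles, sim$haplotypes$alleles, ignore_attr = TRUE)
  cfg2 <- yaml::read_yaml(paths["config"])
  expect_equal(cfg2$seed, cfg$seed)
})
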