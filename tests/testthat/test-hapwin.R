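make_hap <- function(alleles, map = NULL) {
  n <- nrow(alleles) / 2
  if (is.null(map)) map <- toy_map(ncol(alleles))
  haplotype_matrix(alleles, paste0("i", seq_len(n)), map)
}

test_that("window construction counts and spans are exact", {
  expect_equal(nrow(make_windows(toy_map(100), 50, 50)), 2L)
  expect_equal(nrow(make_windows(toy_map(99), 50, 50)), 1L)
  expect_warning(w <- make_windows(toy_map(10), 50), "fewer SNPs")
  expect_equal(nrow(w), 0L)
  w <- make_windows(toy_map(100, spacing = 68000L), 50, 50)
  expect_equal(w$span_bp, rep(49 * 68000L, 2))
  # step 1 slides one SNP at a time
  expect_equal(nrow(make_windows(toy_map(60), 50, 1)), 11L)
  # windows never span chromosomes
  map2 <- marker_map(rep(c("1", "2"), each = 50),
                     rep(seq_len(50) * 1000, 2), paste0("s", 1:100))
  w2 <- make_windows(map2, 50, 50)
  expect_equal(w2$chrom, c("1", "2"))
})

test_that("a monomorphic window has one allele with full homozygosity", {
  a <- matrix(rep(c(0L, 1L), length.out = 10), nrow = 4, ncol = 10,
              byrow = TRUE)                          # all haplotypes equal
  hap <- make_hap(a)
  w <- make_windows(hap$map, 10, 10)
  ws <- window_summary(hap, w[1, ])
  expect_equal(ws$n_alleles, 1L)
  expect_equal(unname(ws$freq), 1)
  expect_equal(unname(ws$expected_hh), 1)
  expect_equal(unname(ws$observed_hh), 1)
  expect_equal(ws$obs_hh_total, 1)
})

test_that("expected homozygosity is the squared frequency", {
  expect_equal(round(expected_hh(0.215), 3), 0.046)
  expect_equal(expected_hh(c(0.5, 0.1)), c(0.25, 0.01))
})

test_that("window catalogue matches the brute-force counting oracle", {
  set.seed(404)
  for (rep in 1:20) {
    a <- matrix(rbinom(40 * 12, 1, 0.5), 40, 12)
    # duplicate some haplotypes so frequencies differ
    a[seq(2, 40, by = 4), ] <- a[seq(1, 40, by = 4), ]
    hap <- make_hap(a)
    w <- make_windows(hap$map, 12, 12)
    ws <- window_summary(hap, w[1, ])
    oracle <- window_count_oracle(a)
    expect_equal(unname(ws$freq), unname(oracle$freq))
    expect_equal(names(ws$freq), oracle$alleles)
    expect_equal(unname(ws$observed_hh), unname(oracle$obs_hh))
    # invariants: frequencies sum to 1, sum of squared freqs <= 1
    expect_equal(sum(ws$freq), 1)
    expect_lte(sum(ws$expected_hh), 1 + 1e-12)
    # total observed HH = fraction of identical row pairs
    n <- length(hap$ids)
    key <- apply(a, 1, paste0, collapse = "")
    expect_equal(ws$obs_hh_total,
                 mean(key[2 * (1:n) - 1] == key[2 * (1:n)]))
    expect_equal(sum(ws$observed_hh), ws$obs_hh_total)
  }
})

test_that("most-frequent-allele dosage is consistent with the row pairs", {
  a <- rbind(c(0, 0, 0), c(0, 0, 0),    # i1: 2 copies
             c(0, 0, 0), c(1, 1, 1),    # i2: 1 copy
             c(1, 1, 1), c(1, 0, 1),    # i3: 0 copies
             c(0, 0, 0), c(0, 0, 0))    # i4: 2 copies
  hap <- make_hap(a)
  w <- make_windows(hap$map, 3, 3)
  ws <- window_summary(hap, w[1, ])
  expect_equal(unname(ws$dosage), c(2L, 1L, 0L, 2L))
  expect_equal(names(ws$freq)[1], "000")
})

test_that("collapsing haplotypes reproduces genotype codes", {
  set.seed(15)
  a <- matrix(rbinom(20 * 30, 1, 0.4), 20, 30)
  hap <- make_hap(a)
  g <- collapse_haplotypes(hap)
  n <- length(hap$ids)
  expect_equal(g$geno, a[2 * (1:n) - 1, ] + a[2 * (1:n), ],
               ignore_attr = TRUE)
})

test_that("haplotype text round trip preserves alleles", {
  set.seed(25)
  a <- matrix(rbinom(12 * 40, 1, 0.5), 12, 40)
  hap <- make_hap(a)
  path <- withr::local_tempfile()
  write_haplotypes(hap, path)
  hap2 <- read_haplotypes(path, hap$map)
  expect_equal(hap2$alleles, hap$alleles, ignore_attr = TRUE)
  expect_equal(hap2$ids, hap$ids)
})

test_that("ROH and haplotype homozygosity correlate by construction", {
  set.seed(66)
  n <- 30; m <- 100
  # construct a cohort where ROH exactly tile windows of one shared allele
  shared <- rbinom(m, 1, 0.5)
  a <- matrix(rbinom(2 * n * m, 1, 0.5), 2 * n, m)
  homoz_ind <- 1:10
  windows_idx <- list(1:50, 51:100)
  for (i in homoz_ind) {
    a[2 * i - 1, 1:50] <- shared[1:50]
    a[2 * i, 1:50] <- shared[1:50]
  }
  hap <- make_hap(a)
  g <- collapse_haplotypes(hap)
  seg <- detect_roh(g, roh_definition(min_snps = 50))
  H <- roh_state_matrix(seg, g)
  w <- make_windows(hap$map, 50, 50)
  res <- hh_vs_roh_correlation(H, hap, w)
  expect_equal(res$r, 1)
  # degenerate: no variation across windows
  H0 <- H * 0L
  a0 <- a; a0[seq(2, 2 * n, 2), ] <- 1L - a0[seq(1, 2 * n, 2), ]
  expect_warning(r0 <- hh_vs_roh_correlation(H0, make_hap(a0), w))
  expect_true(is.na(r0$r))
})

# haplotypes drawn from a small pool of distinct window haplotypes, so
# window alleles recur and homozygotes are common (as after inbreeding)
pool_haplotypes <- function(n, m, window_snps, k_pool = 4,
                            probs = c(0.5, 0.25, 0.15, 0.1)) {
  a <- matrix(0L, 2 * n, m)
  for (start in seq(1, m, by = window_snps)) {
    idx <- start:min(start + window_snps - 1, m)
    pool <- matrix(rbinom(k_pool * length(idx), 1, 0.5), k_pool)
    pick <- sample(k_pool, 2 * n, replace = TRUE, prob = probs[1:k_pool])
    a[, idx] <- pool[pick, , drop = FALSE]
  }
  a
}

test_that("additive and recessive trait models recover their constructions", {
  set.seed(91)
  n <- 60; m <- 40
  a <- pool_haplotypes(n, m, 20)
  hap <- make_hap(a)
  w <- make_windows(hap$map, 20, 20)
  D <- window_dosage(hap, w)
  # trait equal to dosage in window 1 -> additive slope 1, recessive weaker
  trait <- as.numeric(D[, 1])
  add <- haplotype_trait_association(hap, w, trait, "additive")
  rec <- haplotype_trait_association(hap, w, trait, "recessive")
  expect_equal(add$slope[1], 1, tolerance = 1e-10)
  expect_equal(add$neglog10p[1], 300)
  expect_lt(rec$neglog10p[1], add$neglog10p[1])
  # trait equal to the homozygote indicator -> recessive slope 1, exact
  trait2 <- as.numeric(D[, 2] == 2)
  rec2 <- haplotype_trait_association(hap, w, trait2, "recessive")
  expect_equal(rec2$slope[2], 1, tolerance = 1e-10)
  expect_equal(rec2$neglog10p[2], 300)
})

test_that("planted recessive window effect is found and models correlate", {
  set.seed(505)
  n <- 150; m <- 200
  # pool-derived haplotypes, then plant a recessive effect at window 3
  a <- pool_haplotypes(n, m, 20)
  hap <- make_hap(a)
  w <- make_windows(hap$map, 20, 20)
  D <- window_dosage(hap, w)
  hom3 <- as.numeric(D[, 3] == 2)
  trait <- -0.8 * hom3 + rnorm(n, 0, 0.3)
  rec <- haplotype_trait_association(hap, w, trait, "recessive")
  expect_equal(which.max(rec$neglog10p), 3L)
  expect_lt(rec$slope[3], 0)
  add <- haplotype_trait_association(hap, w, trait, "additive")
  # genome-wide, the two effect profiles agree in direction
  expect_gt(cor(rec$slope, add$slope), 0.5)
})
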