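# Synthetic-data generator: genome, founder LD, mating design, meiosis,
# phenotypes, assay observation.

test_that("simulate_genome places the configured markers and QTL deterministically", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6, n_markers = 10,
                    n_qtl = 2, n_founders = 10, seed = 1)
  map <- simulate_genome(cfg)
  expect_equal(nrow(map), 10)
  expect_equal(sum(map$role == "qtl"), 2)
  expect_false(is.unsorted(map$pos_bp, strictly = TRUE))
  expect_false(anyDuplicated(map$marker_id) > 0)
  expect_identical(map, simulate_genome(cfg))

  bad <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e6, n_markers = 10,
                    n_qtl = 11, n_founders = 10)
  expect_error(simulate_genome(bad), "n_qtl")
  expect_error(simulate_genome(sim_config(n_chromosomes = 1, chrom_length_bp = 5,
                                          n_markers = 10, n_qtl = 0, n_founders = 5)),
               "distinct positions")
})

test_that("founder haplotypes are reproducible and respect the MAF floor", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e7, n_markers = 200,
                    n_qtl = 0, n_founders = 50, seed = 3)
  map <- simulate_genome(cfg)
  f1 <- simulate_founders(map, cfg)
  f2 <- simulate_founders(map, cfg)
  expect_identical(f1$h1, f2$h1)
  expect_identical(f1$h2, f2$h2)
  p <- attr(f1, "allele_freq")
  expect_true(all(pmin(p, 1 - p) >= cfg$founder_maf_min))
  expect_true(all(dosage(f1) == f1$h1 + f1$h2))
  cfg_bad <- sim_config(ld_target_r2 = 1.2)
  expect_error(simulate_founders(map, cfg_bad), "unattainable")
})

test_that("with no copying the loci are independent at the sampling floor", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1e7, n_markers = 120,
                    n_qtl = 0, n_founders = 100, seed = 5)
  map <- simulate_genome(cfg)
  f <- simulate_founders(map, cfg, copy_decay = 1)  # copy prob ~ exp(-gap) ~ 0
  H <- rbind(f$h1, f$h2)
  cc <- stats::cor(H)
  r2 <- cc[upper.tri(cc)]^2
  # oracle: mean r2 of truly independent loci with the same frequency spectrum,
  # simulated by independent Bernoulli draws
  set.seed(99)
  p <- attr(f, "allele_freq")
  Ho <- sapply(p, function(pk) stats::rbinom(nrow(H), 1, pk))
  co <- stats::cor(Ho)
  r2o <- co[upper.tri(co)]^2
  expect_lt(abs(mean(r2) - mean(r2o)), 3 * stats::sd(r2o) / sqrt(length(r2o)) + 2e-3)
  # both sit near the 1/(n_haplotypes - 1) floor
  expect_lt(mean(r2), 3 / (nrow(H) - 1))
})

test_that("founder LD calibration hits the target band and decays monotonically", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 5e7, n_markers = 1000,
                    n_qtl = 0, n_founders = 200, seed = 7)
  map <- simulate_genome(cfg)
  f <- simulate_founders(map, cfg)
  ld <- pairwise_ld(dosage(f), map, max_dist_bp = 2e6)
  at_target <- ld$r2[ld$dist_bp >= 4.5e5 & ld$dist_bp <= 5.5e5]
  expect_gt(mean(at_target), 0.15)
  expect_lt(mean(at_target), 0.25)
  bins <- cut(ld$dist_bp, breaks = seq(0, 2e6, by = 4e5))
  m <- tapply(ld$r2, bins, mean)
  expect_true(all(diff(m) < 0.02))  # non-increasing within sampling tolerance
})

test_that("partial factorial mating uses every parent exactly twice with no duplicate pair", {
  m <- mate_partial_factorial(paste0("s", 1:100), paste0("d", 1:100), 200, seed = 2)
  expect_equal(unname(table(m$sire)), rep(2L, 100), ignore_attr = TRUE)
  expect_equal(unname(table(m$dam)), rep(2L, 100), ignore_attr = TRUE)
  expect_equal(anyDuplicated(paste(m$sire, m$dam)), 0L)
  expect_error(mate_partial_factorial("s1", "d1", 2), "duplicated|incompatible")
  expect_error(mate_partial_factorial(paste0("s", 1:3), paste0("d", 1:3), 8),
               "incompatible")
})

test_that("meiosis is Mendelian-consistent and degenerates correctly", {
  pop <- fix_pop()
  # homozygous-opposite parents force heterozygous offspring
  map <- pop$map
  h <- structure(list(
    h1 = rbind(p1 = rep(0L, nrow(map)), p2 = rep(1L, nrow(map))),
    h2 = rbind(p1 = rep(0L, nrow(map)), p2 = rep(1L, nrow(map)))
  ), class = "haplotype_set")
  colnames(h$h1) <- colnames(h$h2) <- map$marker_id
  mt <- data.frame(family = "f1", sire = "p1", dam = "p2")
  pr <- make_progeny(mt, h, map, n_per_family = 5, seed = 1)
  expect_true(all(dosage(pr$haplotypes) == 1L))

  # zero recombination: each gamete is an intact parental chromosome
  f <- pop$founders
  pr0 <- make_progeny(pop$matings[1, ], f, map, n_per_family = 4,
                      recombination_rate_per_mbp = 0, seed = 2)
  s <- pop$matings$sire[1]
  for (i in 1:4) {
    gam <- pr0$haplotypes$h1[i, ]
    for (ch in unique(map$chrom)) {
      idx <- map$chrom == ch
      expect_true(identical(gam[idx], f$h1[s, idx]) ||
                    identical(gam[idx], f$h2[s, idx]))
    }
  }

  # full sibs share half their genome on average (via genomic relationship)
  p <- colMeans(pop$g_p) / 2
  G <- genomic_relationship(pop$g_p[, p > 0 & p < 1])
  fam <- pop$prog$pedigree$family
  same <- outer(fam, fam, `==`) & upper.tri(G)
  expect_lt(abs(mean(G[same]) - 0.5), 0.06)
  expect_gt(stats::sd(G[same]), 0.01)  # within-family Mendelian sampling variation

  expect_error(make_progeny(data.frame(family = "f", sire = "nope", dam = s),
                            f, map, 1), "missing parent")
})

test_that("phenotypes decompose into cohort + true BV + family + residual", {
  pop <- fix_pop()
  tm <- fix_trait_model()
  qtl <- simulate_qtl_effects(pop$map, pop$founders, tm, seed = 3)
  # realized founder additive covariance equals G_p by construction
  tbv_f <- true_breeding_values(pop$founders, qtl)
  expect_equal(stats::cov(tbv_f), tm$G_p, tolerance = 1e-8)

  # zero family and residual variance: phenotype minus cohort effect = true BV
  tm0 <- structure(list(
    traits = "t1", G_p = matrix(1, dimnames = list("t1", "t1")),
    G_n = matrix(0, dimnames = list("t1", "t1")),
    R = matrix(0, dimnames = list("t1", "t1")),
    h2 = c(t1 = 1), c2 = c(t1 = 0), env = c(t1 = "marine")
  ), class = "trait_model")
  tbv <- matrix(rnorm(40), 40, 1, dimnames = list(sprintf("i%02d", 1:40), "t1"))
  des <- data.frame(id = rownames(tbv), family = rep(c("a", "b"), 20),
                    environment = "marine", cohort = "c1")
  recs <- simulate_phenotypes(tbv, des, tm0, seed = 4, cohort_effect_sd = 1)
  coh <- mean(recs$value - tbv[recs$id, 1])
  expect_equal(recs$value - coh, unname(tbv[recs$id, 1]), tolerance = 1e-4)

  # environment routing: freshwater traits only on freshwater fish
  qt <- simulate_qtl_effects(pop$map, pop$founders, tm, seed = 5)
  tb <- true_breeding_values(pop$prog$haplotypes, qt)
  des2 <- data.frame(id = rownames(tb), family = pop$prog$pedigree$family,
                     environment = rep(c("marine", "freshwater"), length.out = nrow(tb)),
                     cohort = "yc1")
  r2 <- simulate_phenotypes(tb, des2, tm, seed = 6)
  expect_true(all(r2$environment[r2$trait == "weight_fresh"] == "freshwater"))
  expect_true(all(r2$environment[r2$trait == "agd_acquired"] == "marine"))
  des_bad <- des2; des_bad$environment[1] <- NA
  expect_error(simulate_phenotypes(tb, des_bad, tm, seed = 6), "environment")
})

test_that("heritability and genetic correlation are realized within sampling error", {
  pop <- fix_pop()
  tm <- fix_trait_model()
  qtl <- simulate_qtl_effects(pop$map, pop$founders, tm, seed = 13)
  mat <- mate_partial_factorial(sprintf("F%04d", 11:40), sprintf("F%04d", 111:140),
                                60, seed = 13)
  pr <- make_progeny(mat, pop$founders, pop$map, n_per_family = 12, seed = 14)
  tb <- true_breeding_values(pr$haplotypes, qtl)
  des <- data.frame(id = rownames(tb), family = pr$pedigree$family,
                    environment = "marine", cohort = "yc")
  recs <- simulate_phenotypes(tb, des, tm, seed = 15)
  y <- recs$value[recs$trait == "weight_harvest"]
  ids <- recs$id[recs$trait == "weight_harvest"]
  h2_hat <- stats::var(tb[ids, "weight_harvest"]) / stats::var(y)
  expect_lt(abs(h2_hat - 0.44), 0.12)
  # regression of phenotype on true BV ~ 1
  b <- stats::coef(stats::lm(y ~ tb[ids, "weight_harvest"]))[2]
  expect_lt(abs(b - 1), 0.15)
  # genetic correlation of the fresh/marine weight true BVs
  expect_lt(abs(stats::cor(tb[, "weight_harvest"], tb[, "weight_fresh"]) - 0.63), 0.1)
})

test_that("simulate_assay restricts, drops out and mistypes at the configured rates", {
  pop <- fix_pop()
  g <- pop$g_f
  panel <- colnames(g)[seq(1, ncol(g), by = 4)]
  a0 <- simulate_assay(g, panel, 0, 0, seed = 1)
  expect_identical(a0[, panel], g[, panel])
  expect_true(all(is.na(a0[, setdiff(colnames(g), panel)])))
  expect_true(all(is.na(simulate_assay(g, character(0), 0, 0, seed = 1))))

  a <- simulate_assay(g, panel, missing_rate = 0.2, error_rate = 0.05, seed = 2)
  miss <- mean(is.na(a[, panel]))
  se3 <- 3 * sqrt(0.2 * 0.8 / (length(panel) * nrow(g)))
  expect_lt(abs(miss - 0.2), se3 + 0.005)
  obs <- !is.na(a[, panel])
  err <- mean(a[, panel][obs] != g[, panel][obs])
  expect_lt(abs(err - 0.05), 0.01)  # dropout is independent of mistyping
  expect_error(simulate_assay(g, panel, missing_rate = 1.2), "missing_rate")
})

test_that("the breeding cycle is reproducible and tracks the genetic trend", {
  sim <- fix_sim()
  expect_s3_class(sim, "gs_sim")
  expect_equal(sort(unique(sim$genetic_trend$year_class)), 1:3)
  expect_setequal(unique(sim$genetic_trend$trait), fix_trait_model()$traits)
  # every selected parent used exactly twice each year
  for (s in sim$selections) {
    expect_equal(unname(table(s$matings$sire)), rep(2L, length(s$sires)),
                 ignore_attr = TRUE)
  }
  # marine fish never selected as parents
  marine <- sim$pedigree$id[sim$pedigree$role == "marine"]
  expect_length(intersect(marine, unlist(lapply(sim$selections, function(x)
    c(x$sires, x$dams)))), 0)
  # determinism across a fresh run
  sim2 <- simulate_breeding_cycle(sim$config, sim$trait_model, scheme = "genomic",
                                  evaluate_both = TRUE, index_weights = sim$index_weights)
  expect_identical(sim$genetic_trend, sim2$genetic_trend)
  expect_identical(sim$bv_history, sim2$bv_history)
  expect_identical(sim$genotypes, sim2$genotypes)
})
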