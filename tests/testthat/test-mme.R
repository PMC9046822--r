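# Henderson MME: degenerate cases, closed-form BLUP, solver agreement,
# prediction error variances, EBV/GEBV equivalences, GWAS screen.

tm_uni <- function(h2 = 0.4, c2 = 0.2) trait_model(c(y = h2), c2 = c2)

test_that("without random effects the MME are the least-squares normal equations", {
  set.seed(1)
  recs <- data.frame(id = sprintf("i%02d", 1:30), trait = "y", value = rnorm(30),
                     cohort = rep(c("c1", "c2"), 15))
  sys <- build_mme(recs, tm_uni(), K_inv = NULL, random_family = FALSE)
  sol <- solve_mme(sys)
  ols <- tapply(recs$value, recs$cohort, mean)
  expect_equal(unname(sol$tau[paste0("y:", names(ols))]), as.numeric(ols),
               tolerance = 1e-10)
})

test_that("balanced half-sib family BLUP equals the shrunken family mean", {
  set.seed(2)
  nfam <- 5; n <- 8
  tm <- tm_uni()
  recs <- data.frame(id = sprintf("i%02d", 1:(nfam * n)), trait = "y",
                     value = rnorm(nfam * n), cohort = "c1",
                     family = rep(paste0("f", 1:nfam), each = n))
  sol <- solve_mme(build_mme(recs, tm, K_inv = NULL, random_family = TRUE))
  t_icc <- tm$G_n[1, 1] / (tm$G_n[1, 1] + tm$R[1, 1])
  k <- n * t_icc / (1 + (n - 1) * t_icc)
  fm <- tapply(recs$value, recs$family, mean)
  expect_equal(as.numeric(sol$u_family[names(fm), 1]),
               as.numeric(k * (fm - mean(recs$value))), tolerance = 1e-8)
})

test_that("identical phenotypes give zero breeding values and mean-valued BLUE", {
  ped <- data.frame(id = c("a", "b", "c"), sire = c(NA, NA, "a"), dam = c(NA, NA, "b"))
  recs <- data.frame(id = c("a", "b", "c"), trait = "y", value = 3.3,
                     cohort = "c", family = "f")
  sol <- solve_mme(build_mme(recs, tm_uni(), a_inverse(ped)))
  expect_equal(unname(sol$tau), 3.3, tolerance = 1e-9)
  expect_equal(max(abs(sol$u_animal)), 0, tolerance = 1e-9)
})

test_that("direct and conjugate-gradient solutions agree", {
  sim <- fix_sim()
  recs <- sim$phenotypes[sim$phenotypes$trait == "weight_harvest", ]
  sys <- build_mme(recs, subset_traits(sim$trait_model, "weight_harvest"),
                   a_inverse(sim$pedigree[, c("id", "sire", "dam")]))
  d <- solve_mme(sys, "direct")
  cg <- solve_mme(sys, "cg", tol = 1e-12)
  expect_lt(max(abs(d$solution - cg$solution)), 1e-6)
  expect_lt(d$relative_residual, 1e-10)
})

test_that("prediction error variances behave like information", {
  tm <- tm_uni()
  # five paternal half-sib groups: information on a sire comes from the
  # contrast of its progeny against the other sires' progeny
  sires <- paste0("s", 1:5)
  dams <- paste0("d", 1:25)
  prog <- paste0("o", 1:50)
  ped <- data.frame(id = c(sires, dams, "x", prog),
                    sire = c(rep(NA, 30), NA, rep(sires, each = 10)),
                    dam = c(rep(NA, 30), NA, rep(dams, each = 2)))
  set.seed(3)
  many <- data.frame(id = prog, trait = "y", value = rnorm(50),
                     cohort = "c", family = rep(dams, each = 2))
  few <- many[-(2:9), ]  # drop most of sire s1's progeny records
  Ai <- a_inverse(ped)
  pev_few <- prediction_error_variance(build_mme(few, tm, Ai))
  pev_many <- prediction_error_variance(build_mme(many, tm, Ai))
  # founder with no data anywhere: prior additive variance
  expect_equal(pev_few$se[pev_few$id == "x"]^2, tm$G_p[1, 1], tolerance = 1e-8)
  # more progeny records strictly lower the sire's SE
  expect_lt(pev_many$se[pev_many$id == "s1"], pev_few$se[pev_few$id == "s1"])
  # matches the full-inverse oracle on a small system
  sys <- build_mme(few, tm, Ai)
  full_inv <- solve(sys$C)
  off <- sys$n_fixed + length(sys$fam_levels)
  oracle_se <- sqrt(diag(full_inv)[off + seq_along(sys$ids)])
  expect_equal(pev_few$se, unname(oracle_se), tolerance = 1e-8)
})

test_that("GEBV equal EBV exactly when no one is genotyped, and when G* = A22 = A", {
  sim <- fix_sim()
  ped <- sim$pedigree[, c("id", "sire", "dam")]
  recs <- sim$phenotypes
  tm <- sim$trait_model
  ebv <- run_evaluation(recs, ped, tm, "A", compute_se = FALSE)
  gebv0 <- run_evaluation(recs, ped, tm, "H", genotypes = NULL, compute_se = FALSE)
  expect_equal(ebv$value, gebv0$value, tolerance = 1e-12)

  # all genotyped with G* = A22 = A: the H correction cancels exactly
  A <- numerator_relationship(ped)
  Ai <- a_inverse(ped, A)
  h <- h_matrix(A, A, rownames(A))
  tms <- subset_traits(tm, "weight_harvest")
  r1 <- solve_mme(build_mme(recs[recs$trait == "weight_harvest", ], tms, Ai))
  r2 <- solve_mme(build_mme(recs[recs$trait == "weight_harvest", ], tms, h$Hinv))
  expect_equal(r1$u_animal, r2$u_animal, tolerance = 1e-8)
})

test_that("the multi-trait model accepts trait-by-cohort fixed effects and stays symmetric", {
  sim <- fix_sim()
  sys <- build_mme(sim$phenotypes, sim$trait_model,
                   a_inverse(sim$pedigree[, c("id", "sire", "dam")]))
  expect_true(isSymmetric(sys$C, tol = 1e-10))
  expect_true(all(grepl(":", sys$fixed_levels)))  # trait:cohort cells
  expect_error(
    build_mme(transform(sim$phenotypes[1:5, ], id = "ghost"),
              sim$trait_model, a_inverse(sim$pedigree[, c("id", "sire", "dam")])),
    "absent from the relationship matrix")
})

test_that("single-step prediction is unbiased and discriminates within family", {
  sim <- fix_sim()
  final <- sim$bv_history[vapply(sim$bv_history, function(x) x$year[1] == 5, logical(1))]
  tags <- vapply(final, function(x) x$tag[1], character(1))
  gebv <- final[[which(tags == "GEBV")]]
  ebv <- final[[which(tags == "EBV")]]
  cand <- sim$pedigree[sim$pedigree$birth_year == 3 &
                         sim$pedigree$role == "candidate_fresh", ]
  tr <- "agd_acquired"
  gv <- stats::setNames(gebv$value[gebv$trait == tr], gebv$id[gebv$trait == tr])[cand$id]
  ev <- stats::setNames(ebv$value[ebv$trait == tr], ebv$id[ebv$trait == tr])[cand$id]
  tv <- sim$true_bv[cand$id, tr]
  expect_gt(stats::cor(gv, tv), stats::cor(ev, tv))
  # regression of true BV on GEBV ~ 1 (unbiasedness) on cohorts not under
  # parental selection (the first spawning ranks founders by id only)
  slopes <- sapply(c("agd_acquired", "weight_harvest"), function(trj) {
    v <- stats::setNames(gebv$value[gebv$trait == trj], gebv$id[gebv$trait == trj])
    sapply(1:2, function(yc) {
      ids <- sim$pedigree$id[sim$pedigree$birth_year == yc]
      stats::coef(stats::lm(sim$true_bv[ids, trj] ~ v[ids]))[2]
    })
  })
  expect_lt(abs(mean(slopes) - 1), 0.35)
  # within-family spread: GEBV vary among sibs far more than EBV
  vg <- tapply(gv, cand$family, stats::var)
  ve <- tapply(ev, cand$family, stats::var)
  expect_gt(mean(vg, na.rm = TRUE), mean(ve, na.rm = TRUE))
})

test_that("the GWAS screen finds planted signal, is calibrated, and recovers effects", {
  pop <- fix_pop()
  g <- pop$g_f
  p <- colMeans(g) / 2
  g <- g[, p > 0.05 & p < 0.95]
  set.seed(9)
  j <- which.max(apply(g, 2, stats::var))  # a common, well-powered marker
  beta_true <- 1
  y <- beta_true * g[, j] + rnorm(nrow(g), sd = 0.5)
  names(y) <- rownames(g)
  res <- gwas_scan(y, g, covariates = data.frame(batch = rep(c("a", "b"), length.out = nrow(g))))
  expect_equal(res$marker[which.min(res$p)], colnames(g)[j])
  est <- res$beta[j]; se <- res$se[j]
  expect_lt(abs(est - beta_true), 3 * se)
  # type-I calibration on a pure-noise phenotype
  y0 <- rnorm(nrow(g)); names(y0) <- rownames(g)
  res0 <- gwas_scan(y0, g)
  frac <- mean(res0$p < 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 0.03)
  expect_true(is.numeric(attr(res0, "bonferroni")))
  # monomorphic marker skipped with a note
  gm <- cbind(g[, 1:10], mono = 0L)
  expect_message(resm <- gwas_scan(y0, gm), "monomorphic")
  expect_true(resm$skipped[11])
})
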