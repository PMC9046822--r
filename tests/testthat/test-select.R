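# Standardization, derived trait, index, parent selection, gain and the
# validation framework.

mk_bv <- function(ids, traits, values, se = NA_real_, tag = "EBV", year = 1L) {
  data.frame(id = rep(ids, length(traits)),
             trait = rep(traits, each = length(ids)),
             value = values, se = se, tag = tag, year = year,
             stringsAsFactors = FALSE)
}

test_that("standardization scales values and SEs without reranking", {
  bv <- mk_bv(c("a", "b", "c"), c("t1", "t2"), c(2, 1, 0, 4, 2, 0), se = 0.5)
  sds <- c(t1 = 2, t2 = 4)
  s <- standardize_bv(bv, sds)
  expect_equal(s$value[s$trait == "t1"], c(1, 0.5, 0))
  expect_equal(s$value[s$trait == "t2"], c(1, 0.5, 0))
  expect_equal(s$se, rep(c(0.25, 0.125), each = 3))
  expect_identical(order(s$value[s$trait == "t1"]), order(bv$value[bv$trait == "t1"]))
  expect_error(standardize_bv(bv, c(t1 = 0, t2 = 1)), "positive")
  zero <- standardize_bv(mk_bv("a", "t1", 0), c(t1 = 3))
  expect_equal(zero$value, 0)
})

test_that("the derived acquired-resistance trait is the stated weighted combination", {
  ids <- paste0("a", 1:5)
  bv <- mk_bv(ids, c("agd2", "agd3"), c(1:5 / 5, 5:1 / 5), se = 0.2)
  out <- acquired_agd_bv(bv, c("agd2", "agd3"))
  # arithmetic oracle on the 5-animal toy
  v2 <- bv$value[bv$trait == "agd2"]; v3 <- bv$value[bv$trait == "agd3"]
  expect_equal(out$value, 0.5 * v2 + 0.5 * v3)
  expect_equal(out$se, rep(sqrt(2 * (0.5 * 0.2)^2), 5))
  # single component with weight 1 is the identity
  one <- acquired_agd_bv(bv, "agd2", weights = 1)
  expect_equal(one$value, v2)
  # identical components: same value under equal weights
  same <- acquired_agd_bv(mk_bv(ids, c("agd2", "agd3"), rep(1:5 / 5, 2)),
                          c("agd2", "agd3"))
  expect_equal(same$value, 1:5 / 5)
  expect_error(acquired_agd_bv(bv, c("agd2", "agd3"), weights = c(-1, 2)),
               "non-negative")
})

test_that("the selection index is a normalized weighted sum, order-invariant and linear", {
  ids <- c("a", "b")
  std <- mk_bv(ids, c("t1", "t2"), c(1, 0, 0, 1))
  w <- c(t1 = 0.38, t2 = 0.25)
  ix <- selection_index(std, w)
  expect_equal(ix$index[ix$id == "a"], 0.38 / 0.63)
  expect_equal(ix$index[ix$id == "b"], 0.25 / 0.63)
  # permuting trait rows leaves the index unchanged
  ix2 <- selection_index(std[order(std$trait, decreasing = TRUE), ], w)
  expect_equal(ix2[order(ix2$id), ], ix[order(ix$id), ], ignore_attr = TRUE)
  # single trait with weight 1: index equals the standardized BV
  ix3 <- selection_index(std[std$trait == "t1", ], c(t1 = 1))
  expect_equal(ix3$index, std$value[std$trait == "t1"])
  # linearity in the BV table
  std_b <- std; std_b$value <- c(0.4, 0.2, 0.8, 0.1)
  lam <- 0.3
  mix <- std; mix$value <- lam * std$value + (1 - lam) * std_b$value
  expect_equal(selection_index(mix, w)$index,
               lam * selection_index(std, w)$index +
                 (1 - lam) * selection_index(std_b, w)$index)
  # the full set of published pressures is accepted and normalized
  big <- mk_bv("a", names(saltas_index_weights()), rep(1, 6))
  expect_equal(selection_index(big, saltas_index_weights())$index, 1)
  expect_error(selection_index(std, c(t1 = -0.1, t2 = 0.5)), "non-negative")
  expect_message(selection_index(std[-1, ], w), "excluded")
})

test_that("parent selection truncates on the index with a working family cap", {
  cand <- data.frame(id = sprintf("c%02d", 1:12),
                     sex = rep(c("M", "F"), 6),
                     family = rep(c("f1", "f1", "f2", "f2", "f3", "f3"), 2))
  ix <- stats::setNames(12:1 / 12, cand$id)
  sel <- select_parents(cand, ix, n_sires = 3, n_dams = 3)
  top_m <- cand$id[cand$sex == "M"][order(-ix[cand$id[cand$sex == "M"]])][1:3]
  expect_equal(sel$sires, top_m)
  # mean index of the truncation pick dominates any other feasible triple
  expect_gte(mean(ix[sel$sires]), mean(ix[cand$id[cand$sex == "M"]][1:3]))
  sel1 <- select_parents(cand, ix, 2, 2, max_per_family = 1)
  fam <- stats::setNames(cand$family, cand$id)
  expect_false(any(duplicated(fam[sel1$sires])))
  expect_false(any(duplicated(fam[sel1$dams])))
  expect_error(select_parents(cand, ix, 4, 4, max_per_family = 1), "cap")
  expect_error(select_parents(cand, ix, 7, 2), "not enough")
})

test_that("genetic gain recovers planted trends exactly", {
  ycs <- 1:5
  ids <- sprintf("i%03d", 1:100)
  bv <- expand.grid(id = ids, year_class = ycs, stringsAsFactors = FALSE)
  bv$trait <- "t1"
  bv$value <- 0.5 * bv$year_class + rep(seq(-0.05, 0.05, length.out = 100), 5)
  g <- genetic_gain(bv)
  expect_equal(g$gains$annual, 0.5, tolerance = 1e-10)
  expect_equal(g$gains$cumulative, 0.5 * 4, tolerance = 1e-10)
  # cumulative ~ annual x elapsed years for a linear trend
  expect_equal(g$gains$cumulative, g$gains$annual * (max(ycs) - min(ycs)))
  # constant values: zero gain
  bv0 <- bv; bv0$value <- 1.7
  g0 <- genetic_gain(bv0)
  expect_equal(g0$gains$annual, 0)
  expect_equal(g0$gains$cumulative, 0)
  # genetic-SD units
  gs <- genetic_gain(bv, genetic_sds = c(t1 = 2))
  expect_equal(gs$gains$annual, 0.25, tolerance = 1e-10)
  expect_error(genetic_gain(bv[bv$year_class == 1, ]), "two year classes")
  expect_error(genetic_gain(bv, baseline = 99), "baseline")
  # brute-force year-class means agree
  expect_equal(g$means$value[g$means$year_class == 3],
               mean(bv$value[bv$year_class == 3]), tolerance = 1e-12)
})

test_that("validation identities: perfect agreement, reversal, and delta consistency", {
  ids <- sprintf("p%02d", 1:10)
  sds <- c(t1 = 1)
  w <- c(t1 = 1)
  base <- mk_bv(ids, "t1", seq(1, 2, length.out = 10), se = 0.3, tag = "GEBV")
  worse <- base; worse$value <- rev(worse$value); worse$tag <- "EBV"; worse$se <- 0.6
  noisy <- base; noisy$value <- base$value + c(0.01, -0.02, 0.03, 0, -0.01, 0.02, -0.03, 0.01, 0, -0.02)
  r <- validate_accuracy(spawn_ebv = worse, spawn_gebv = base,
                         updated_ebv = worse, updated_gebv = noisy,
                         parent_ids = ids, weights = w, genetic_sds = sds)
  expect_equal(attr(r, "truth_run"), "GEBV")  # lower SE wins
  expect_equal(r$r_gebv[r$trait == "t1"], 1)   # identical ranks
  expect_equal(r$r_ebv[r$trait == "t1"], -1)   # reversed ranks
  expect_equal(r$delta, r$r_gebv - r$r_ebv)
  expect_equal(r$r_gebv[r$trait == "INDEX"], 1)
  expect_error(validate_accuracy(worse, base, worse, noisy, ids[1:2], w, sds),
               "fewer than 3")
})

test_that("the genomic scheme outranks pedigree selection within family when sibs are unphenotyped", {
  # constructed scenario: full sibs with no own phenotypes are tied under
  # pedigree BLUP but split by their genomic relationships
  sim <- fix_sim()
  final <- sim$bv_history[vapply(sim$bv_history, function(x) x$year[1] == 5, logical(1))]
  tags <- vapply(final, function(x) x$tag[1], character(1))
  gebv <- final[[which(tags == "GEBV")]]; ebv <- final[[which(tags == "EBV")]]
  cand <- sim$pedigree[sim$pedigree$birth_year == 3 & sim$pedigree$role == "candidate_fresh", ]
  tr <- "agd_acquired"  # marine-only: candidates carry no own record
  fam_big <- names(which.max(table(cand$family)))
  sibs <- cand$id[cand$family == fam_big]
  gv <- stats::setNames(gebv$value[gebv$trait == tr], gebv$id[gebv$trait == tr])[sibs]
  ev <- stats::setNames(ebv$value[ebv$trait == tr], ebv$id[ebv$trait == tr])[sibs]
  tv <- sim$true_bv[sibs, tr]
  # EBV of unphenotyped full sibs are (near-)identical: no within-family signal
  expect_lt(stats::sd(ev), 0.05 * stats::sd(gv) + 1e-6)
  expect_gt(stats::cor(gv, tv), 0)
})
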