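# Readers/writers, two-level QC, Mendelian-error checking, parentage.

test_that("genotype TSV and VCF round-trip, with the biallelic VCF dialect enforced", {
  pop <- fix_pop()
  g <- pop$g_f[1:5, 1:5]
  g[1, 2] <- NA; g[3, 4] <- NA; g[5, 5] <- NA
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, tsv, "tsv")
  expect_identical(read_genotypes(tsv, "tsv"), g)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, vcf, "vcf", map = pop$map)
  g2 <- read_genotypes(vcf, "vcf")
  expect_identical(g2[rownames(g), colnames(g)], g)

  # multiallelic site rejected with a warning, the rest kept
  lines <- readLines(vcf)
  body <- which(!startsWith(lines, "#"))
  parts <- strsplit(lines[body[2]], "\t")[[1]]
  parts[5] <- "B,C"
  lines[body[2]] <- paste(parts, collapse = "\t")
  writeLines(lines, vcf)
  expect_warning(g3 <- read_genotypes(vcf, "vcf"), "multiallelic")
  expect_equal(ncol(g3), 4)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_genotypes(empty, "tsv"), "empty")
})

test_that("pedigree/phenotype/map tables round-trip", {
  ped <- data.frame(id = c("a", "b", "c"), sire = c(NA, NA, "a"),
                    dam = c(NA, NA, "b"), sex = c("M", "F", "M"),
                    year_class = c(0L, 0L, 1L), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  expect_equal(read_pedigree(f), ped)
  m <- withr::local_tempfile(fileext = ".tsv")
  write_marker_map(fix_pop()$map[1:10, ], m)
  expect_equal(read_marker_map(m), fix_pop()$map[1:10, ], ignore_attr = TRUE)
})

test_that("qc_filter applies the MAF/call-rate rules and the basic/full distinction", {
  set.seed(1)
  g <- matrix(rbinom(100 * 60, 2, 0.4), 100, 60,
              dimnames = list(sprintf("i%03d", 1:100), sprintf("m%02d", 1:60)))
  g[, 1] <- c(rep(1L, 1), rep(0L, 99))            # MAF 0.005 -> removed
  g[sample(100, 30), 2] <- NA                      # call rate 0.70 -> removed
  g[1, ] <- NA; g[1, 1:5] <- 0L                    # individual call rate ~0.08

  basic <- qc_filter(g, mode = "basic")
  expect_true(all(c("m01", "m02") %in% basic$report$markers_removed$marker))
  expect_equal(nrow(basic$report$individuals_removed), 0)   # no individuals in basic
  expect_equal(nrow(basic$genotypes), 100)

  full <- qc_filter(g, mode = "full")
  expect_true("i001" %in% full$report$individuals_removed$id)
  expect_false("i001" %in% rownames(full$genotypes))

  # boundary: MAF exactly at the threshold is kept
  g2 <- matrix(rbinom(100 * 5, 2, 0.5), 100, 5,
               dimnames = list(sprintf("i%03d", 1:100), paste0("k", 1:5)))
  g2[, 1] <- c(rep(1L, 4), rep(0L, 96))            # MAF exactly 0.02
  at <- qc_filter(g2, maf_min = 0.02, mode = "full")
  expect_true("k1" %in% colnames(at$genotypes))

  # all markers pass -> identity with an empty report
  clean <- qc_filter(g2[, -1], mode = "full")
  expect_identical(clean$genotypes, g2[, -1])
  expect_equal(nrow(clean$report$markers_removed), 0)

  # idempotence at the same thresholds
  again <- qc_filter(full$genotypes, mode = "full")
  expect_identical(again$genotypes, full$genotypes)
})

test_that("mendelian_error_check counts opposing homozygotes and trio impossibilities", {
  g <- rbind(p = c(0L, 0L, 2L, 1L), o = c(2L, 1L, 0L, 1L))
  colnames(g) <- paste0("m", 1:4)
  ped <- data.frame(id = c("p", "o"), sire = c(NA, "p"), dam = c(NA, NA))
  res <- mendelian_error_check(g, ped)
  expect_equal(res$per_trio$n_errors, 2L)  # m1 (0 vs 2) and m3 (2 vs 0)
  expect_equal(res$per_marker$n_errors, c(1, 0, 1, 0))

  # trio-impossible without opposing homozygotes: parents 0 x 0, offspring 1
  g3 <- rbind(s = 0L, d = 0L, o = 1L)
  colnames(g3) <- "m1"
  ped3 <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d"))
  expect_equal(mendelian_error_check(g3, ped3)$per_trio$n_errors, 1L)

  # clean simulated progeny carry zero errors
  pop <- fix_pop()
  clean <- mendelian_error_check(pop$g_all, pop$ped)
  expect_equal(sum(clean$per_marker$n_errors), 0)
  expect_length(clean$flagged_markers, 0)

  # no genotyped trios -> empty report, not an error
  lone <- mendelian_error_check(pop$g_f[1:3, ],
                                data.frame(id = "zzz", sire = NA, dam = NA))
  expect_equal(nrow(lone$per_trio), 0)
})

test_that("injected genotyping errors are detected at the enumeration-expected rate", {
  pop <- fix_pop()
  err_rate <- 0.1
  g <- pop$g_all
  off_ids <- pop$prog$pedigree$id
  set.seed(21)
  ge <- g
  flip <- matrix(stats::runif(length(off_ids) * ncol(g)) < err_rate,
                 length(off_ids), ncol(g))
  shift <- 1L + (matrix(stats::runif(length(off_ids) * ncol(g)), length(off_ids)) < 0.5)
  ge[off_ids, ][flip] <- (ge[off_ids, ][flip] + shift[flip]) %% 3L

  res <- mendelian_error_check(ge, pop$ped)
  detected <- sum(res$per_trio$n_errors) / sum(res$per_trio$n_checks)

  # oracle: brute-force expected detectable fraction, enumerating over the
  # observed (sire, dam, true offspring) dosage combinations in these trios
  imp <- array(FALSE, c(3, 3, 3))
  for (s in 0:2) for (d in 0:2) for (o in 0:2) {
    ps <- c(0, .5, 1)[s + 1]; pd <- c(0, .5, 1)[d + 1]
    pr <- switch(o + 1, (1 - ps) * (1 - pd), ps * (1 - pd) + (1 - ps) * pd, ps * pd)
    imp[s + 1, d + 1, o + 1] <- pr == 0
  }
  sires <- g[pop$ped$sire[match(off_ids, pop$ped$id)], ]
  dams <- g[pop$ped$dam[match(off_ids, pop$ped$id)], ]
  otrue <- g[off_ids, ]
  # P(detected) = err_rate * mean over cells of P(mistype lands on an impossible dosage)
  p_detect <- 0
  for (cell in seq_along(otrue)) {
    o <- otrue[cell]
    others <- setdiff(0:2, o)
    p_detect <- p_detect +
      err_rate * mean(imp[cbind(sires[cell] + 1, dams[cell] + 1, others + 1)])
  }
  p_detect <- p_detect / length(otrue)
  expect_lt(abs(detected - p_detect), 3 * sqrt(p_detect / length(otrue)) + 0.003)
})

test_that("parentage assignment recovers true parents and refuses unsafe calls", {
  pop <- fix_pop()
  meta <- data.frame(id = rownames(pop$g_f),
                     sex = ifelse(rownames(pop$g_f) %in% pop$matings$dam, "F", "M"),
                     stringsAsFactors = FALSE)
  off <- pop$g_p[1:30, ]
  res <- assign_parentage(off, pop$g_f, meta, max_mismatch_rate = 0.02)
  truth <- pop$prog$pedigree[match(rownames(off), pop$prog$pedigree$id), ]
  expect_true(all(res$assigned))
  expect_equal(res$sire, truth$sire)
  expect_equal(res$dam, truth$dam)
  expect_true(all(res$mismatch_rate == 0))

  # absent true sire: no pair acceptable
  cand <- pop$g_f[setdiff(rownames(pop$g_f), truth$sire[1]), ]
  meta2 <- meta[meta$id %in% rownames(cand), ]
  res2 <- assign_parentage(off[1, , drop = FALSE], cand, meta2,
                           max_mismatch_rate = 0.02)
  expect_false(res2$assigned)

  # duplicated candidate genotype: ambiguous, unassigned
  dup <- rbind(pop$g_f, DUP = pop$g_f[truth$sire[1], ])
  meta3 <- rbind(meta, data.frame(id = "DUP", sex = "M"))
  res3 <- assign_parentage(off[1, , drop = FALSE], dup, meta3,
                           max_mismatch_rate = 0.02)
  expect_false(res3$assigned)
  expect_match(res3$reason, "ambiguous|margin")

  # no candidates of one sex
  res4 <- assign_parentage(off[1, , drop = FALSE], pop$g_f,
                           transform(meta, sex = "M"))
  expect_false(res4$assigned)
  expect_match(res4$reason, "sex")

  expect_error(assign_parentage(off[, 1:10], pop$g_f[, 1:10], meta), "shared markers")
})
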