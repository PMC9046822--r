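# Breeding-program simulator: genomes, founder haplotypes with calibrated LD,
# partial factorial matings, meiosis, multi-trait phenotypes, assay
# observations, and the multi-year-class program driver.

#' Simulation configuration
#'
#' Bundles the parameters of the simulated breeding program. Defaults follow
#' the structure of a large family-based salmon program: ~200 full-sib
#' families per year class from a partial factorial design in which every
#' parent is crossed exactly twice, ~50,000 pooled eyed-eggs from which 8000
#' presmolt are sampled at random for genotyping (3/8 retained as freshwater
#' broodstock candidates, the rest marine-tested), ~15% repeat spawners per
#' year class, males usable from age 2 and females from age 3, and founder
#' linkage disequilibrium calibrated to mean r-squared 0.2 at 500 kbp.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in base pairs (all equal).
#' @param n_markers total marker count across the genome.
#' @param n_qtl number of markers flagged as QTL.
#' @param n_founders founder population size.
#' @param families_per_year full-sib families per year class (must be even).
#' @param pool_per_family eyed-eggs contributed per family to the communal pool.
#' @param progeny_genotyped_per_year presmolt sampled from the pool and genotyped.
#' @param candidate_fresh_fraction fraction of sampled presmolt kept as
#'   freshwater broodstock candidates (the rest are marine-tested).
#' @param repeat_spawner_fraction fraction of each year's parents drawn from
#'   previously used broodstock, in `[0, 1)`.
#' @param n_year_classes number of year classes to spawn.
#' @param ld_target_r2 target mean r-squared at `ld_target_dist_bp`.
#' @param ld_target_dist_bp distance at which founder LD is calibrated.
#' @param founder_maf_min lower truncation of the founder allele-frequency
#'   spectrum (minor allele frequency).
#' @param assay_missing_rate,assay_error_rate per-genotype missing and
#'   mis-call rates of the simulated assay, in `[0, 1)`.
#' @param recombination_rate_per_mbp Morgans per Mbp (default 0.01, i.e.
#'   1 Morgan per 100 Mbp, Haldane mapping without interference).
#' @param male_min_age,female_min_age minimum spawning ages by sex.
#' @param cohort_effect_sd standard deviation of simulated cohort (fixed)
#'   effects, in phenotype units.
#' @param seed default seed for runs driven by this configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length_bp = 1e8,
                       n_markers = 5000,
                       n_qtl = 200,
                       n_founders = 400,
                       families_per_year = 200,
                       pool_per_family = 250,
                       progeny_genotyped_per_year = 8000,
                       candidate_fresh_fraction = 3000 / 8000,
                       repeat_spawner_fraction = 0.15,
                       n_year_classes = 3,
                       ld_target_r2 = 0.2,
                       ld_target_dist_bp = 5e5,
                       founder_maf_min = 0.02,
                       assay_missing_rate = 0,
                       assay_error_rate = 0,
                       recombination_rate_per_mbp = 0.01,
                       male_min_age = 2,
                       female_min_age = 3,
                       cohort_effect_sd = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_markers = as.integer(n_markers),
    n_qtl = as.integer(n_qtl),
    n_founders = as.integer(n_founders),
    families_per_year = as.integer(families_per_year),
    pool_per_family = as.integer(pool_per_family),
    progeny_genotyped_per_year = as.integer(progeny_genotyped_per_year),
    candidate_fresh_fraction = candidate_fresh_fraction,
    repeat_spawner_fraction = repeat_spawner_fraction,
    n_year_classes = as.integer(n_year_classes),
    ld_target_r2 = ld_target_r2,
    ld_target_dist_bp = as.numeric(ld_target_dist_bp),
    founder_maf_min = founder_maf_min,
    assay_missing_rate = assay_missing_rate,
    assay_error_rate = assay_error_rate,
    recombination_rate_per_mbp = recombination_rate_per_mbp,
    male_min_age = as.integer(male_min_age),
    female_min_age = as.integer(female_min_age),
    cohort_effect_sd = cohort_effect_sd,
    seed = as.integer(seed)
  )
  for (f in c("n_chromosomes", "chrom_length_bp", "n_markers", "n_founders",
              "families_per_year", "pool_per_family",
              "progeny_genotyped_per_year", "n_year_classes")) {
    check_scalar(cfg[[f]], f, lo = 1)
  }
  check_scalar(cfg$n_qtl, "n_qtl", lo = 0)
  check_scalar(cfg$repeat_spawner_fraction, "repeat_spawner_fraction",
               lo = 0, hi = 1, open_hi = TRUE)
  check_scalar(cfg$candidate_fresh_fraction, "candidate_fresh_fraction",
               lo = 0, hi = 1)
  check_scalar(cfg$assay_missing_rate, "assay_missing_rate", 0, 1, open_hi = TRUE)
  check_scalar(cfg$assay_error_rate, "assay_error_rate", 0, 1, open_hi = TRUE)
  if (cfg$families_per_year %% 2L != 0L) {
    stop("'families_per_year' must be even (each parent is crossed exactly twice)")
  }
  if (cfg$progeny_genotyped_per_year > cfg$families_per_year * cfg$pool_per_family) {
    stop("cannot sample more progeny than the pooled eyed-egg count")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Multi-trait variance structure
#'
#' Defines the additive-genetic (`G_p`), family/common-environment (`G_n`)
#' and residual (`R`) covariance matrices across traits from heritabilities,
#' genetic correlations and variance fractions, on a phenotypic variance of
#' `var_p` per trait. Heritability here is the ratio of additive variance to
#' total (additive + family + residual) variance.
#'
#' @param h2 named numeric vector of heritabilities in (0, 1); names are the
#'   trait names.
#' @param r_g genetic correlation matrix across traits (default identity).
#' @param c2 common-environment (full-sib family) variance fraction, scalar
#'   or per-trait; must satisfy `h2 + c2 < 1`.
#' @param var_p phenotypic variance per trait (scalar or per-trait).
#' @param env trait environment, `"marine"` or `"freshwater"`: a trait is
#'   expressed only on individuals allocated to its environment.
#' @return a list of class `trait_model` with elements `traits`, `G_p`,
#'   `G_n`, `R`, `h2`, `c2`, `env`.
#' @export
trait_model <- function(h2, r_g = NULL, c2 = 0.1, var_p = 1,
                        env = rep("marine", length(h2))) {
  if (is.null(names(h2))) stop("'h2' must be a named vector of trait heritabilities")
  traits <- names(h2)
  nt <- length(traits)
  if (any(h2 <= 0 | h2 >= 1)) stop("each h2 must be in (0, 1)")
  c2 <- rep_len(c2, nt)
  var_p <- rep_len(var_p, nt)
  if (any(h2 + c2 >= 1)) stop("h2 + c2 must be < 1 for every trait")
  if (is.null(r_g)) r_g <- diag(nt)
  r_g <- as.matrix(r_g)
  if (!all(dim(r_g) == nt)) stop("'r_g' must be a square matrix over the traits")
  if (!is_psd(r_g)) stop("'r_g' must be symmetric positive semi-definite")
  env <- rep_len(env, nt)
  if (!all(env %in% c("marine", "freshwater"))) {
    stop("trait 'env' must be 'marine' or 'freshwater'")
  }
  sd_a <- sqrt(h2 * var_p)
  G_p <- diag(sd_a, nt) %*% r_g %*% diag(sd_a, nt)
  G_n <- diag(c2 * var_p, nt)
  R <- diag((1 - h2 - c2) * var_p, nt)
  dimnames(G_p) <- dimnames(G_n) <- dimnames(R) <- list(traits, traits)
  structure(list(traits = traits, G_p = G_p, G_n = G_n, R = R,
                 h2 = stats::setNames(as.numeric(h2), traits),
                 c2 = stats::setNames(c2, traits),
                 env = stats::setNames(env, traits)),
            class = "trait_model")
}

#' Restrict a trait model to a subset of traits
#' @param tm a [trait_model()].
#' @param traits character vector of trait names to keep.
#' @return a `trait_model` over the subset.
#' @export
subset_traits <- function(tm, traits) {
  stopifnot(inherits(tm, "trait_model"))
  miss <- setdiff(traits, tm$traits)
  if (length(miss)) stop("unknown traits: ", paste(miss, collapse = ", "))
  idx <- match(traits, tm$traits)
  structure(list(traits = traits,
                 G_p = tm$G_p[idx, idx, drop = FALSE],
                 G_n = tm$G_n[idx, idx, drop = FALSE],
                 R = tm$R[idx, idx, drop = FALSE],
                 h2 = tm$h2[idx], c2 = tm$c2[idx], env = tm$env[idx]),
            class = "trait_model")
}

#' Default trait model of the breeding objective
#'
#' Six objective traits plus the freshwater expressions of weight and
#' maturation, with heritabilities taken from the program's published
#' breeding-objective table: acquired AGD resistance 0.36, harvest weight
#' 0.44, innate AGD resistance 0.16, marine maturation 0.20, flesh colour
#' 0.65, flesh fat 0.28. Freshwater and marine weight share a genetic
#' correlation of 0.63 and the two maturation expressions 0.76; genetic
#' correlations not reported for this population are set to zero.
#'
#' @param c2 common-environment variance fraction (default 0.1).
#' @return a [trait_model()].
#' @export
saltas_trait_model <- function(c2 = 0.1) {
  h2 <- c(weight_harvest = 0.44, weight_fresh = 0.44,
          mat_marine = 0.20, mat_fresh = 0.20,
          agd_innate = 0.16, agd_acquired = 0.36,
          color = 0.65, fat = 0.28)
  r_g <- diag(length(h2))
  dimnames(r_g) <- list(names(h2), names(h2))
  r_g["weight_harvest", "weight_fresh"] <- r_g["weight_fresh", "weight_harvest"] <- 0.63
  r_g["mat_marine", "mat_fresh"] <- r_g["mat_fresh", "mat_marine"] <- 0.76
  env <- c(weight_harvest = "marine", weight_fresh = "freshwater",
           mat_marine = "marine", mat_fresh = "freshwater",
           agd_innate = "marine", agd_acquired = "marine",
           color = "marine", fat = "marine")
  trait_model(h2, r_g = r_g, c2 = c2, env = env[names(h2)])
}

#' Default selection-index weights
#'
#' Selection pressures of the breeding objective: acquired AGD resistance
#' 38%, harvest weight 25%, innate AGD resistance 13%, marine maturation
#' 13%, flesh colour 13%; flesh fat is monitored at zero weight.
#'
#' @return named numeric vector of per-trait selection pressures.
#' @export
saltas_index_weights <- function() {
  c(agd_acquired = 0.38, weight_harvest = 0.25, agd_innate = 0.13,
    mat_marine = 0.13, color = 0.13, fat = 0)
}

#' Simulate a marker map
#'
#' Places markers uniformly at random (without replacement, sorted) along
#' each chromosome, splitting the marker count as evenly as possible across
#' chromosomes, and flags a random subset as QTL.
#'
#' @param config a [sim_config()].
#' @param seed seed (default `config$seed`).
#' @return data.frame with columns `marker_id`, `chrom`, `pos_bp`, `role`
#'   (`"neutral"` or `"qtl"`), ordered by chromosome then position.
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  nc <- config$n_chromosomes
  m <- config$n_markers
  if (config$n_qtl > m) stop("n_qtl cannot exceed n_markers")
  per <- rep(m %/% nc, nc)
  extra <- m %% nc
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  if (any(per > config$chrom_length_bp)) {
    stop("more markers than representable distinct positions on a chromosome")
  }
  with_rng(seed, {
    pos <- lapply(seq_len(nc), function(k) sort(sample.int(config$chrom_length_bp, per[k])))
    map <- data.frame(
      marker_id = sprintf("M%06d", seq_len(m)),
      chrom = rep(seq_len(nc), per),
      pos_bp = as.integer(unlist(pos)),
      role = "neutral",
      stringsAsFactors = FALSE
    )
    if (config$n_qtl > 0) {
      map$role[sample.int(m, config$n_qtl)] <- "qtl"
    }
    map
  })
}

# Correlation factor between allele indicators at two loci on a shared
# (copied-through) background: corr = (min(p,q) - p q) / sqrt(p(1-p)q(1-q)).
ld_freq_factor <- function(p, q) {
  (pmin(p, q) - p * q) / sqrt(p * (1 - p) * q * (1 - q))
}

#' Simulate founder haplotypes with calibrated linkage disequilibrium
#'
#' Founder haplotypes are generated by a first-order Markov copying walk
#' along each chromosome: each haplotype carries a latent uniform that is
#' retained between adjacent markers with probability `exp(-lambda * gap)`
#' and redrawn otherwise; the allele at a marker is the indicator that the
#' latent uniform falls below the marker's allele frequency. Alleles at two
#' loci are therefore correlated exactly when the latent value survives the
#' intervening walk, giving mean r-squared `C(d)^2 * kappa` at distance `d`,
#' where `kappa` is the mean squared frequency-mismatch factor over the
#' allele-frequency spectrum. `lambda` is solved so that mean r-squared at
#' `config$ld_target_dist_bp` equals `config$ld_target_r2`. Allele
#' frequencies are drawn from a U-shaped Beta(0.5, 0.5) spectrum truncated
#' at `config$founder_maf_min`.
#'
#' @param map marker map from [simulate_genome()].
#' @param config a [sim_config()].
#' @param seed seed (default `config$seed`).
#' @param copy_decay optional override of the per-bp decay rate `lambda`;
#'   `0` makes all loci independent.
#' @return a `haplotype_set`: list with phased 0/1 matrices `h1`, `h2`
#'   (individuals x markers) and attribute `allele_freq`.
#' @export
simulate_founders <- function(map, config, seed = config$seed, copy_decay = NULL) {
  if (nrow(map) == 0) stop("marker map is empty")
  r2t <- config$ld_target_r2
  if (is.null(copy_decay) && (r2t <= 0 || r2t >= 1)) {
    stop("unattainable ld_target_r2: must be in (0, 1)")
  }
  n <- config$n_founders
  H <- 2L * n
  with_rng(seed, {
    # truncated U-shaped allele frequency spectrum
    m <- nrow(map)
    p <- numeric(0)
    while (length(p) < m) {
      cand <- stats::rbeta(2L * (m - length(p)) + 16L, 0.5, 0.5)
      cand <- cand[pmin(cand, 1 - cand) >= config$founder_maf_min]
      p <- c(p, cand)
    }
    p <- p[seq_len(m)]

    if (is.null(copy_decay)) {
      # kappa: mean squared correlation factor over random frequency pairs
      i <- sample.int(m, 20000L, replace = TRUE)
      j <- sample.int(m, 20000L, replace = TRUE)
      kappa <- mean(ld_freq_factor(p[i], p[j])^2)
      C2 <- r2t / kappa
      if (C2 >= 1) {
        stop(sprintf(
          "ld_target_r2 = %.3f is unattainable: the frequency spectrum caps mean r2 at %.3f",
          r2t, kappa
        ))
      }
      lambda <- -log(C2) / (2 * config$ld_target_dist_bp)
    } else {
      lambda <- copy_decay
    }

    haps <- matrix(0L, H, m)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      pos <- map$pos_bp[idx]
      u <- stats::runif(H)
      haps[, idx[1L]] <- as.integer(u < p[idx[1L]])
      if (length(idx) > 1L) {
        cprob <- exp(-lambda * diff(pos))
        for (k in 2:length(idx)) {
          redraw <- stats::runif(H) >= cprob[k - 1L]
          if (any(redraw)) u[redraw] <- stats::runif(sum(redraw))
          haps[, idx[k]] <- as.integer(u < p[idx[k]])
        }
      }
    }
    ids <- sprintf("F%04d", seq_len(n))
    h1 <- haps[seq_len(n), , drop = FALSE]
    h2 <- haps[n + seq_len(n), , drop = FALSE]
    dimnames(h1) <- dimnames(h2) <- list(ids, map$marker_id)
    structure(list(h1 = h1, h2 = h2),
              class = "haplotype_set",
              allele_freq = stats::setNames(p, map$marker_id),
              copy_decay = lambda)
  })
}

#' Partial factorial mating design
#'
#' Builds `n_families` single-pair crosses in which every listed sire and
#' every listed dam appears in exactly two families and no sire x dam pair
#' is duplicated (a ring design over a random permutation of the parents).
#'
#' @param sires,dams character vectors of parent ids; each must have length
#'   `n_families / 2`.
#' @param n_families number of crosses (even, >= 4 for a valid ring).
#' @param seed seed for the permutation.
#' @param family_prefix prefix for generated family ids.
#' @return data.frame with columns `family`, `sire`, `dam`.
#' @export
mate_partial_factorial <- function(sires, dams, n_families, seed = 1L,
                                   family_prefix = "FAM") {
  sires <- as.character(sires); dams <- as.character(dams)
  if (anyDuplicated(sires) || anyDuplicated(dams)) {
    stop("parent lists must not contain duplicates")
  }
  if (n_families %% 2L != 0L) {
    stop("parent counts incompatible with exact-twice usage: n_families must be even")
  }
  k <- n_families / 2L
  if (length(sires) != k || length(dams) != k) {
    stop(sprintf(
      "parent counts incompatible with exact-twice usage: need %d sires and %d dams for %d families",
      k, k, as.integer(n_families)
    ))
  }
  if (k < 2L) {
    stop("parent counts incompatible with exact-twice usage: a single sire x dam pair would be duplicated")
  }
  with_rng(seed, {
    s <- sample(sires)
    d <- sample(dams)
    fam <- data.frame(
      family = sprintf("%s%04d", family_prefix, seq_len(n_families)),
      sire = c(s, s),
      dam = c(d, d[c(2:k, 1L)]),
      stringsAsFactors = FALSE
    )
    fam[order(fam$family), , drop = FALSE]
  })
}

# One gamete from a parent's two phased haplotypes: Poisson crossover count
# per chromosome (Haldane, no interference), uniform crossover positions,
# random starting phase.
gamete <- function(h1, h2, chrom_index, chrom_len, rate_per_mbp) {
  out <- integer(length(h1))
  for (ch in seq_along(chrom_index)) {
    idx <- chrom_index[[ch]]$idx
    pos <- chrom_index[[ch]]$pos
    exp_xo <- rate_per_mbp * chrom_len[ch] / 1e6
    nxo <- stats::rpois(1L, exp_xo)
    start <- stats::runif(1) < 0.5
    if (nxo == 0L) {
      phase <- rep.int(as.integer(start), length(idx))
    } else {
      xo <- sort(stats::runif(nxo, 0, chrom_len[ch]))
      phase <- (as.integer(start) + findInterval(pos, xo)) %% 2L
    }
    out[idx] <- ifelse(phase == 0L, h1[idx], h2[idx])
  }
  out
}

#' Generate full-sib progeny by simulated meiosis
#'
#' Each offspring receives one recombinant gamete from each parent, with
#' crossover counts Poisson per chromosome (Haldane mapping, no
#' interference) at `recombination_rate_per_mbp` Morgans per Mbp and
#' crossover positions uniform along the chromosome.
#'
#' @param matings data.frame with columns `family`, `sire`, `dam`.
#' @param parent_haps `haplotype_set` containing both parents of every family.
#' @param map marker map.
#' @param n_per_family offspring per family (scalar or per-family vector).
#' @param recombination_rate_per_mbp Morgans per Mbp.
#' @param seed seed.
#' @param id_prefix prefix for offspring ids.
#' @return list with `haplotypes` (a `haplotype_set`) and `pedigree`
#'   (data.frame `id`, `sire`, `dam`, `family`).
#' @export
make_progeny <- function(matings, parent_haps, map, n_per_family,
                         recombination_rate_per_mbp = 0.01, seed = 1L,
                         id_prefix = "P") {
  stopifnot(inherits(parent_haps, "haplotype_set"))
  parents <- unique(c(matings$sire, matings$dam))
  missing_par <- setdiff(parents, rownames(parent_haps$h1))
  if (length(missing_par)) {
    stop("missing parent haplotypes for: ", paste(utils::head(missing_par, 5), collapse = ", "))
  }
  n_per_family <- rep_len(as.integer(n_per_family), nrow(matings))
  chroms <- unique(map$chrom)
  chrom_index <- lapply(chroms, function(ch) {
    idx <- which(map$chrom == ch)
    list(idx = idx, pos = map$pos_bp[idx])
  })
  chrom_len <- vapply(chrom_index, function(x) max(x$pos), numeric(1))
  total <- sum(n_per_family)
  m <- nrow(map)
  h1 <- matrix(0L, total, m)
  h2 <- matrix(0L, total, m)
  ids <- character(total)
  ped <- data.frame(id = character(total), sire = character(total),
                    dam = character(total), family = character(total),
                    stringsAsFactors = FALSE)
  with_rng(seed, {
    row <- 0L
    for (f in seq_len(nrow(matings))) {
      if (n_per_family[f] == 0L) next
      s <- matings$sire[f]; d <- matings$dam[f]
      s1 <- parent_haps$h1[s, ]; s2 <- parent_haps$h2[s, ]
      d1 <- parent_haps$h1[d, ]; d2 <- parent_haps$h2[d, ]
      for (o in seq_len(n_per_family[f])) {
        row <- row + 1L
        h1[row, ] <- gamete(s1, s2, chrom_index, chrom_len, recombination_rate_per_mbp)
        h2[row, ] <- gamete(d1, d2, chrom_index, chrom_len, recombination_rate_per_mbp)
        ids[row] <- sprintf("%s%s_%03d", id_prefix, matings$family[f], o)
        ped$id[row] <- ids[row]; ped$sire[row] <- s; ped$dam[row] <- d
        ped$family[row] <- matings$family[f]
      }
    }
  })
  dimnames(h1) <- dimnames(h2) <- list(ids, map$marker_id)
  list(haplotypes = structure(list(h1 = h1, h2 = h2), class = "haplotype_set"),
       pedigree = ped)
}

#' Draw QTL effects realizing the additive covariance structure
#'
#' Per-QTL effect vectors are drawn multivariate normal across traits and
#' then linearly rescaled so that the sample covariance of founder true
#' breeding values equals `G_p` exactly (an infinitesimal-like architecture
#' with no large-effect QTL).
#'
#' @param map marker map with QTL flags.
#' @param founder_haps founder `haplotype_set`.
#' @param tm a [trait_model()].
#' @param seed seed.
#' @return list of class `qtl_effects` with `qtl_ids` and `effects`
#'   (QTL x traits matrix).
#' @export
simulate_qtl_effects <- function(map, founder_haps, tm, seed = 1L) {
  qtl_ids <- map$marker_id[map$role == "qtl"]
  if (length(qtl_ids) < length(tm$traits)) {
    stop("need at least as many QTL as traits to realize G_p")
  }
  g <- dosage(founder_haps)[, qtl_ids, drop = FALSE]
  with_rng(seed, {
    nq <- length(qtl_ids); nt <- length(tm$traits)
    raw <- matrix(stats::rnorm(nq * nt), nq, nt) %*% chol(tm$G_p + diag(1e-10, nt)) / sqrt(nq)
    tbv_raw <- g %*% raw
    B <- stats::cov(tbv_raw)
    U_B <- tryCatch(chol(B), error = function(e) {
      stop("founder QTL genotypes are too degenerate to realize G_p (singular covariance)")
    })
    M <- backsolve(U_B, chol(tm$G_p + diag(1e-12, nt)))
    eff <- raw %*% M
    dimnames(eff) <- list(qtl_ids, tm$traits)
    structure(list(qtl_ids = qtl_ids, effects = eff), class = "qtl_effects")
  })
}

#' True additive genetic values from QTL dosages
#'
#' @param x a `haplotype_set` or a dosage matrix containing the QTL columns.
#' @param qtl a `qtl_effects` object.
#' @return matrix (individuals x traits) of true breeding values.
#' @export
true_breeding_values <- function(x, qtl) {
  g <- if (inherits(x, "haplotype_set")) dosage(x) else x
  g[, qtl$qtl_ids, drop = FALSE] %*% qtl$effects
}

#' Simulate phenotypes under the additive + family + residual model
#'
#' Each record is `cohort effect + true breeding value + family deviation +
#' residual`. Family deviations are shared by full sibs and drawn
#' multivariate normal with covariance `G_n`; residuals have covariance `R`.
#' A trait is recorded only on individuals allocated to that trait's
#' environment (marine traits on marine-tested fish, freshwater traits on
#' broodstock candidates).
#'
#' @param tbv true breeding value matrix (individuals x traits, rownames ids).
#' @param design data.frame with columns `id`, `family`, `environment`
#'   (`"marine"` or `"freshwater"`), `cohort`.
#' @param tm the [trait_model()] that generated `tbv`'s trait columns.
#' @param seed seed.
#' @param cohort_effect_sd SD of the simulated cohort fixed effects.
#' @return data.frame of records: `id`, `trait`, `value`, `cohort`,
#'   `family`, `environment`.
#' @export
simulate_phenotypes <- function(tbv, design, tm, seed = 1L, cohort_effect_sd = 0.5) {
  stopifnot(inherits(tm, "trait_model"))
  if (!all(c("id", "family", "environment", "cohort") %in% names(design))) {
    stop("'design' needs columns id, family, environment, cohort")
  }
  if (anyNA(design$environment)) {
    stop("individual with phenotype but no environment allocation")
  }
  if (!is_psd(tm$G_n) || !is_psd(tm$R)) stop("trait model covariances must be PSD")
  ids <- design$id
  if (!all(ids %in% rownames(tbv))) stop("every designed individual needs a true BV row")
  nt <- length(tm$traits)
  with_rng(seed, {
    fams <- unique(design$family)
    fam_dev <- matrix(stats::rnorm(length(fams) * nt), length(fams), nt) %*%
      chol(tm$G_n + diag(1e-12, nt))
    rownames(fam_dev) <- fams
    res <- matrix(stats::rnorm(length(ids) * nt), length(ids), nt) %*%
      chol(tm$R + diag(1e-12, nt))
    cohorts <- unique(design$cohort)
    coh_eff <- matrix(stats::rnorm(length(cohorts) * nt, sd = cohort_effect_sd),
                      length(cohorts), nt)
    rownames(coh_eff) <- cohorts
    y <- coh_eff[design$cohort, , drop = FALSE] +
      tbv[ids, tm$traits, drop = FALSE] +
      fam_dev[design$family, , drop = FALSE] + res
    recs <- data.frame(
      id = rep(ids, nt),
      trait = rep(tm$traits, each = length(ids)),
      value = as.vector(y),
      cohort = rep(design$cohort, nt),
      family = rep(design$family, nt),
      environment = rep(design$environment, nt),
      stringsAsFactors = FALSE
    )
    keep <- tm$env[recs$trait] == recs$environment
    recs[keep, , drop = FALSE]
  })
}

#' Simulate an assay observation of a genotype matrix
#'
#' Restricts genotypes to a panel (all other markers set missing) and then
#' applies independent per-genotype dropout and mis-typing, emulating an
#' array or GBS assay.
#'
#' @param g dosage matrix (individuals x markers), values 0/1/2/NA.
#' @param panel character vector of assayed marker ids (subset of columns).
#' @param missing_rate per-genotype missing probability in `[0, 1)`.
#' @param error_rate per-genotype probability of mis-typing to a uniformly
#'   chosen other dosage, in `[0, 1)`.
#' @param seed seed.
#' @return matrix of the same shape as `g` with non-panel entries `NA`.
#' @export
simulate_assay <- function(g, panel, missing_rate = 0, error_rate = 0, seed = 1L) {
  check_scalar(missing_rate, "missing_rate", 0, 1, open_hi = TRUE)
  check_scalar(error_rate, "error_rate", 0, 1, open_hi = TRUE)
  bad <- setdiff(panel, colnames(g))
  if (length(bad)) stop("panel markers absent from genotype matrix: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  out <- g
  out[, !(colnames(g) %in% panel)] <- NA_integer_
  with_rng(seed, {
    sel <- which(colnames(g) %in% panel)
    block <- out[, sel, drop = FALSE]
    nz <- which(!is.na(block))
    if (error_rate > 0 && length(nz)) {
      err <- nz[stats::runif(length(nz)) < error_rate]
      if (length(err)) {
        shift <- 1L + (stats::runif(length(err)) < 0.5)  # +1 or +2 mod 3
        block[err] <- (block[err] + shift) %% 3L
      }
    }
    if (missing_rate > 0 && length(nz)) {
      drop <- nz[stats::runif(length(nz)) < missing_rate]
      block[drop] <- NA_integer_
    }
    out[, sel] <- block
  })
  out
}
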