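# Multi-year breeding-program driver: spawn -> communal rearing & sampling ->
# phenotype -> evaluate -> select (with repeat spawners) -> next year class.

#' Simulate a multi-year-class breeding program
#'
#' Runs the full cycle for `config$n_year_classes` spawning years. Each year:
#' eligible broodstock (males from `male_min_age`, females from
#' `female_min_age`; marine-tested fish never return) are ranked on the
#' selection index from the scheme's evaluation (pedigree EBV or single-step
#' GEBV over all records available that year), a configured fraction of the
#' selected parents are repeat spawners, parents are crossed in a partial
#' factorial (each used exactly twice), progeny are pooled and a random
#' sample is genotyped and split between freshwater broodstock candidates
#' and marine testing, and phenotypes are generated with a two-year
#' availability lag (sib testing: marine traits are never measured on
#' candidates). True genetic means per year class are tracked.
#'
#' @param config a [sim_config()].
#' @param tm trait model (default [saltas_trait_model()]).
#' @param scheme `"genomic"` (select on GEBV) or `"pedigree_only"` (EBV).
#' @param seed master seed; every stage derives its own substream.
#' @param index_weights named selection pressures (default
#'   [saltas_index_weights()] restricted to the model's traits).
#' @param selection `"index"` (truncation on the index) or `"random"`
#'   (selection off; the null scheme).
#' @param evaluate_both run both the A- and H-based evaluation every year
#'   (needed for the accuracy-validation framework).
#' @param final_evaluation run an updated evaluation (with standard errors)
#'   two years after the last spawning, when all progeny records are in.
#' @param keep_haplotypes retain all haplotypes in the result.
#' @return an object of class `gs_sim`: pedigree, phenotype records, true
#'   breeding values, genotypes, per-year evaluations (`bv_history`),
#'   selection history, and the true genetic trend.
#' @export
simulate_breeding_cycle <- function(config, tm = saltas_trait_model(),
                                    scheme = c("genomic", "pedigree_only"),
                                    seed = config$seed,
                                    index_weights = NULL,
                                    selection = c("index", "random"),
                                    evaluate_both = FALSE,
                                    final_evaluation = TRUE,
                                    keep_haplotypes = FALSE) {
  scheme <- match.arg(scheme)
  selection <- match.arg(selection)
  stopifnot(inherits(config, "sim_config"), inherits(tm, "trait_model"))
  if (is.null(index_weights)) {
    index_weights <- saltas_index_weights()
    index_weights <- index_weights[names(index_weights) %in% tm$traits]
    if (!length(index_weights)) stop("no default index weights apply to this trait model")
  }
  gsd <- sqrt(diag(tm$G_p))

  map <- simulate_genome(config, stage_seed(seed, "genome"))
  haps <- simulate_founders(map, config, stage_seed(seed, "founders"))
  qtl <- simulate_qtl_effects(map, haps, tm, stage_seed(seed, "qtl"))
  founder_ids <- rownames(haps$h1)
  sex <- with_rng(stage_seed(seed, "sex0"),
                  sample(c("M", "F"), length(founder_ids), replace = TRUE))
  ped <- data.frame(id = founder_ids, sire = NA_character_, dam = NA_character_,
                    sex = sex, birth_year = -2L, family = NA_character_,
                    role = "founder", stringsAsFactors = FALSE)
  tbv <- true_breeding_values(haps, qtl)
  gmat <- dosage(haps)
  phen <- NULL
  trend <- list()
  selections <- list()
  bv_history <- list()
  n_par <- config$families_per_year / 2L

  evaluate <- function(year, kinds, compute_se) {
    avail <- phen[phen$avail_year <= year, , drop = FALSE]
    if (is.null(avail) || !nrow(avail)) return(NULL)
    lapply(stats::setNames(kinds, kinds), function(k) {
      run_evaluation(avail, ped[, c("id", "sire", "dam")], tm, K_kind = k,
                     genotypes = if (k == "H") gmat else NULL,
                     model_name = "All", year = year, compute_se = compute_se)
    })
  }

  for (t in seq_len(config$n_year_classes)) {
    kinds <- if (evaluate_both) c("A", "H") else if (scheme == "genomic") "H" else "A"
    # under random selection the scores are unused: skip spawn-year evaluations
    evs <- if (selection == "random" && !evaluate_both) NULL else
      evaluate(t, kinds, compute_se = FALSE)
    own <- if (is.null(evs)) NULL else
      evs[[if (scheme == "genomic") "H" else "A"]]
    if (!is.null(evs)) bv_history <- c(bv_history, unname(evs))

    # score candidates
    elig <- ped[ped$role %in% c("founder", "candidate_fresh"), , drop = FALSE]
    age <- t - elig$birth_year
    elig <- elig[(elig$sex == "M" & age >= config$male_min_age) |
                   (elig$sex == "F" & age >= config$female_min_age), , drop = FALSE]
    score <- if (selection == "random") {
      with_rng(stage_seed(seed, paste0("randsel", t)),
               stats::setNames(stats::runif(nrow(elig)), elig$id))
    } else if (is.null(own)) {
      stats::setNames(rep(0, nrow(elig)), elig$id)  # no data yet: id order
    } else {
      ix <- selection_index(standardize_bv(own, gsd), index_weights)
      s <- stats::setNames(ix$index, ix$id)[elig$id]
      s[is.na(s)] <- -Inf
      names(s) <- elig$id
      s
    }

    used_before <- unique(c(character(0),
                            unlist(lapply(selections, function(x) c(x$sires, x$dams)))))
    pick_sex <- function(sx) {
      pool <- elig$id[elig$sex == sx]
      if (length(pool) < n_par) {
        stop(sprintf("year %d: only %d eligible %s for %d slots", t, length(pool),
                     if (sx == "M") "males" else "females", n_par))
      }
      ord <- function(v) v[order(-score[v], v)]
      rs_target <- round(config$repeat_spawner_fraction * n_par)
      old <- ord(intersect(pool, used_before))
      new <- ord(setdiff(pool, used_before))
      n_old <- min(rs_target, length(old))
      sel <- c(old[seq_len(n_old)], new[seq_len(min(n_par - n_old, length(new)))])
      if (length(sel) < n_par) {
        sel <- c(sel, setdiff(ord(pool), sel)[seq_len(n_par - length(sel))])
      }
      sel
    }
    sires <- pick_sex("M")
    dams <- pick_sex("F")
    matings <- mate_partial_factorial(sires, dams, config$families_per_year,
                                      seed = stage_seed(seed, paste0("mate", t)),
                                      family_prefix = sprintf("Y%dF", t))

    # communal rearing: hypergeometric family composition of the sample
    fam_counts <- with_rng(stage_seed(seed, paste0("sample", t)), {
      labels <- rep(seq_len(nrow(matings)), each = config$pool_per_family)
      tabulate(sample(labels, config$progeny_genotyped_per_year),
               nbins = nrow(matings))
    })
    prog <- make_progeny(matings, haps, map, fam_counts,
                         config$recombination_rate_per_mbp,
                         seed = stage_seed(seed, paste0("meiosis", t)),
                         id_prefix = "")
    new_ids <- prog$pedigree$id
    n_new <- length(new_ids)
    alloc <- with_rng(stage_seed(seed, paste0("alloc", t)), {
      sex_new <- sample(c("M", "F"), n_new, replace = TRUE)
      n_fresh <- round(config$candidate_fresh_fraction * n_new)
      fresh <- sample(new_ids, n_fresh)
      list(sex = sex_new, fresh = fresh)
    })
    role <- ifelse(new_ids %in% alloc$fresh, "candidate_fresh", "marine")
    ped <- rbind(ped, data.frame(id = new_ids, sire = prog$pedigree$sire,
                                 dam = prog$pedigree$dam, sex = alloc$sex,
                                 birth_year = t, family = prog$pedigree$family,
                                 role = role, stringsAsFactors = FALSE))
    tbv_new <- true_breeding_values(prog$haplotypes, qtl)
    tbv <- rbind(tbv, tbv_new)
    gmat <- rbind(gmat, dosage(prog$haplotypes))
    haps <- bind_haplotypes(haps, prog$haplotypes)
    trend[[t]] <- data.frame(year_class = t, trait = colnames(tbv_new),
                             mean_tbv = colMeans(tbv_new), row.names = NULL,
                             stringsAsFactors = FALSE)

    design <- data.frame(id = new_ids, family = prog$pedigree$family,
                         environment = ifelse(role == "marine", "marine", "freshwater"),
                         cohort = sprintf("YC%d", t), stringsAsFactors = FALSE)
    recs <- simulate_phenotypes(tbv_new, design, tm,
                                seed = stage_seed(seed, paste0("phen", t)),
                                cohort_effect_sd = config$cohort_effect_sd)
    recs$avail_year <- t + 2L
    phen <- if (is.null(phen)) recs else rbind(phen, recs)
    selections[[t]] <- list(year = t, sires = sires, dams = dams,
                            matings = matings,
                            repeat_spawners = intersect(c(sires, dams), used_before))
  }

  if (final_evaluation) {
    kinds <- if (evaluate_both || scheme == "genomic") c("A", "H") else "A"
    evs <- evaluate(config$n_year_classes + 2L, kinds, compute_se = TRUE)
    if (!is.null(evs)) bv_history <- c(bv_history, unname(evs))
  }

  structure(list(
    config = config, trait_model = tm, scheme = scheme, selection = selection,
    index_weights = index_weights, genetic_sds = gsd,
    map = map, qtl = qtl, pedigree = ped, phenotypes = phen,
    true_bv = tbv, genotypes = gmat,
    genetic_trend = do.call(rbind, trend),
    selections = selections,
    bv_history = bv_history,
    haplotypes = if (keep_haplotypes) haps else NULL
  ), class = "gs_sim")
}
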