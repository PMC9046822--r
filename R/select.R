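# Breeding-value standardization, derived acquired-resistance trait,
# selection index, parent selection, genetic-gain tracking, and the
# prediction-accuracy validation framework.

#' Standardize breeding values to genetic standard deviation units
#'
#' @param bv breeding value table (`id`, `trait`, `value`, optionally `se`).
#' @param genetic_sds named vector of additive genetic SDs per trait.
#' @return the table with `value` (and `se`) divided by the trait's genetic
#'   SD.
#' @export
standardize_bv <- function(bv, genetic_sds) {
  miss <- setdiff(unique(bv$trait), names(genetic_sds))
  if (length(miss)) stop("no genetic SD supplied for: ", paste(miss, collapse = ", "))
  sds <- genetic_sds[bv$trait]
  if (any(sds <= 0)) stop("genetic SDs must be positive")
  bv$value <- bv$value / sds
  if ("se" %in% names(bv)) bv$se <- bv$se / sds
  bv
}

#' Derived acquired-resistance breeding value
#'
#' Combines the breeding values of repeated disease scores into a single
#' derived trait as a weighted linear combination (the standard derived-trait
#' construction for repeated measures). Innate resistance is the
#' first-infection score; the acquired trait combines the post-naive scores.
#' Individuals with some components missing use the available components
#' with renormalized weights; individuals missing all components are
#' omitted.
#'
#' @param bv (standardized) breeding value table.
#' @param score_traits names of the post-naive score traits to combine.
#' @param weights combining weights (default equal), recycled over
#'   `score_traits`.
#' @param out_trait name of the derived trait.
#' @return data.frame `id`, `trait`, `value`, `se` (error-propagated
#'   assuming independent component errors).
#' @export
acquired_agd_bv <- function(bv, score_traits, weights = NULL,
                            out_trait = "agd_acquired") {
  if (is.null(weights)) weights <- rep(1, length(score_traits))
  weights <- rep_len(weights, length(score_traits))
  if (any(weights < 0)) stop("combining weights must be non-negative")
  sub <- bv[bv$trait %in% score_traits, , drop = FALSE]
  if (!nrow(sub)) stop("no component breeding values found for: ",
                       paste(score_traits, collapse = ", "))
  w <- stats::setNames(weights, score_traits)
  ids <- unique(sub$id)
  out <- lapply(ids, function(i) {
    x <- sub[sub$id == i, , drop = FALSE]
    wi <- w[x$trait]
    if (!sum(wi)) return(NULL)
    wi <- wi / sum(wi)
    data.frame(id = i, trait = out_trait,
               value = sum(wi * x$value),
               se = if ("se" %in% names(x) && !anyNA(x$se)) sqrt(sum(wi^2 * x$se^2)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped) message(dropped, " individual(s) omitted: no component breeding values")
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Selection index from standardized breeding values
#'
#' `index_i = sum_t w_t * standardized BV_it` with the weights normalized to
#' sum to one. Individuals missing any positively weighted trait are
#' excluded (with a message). Zero-weight (monitor) traits are ignored.
#'
#' @param std_bv standardized breeding value table (`id`, `trait`, `value`).
#' @param weights named non-negative selection pressures per trait.
#' @return data.frame `id`, `index`.
#' @export
selection_index <- function(std_bv, weights) {
  if (any(weights < 0)) stop("selection-index weights must be non-negative")
  weights <- weights[weights > 0]
  miss <- setdiff(names(weights), unique(std_bv$trait))
  if (length(miss)) stop("no breeding values for weighted trait(s): ",
                         paste(miss, collapse = ", "))
  w <- weights / sum(weights)
  sub <- std_bv[std_bv$trait %in% names(w), , drop = FALSE]
  wide <- stats::reshape(sub[, c("id", "trait", "value")], idvar = "id",
                         timevar = "trait", direction = "wide")
  cols <- paste0("value.", names(w))
  complete <- stats::complete.cases(wide[, cols, drop = FALSE])
  if (any(!complete)) {
    message(sum(!complete), " individual(s) excluded from the index: missing a weighted trait BV")
  }
  wide <- wide[complete, , drop = FALSE]
  data.frame(id = wide$id,
             index = as.numeric(as.matrix(wide[, cols, drop = FALSE]) %*% w),
             stringsAsFactors = FALSE)
}

#' Truncation selection of parents on the index
#'
#' Selects the top `n_sires` males and `n_dams` females by index within sex,
#' optionally capping the number selected per full-sib family; ties are
#' broken by id (ascending) for determinism.
#'
#' @param candidates data.frame `id`, `sex` (`"M"`/`"F"`), optional `family`.
#' @param index data.frame `id`, `index` (or named numeric vector).
#' @param n_sires,n_dams numbers to select.
#' @param max_per_family per-full-sib-family cap (default unlimited).
#' @return list with `sires` and `dams` (character vectors).
#' @export
select_parents <- function(candidates, index, n_sires, n_dams,
                           max_per_family = Inf) {
  if (is.data.frame(index)) index <- stats::setNames(index$index, index$id)
  pick <- function(sex, n) {
    pool <- candidates[candidates$sex == sex & candidates$id %in% names(index), , drop = FALSE]
    pool$index <- index[pool$id]
    pool <- pool[order(-pool$index, pool$id), , drop = FALSE]
    if (is.infinite(max_per_family) || !"family" %in% names(pool)) {
      if (nrow(pool) < n) stop("not enough eligible ", if (sex == "M") "sires" else "dams")
      return(pool$id[seq_len(n)])
    }
    used <- new.env(parent = emptyenv())
    sel <- character(0)
    for (r in seq_len(nrow(pool))) {
      f <- as.character(pool$family[r])
      cnt <- get0(f, envir = used, ifnotfound = 0L)
      if (is.na(f) || f == "" || cnt < max_per_family) {
        sel <- c(sel, pool$id[r])
        if (!is.na(f) && f != "") assign(f, cnt + 1L, envir = used)
        if (length(sel) == n) return(sel)
      }
    }
    stop("infeasible selection: the per-family cap of ", max_per_family,
         " leaves fewer than ", n, " eligible ", if (sex == "M") "sires" else "dams")
  }
  list(sires = pick("M", n_sires), dams = pick("F", n_dams))
}

#' Genetic gain per year class
#'
#' Computes year-class means of (true or estimated) breeding values per
#' trait, cumulative gain relative to a baseline year class, and the mean
#' annual gain as the least-squares slope over year classes.
#'
#' @param bv_by_year data.frame `year_class`, `trait`, `value` (one row per
#'   individual and trait).
#' @param baseline baseline year class (default: the earliest).
#' @param genetic_sds optional named genetic SDs; when supplied, gains are
#'   expressed in genetic SD units.
#' @param baseline_means optional named per-trait baseline phenotypic means;
#'   when supplied, gains are expressed as percent of the baseline mean.
#' @return list with `means` (year_class x trait means), `gains`
#'   (data.frame `trait`, `cumulative`, `annual`), and `unit`.
#' @export
genetic_gain <- function(bv_by_year, baseline = NULL, genetic_sds = NULL,
                         baseline_means = NULL) {
  ycs <- sort(unique(bv_by_year$year_class))
  if (length(ycs) < 2L) stop("at least two year classes are required")
  if (is.null(baseline)) baseline <- ycs[1L]
  if (!baseline %in% ycs) stop("missing baseline year class: ", baseline)
  agg <- stats::aggregate(value ~ year_class + trait, data = bv_by_year, FUN = mean)
  traits <- unique(agg$trait)
  gains <- do.call(rbind, lapply(traits, function(tr) {
    sub <- agg[agg$trait == tr, , drop = FALSE]
    sub <- sub[order(sub$year_class), , drop = FALSE]
    base <- sub$value[sub$year_class == baseline]
    if (!length(base)) stop("missing baseline year class for trait ", tr)
    cum <- sub$value[nrow(sub)] - base
    ann <- unname(stats::coef(stats::lm(value ~ year_class, data = sub))[2L])
    scale <- 1; unit <- "raw"
    if (!is.null(genetic_sds)) {
      scale <- genetic_sds[tr]; unit <- "genetic_sd"
    } else if (!is.null(baseline_means)) {
      scale <- abs(baseline_means[tr]) / 100; unit <- "percent_of_baseline"
    }
    data.frame(trait = tr, cumulative = cum / scale, annual = ann / scale,
               unit = unit, stringsAsFactors = FALSE)
  }))
  list(means = agg, gains = gains,
       unit = gains$unit[1L])
}

#' Validate prediction accuracy of at-spawning breeding values
#'
#' Compares EBV and GEBV available at the time of parent selection with the
#' best later estimate of the true breeding value: the updated run (EBV- or
#' GEBV-based, at least two years later) with the lowest mean standard
#' error, preferring the genomic run on ties. Reports Spearman rank
#' correlations per trait and for the selection index (recomputed from the
#' updated breeding values), plus the gain in accuracy
#' `delta = r(That, GEBV) - r(That, EBV)`.
#'
#' @param spawn_ebv,spawn_gebv at-spawning breeding value tables.
#' @param updated_ebv,updated_gebv updated tables (with `se`).
#' @param parent_ids the parents to validate over (>= 3 required).
#' @param weights selection-index weights.
#' @param genetic_sds genetic SDs for standardization.
#' @return data.frame `trait` (traits plus `"INDEX"`), `r_gebv`, `r_ebv`,
#'   `delta`, with attribute `"truth_run"` (`"EBV"`/`"GEBV"`).
#' @export
validate_accuracy <- function(spawn_ebv, spawn_gebv, updated_ebv, updated_gebv,
                              parent_ids, weights, genetic_sds) {
  parent_ids <- intersect(
    parent_ids,
    Reduce(intersect, list(unique(spawn_ebv$id), unique(spawn_gebv$id),
                           unique(updated_ebv$id), unique(updated_gebv$id)))
  )
  if (length(parent_ids) < 3L) {
    stop("fewer than 3 shared parents: correlation undefined at useful precision")
  }
  se_e <- mean(updated_ebv$se[updated_ebv$id %in% parent_ids], na.rm = TRUE)
  se_g <- mean(updated_gebv$se[updated_gebv$id %in% parent_ids], na.rm = TRUE)
  truth <- if (!is.na(se_g) && (is.na(se_e) || se_g <= se_e)) updated_gebv else updated_ebv
  truth_run <- if (identical(truth, updated_gebv)) "GEBV" else "EBV"

  traits <- intersect(unique(truth$trait), unique(spawn_ebv$trait))
  val <- function(tab, tr) {
    x <- tab[tab$trait == tr & tab$id %in% parent_ids, ]
    stats::setNames(x$value, x$id)[parent_ids]
  }
  rows <- lapply(traits, function(tr) {
    th <- val(truth, tr)
    rg <- stats::cor(th, val(spawn_gebv, tr), method = "spearman")
    re <- stats::cor(th, val(spawn_ebv, tr), method = "spearman")
    data.frame(trait = tr, r_gebv = rg, r_ebv = re, delta = rg - re,
               stringsAsFactors = FALSE)
  })
  idx_of <- function(tab) {
    ix <- selection_index(standardize_bv(tab, genetic_sds),
                          weights[names(weights) %in% traits])
    stats::setNames(ix$index, ix$id)[parent_ids]
  }
  th_i <- idx_of(truth)
  rows <- c(rows, list(data.frame(
    trait = "INDEX",
    r_gebv = stats::cor(th_i, idx_of(spawn_gebv), method = "spearman"),
    r_ebv = stats::cor(th_i, idx_of(spawn_ebv), method = "spearman"),
    delta = NA_real_, stringsAsFactors = FALSE
  )))
  out <- do.call(rbind, rows)
  out$delta <- out$r_gebv - out$r_ebv
  attr(out, "truth_run") <- truth_run
  out
}

#' Compare genomic and pedigree selection schemes
#'
#' Runs paired breeding-program simulations (identical founders and stage
#' seeds per replicate) under genomic (GEBV-based) and pedigree-only
#' (EBV-based) selection, and compares rates of genetic gain in the true
#' selection index. Reports per-trait and index gains, the
#' genomic-to-pedigree ratio of mean index gains with a paired bootstrap
#' confidence interval, and a one-sided paired t-test p-value.
#'
#' @param config a [sim_config()].
#' @param tm trait model.
#' @param weights selection-index weights (default [saltas_index_weights()]
#'   restricted to the model's traits).
#' @param n_replicates paired replicates.
#' @param seed master seed.
#' @param selection `"index"` (selection on) or `"random"` (selection off).
#' @param n_boot bootstrap draws for the ratio CI.
#' @return list of class `scheme_comparison`.
#' @export
compare_schemes <- function(config, tm, weights = NULL, n_replicates = 20,
                            seed = 1L, selection = c("index", "random"),
                            n_boot = 2000) {
  selection <- match.arg(selection)
  gsd <- sqrt(diag(tm$G_p))
  if (is.null(weights)) {
    weights <- saltas_index_weights()
    weights <- weights[names(weights) %in% tm$traits]
    if (!length(weights)) stop("no default index weights apply to this trait model")
  }
  w <- weights[weights > 0] / sum(weights[weights > 0])
  index_gain <- function(sim) {
    tr <- sim$genetic_trend
    tr$std <- tr$mean_tbv / gsd[tr$trait]
    # weighted sum across traits per year class
    wide <- stats::reshape(tr[tr$trait %in% names(w), c("year_class", "trait", "std")],
                           idvar = "year_class", timevar = "trait", direction = "wide")
    vals <- as.matrix(wide[, paste0("std.", names(w)), drop = FALSE]) %*% w
    unname(stats::coef(stats::lm(vals ~ wide$year_class))[2L])
  }
  per_rep <- lapply(seq_len(n_replicates), function(r) {
    s <- stage_seed(seed, paste0("rep", r))
    gen <- simulate_breeding_cycle(config, tm, scheme = "genomic", seed = s,
                                   index_weights = weights, selection = selection,
                                   final_evaluation = FALSE)
    ped <- simulate_breeding_cycle(config, tm, scheme = "pedigree_only", seed = s,
                                   index_weights = weights, selection = selection,
                                   final_evaluation = FALSE)
    data.frame(replicate = r, gain_genomic = index_gain(gen),
               gain_pedigree = index_gain(ped))
  })
  per_rep <- do.call(rbind, per_rep)
  gg <- per_rep$gain_genomic; gp <- per_rep$gain_pedigree
  ratio <- mean(gg) / mean(gp)
  ci <- with_rng(stage_seed(seed, "boot"), {
    bs <- replicate(n_boot, {
      i <- sample.int(length(gg), replace = TRUE)
      mean(gg[i]) / mean(gp[i])
    })
    stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  })
  tt <- stats::t.test(gg - gp, alternative = "greater")
  structure(list(
    per_replicate = per_rep,
    mean_gain_genomic = mean(gg),
    mean_gain_pedigree = mean(gp),
    gain_ratio = ratio,
    gain_ratio_ci = ci,
    p_value_one_sided = tt$p.value,
    selection = selection
  ), class = "scheme_comparison")
}
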