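# Two-stage genotype imputation (Mendelian fixed-point + window-based
# population matching) and masking-based validation.

#' Family (Mendelian) imputation to a fixed point
#'
#' Iteratively fills missing genotypes that are forced by relatives:
#' offspring dosage is forced when both parents are homozygous (0 x 0 -> 0,
#' 0 x 2 -> 1, 2 x 2 -> 2), and a missing parent is forced to 1 when its
#' genotyped offspring include both a 0 and a 2 at the marker. Observed
#' calls are never overwritten; observed trios that are already inconsistent
#' are left untouched and flagged.
#'
#' @param g dosage matrix with missing values.
#' @param ped pedigree (`id`, `sire`, `dam`).
#' @return matrix with the same shape; attribute `"n_filled"` gives the
#'   number of imputed entries and `"inconsistent"` flags observed conflicts
#'   (data.frame `id`, `marker`).
#' @export
mendelian_impute <- function(g, ped) {
  ids <- rownames(g)
  ped <- ped[ped$id %in% ids, , drop = FALSE]
  oi <- match(ped$id, ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  has_par <- !is.na(si) & !is.na(di)
  kids_of <- split(c(oi, oi), factor(c(si, di), levels = seq_along(ids)))
  n_filled <- 0L
  repeat {
    filled <- 0L
    # offspring forced by two homozygous parents
    for (r in which(has_par)) {
      o <- g[oi[r], ]; s <- g[si[r], ]; d <- g[di[r], ]
      forced <- is.na(o) & !is.na(s) & !is.na(d) &
        (s %in% c(0L, 2L)) & (d %in% c(0L, 2L))
      if (any(forced)) {
        g[oi[r], forced] <- (s[forced] + d[forced]) %/% 2L
        filled <- filled + sum(forced)
      }
    }
    # parent forced heterozygous by opposing homozygous offspring
    for (p in seq_along(ids)) {
      kids <- kids_of[[p]]
      if (length(kids) < 2L) next
      miss <- is.na(g[p, ])
      if (!any(miss)) next
      gk <- g[kids, miss, drop = FALSE]
      has0 <- colSums(!is.na(gk) & gk == 0L) > 0L
      has2 <- colSums(!is.na(gk) & gk == 2L) > 0L
      forced <- has0 & has2
      if (any(forced)) {
        g[p, which(miss)[forced]] <- 1L
        filled <- filled + sum(forced)
      }
    }
    n_filled <- n_filled + filled
    if (filled == 0L) break
  }
  # flag observed inconsistencies (not repaired)
  inc <- list()
  for (r in which(has_par)) {
    o <- g[oi[r], ]; s <- g[si[r], ]; d <- g[di[r], ]
    ok <- !is.na(o) & !is.na(s) & !is.na(d)
    bad <- ok & trio_impossible[cbind(s + 1L, d + 1L, o + 1L)]
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      inc[[length(inc) + 1L]] <- data.frame(id = ped$id[r],
                                            marker = colnames(g)[bad],
                                            stringsAsFactors = FALSE)
    }
  }
  attr(g, "n_filled") <- n_filled
  attr(g, "inconsistent") <- if (length(inc)) do.call(rbind, inc) else
    data.frame(id = character(0), marker = character(0))
  g
}

#' Population imputation by window template matching
#'
#' Slides windows of `window_markers` markers along each chromosome of the
#' standard (reference) marker set. For each target individual and window,
#' the `n_neighbors` reference individuals with the lowest dosage mismatch
#' rate against the target's observed genotypes in the window are selected,
#' and each missing entry is filled with the neighbours' majority dosage
#' (ties broken toward the dosage most frequent in the full reference at
#' that marker, then the lower dosage). Windows without observed target
#' genotypes fall back to neighbours matched over the whole chromosome.
#'
#' @param g dosage matrix of target individuals over the standard marker
#'   set (missing entries to fill).
#' @param reference complete dosage matrix of reference individuals over the
#'   same markers.
#' @param map marker map covering the columns.
#' @param window_markers window size in markers (default 20).
#' @param n_neighbors reference templates per consensus call (default 5).
#' @return completed dosage matrix (no missing entries; observed entries
#'   preserved).
#' @export
population_impute <- function(g, reference, map, window_markers = 20,
                              n_neighbors = 5) {
  if (nrow(reference) == 0) stop("empty reference panel")
  if (anyNA(reference)) stop("reference panel must be fully genotyped")
  if (!all(colnames(g) == colnames(reference))) {
    stop("target and reference must share the same (standard) marker set")
  }
  map <- map[match(colnames(g), map$marker_id), , drop = FALSE]
  n_neighbors <- min(n_neighbors, nrow(reference))
  ind <- function(M, v) { x <- (!is.na(M)) & (M == v); storage.mode(x) <- "double"; x }
  Rv <- lapply(0:2, function(v) ind(reference, v))
  ref_mode <- apply(reference, 2L, function(x) {
    tb <- tabulate(x + 1L, 3L); which.max(tb) - 1L  # ties -> lower dosage
  })
  out <- g
  for (ch in unique(map$chrom)) {
    cidx <- which(map$chrom == ch)
    cidx <- cidx[order(map$pos_bp[cidx])]
    tg <- g[, cidx, drop = FALSE]
    Tv <- lapply(0:2, function(v) ind(tg, v))
    obs <- (!is.na(tg)) * 1
    # chromosome-wide mismatch (fallback and tie-break)
    match_all <- Reduce(`+`, lapply(1:3, function(v) Tv[[v]] %*% t(Rv[[v]][, cidx, drop = FALSE])))
    n_all <- rowSums(obs)
    glob_mm <- (n_all - match_all) / pmax(n_all, 1)
    starts <- seq(1L, length(cidx), by = window_markers)
    for (st in starts) {
      w <- st:min(st + window_markers - 1L, length(cidx))
      need_rows <- which(rowSums(is.na(tg[, w, drop = FALSE])) > 0L)
      if (!length(need_rows)) next
      mw <- Reduce(`+`, lapply(1:3, function(v)
        Tv[[v]][need_rows, w, drop = FALSE] %*% t(Rv[[v]][, cidx[w], drop = FALSE])))
      nw <- rowSums(obs[need_rows, w, drop = FALSE])
      # neighbour one-hot matrix (targets x references)
      NB <- matrix(0, length(need_rows), nrow(reference))
      for (k in seq_along(need_rows)) {
        sc <- if (nw[k] > 0) {
          (nw[k] - mw[k, ]) / nw[k] + 1e-9 * glob_mm[need_rows[k], ]
        } else {
          glob_mm[need_rows[k], ]
        }
        NB[k, order(sc)[seq_len(n_neighbors)]] <- 1
      }
      cnt <- lapply(1:3, function(v) NB %*% Rv[[v]][, cidx[w], drop = FALSE])
      mx <- pmax(cnt[[1]], cnt[[2]], cnt[[3]])
      t0 <- cnt[[1]] == mx; t1 <- cnt[[2]] == mx; t2 <- cnt[[3]] == mx
      nt <- t0 + t1 + t2
      RM <- matrix(ref_mode[cidx[w]], length(need_rows), length(w), byrow = TRUE)
      mode_in_top <- (RM == 0 & t0) | (RM == 1 & t1) | (RM == 2 & t2)
      min_top <- ifelse(t0, 0L, ifelse(t1, 1L, 2L))
      best <- ifelse(nt == 1L, t1 + 2L * t2, ifelse(mode_in_top, RM, min_top))
      blk <- out[need_rows, cidx[w], drop = FALSE]
      na_mask <- is.na(blk)
      blk[na_mask] <- best[na_mask]
      out[need_rows, cidx[w]] <- blk
    }
  }
  out
}

#' Frequency-only baseline imputer
#'
#' Fills every missing entry with the most common genotype of the marker in
#' the reference panel (ties toward the lower dosage) — the no-information
#' baseline against which family/population imputation is judged.
#'
#' @inheritParams population_impute
#' @return completed dosage matrix.
#' @export
frequency_impute <- function(g, reference) {
  if (nrow(reference) == 0) stop("empty reference panel")
  mode_g <- apply(reference, 2L, function(x) {
    tb <- tabulate(x[!is.na(x)] + 1L, 3L)
    which.max(tb) - 1L
  })
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- mode_g[j]
  }
  g
}

#' Two-stage imputation up to the standard marker set
#'
#' Runs [mendelian_impute()] (family information) and then
#' [population_impute()] (haplotype-window templates) so that the output has
#' no missing entries; observed genotypes are preserved verbatim.
#'
#' @param g target dosage matrix over the standard marker set.
#' @param ped pedigree linking targets and reference individuals.
#' @param reference complete reference dosage matrix over the same markers.
#' @param map marker map.
#' @param window_markers,n_neighbors see [population_impute()].
#' @return completed dosage matrix with attribute `"n_family_filled"`.
#' @export
impute_genotypes <- function(g, ped, reference, map, window_markers = 20,
                             n_neighbors = 5) {
  combined <- rbind(g, reference[setdiff(rownames(reference), rownames(g)), ,
                                 drop = FALSE])
  fam <- mendelian_impute(combined, ped)
  gf <- fam[rownames(g), , drop = FALSE]
  out <- population_impute(gf, reference, map, window_markers, n_neighbors)
  attr(out, "n_family_filled") <- attr(fam, "n_filled")
  out
}

#' Masking-based imputation validation
#'
#' Restricts target individuals to a low-density panel (all other markers
#' masked), imputes back to the standard set using the reference
#' individuals at full density, and reports the proportion of masked
#' genotypes imputed correctly. Optionally refits the genomic evaluation
#' with original and with imputed genotypes and reports the Spearman
#' concordance of the resulting GEBV per trait.
#'
#' @param hd_g complete high-density dosage matrix covering targets and
#'   references.
#' @param panel low-density panel (data.frame or marker id vector).
#' @param ped pedigree.
#' @param target_ids individuals to mask (e.g. the newest year class).
#' @param reference_ids individuals kept at full density (disjoint from
#'   `target_ids`).
#' @param map marker map.
#' @param window_markers,n_neighbors imputation parameters.
#' @param gebv optional list to also measure GEBV concordance:
#'   `phenotypes`, `tm`, plus optional `model_name`/`traits` and `tau`,
#'   passed to [run_evaluation()].
#' @return list of class `imputation_report`: `n_masked`, `n_imputed`,
#'   `accuracy_overall`, `per_marker` accuracies, and `gebv_concordance`
#'   (named per trait) when requested.
#' @export
mask_and_validate <- function(hd_g, panel, ped, target_ids, reference_ids,
                              map, window_markers = 20, n_neighbors = 5,
                              gebv = NULL) {
  if (length(intersect(target_ids, reference_ids))) {
    stop("target and reference sets must be disjoint")
  }
  panel_ids <- if (is.data.frame(panel)) panel$marker_id else panel
  masked_cols <- setdiff(colnames(hd_g), panel_ids)
  if (!length(masked_cols)) stop("panel covers all markers: nothing to mask")
  truth <- hd_g[target_ids, , drop = FALSE]
  masked <- truth
  masked[, masked_cols] <- NA_integer_
  imp <- impute_genotypes(masked, ped, hd_g[reference_ids, , drop = FALSE],
                          map, window_markers, n_neighbors)
  cmp_cols <- masked_cols
  was_obs <- !is.na(truth[, cmp_cols, drop = FALSE])
  correct <- was_obs & (imp[, cmp_cols, drop = FALSE] == truth[, cmp_cols, drop = FALSE])
  per_marker <- colSums(correct) / pmax(colSums(was_obs), 1L)
  rep <- list(
    n_masked = sum(was_obs),
    n_imputed = sum(was_obs),
    accuracy_overall = sum(correct) / sum(was_obs),
    per_marker = per_marker,
    panel_size = length(intersect(panel_ids, colnames(hd_g)))
  )
  if (!is.null(gebv)) {
    full <- hd_g[c(reference_ids, target_ids), , drop = FALSE]
    imputed_full <- full
    imputed_full[target_ids, ] <- imp[target_ids, colnames(full)]
    args_common <- list(phenotypes = gebv$phenotypes, pedigree = ped,
                        tm = gebv$tm, K_kind = "H",
                        model_name = if (is.null(gebv$model_name)) "All" else gebv$model_name,
                        traits = gebv$traits,
                        tau = if (is.null(gebv$tau)) 0.05 else gebv$tau,
                        compute_se = FALSE)
    bv_orig <- do.call(run_evaluation, c(args_common, list(genotypes = full)))
    bv_imp <- do.call(run_evaluation, c(args_common, list(genotypes = imputed_full)))
    traits <- unique(bv_orig$trait)
    conc <- vapply(traits, function(tr) {
      a <- bv_orig[bv_orig$trait == tr & bv_orig$id %in% target_ids, ]
      b <- bv_imp[bv_imp$trait == tr & bv_imp$id %in% target_ids, ]
      stats::cor(a$value, b$value[match(a$id, b$id)], method = "spearman")
    }, numeric(1))
    rep$gebv_concordance <- conc
  }
  class(rep) <- "imputation_report"
  rep
}
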