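# LD computation and two-tier SNP panel design: a high-density array built
# from an LD-pruned scaffold plus per-bin fill, and a low-density subset
# chosen by even physical spacing.

#' Pairwise linkage disequilibrium within a distance window
#'
#' r-squared is the squared Pearson correlation of dosages, computed for all
#' same-chromosome marker pairs within `max_dist_bp` (pairwise-complete
#' observations).
#'
#' @param g dosage matrix (individuals x markers).
#' @param map marker map covering the columns of `g`.
#' @param max_dist_bp maximum inter-marker distance.
#' @return data.frame `marker1`, `marker2`, `chrom`, `dist_bp`, `r2`.
#'   Zero-variance markers are skipped (attribute `"skipped"`).
#' @export
pairwise_ld <- function(g, map, max_dist_bp = Inf) {
  map <- map[match(colnames(g), map$marker_id), , drop = FALSE]
  if (anyNA(map$marker_id)) stop("genotype columns missing from the marker map")
  out <- vector("list", length(unique(map$chrom)))
  skipped <- character(0)
  for (ci in seq_along(unique(map$chrom))) {
    ch <- unique(map$chrom)[ci]
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$pos_bp[idx])]
    if (length(idx) < 2L) next
    gc <- g[, idx, drop = FALSE]
    v <- apply(gc, 2L, stats::var, na.rm = TRUE)
    zv <- !is.finite(v) | v < 1e-12
    skipped <- c(skipped, colnames(gc)[zv])
    keep <- which(!zv)
    if (length(keep) < 2L) next
    gc <- gc[, keep, drop = FALSE]
    pos <- map$pos_bp[idx][keep]
    cc <- suppressWarnings(stats::cor(gc, use = "pairwise.complete.obs"))
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- pos[pr[, 2L]] - pos[pr[, 1L]]
    ok <- d <= max_dist_bp
    out[[ci]] <- data.frame(
      marker1 = colnames(gc)[pr[ok, 1L]],
      marker2 = colnames(gc)[pr[ok, 2L]],
      chrom = ch,
      dist_bp = d[ok],
      r2 = cc[pr][ok]^2,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(marker1 = character(0), marker2 = character(0),
                      chrom = integer(0), dist_bp = numeric(0), r2 = numeric(0))
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- unique(skipped)
  res
}

#' Greedy LD pruning
#'
#' Left-to-right scan per chromosome: a marker is kept iff its r-squared with
#' every already-kept marker inside the LD table's distance window is below
#' `r2_max` (first-kept tie-break).
#'
#' @param ld LD table from [pairwise_ld()] covering the candidate pairs.
#' @param markers marker ids to scan, in map order.
#' @param r2_max pruning threshold (default 0.2; pairs at exactly the
#'   threshold are pruned).
#' @return character vector of retained marker ids, input order preserved.
#' @export
ld_prune <- function(ld, markers, r2_max = 0.2) {
  high <- ld[ld$r2 >= r2_max, c("marker1", "marker2")]
  conflict <- new.env(parent = emptyenv(), size = 2L * nrow(high) + 1L)
  add_edge <- function(a, b) assign(a, c(get0(a, envir = conflict), b), envir = conflict)
  for (r in seq_len(nrow(high))) {
    add_edge(high$marker1[r], high$marker2[r])
    add_edge(high$marker2[r], high$marker1[r])
  }
  kept <- new.env(parent = emptyenv(), size = length(markers))
  out <- character(0)
  for (mk in markers) {
    partners <- get0(mk, envir = conflict)
    if (is.null(partners) || !any(vapply(partners, function(p)
      isTRUE(get0(p, envir = kept)), logical(1)))) {
      assign(mk, TRUE, envir = kept)
      out <- c(out, mk)
    }
  }
  out
}

#' Assign markers to fixed-width physical bins
#'
#' Half-open bins per chromosome: bin `k` (0-based) covers 1-based positions
#' `[k * bin_bp + 1, (k + 1) * bin_bp]`, so position 100,000 falls in bin 0
#' and position 100,001 in bin 1 for 100 kbp bins.
#'
#' @param map marker map.
#' @param bin_bp bin width in bp (default 100 kbp).
#' @return data.frame `marker_id`, `chrom`, `bin` (0-based index within
#'   chromosome), `bin_id` (chromosome-qualified label).
#' @export
bin_markers <- function(map, bin_bp = 1e5) {
  bin <- (map$pos_bp - 1L) %/% bin_bp
  data.frame(marker_id = map$marker_id, chrom = map$chrom, bin = bin,
             bin_id = paste0(map$chrom, ":", bin), stringsAsFactors = FALSE)
}

# Mean r2 of each marker with its nearby markers (local LD score), from an
# LD table; markers without covered pairs get 0.
local_ld_score <- function(ld, markers) {
  sc <- stats::setNames(numeric(length(markers)), markers)
  if (nrow(ld)) {
    sums <- rowsum(c(ld$r2, ld$r2), c(ld$marker1, ld$marker2))
    cnts <- rowsum(rep(1, 2L * nrow(ld)), c(ld$marker1, ld$marker2))
    mns <- sums[, 1L] / cnts[, 1L]
    hit <- intersect(names(mns), markers)
    sc[hit] <- mns[hit]
  }
  sc
}

#' Design a high-density SNP panel
#'
#' Implements the segment-tagging design: the LD-pruned scaffold and all
#' trait-associated markers are included first; remaining slots are filled
#' per 100 kbp bin with the marker maximizing `rank(MAF) - rank(local mean
#' r2)` among eligible markers, ensuring every occupied bin is tagged before
#' any bin receives a second filler. Deterministic given input order.
#'
#' @param g dosage matrix for computing MAF.
#' @param map marker map.
#' @param scaffold marker ids from [ld_prune()].
#' @param trait_markers trait-associated marker ids to force-include.
#' @param target_size total panel size.
#' @param ld LD table for the local-LD score (optional; zero scores if NULL).
#' @param bin_bp bin width.
#' @param maf_min eligibility floor for filler markers.
#' @return data.frame panel spec: `marker_id`, `provenance`
#'   (`"segment-tag"`, `"trait-associated"`, `"filler"`), in map order.
#' @export
design_hd_panel <- function(g, map, scaffold, trait_markers = character(0),
                            target_size, ld = NULL, bin_bp = 1e5,
                            maf_min = 0.02) {
  base <- union(scaffold, trait_markers)
  if (target_size < length(base)) {
    stop(sprintf("target_size %d is below the minimum feasible size %d (scaffold + trait markers)",
                 as.integer(target_size), length(base)))
  }
  if (target_size > nrow(map)) stop("target_size exceeds the number of available markers")
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)[map$marker_id]
  bins <- bin_markers(map, bin_bp)
  ldsc <- if (is.null(ld)) {
    stats::setNames(numeric(nrow(map)), map$marker_id)
  } else {
    local_ld_score(ld, map$marker_id)
  }
  score <- rank(maf, ties.method = "first") - rank(ldsc, ties.method = "first")
  names(score) <- map$marker_id

  chosen <- intersect(map$marker_id, base)  # map order
  prov <- ifelse(chosen %in% trait_markers, "trait-associated", "segment-tag")
  eligible <- map$marker_id[!(map$marker_id %in% base) & maf >= maf_min &
                              !is.na(maf)]
  slots <- target_size - length(chosen)
  if (slots > 0 && length(eligible)) {
    bin_of <- stats::setNames(bins$bin_id, bins$marker_id)
    n_in_bin <- table(bin_of[chosen])
    # queue eligible markers per bin, best score first
    by_bin <- split(eligible, bin_of[eligible])
    by_bin <- lapply(by_bin, function(mk) mk[order(-score[mk], mk)])
    fill <- character(0)
    round <- 0L
    while (slots > length(fill) && length(by_bin)) {
      # bins currently at the minimum coverage get served first
      cover <- vapply(names(by_bin), function(b) {
        sum(n_in_bin[b], na.rm = TRUE)
      }, numeric(1))
      take <- names(by_bin)[order(cover, names(by_bin))]
      for (b in take) {
        if (length(fill) >= slots) break
        mk <- by_bin[[b]][1L]
        by_bin[[b]] <- by_bin[[b]][-1L]
        if (!length(by_bin[[b]])) by_bin[[b]] <- NULL
        fill <- c(fill, mk)
        n_in_bin[b] <- sum(n_in_bin[b], na.rm = TRUE) + 1L
      }
      round <- round + 1L
      if (round > target_size) break
    }
    chosen <- c(chosen, fill)
    prov <- c(prov, rep("filler", length(fill)))
  }
  if (length(chosen) < target_size) {
    # eligible pool exhausted: top up with the best remaining markers so the
    # requested size is always met (only reachable when target ~ all markers)
    rest <- setdiff(map$marker_id, chosen)
    rest <- rest[order(-score[rest], rest)]
    extra <- rest[seq_len(min(length(rest), target_size - length(chosen)))]
    chosen <- c(chosen, extra)
    prov <- c(prov, rep("filler", length(extra)))
  }
  o <- order(match(chosen, map$marker_id))
  data.frame(marker_id = chosen[o], provenance = prov[o], stringsAsFactors = FALSE)
}

#' Design a low-density panel from the high-density panel
#'
#' One marker per even physical-spacing window (window length = genome
#' length / `target_size`), preferring within each window the high-MAF,
#' low-local-LD marker; trait-associated markers are force-included. If
#' fewer windows are occupied than `target_size`, remaining slots are filled
#' by the best-scoring unchosen HD markers genome-wide.
#'
#' @param g dosage matrix for MAF.
#' @param map marker map.
#' @param hd_panel data.frame from [design_hd_panel()] (or character vector
#'   of HD marker ids).
#' @param target_size 1000- or 3000-class panel size (any positive size
#'   `<=` HD panel size accepted).
#' @param trait_markers force-included marker ids (must be on the HD panel).
#' @param ld optional LD table for the local-LD score.
#' @return data.frame panel spec (`marker_id`, `provenance`).
#' @export
design_ld_panel <- function(g, map, hd_panel, target_size,
                            trait_markers = character(0), ld = NULL) {
  hd_ids <- if (is.data.frame(hd_panel)) hd_panel$marker_id else hd_panel
  if (target_size > length(hd_ids)) stop("target_size exceeds the HD panel size")
  sub <- map[map$marker_id %in% hd_ids, , drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)[sub$marker_id]
  ldsc <- if (is.null(ld)) stats::setNames(numeric(nrow(sub)), sub$marker_id) else
    local_ld_score(ld, sub$marker_id)
  score <- rank(maf, ties.method = "first") - rank(ldsc, ties.method = "first")
  names(score) <- sub$marker_id

  genome_len <- sum(tapply(map$pos_bp, map$chrom, max))
  w <- genome_len / target_size
  win <- paste0(sub$chrom, ":", floor((sub$pos_bp - 1) / w))
  forced <- intersect(trait_markers, sub$marker_id)
  chosen <- forced
  by_win <- split(sub$marker_id, win)
  for (b in names(by_win)) {
    if (any(by_win[[b]] %in% chosen)) next
    mk <- by_win[[b]]
    chosen <- c(chosen, mk[order(-score[mk], mk)][1L])
  }
  if (length(chosen) > target_size) {
    # keep forced markers, trim lowest-score window picks
    extra <- setdiff(chosen, forced)
    extra <- extra[order(-score[extra], extra)]
    chosen <- c(forced, extra[seq_len(max(0, target_size - length(forced)))])
  } else if (length(chosen) < target_size) {
    rest <- setdiff(sub$marker_id, chosen)
    rest <- rest[order(-score[rest], rest)]
    chosen <- c(chosen, rest[seq_len(min(length(rest), target_size - length(chosen)))])
  }
  o <- order(match(chosen, map$marker_id))
  data.frame(marker_id = chosen[o],
             provenance = ifelse(chosen[o] %in% forced, "trait-associated", "segment-tag"),
             stringsAsFactors = FALSE)
}

#' Summary statistics of a panel
#'
#' @param panel panel spec data.frame or character vector of marker ids.
#' @param map marker map.
#' @param g dosage matrix for MAF.
#' @param bin_bp bin width for the coverage statistic.
#' @return list: `n_markers`, `mean_spacing_bp`, `largest_gap_bp`,
#'   `mean_maf`, `bin_coverage` (fraction of occupied map bins containing a
#'   panel marker).
#' @export
panel_summary <- function(panel, map, g, bin_bp = 1e5) {
  ids <- if (is.data.frame(panel)) panel$marker_id else panel
  if (!length(ids)) stop("empty panel")
  sub <- map[map$marker_id %in% ids, , drop = FALSE]
  gaps <- unlist(tapply(sub$pos_bp, sub$chrom, function(x) diff(sort(x))),
                 use.names = FALSE)
  p <- colMeans(g[, ids, drop = FALSE], na.rm = TRUE) / 2
  bins <- bin_markers(map, bin_bp)
  occupied <- unique(bins$bin_id)
  covered <- unique(bins$bin_id[bins$marker_id %in% ids])
  list(
    n_markers = length(ids),
    mean_spacing_bp = if (length(gaps)) mean(gaps) else NA_real_,
    largest_gap_bp = if (length(gaps)) max(gaps) else NA_real_,
    mean_maf = mean(pmin(p, 1 - p)),
    bin_coverage = length(covered) / length(occupied)
  )
}
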