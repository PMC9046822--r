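# File formats, two-level QC, Mendelian-error checking, and genotype-based
# parentage assignment.

#' Read and write genotype matrices
#'
#' TSV layout: first column `id`, remaining columns one marker each, values
#' 0/1/2/NA. VCF dialect: biallelic SNVs only (multiallelic sites are dropped
#' with a warning), GT field required, `./.` maps to missing, 1-based
#' positions; dosage counts the ALT allele.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return integer dosage matrix with individual rownames and marker colnames.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path) || file.size(path) == 0) stop("empty or missing file: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                        colClasses = "character"),
      error = function(e) stop("malformed genotype TSV (", conditionMessage(e), ")")
    )
    if (!nrow(df) || names(df)[1L] != "id") stop("genotype TSV must start with an 'id' column")
    ids <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "integer")
    bad <- which(!is.na(m) & !(m %in% 0:2))
    if (length(bad)) stop("invalid dosage values at ", length(bad), " cells (line ",
                          ((bad[1L] - 1L) %% nrow(m)) + 2L, ")")
    rownames(m) <- ids
    m
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    if (nrow(v@fix) == 0) stop("empty VCF: ", path)
    multi <- grepl(",", v@fix[, "ALT"]) | nchar(v@fix[, "REF"]) != 1L |
      nchar(v@fix[, "ALT"]) != 1L
    if (any(multi)) {
      warning(sum(multi), " multiallelic/non-SNV site(s) rejected")
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    conv <- function(x) {
      x <- gsub("\\|", "/", x)
      out <- rep(NA_integer_, length(x))
      out[x == "0/0"] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x == "1/1"] <- 2L
      out
    }
    m <- apply(gt, 2L, conv)
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(gt), dimnames = dimnames(gt))
    rownames(m) <- v@fix[, "ID"]
    t(m)
  }
}

#' @rdname read_genotypes
#' @param g dosage matrix to write.
#' @param map marker map (required for VCF, supplies CHROM/POS).
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(g), g, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(map)) stop("a marker map is required to write VCF")
    map <- map[match(colnames(g), map$marker_id), , drop = FALSE]
    gt <- matrix("./.", ncol(g), nrow(g))
    gt[t(g) == 0L] <- "0/0"
    gt[t(g) == 1L] <- "0/1"
    gt[t(g) == 2L] <- "1/1"
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=salmogs",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", rownames(g)), collapse = "\t"),
      paste(map$chrom, map$pos_bp, map$marker_id, "A", "B", ".", "PASS", ".",
            "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and write pedigree, phenotype and marker-map tables
#'
#' Pedigree CSV columns: `id, sire, dam, sex, year_class`; phenotype CSV:
#' `id, trait, value, cohort, family, environment`; marker map TSV:
#' `marker_id, chrom, pos_bp, role`.
#'
#' @param path file path.
#' @param x object to write.
#' @return the read data.frame, or (invisibly) `path` for writers.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) stop("pedigree CSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_pedigree
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_pedigree
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_pedigree
#' @export
read_marker_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_pedigree
#' @export
write_marker_map <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-level genotype quality control
#'
#' Removes markers with minor allele frequency below `maf_min` (computed on
#' non-missing calls; markers at exactly the threshold are kept) or call
#' rate below `marker_call_min`. In `"full"` mode, individuals with call
#' rate below `ind_call_min` (over the retained markers) are also removed;
#' in `"basic"` mode no individuals are removed, so the maximum number of
#' individuals remains available for parentage assignment.
#'
#' @param g dosage matrix.
#' @param maf_min MAF threshold (default 0.02; strictly-below removed).
#' @param marker_call_min marker call-rate threshold (default 0.90).
#' @param ind_call_min individual call-rate threshold (default 0.90).
#' @param mode `"basic"` or `"full"`.
#' @return list with `genotypes` (filtered matrix) and `report` (a
#'   `qc_report`: data.frames of removed markers/individuals with reasons).
#' @export
qc_filter <- function(g, maf_min = 0.02, marker_call_min = 0.90,
                      ind_call_min = 0.90, mode = c("full", "basic")) {
  mode <- match.arg(mode)
  for (th in c(maf_min, marker_call_min, ind_call_min)) {
    check_scalar(th, "threshold", 0, 1)
  }
  call_rate_m <- colMeans(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing marker
  drop_maf <- maf < maf_min
  drop_call <- call_rate_m < marker_call_min
  markers_removed <- data.frame(
    marker = colnames(g)[drop_maf | drop_call],
    reason = ifelse(drop_maf[drop_maf | drop_call], "MAF", "call_rate"),
    value = ifelse(drop_maf[drop_maf | drop_call],
                   maf[drop_maf | drop_call], call_rate_m[drop_maf | drop_call]),
    stringsAsFactors = FALSE
  )
  g2 <- g[, !(drop_maf | drop_call), drop = FALSE]
  individuals_removed <- data.frame(id = character(0), reason = character(0),
                                    value = numeric(0), stringsAsFactors = FALSE)
  if (mode == "full" && ncol(g2)) {
    call_rate_i <- rowMeans(!is.na(g2))
    drop_i <- call_rate_i < ind_call_min
    if (any(drop_i)) {
      individuals_removed <- data.frame(id = rownames(g2)[drop_i],
                                        reason = "call_rate",
                                        value = call_rate_i[drop_i],
                                        stringsAsFactors = FALSE)
      g2 <- g2[!drop_i, , drop = FALSE]
    }
  }
  report <- structure(list(markers_removed = markers_removed,
                           individuals_removed = individuals_removed,
                           mode = mode,
                           thresholds = c(maf_min = maf_min,
                                          marker_call_min = marker_call_min,
                                          ind_call_min = ind_call_min)),
                      class = "qc_report")
  list(genotypes = g2, report = report)
}

# Impossible offspring dosage given two parent dosages (9 x 3 lookup):
# entry [s+1, d+1, o+1] is TRUE when P(o | s, d) = 0 under Mendelian
# inheritance.
trio_impossible <- local({
  arr <- array(FALSE, c(3, 3, 3))
  for (s in 0:2) for (d in 0:2) for (o in 0:2) {
    ps <- switch(s + 1L, 0, 0.5, 1)   # P(transmit alt) from sire
    pd <- switch(d + 1L, 0, 0.5, 1)
    prob <- switch(o + 1L,
                   (1 - ps) * (1 - pd),
                   ps * (1 - pd) + (1 - ps) * pd,
                   ps * pd)
    arr[s + 1L, d + 1L, o + 1L] <- prob == 0
  }
  arr
})

#' Mendelian-error check
#'
#' Counts impossible parent-offspring dosage configurations: opposing
#' homozygotes for genotyped parent-offspring pairs (dosages 0 vs 2) and
#' trio-impossible combinations when both parents are genotyped (e.g.
#' parents 0 x 0 with offspring 1). Rates are errors over comparable
#' (fully genotyped) pair or trio calls.
#'
#' @param g dosage matrix.
#' @param ped pedigree (`id`, `sire`, `dam`).
#' @param marker_rate_max per-marker error-rate threshold above which a
#'   marker is flagged for removal (default 0.05).
#' @return list with `per_marker` (marker, n_checks, n_errors, rate,
#'   flagged), `per_trio` (offspring, sire, dam, n_checks, n_errors, rate),
#'   and `flagged_markers`.
#' @export
mendelian_error_check <- function(g, ped, marker_rate_max = 0.05) {
  ids <- rownames(g)
  off <- ped[ped$id %in% ids & (ped$sire %in% ids | ped$dam %in% ids), , drop = FALSE]
  m <- ncol(g)
  mk_err <- mk_n <- numeric(m)
  trio <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    o <- g[off$id[r], ]
    s <- if (!is.na(off$sire[r]) && off$sire[r] %in% ids) g[off$sire[r], ] else NULL
    d <- if (!is.na(off$dam[r]) && off$dam[r] %in% ids) g[off$dam[r], ] else NULL
    if (!is.null(s) && !is.null(d)) {
      ok <- !is.na(o) & !is.na(s) & !is.na(d)
      err <- ok & trio_impossible[cbind(s + 1L, d + 1L, o + 1L)]
    } else {
      p <- if (!is.null(s)) s else d
      ok <- !is.na(o) & !is.na(p)
      err <- ok & ((o == 0L & p == 2L) | (o == 2L & p == 0L))
    }
    err[is.na(err)] <- FALSE
    mk_err <- mk_err + err
    mk_n <- mk_n + ok
    trio[[r]] <- data.frame(offspring = off$id[r],
                            sire = off$sire[r], dam = off$dam[r],
                            n_checks = sum(ok), n_errors = sum(err),
                            rate = if (sum(ok)) sum(err) / sum(ok) else NA_real_,
                            stringsAsFactors = FALSE)
  }
  per_trio <- if (length(trio)) do.call(rbind, trio) else
    data.frame(offspring = character(0), sire = character(0), dam = character(0),
               n_checks = integer(0), n_errors = integer(0), rate = numeric(0))
  rate <- ifelse(mk_n > 0, mk_err / mk_n, NA_real_)
  per_marker <- data.frame(marker = colnames(g), n_checks = mk_n,
                           n_errors = mk_err, rate = rate,
                           flagged = !is.na(rate) & rate > marker_rate_max,
                           stringsAsFactors = FALSE)
  list(per_marker = per_marker, per_trio = per_trio,
       flagged_markers = per_marker$marker[per_marker$flagged])
}

#' Genotype-based parentage assignment by Mendelian exclusion
#'
#' For each offspring, evaluates every male x female candidate pair and
#' selects the pair with the lowest trio mismatch rate (impossible dosage
#' configurations over markers where all three are genotyped). The
#' assignment is accepted only when the best rate is at most
#' `max_mismatch_rate` and the margin to the second-best pair (excluding
#' pairs sharing identical mismatch, e.g. duplicated samples) exceeds
#' `min_margin`.
#'
#' @param offspring dosage matrix of offspring.
#' @param candidates dosage matrix of candidate parents.
#' @param candidate_meta data.frame `id`, `sex` (`"M"`/`"F"`) for candidates.
#' @param max_mismatch_rate acceptance threshold on the trio mismatch rate.
#' @param min_margin required gap to the second-best pair's rate.
#' @param min_shared_markers minimum markers shared offspring/candidates.
#' @return data.frame `id`, `sire`, `dam`, `mismatch_rate`, `margin`,
#'   `assigned`, `reason`.
#' @export
assign_parentage <- function(offspring, candidates, candidate_meta,
                             max_mismatch_rate = 0.05, min_margin = 0.02,
                             min_shared_markers = 80) {
  shared <- intersect(colnames(offspring), colnames(candidates))
  if (length(shared) < min_shared_markers) {
    stop("fewer than ", min_shared_markers, " shared markers between offspring and candidates")
  }
  offspring <- offspring[, shared, drop = FALSE]
  candidates <- candidates[, shared, drop = FALSE]
  males <- candidate_meta$id[candidate_meta$sex == "M"]
  females <- candidate_meta$id[candidate_meta$sex == "F"]
  out <- data.frame(id = rownames(offspring), sire = NA_character_,
                    dam = NA_character_, mismatch_rate = NA_real_,
                    margin = NA_real_, assigned = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  if (!length(males) || !length(females)) {
    out$reason <- "no candidates of one sex"
    return(out)
  }
  S <- candidates[males, , drop = FALSE]
  D <- candidates[females, , drop = FALSE]
  # dosage-class indicators (NA-safe)
  ind <- function(M, v) { x <- (!is.na(M)) & (M == v); storage.mode(x) <- "double"; x }
  Sv <- lapply(0:2, function(v) ind(S, v)); Sk <- Reduce(`+`, Sv)
  Dv <- lapply(0:2, function(v) ind(D, v)); Dk <- Reduce(`+`, Dv)
  for (r in seq_len(nrow(offspring))) {
    o <- offspring[r, ]
    res <- trio_mismatch_matrix(o, Sv, Dv, Sk, Dk)
    rate <- res$err / pmax(res$n, 1)
    rate[res$n == 0] <- NA_real_
    if (all(is.na(rate))) { out$reason[r] <- "no comparable markers"; next }
    best <- which(rate == min(rate, na.rm = TRUE), arr.ind = TRUE)
    if (nrow(best) > 1L) {
      out$reason[r] <- "ambiguous: multiple best pairs"
      out$mismatch_rate[r] <- min(rate, na.rm = TRUE)
      next
    }
    b1 <- rate[best]
    li <- (best[1, 2] - 1L) * nrow(rate) + best[1, 1]
    second <- suppressWarnings(min(rate[-li], na.rm = TRUE))
    margin <- second - b1
    out$mismatch_rate[r] <- b1
    out$margin[r] <- margin
    if (b1 > max_mismatch_rate) {
      out$reason[r] <- "best pair above mismatch threshold"
    } else if (is.finite(margin) && margin < min_margin) {
      out$reason[r] <- "margin to second-best pair too small"
    } else {
      out$sire[r] <- males[best[1, 1]]
      out$dam[r] <- females[best[1, 2]]
      out$assigned[r] <- TRUE
      out$reason[r] <- "ok"
    }
  }
  out
}

# Trio mismatch counts for one offspring against all sire x dam pairs via
# dosage-class indicator products. For offspring dosage o at a marker the
# impossible (s, d) classes are:
#   o = 0: s = 2 or d = 2
#   o = 1: (s = 0 and d = 0) or (s = 2 and d = 2)
#   o = 2: s = 0 or d = 0
trio_mismatch_matrix <- function(o, Sv, Dv, Sk, Dk) {
  K <- lapply(0:2, function(v) as.double(!is.na(o) & o == v))
  w <- function(Sm, km) sweep(Sm, 2L, km, `*`)  # mask marker columns
  nS <- nrow(Sv[[1]]); nD <- nrow(Dv[[1]])
  err <- matrix(0, nS, nD)
  # o = 0: OR(s2, d2) = s2 + d2 - s2 d2
  k <- K[[1]]
  err <- err + outer(drop(w(Sv[[3]], k) %*% rep(1, length(o))), rep(1, nD)) +
    outer(rep(1, nS), drop(w(Dv[[3]], k) %*% rep(1, length(o)))) -
    w(Sv[[3]], k) %*% t(Dv[[3]])
  # o = 1: s0 d0 + s2 d2
  k <- K[[2]]
  err <- err + w(Sv[[1]], k) %*% t(Dv[[1]]) + w(Sv[[3]], k) %*% t(Dv[[3]])
  # o = 2: OR(s0, d0)
  k <- K[[3]]
  err <- err + outer(drop(w(Sv[[1]], k) %*% rep(1, length(o))), rep(1, nD)) +
    outer(rep(1, nS), drop(w(Dv[[1]], k) %*% rep(1, length(o)))) -
    w(Sv[[1]], k) %*% t(Dv[[1]])
  # comparable markers: all three genotyped
  kall <- as.double(!is.na(o))
  n <- w(Sk, kall) %*% t(Dk)
  list(err = err, n = n)
}
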