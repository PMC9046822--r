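# Pedigree (A), genomic (G), blended (G*) and single-step augmented (H)
# relationship matrices.

# Topologically sort a pedigree (parents before offspring). Errors on cycles
# or parents that are not themselves listed individuals (unknown parents are
# NA). Returns the row permutation.
pedigree_order <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicated individual ids in pedigree")
  s <- match(as.character(ped$sire), id)
  d <- match(as.character(ped$dam), id)
  if (any(!is.na(ped$sire) & is.na(s)) || any(!is.na(ped$dam) & is.na(d))) {
    stop("pedigree parents must be listed individuals or NA")
  }
  n <- length(id)
  placed <- logical(n)
  ord <- integer(0)
  s1 <- replace(s, is.na(s), 1L)  # dummy index; masked by is.na() below
  d1 <- replace(d, is.na(d), 1L)
  repeat {
    ready <- which(!placed & (is.na(s) | placed[s1]) & (is.na(d) | placed[d1]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) stop("cycle in pedigree: no topological order exists")
  ord
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes Wright's numerator relationship matrix A by the tabular method:
#' `a_ii = 1 + F_i` with `F_i = a_{sire,dam} / 2`, and
#' `a_ij = (a_{j,sire(i)} + a_{j,dam(i)}) / 2` for `j` preceding `i`;
#' unknown parents contribute zero.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (NA for unknown
#'   parents). Any order; sorted internally, output follows input order.
#' @return symmetric matrix with dimnames = ids, in the input id order.
#' @export
numerator_relationship <- function(ped) {
  ord <- pedigree_order(ped)
  id <- as.character(ped$id)[ord]
  s <- match(as.character(ped$sire)[ord], id)
  d <- match(as.character(ped$dam)[ord], id)
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(si)) row <- row + 0.5 * A[si, j]
      if (!is.na(di)) row <- row + 0.5 * A[di, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  back <- match(as.character(ped$id), id)
  A[back, back, drop = FALSE]
}

#' Inverse of the numerator relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from pedigree structure, accounting for
#' inbreeding via the Mendelian-sampling variances
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (both parents known),
#' `0.75 - 0.25 F_p` (one known) or 1 (none known).
#'
#' @param ped pedigree data.frame (`id`, `sire`, `dam`).
#' @param A optional precomputed A (used for the inbreeding coefficients);
#'   computed if missing.
#' @return the inverse of A, in the input id order.
#' @export
a_inverse <- function(ped, A = NULL) {
  if (is.null(A)) A <- numerator_relationship(ped)
  id <- as.character(ped$id)
  Fi <- diag(A)[id] - 1
  s <- match(as.character(ped$sire), id)
  d <- match(as.character(ped$dam), id)
  n <- length(id)
  Ai <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    di_ms <- if (!is.na(si) && !is.na(di)) {
      0.5 - 0.25 * (Fi[si] + Fi[di])
    } else if (!is.na(si)) {
      0.75 - 0.25 * Fi[si]
    } else if (!is.na(di)) {
      0.75 - 0.25 * Fi[di]
    } else 1
    al <- 1 / di_ms
    Ai[i, i] <- Ai[i, i] + al
    for (p in c(si, di)) {
      if (is.na(p)) next
      Ai[i, p] <- Ai[i, p] - al / 2
      Ai[p, i] <- Ai[p, i] - al / 2
    }
    if (!is.na(si) && !is.na(di)) {
      Ai[si, si] <- Ai[si, si] + al / 4
      Ai[di, di] <- Ai[di, di] + al / 4
      Ai[si, di] <- Ai[si, di] + al / 4
      Ai[di, si] <- Ai[di, si] + al / 4
    } else if (!is.na(si)) {
      Ai[si, si] <- Ai[si, si] + al / 4
    } else if (!is.na(di)) {
      Ai[di, di] <- Ai[di, di] + al / 4
    }
  }
  Ai
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = (M - 2P)(M - 2P)' / (2 * sum p_k (1 - p_k))`, with `M` the dosage
#' matrix and `P` the per-marker allele frequencies. Frequencies default to
#' those observed in the genotyped set.
#'
#' @param g complete dosage matrix (individuals x markers), no missing values.
#' @param allele_freq optional per-marker frequencies of the counted allele;
#'   defaults to observed `colMeans(g) / 2`.
#' @return symmetric genomic relationship matrix with id dimnames.
#' @export
genomic_relationship <- function(g, allele_freq = NULL) {
  if (anyNA(g)) stop("genotypes contain missing values: impute before computing G")
  p <- if (is.null(allele_freq)) colMeans(g) / 2 else allele_freq
  if (length(p) != ncol(g)) stop("one allele frequency per marker required")
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic marker (allele frequency 0 or 1): remove in QC first")
  }
  Z <- sweep(g, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(g), rownames(g))
  G
}

mean_offdiag <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  (sum(m) - sum(diag(m))) / (n * (n - 1))
}

#' Scale and blend G toward pedigree compatibility
#'
#' First rescales G with the two-parameter fit `G_scaled = a + b G` chosen so
#' that the mean diagonal and mean off-diagonal of `G_scaled` equal those of
#' `A22` (the pedigree relationships among genotyped individuals); then blends
#' `G* = (1 - tau) G_scaled + tau A22` so the result is invertible and carries
#' a polygenic weight `tau`.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship matrix restricted to the same individuals
#'   in the same order.
#' @param tau polygenic blending weight in (0, 1); default 0.05.
#' @return the blended matrix `G*`.
#' @export
scale_blend_G <- function(G, A22, tau = 0.05) {
  if (!(tau > 0 && tau < 1)) stop("'tau' must be in (0, 1)")
  if (!all(dim(G) == dim(A22))) stop("G and A22 must have identical dimensions")
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22))) {
    stop("G and A22 must be indexed by the same individuals in the same order")
  }
  md_G <- mean(diag(G)); mo_G <- mean_offdiag(G)
  md_A <- mean(diag(A22)); mo_A <- mean_offdiag(A22)
  if (nrow(G) >= 2L) {
    if (abs(md_G - mo_G) < 1e-12) stop("degenerate G: diagonal and off-diagonal means coincide")
    b <- (md_A - mo_A) / (md_G - mo_G)
    a <- md_A - b * md_G
    Gs <- a + b * G
  } else {
    Gs <- G + (md_A - md_G)
  }
  Gstar <- (1 - tau) * Gs + tau * A22
  ok <- tryCatch({ chol(Gstar); TRUE }, error = function(e) FALSE)
  if (!ok) stop("G* is singular after blending; increase tau or check inputs")
  dimnames(Gstar) <- dimnames(A22)
  Gstar
}

#' Single-step augmented relationship matrix H and its inverse
#'
#' Standard single-step construction:
#' `H^-1 = A^-1 + [[0, 0], [0, G*^-1 - A22^-1]]` on the genotyped block.
#' With `method = "direct"` the equivalent joint-distribution form is used:
#' `H11 = A11 + A12 A22^-1 (G* - A22) A22^-1 A21`,
#' `H12 = A12 A22^-1 G*`, `H22 = G*`.
#'
#' @param A numerator relationship matrix over all individuals.
#' @param Gstar blended genomic matrix over the genotyped individuals (ids in
#'   its dimnames, a subset of A's).
#' @param genotyped_ids ids of the genotyped individuals (default: rownames
#'   of `Gstar`).
#' @param method `"inverse"` (build H^-1, invert for H) or `"direct"`.
#' @return list with elements `H` and `Hinv`, both over A's id order.
#' @export
h_matrix <- function(A, Gstar, genotyped_ids = rownames(Gstar),
                     method = c("inverse", "direct")) {
  method <- match.arg(method)
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry individual ids as dimnames")
  if (length(genotyped_ids) == 0) {
    return(list(H = A, Hinv = solve(A)))
  }
  if (!all(genotyped_ids %in% ids)) stop("genotyped ids must be a subset of A's ids")
  gi <- match(genotyped_ids, ids)
  A22 <- A[gi, gi, drop = FALSE]
  A22inv <- tryCatch(solve(A22), error = function(e) stop("A22 is singular"))
  Gstar <- Gstar[genotyped_ids, genotyped_ids, drop = FALSE]
  if (method == "inverse") {
    Ainv <- solve(A)
    Hinv <- Ainv
    Hinv[gi, gi] <- Hinv[gi, gi] + solve(Gstar) - A22inv
    H <- solve(Hinv)
    dimnames(H) <- dimnames(Hinv) <- dimnames(A)
    list(H = H, Hinv = Hinv)
  } else {
    ni <- setdiff(seq_along(ids), gi)
    H <- A
    A12 <- A[ni, gi, drop = FALSE]
    B <- A12 %*% A22inv                     # regression of ungenotyped on genotyped
    D <- Gstar - A22
    H[ni, ni] <- A[ni, ni] + B %*% D %*% t(B)
    H[ni, gi] <- B %*% Gstar
    H[gi, ni] <- t(H[ni, gi])
    H[gi, gi] <- Gstar
    dimnames(H) <- dimnames(A)
    list(H = H, Hinv = solve(H))
  }
}
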