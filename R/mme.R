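# Henderson mixed-model equations for multi-trait EBV/GEBV with pedigree (A)
# or single-step (H) animal covariance, plus a single-marker GWAS screen.

#' Build Henderson mixed-model equations
#'
#' Assembles the coefficient matrix and right-hand side for the multi-trait
#' animal model `y = X tau + Z_n u_n + Z_g u_g + e` with trait-by-cohort cell
#' means as fixed effects, trait-by-family random effects with covariance
#' `G_n (x) I`, trait-by-animal effects with covariance `G_p (x) K`, and
#' residual covariance `R` across an individual's observed traits (records of
#' different individuals are independent). The equations are weighted by
#' `R^-1`, so the inverse coefficient matrix is the prediction error
#' (co)variance directly.
#'
#' @param records data.frame of phenotype records: `id`, `trait`, `value`,
#'   `cohort`, `family`.
#' @param tm [trait_model()] supplying `G_p`, `G_n`, `R` (variance
#'   components are inputs, not estimated).
#' @param K_inv inverse animal relationship matrix (A or H inverse) with id
#'   dimnames covering every recorded individual; `NULL` drops the animal
#'   effect (degenerate fixed-effects-only system).
#' @param random_family include the family random effect (default TRUE).
#' @return an object of class `mme_system`.
#' @export
build_mme <- function(records, tm, K_inv, random_family = TRUE) {
  stopifnot(inherits(tm, "trait_model"))
  need <- c("id", "trait", "value", "cohort")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  if (random_family && !"family" %in% names(records)) {
    stop("records need a 'family' column for the family random effect")
  }
  bad <- setdiff(unique(records$trait), tm$traits)
  if (length(bad)) stop("records contain traits absent from the trait model: ",
                        paste(bad, collapse = ", "))
  if (!is_psd(tm$G_p) || !is_psd(tm$G_n) || !is_psd(tm$R)) {
    stop("trait model covariance matrices must be PSD")
  }
  traits <- tm$traits
  nt <- length(traits)
  has_animal <- !is.null(K_inv)
  if (has_animal) {
    ids <- rownames(K_inv)
    if (is.null(ids)) stop("K_inv must carry individual ids as dimnames")
    absent <- setdiff(unique(records$id), ids)
    if (length(absent)) {
      stop("phenotyped individuals absent from the relationship matrix: ",
           paste(utils::head(absent, 5), collapse = ", "))
    }
  } else {
    ids <- character(0)
  }
  n_ind <- length(ids)
  nrec <- nrow(records)
  ti <- match(records$trait, traits)

  # fixed: trait-by-cohort cell means
  cell <- interaction(records$trait, records$cohort, drop = TRUE, sep = ":")
  fixed_levels <- levels(cell)
  X <- Matrix::sparseMatrix(i = seq_len(nrec), j = as.integer(cell),
                            x = 1, dims = c(nrec, length(fixed_levels)))

  blocks <- list(X)
  fam_levels <- character(0)
  if (random_family) {
    fam <- factor(records$family)
    fam_levels <- levels(fam)
    nf <- length(fam_levels)
    Zn <- Matrix::sparseMatrix(i = seq_len(nrec),
                               j = (ti - 1L) * nf + as.integer(fam),
                               x = 1, dims = c(nrec, nt * nf))
    blocks <- c(blocks, list(Zn))
  }
  if (has_animal) {
    Za <- Matrix::sparseMatrix(i = seq_len(nrec),
                               j = (ti - 1L) * n_ind + match(records$id, ids),
                               x = 1, dims = c(nrec, nt * n_ind))
    blocks <- c(blocks, list(Za))
  }
  W <- do.call(cbind, blocks)

  # R^-1, block per individual over its observed traits
  grp <- split(seq_len(nrec), records$id)
  trip_i <- vector("list", length(grp))
  trip_j <- vector("list", length(grp))
  trip_x <- vector("list", length(grp))
  cache <- new.env(parent = emptyenv())
  for (k in seq_along(grp)) {
    rows <- grp[[k]]
    tt <- ti[rows]
    if (anyDuplicated(tt)) {
      stop("an individual has multiple records for one trait; one record per trait per individual is supported")
    }
    key <- paste(sort(tt), collapse = ",")
    Rinv_blk <- get0(key, envir = cache)
    if (is.null(Rinv_blk)) {
      Rinv_blk <- solve(tm$R[tt, tt, drop = FALSE][order(tt), order(tt), drop = FALSE])
      assign(key, Rinv_blk, envir = cache)
    }
    o <- order(tt)
    rows_o <- rows[o]
    nb <- length(rows_o)
    trip_i[[k]] <- rep(rows_o, each = nb)
    trip_j[[k]] <- rep(rows_o, times = nb)
    trip_x[[k]] <- as.vector(Rinv_blk)
  }
  Rinv <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_x), dims = c(nrec, nrec))

  y <- records$value
  WtRi <- Matrix::t(W) %*% Rinv
  C <- as.matrix(WtRi %*% W)
  rhs <- as.numeric(WtRi %*% y)

  # add random-effect precisions
  off <- length(fixed_levels)
  if (random_family) {
    nf <- length(fam_levels)
    Gn_inv <- solve(tm$G_n)
    C[off + seq_len(nt * nf), off + seq_len(nt * nf)] <-
      C[off + seq_len(nt * nf), off + seq_len(nt * nf)] +
      kronecker(Gn_inv, diag(nf))
    off <- off + nt * nf
  }
  if (has_animal) {
    Gp_inv <- solve(tm$G_p)
    idx <- off + seq_len(nt * n_ind)
    C[idx, idx] <- C[idx, idx] + kronecker(Gp_inv, as.matrix(K_inv))
  }
  C <- (C + t(C)) / 2

  structure(list(
    C = C, rhs = rhs, y = y,
    n_fixed = length(fixed_levels), fixed_levels = fixed_levels,
    fam_levels = fam_levels, random_family = random_family,
    ids = ids, traits = traits, has_animal = has_animal
  ), class = "mme_system")
}

#' Solve mixed-model equations
#'
#' @param sys an `mme_system` from [build_mme()].
#' @param method `"direct"` (Cholesky) or `"cg"` (Jacobi-preconditioned
#'   conjugate gradients).
#' @param tol relative residual tolerance for the solution.
#' @return list with `tau` (named fixed-effect estimates), `u_family`
#'   (family x trait matrix or NULL), `u_animal` (individual x trait matrix
#'   or NULL), `solution` (full vector), and `relative_residual`.
#' @export
solve_mme <- function(sys, method = c("direct", "cg"), tol = 1e-10) {
  method <- match.arg(method)
  C <- sys$C
  b <- sys$rhs
  if (method == "direct") {
    U <- tryCatch(chol(C), error = function(e) {
      stop("coefficient matrix is not positive definite (confounded fixed effects or invalid variance components)")
    })
    x <- backsolve(U, backsolve(U, b, transpose = TRUE))
  } else {
    x <- numeric(length(b))
    pre <- 1 / diag(C)
    r <- b
    z <- pre * r
    p <- z
    rz <- sum(r * z)
    bnorm <- sqrt(sum(b^2))
    for (it in seq_len(10L * length(b))) {
      Cp <- as.numeric(C %*% p)
      alpha <- rz / sum(p * Cp)
      x <- x + alpha * p
      r <- r - alpha * Cp
      if (sqrt(sum(r^2)) <= tol * bnorm) break
      z <- pre * r
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
  }
  rel <- sqrt(sum((as.numeric(C %*% x) - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
  nt <- length(sys$traits)
  off <- sys$n_fixed
  tau <- stats::setNames(x[seq_len(off)], sys$fixed_levels)
  u_family <- NULL
  if (sys$random_family) {
    nf <- length(sys$fam_levels)
    u_family <- matrix(x[off + seq_len(nt * nf)], nf, nt,
                       dimnames = list(sys$fam_levels, sys$traits))
    off <- off + nt * nf
  }
  u_animal <- NULL
  if (sys$has_animal) {
    n <- length(sys$ids)
    u_animal <- matrix(x[off + seq_len(nt * n)], n, nt,
                       dimnames = list(sys$ids, sys$traits))
  }
  list(tau = tau, u_family = u_family, u_animal = u_animal,
       solution = x, relative_residual = rel)
}

#' Prediction error variances of breeding values
#'
#' Standard errors are the square roots of the animal-block diagonal of the
#' inverse coefficient matrix. Because [build_mme()] assembles `R^-1`-weighted
#' equations, those diagonals are prediction error variances in trait units:
#' an individual carrying no information has `SE^2` equal to its prior
#' additive variance.
#'
#' @param sys an `mme_system` with an animal effect.
#' @param ids optional subset of individuals.
#' @return data.frame `id`, `trait`, `se`.
#' @export
prediction_error_variance <- function(sys, ids = NULL) {
  if (!sys$has_animal) stop("system has no animal effect")
  Cinv_diag <- tryCatch(diag(chol2inv(chol(sys$C))), error = function(e) {
    stop("coefficient matrix is not positive definite")
  })
  nt <- length(sys$traits)
  n <- length(sys$ids)
  off <- sys$n_fixed + if (sys$random_family) nt * length(sys$fam_levels) else 0L
  pev <- matrix(Cinv_diag[off + seq_len(nt * n)], n, nt,
                dimnames = list(sys$ids, sys$traits))
  keep <- if (is.null(ids)) sys$ids else ids
  data.frame(
    id = rep(keep, nt),
    trait = rep(sys$traits, each = length(keep)),
    se = as.vector(sqrt(pmax(pev[keep, , drop = FALSE], 0))),
    stringsAsFactors = FALSE
  )
}

# Map a named evaluation model to its trait set, given the traits available.
model_traits <- function(model_name, available) {
  pick <- switch(model_name,
    AGD = grep("^agd", available, value = TRUE),
    Weight = grep("^weight", available, value = TRUE),
    Maturation = grep("^mat", available, value = TRUE),
    Quality = intersect(c("color", "fat"), available),
    All = available,
    Custom = available,
    stop("unknown model_name: ", model_name)
  )
  if (!length(pick)) stop("no traits available for model ", model_name)
  pick
}

#' Run a pedigree or single-step genomic evaluation
#'
#' Fits the model of [build_mme()] with `K = A` (pedigree EBV) or `K = H`
#' (single-step GEBV) and returns a breeding value table. The two runs are
#' identical apart from the animal covariance, so EBV and GEBV are directly
#' comparable. For `K_kind = "H"` the genomic matrix is VanRaden method 1 on
#' observed allele frequencies, scaled and blended against `A22` with
#' polygenic weight `tau` before augmenting `A`; with zero genotyped
#' individuals the run reduces exactly to the pedigree evaluation.
#'
#' @param phenotypes records data.frame (`id`, `trait`, `value`, `cohort`,
#'   `family`).
#' @param pedigree data.frame `id`, `sire`, `dam` covering all phenotyped
#'   individuals and their ancestors.
#' @param tm full [trait_model()]; subset internally by `model_name`/`traits`.
#' @param K_kind `"A"` or `"H"`.
#' @param genotypes complete dosage matrix of the genotyped individuals
#'   (required for `"H"` unless no individual is genotyped).
#' @param model_name one of `"AGD"`, `"Weight"`, `"Maturation"`,
#'   `"Quality"`, `"All"`, `"Custom"`.
#' @param traits trait subset when `model_name = "Custom"`.
#' @param tau polygenic blending weight for G*.
#' @param year evaluation year recorded in the output.
#' @param compute_se compute prediction error variances (the expensive step).
#' @return data.frame breeding value table: `id`, `trait`, `value`, `se`,
#'   `tag` (`"EBV"`/`"GEBV"`), `year`.
#' @export
run_evaluation <- function(phenotypes, pedigree, tm, K_kind = c("A", "H"),
                           genotypes = NULL, model_name = "All", traits = NULL,
                           tau = 0.05, year = NA_integer_, compute_se = TRUE) {
  K_kind <- match.arg(K_kind)
  use_traits <- if (model_name == "Custom" && !is.null(traits)) {
    model_traits("Custom", intersect(traits, tm$traits))
  } else {
    model_traits(model_name, tm$traits)
  }
  missing_tr <- setdiff(use_traits, unique(phenotypes$trait))
  if (length(missing_tr)) {
    stop("missing trait columns in phenotypes: ", paste(missing_tr, collapse = ", "))
  }
  tms <- subset_traits(tm, use_traits)
  recs <- phenotypes[phenotypes$trait %in% use_traits, , drop = FALSE]

  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, , drop = FALSE]
  A <- numerator_relationship(ped)
  Ainv <- a_inverse(ped, A)

  gids <- if (is.null(genotypes)) character(0) else intersect(rownames(genotypes), ped$id)
  if (K_kind == "H" && length(gids) > 0) {
    g <- genotypes[gids, , drop = FALSE]
    p <- colMeans(g) / 2
    poly <- p > 0 & p < 1
    if (!any(poly)) stop("no polymorphic markers among genotyped individuals")
    G <- genomic_relationship(g[, poly, drop = FALSE])
    A22 <- A[gids, gids, drop = FALSE]
    Gstar <- scale_blend_G(G, A22, tau = tau)
    K_inv <- Ainv
    gi <- match(gids, ped$id)
    K_inv[gi, gi] <- K_inv[gi, gi] + solve(Gstar) - solve(A22)
    tag <- "GEBV"
  } else {
    K_inv <- Ainv
    tag <- if (K_kind == "H") "GEBV" else "EBV"
  }

  sys <- build_mme(recs, tms, K_inv)
  sol <- solve_mme(sys, method = "direct")
  out <- data.frame(
    id = rep(rownames(sol$u_animal), length(use_traits)),
    trait = rep(use_traits, each = nrow(sol$u_animal)),
    value = as.vector(sol$u_animal),
    se = NA_real_,
    tag = tag,
    year = year,
    stringsAsFactors = FALSE
  )
  if (compute_se) {
    se <- prediction_error_variance(sys)
    out$se <- se$se[match(paste(out$id, out$trait), paste(se$id, se$trait))]
  }
  out
}

#' Single-marker GWAS screen
#'
#' Regresses the phenotype on each marker dosage after projecting out the
#' fixed covariates; intended as a screen for large-effect QTL, not a
#' discovery engine (no kinship correction by default — pre-adjust the
#' phenotype by a pedigree BLUP if structure is a concern).
#'
#' @param y named phenotype vector (names = individual ids).
#' @param g complete dosage matrix with rownames covering `names(y)`.
#' @param covariates optional data.frame of fixed covariates (factors or
#'   numeric) for the same individuals; intercept always included.
#' @return data.frame `marker`, `beta`, `se`, `statistic`, `p`, `skipped`,
#'   with the Bonferroni 0.05 threshold in attribute `"bonferroni"`.
#' @export
gwas_scan <- function(y, g, covariates = NULL) {
  if (is.null(names(y))) stop("'y' must be named by individual id")
  if (anyNA(g)) stop("genotypes contain missing values: impute or QC first")
  ids <- names(y)
  g <- g[ids, , drop = FALSE]
  X <- if (is.null(covariates)) {
    matrix(1, length(y), 1)
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, g)
  ss <- colSums(RG^2)
  mono <- ss < 1e-12
  beta <- se <- tstat <- pval <- rep(NA_real_, ncol(g))
  dfree <- length(y) - qrX$rank - 1L
  if (dfree < 1L) stop("not enough observations for the covariate set")
  ok <- !mono
  beta[ok] <- colSums(ry * RG[, ok, drop = FALSE]) / ss[ok]
  rss <- sum(ry^2) - beta[ok]^2 * ss[ok]
  sigma2 <- pmax(rss, 0) / dfree
  se[ok] <- sqrt(sigma2 / ss[ok])
  tstat[ok] <- beta[ok] / se[ok]
  pval[ok] <- 2 * stats::pt(abs(tstat[ok]), dfree, lower.tail = FALSE)
  if (any(mono)) {
    message(sum(mono), " monomorphic marker(s) skipped")
  }
  out <- data.frame(marker = colnames(g), beta = beta, se = se,
                    statistic = tstat, p = pval, skipped = mono,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni") <- 0.05 / sum(ok)
  out
}
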