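# Internal helpers shared across modules.

#' Evaluate code under a local RNG state
#'
#' Saves the caller's RNG state, seeds with `seed`, runs `code`, and restores
#' the previous state on exit, so package functions are reproducible without
#' clobbering the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-seed for a named stage
#'
#' Maps a master seed and a stage label to a reproducible sub-seed (below
#' 2^31), so each stage of a larger run consumes an independent stream.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483399) + 1L
}

# Stop unless x is a single value in [lo, hi] (open/closed per arguments).
check_scalar <- function(x, name, lo = -Inf, hi = Inf, open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name))
  }
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "'%s' must be in %s%s, %s%s (got %g)", name,
      if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]", x
    ))
  }
  invisible(x)
}

# Symmetric positive semi-definite check with a small tolerance.
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1L])))
}

# Dosage matrix from a haplotype set (see haplotype_set()).
#' Genotype dosages from a haplotype set
#'
#' @param haps a haplotype set as returned by [simulate_founders()] or
#'   [make_progeny()].
#' @param ids optional subset of individual ids.
#' @return integer matrix of allele dosages (individuals x markers).
#' @export
dosage <- function(haps, ids = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  g <- haps$h1 + haps$h2
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(g))
    if (length(miss)) stop("no haplotypes for: ", paste(utils::head(miss, 5), collapse = ", "))
    g <- g[ids, , drop = FALSE]
  }
  g
}

# rbind two haplotype sets (same marker set).
bind_haplotypes <- function(a, b) {
  stopifnot(identical(colnames(a$h1), colnames(b$h1)))
  structure(list(
    h1 = rbind(a$h1, b$h1),
    h2 = rbind(a$h2, b$h2)
  ), class = "haplotype_set")
}
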