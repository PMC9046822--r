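# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  v <- get0(key, envir = .fixture_cache)
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .fixture_cache)
  }
  v
}

# three-trait model: marine harvest weight, its freshwater correlate, and a
# marine-only disease trait (no freshwater information source)
fix_trait_model <- function() {
  trait_model(
    c(weight_harvest = 0.44, weight_fresh = 0.44, agd_acquired = 0.36),
    r_g = matrix(c(1, 0.63, 0, 0.63, 1, 0, 0, 0, 1), 3, 3),
    c2 = 0.1,
    env = c("marine", "freshwater", "marine")
  )
}

fix_weights <- function() c(agd_acquired = 0.38, weight_harvest = 0.25)

# small founder population + one progeny generation with known pedigree
fix_pop <- function() {
  memo("pop", function() {
    cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 5e7, n_markers = 800,
                      n_qtl = 80, n_founders = 150, seed = 42)
    map <- simulate_genome(cfg)
    founders <- simulate_founders(map, cfg)
    g_f <- dosage(founders)
    matings <- mate_partial_factorial(sprintf("F%04d", 1:10),
                                      sprintf("F%04d", 101:110), 20, seed = 7)
    prog <- make_progeny(matings, founders, map, n_per_family = 8, seed = 8)
    g_p <- dosage(prog$haplotypes)
    ped <- data.frame(
      id = c(rownames(g_f), prog$pedigree$id),
      sire = c(rep(NA, nrow(g_f)), prog$pedigree$sire),
      dam = c(rep(NA, nrow(g_f)), prog$pedigree$dam),
      stringsAsFactors = FALSE
    )
    list(cfg = cfg, map = map, founders = founders, g_f = g_f,
         matings = matings, prog = prog, g_p = g_p,
         g_all = rbind(g_f, g_p), ped = ped)
  })
}

# small 3-year-class genomic program with both evaluations stored
fix_sim <- function() {
  memo("sim", function() {
    cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 5e7, n_markers = 600,
                      n_qtl = 80, n_founders = 60, families_per_year = 8,
                      pool_per_family = 30, progeny_genotyped_per_year = 80,
                      n_year_classes = 3, seed = 11)
    simulate_breeding_cycle(cfg, fix_trait_model(), scheme = "genomic",
                            evaluate_both = TRUE, index_weights = fix_weights())
  })
}

# independent recursive kinship oracle: a_ij = 2 * phi(i, j)
oracle_A <- function(ped) {
  id <- as.character(ped$id)
  s <- stats::setNames(as.character(ped$sire), id)
  d <- stats::setNames(as.character(ped$dam), id)
  memo_env <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    v <- get0(key, envir = memo_env)
    if (!is.null(v)) return(v)
    oi <- match(i, id); oj <- match(j, id)
    v <- if (i == j) {
      0.5 * (1 + phi(s[[i]], d[[i]]))
    } else if (oi > oj) {
      0.5 * (phi(s[[i]], j) + phi(d[[i]], j))
    } else {
      0.5 * (phi(s[[j]], i) + phi(d[[j]], i))
    }
    assign(key, v, envir = memo_env)
    v
  }
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(id[i], id[j])
  }
  A
}

# random valid pedigree (founders first, parents drawn from earlier rows)
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  id <- sprintf("x%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- seq_len(i - 1L)
    pick <- sample(pool, 2L, replace = FALSE)
    sire[i] <- id[pick[1L]]
    dam[i] <- id[pick[2L]]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}
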