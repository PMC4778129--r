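#' Parsimony-informative sites of an alignment
#'
#' Sites carrying at least two bases that are each present in at least two
#' sequences; singleton-only variation is not informative.
#'
#' @inheritParams polymorphic_sites
#' @return Integer vector of 1-based site positions.
#' @export
informative_sites <- function(aln) {
  m <- if (is.matrix(aln)) aln else .aln_matrix(aln)
  which(apply(m, 2L, function(col) sum(table(col) >= 2L) >= 2L))
}

# minimum homoplasy count needed to explain two sites jointly on one tree:
# e - v + c of the partition intersection graph whose vertices are the
# observed states at each site and whose edges are the observed joint pairs
.pair_incompatibility <- function(a, b) {
  ea <- match(a, unique(a))
  eb <- match(b, unique(b))
  .pair_incompat_codes(ea, max(ea), eb, max(eb))
}

.pair_incompat_codes <- function(ea, ka, eb, kb) {
  joint <- unique((ea - 1L) * kb + eb)       # observed (state_a, state_b) pairs
  e <- length(joint)
  v <- ka + kb
  parent <- seq_len(v)
  root <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in joint) {
    i <- root((p - 1L) %/% kb + 1L)
    j <- root(ka + (p - 1L) %% kb + 1L)
    if (i != j) parent[i] <- j
  }
  cc <- 0L
  for (x in seq_len(v)) if (root(x) == x) cc <- cc + 1L
  e - v + cc
}

#' Pairwise homoplasy index (PHI) test for recombination
#'
#' The statistic is the mean pairwise incompatibility score over pairs of
#' parsimony-informative sites lying within `window` positions of each other
#' on the informative-site subalignment. The incompatibility score of a site
#' pair is the minimum number of homoplasies any tree must invoke to explain
#' both sites (0 for a compatible pair). Under clonal descent, incompatibility
#' does not depend on the distance between sites, so the null distribution is
#' obtained by permuting the order of the informative sites; recombination
#' makes nearby sites more compatible than distant ones and drives the
#' observed statistic below the permutation distribution. The p-value is the
#' plus-one-corrected fraction of permutations with PHI less than or equal to
#' the observed value.
#'
#' @inheritParams polymorphic_sites
#' @param window integer, maximum separation (in informative-site positions)
#'   of a scored pair. When `window` exceeds the number of informative sites
#'   every pair is scored and the statistic is permutation-invariant (p = 1).
#' @param permutations integer, number of site-order permutations.
#' @param seed optional integer seed for the permutation draw.
#' @return List of class `phi_result` with `phi_statistic`, `p_value`,
#'   `n_informative`, `window`, `computable`.
#' @export
phi_test <- function(aln, window = 100L, permutations = 1000L, seed = NULL) {
  m <- if (is.matrix(aln)) aln else .aln_matrix(aln)
  if (nrow(m) < 4L) stop("phi test needs at least 4 sequences")
  inf <- informative_sites(m)
  k <- length(inf)
  out <- structure(list(phi_statistic = NA_real_, p_value = 1,
                        n_informative = k, window = as.integer(window),
                        computable = FALSE), class = "phi_result")
  if (k < 2L) return(out)
  codes <- lapply(seq_len(k), function(j) match(m[, inf[j]], unique(m[, inf[j]])))
  nstates <- vapply(codes, max, integer(1))
  score <- matrix(0, k, k)
  for (i in 1:(k - 1L)) for (j in (i + 1L):k)
    score[i, j] <- score[j, i] <-
      .pair_incompat_codes(codes[[i]], nstates[i], codes[[j]], nstates[j])
  w <- min(as.integer(window), k - 1L)
  band_mean <- function(ord) {
    s <- 0; np <- 0L
    for (d in seq_len(w)) {
      idx <- seq_len(k - d)
      s <- s + sum(score[cbind(ord[idx], ord[idx + d])])
      np <- np + (k - d)
    }
    s / np
  }
  obs <- band_mean(seq_len(k))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  nle <- 0L
  for (r in seq_len(permutations))
    if (band_mean(sample.int(k)) <= obs) nle <- nle + 1L
  out$phi_statistic <- obs
  out$p_value <- (nle + 1) / (permutations + 1)
  out$computable <- TRUE
  out
}

#' Pairwise profile mismatch distribution
#'
#' For every unordered pair of profiles, the number of loci at which the two
#' allele vectors differ. This is the distribution whose variance enters the
#' standardized index of association.
#'
#' @param profiles integer matrix (profiles x loci).
#' @return Integer vector of length `C(n,2)`.
#' @export
pairwise_mismatch_distribution <- function(profiles) {
  profiles <- .as_profile_matrix(profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("need at least 2 profiles")
  d <- matrix(0L, n, n)
  for (k in seq_len(ncol(profiles)))
    d <- d + outer(profiles[, k], profiles[, k], "!=")
  d[upper.tri(d)]
}

#' Standardized index of association (I_A^S)
#'
#' Multilocus linkage-disequilibrium statistic: `V_D` is the (population)
#' variance of the pairwise mismatch distribution, `V_e = sum_j h_j (1-h_j)`
#' its expectation-derived counterpart under linkage equilibrium, with
#' `h_j = n/(n-1) (1 - sum_k p_jk^2)` the unbiased allelic diversity of locus
#' j, and `I_A^S = (V_D/V_e - 1)/(l - 1)`. Near 0 under free recombination,
#' positive under clonality. Significance is assessed by Monte-Carlo
#' resampling: alleles are permuted independently within each locus and the
#' plus-one-corrected fraction of resamples with a statistic at least as
#' large as observed is reported.
#'
#' @param profiles integer matrix (profiles x loci); typically one row per
#'   distinct ST.
#' @param resamples integer, Monte-Carlo resamples (0 skips the p-value).
#' @param seed optional integer seed.
#' @param collapse_to_sts logical; collapse identical rows to unique STs
#'   before computing (default `FALSE`: rows are used as given).
#' @return List of class `ia_result` with `ia_s`, `v_d`, `v_e`, `p_value`,
#'   `n_loci`, `n_profiles`.
#' @export
ia_standardized <- function(profiles, resamples = 1000L, seed = NULL,
                            collapse_to_sts = FALSE) {
  profiles <- .as_profile_matrix(profiles)
  if (collapse_to_sts)
    profiles <- profiles[!duplicated(apply(profiles, 1L, paste, collapse = "_")),
                         , drop = FALSE]
  n <- nrow(profiles); l <- ncol(profiles)
  if (n < 3L) stop("need at least 3 profiles")
  if (l < 2L) stop("need at least 2 loci")
  h <- vapply(seq_len(l), function(j) {
    p <- as.numeric(table(profiles[, j])) / n
    n / (n - 1) * (1 - sum(p^2))
  }, numeric(1))
  v_e <- sum(h * (1 - h))
  if (v_e == 0) stop("all loci monomorphic: V_e = 0, I_A^S undefined")
  pop_var <- function(x) mean(x^2) - mean(x)^2
  mism <- pairwise_mismatch_distribution(profiles)
  v_d <- pop_var(mism)
  ia <- (v_d / v_e - 1) / (l - 1)
  p_value <- NA_real_
  if (resamples > 0L) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    nge <- 0L
    for (r in seq_len(resamples)) {
      perm <- profiles
      for (j in seq_len(l)) perm[, j] <- perm[sample.int(n), j]
      ia_r <- (pop_var(pairwise_mismatch_distribution(perm)) / v_e - 1) / (l - 1)
      if (ia_r >= ia) nge <- nge + 1L
    }
    p_value <- (nge + 1) / (resamples + 1)
  }
  structure(list(ia_s = ia, v_d = v_d, v_e = v_e, p_value = p_value,
                 n_loci = l, n_profiles = n), class = "ia_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("PHI test: statistic = %s, p = %.4g (%d informative sites, window %d)%s\n",
              format(x$phi_statistic, digits = 4), x$p_value,
              x$n_informative, x$window,
              if (x$computable) "" else " [not computable: <2 informative sites]"))
  invisible(x)
}

#' @export
print.ia_result <- function(x, ...) {
  cat(sprintf("I_A^S = %.4f (V_D = %.4f, V_e = %.4f, l = %d, n = %d), p = %s\n",
              x$ia_s, x$v_d, x$v_e, x$n_loci, x$n_profiles,
              format(x$p_value, digits = 3)))
  invisible(x)
}
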