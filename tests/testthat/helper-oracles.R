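# Shared fixtures and independent brute-force oracles used across tests.

toy_loci <- function(n = 1, len = 300, names = paste0("L", seq_len(n))) {
  do.call(rbind, lapply(seq_len(n), function(i)
    locus_def(names[i], len, 0, i)))
}

random_coding_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(mlstpg:::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  n_cod <- len %/% 3L
  body <- paste(sample(sense, n_cod, replace = TRUE), collapse = "")
  rest <- len - 3L * n_cod
  tail <- if (rest > 0) paste(sample(c("A","C","G","T"), rest, replace = TRUE),
                              collapse = "") else ""
  paste0(body, tail)
}

# order-preserving deduplication: the allele-numbering oracle
dedup_oracle <- function(seqs) match(seqs, unique(seqs))

# brute-force connected components by BFS over the all-pairs SLV adjacency
components_oracle <- function(registry) {
  n <- nrow(registry)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- sum(registry[i, ] != registry[j, ]) == 1L
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# brute-force all-pairs nucleotide diversity
pi_oracle <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- nrow(m); L <- ncol(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2) / L
}

# from-definition standardized index of association
ia_oracle <- function(prof) {
  n <- nrow(prof); l <- ncol(prof)
  d <- utils::combn(n, 2, function(ij) sum(prof[ij[1], ] != prof[ij[2], ]))
  vd <- mean(d^2) - mean(d)^2
  h <- sapply(seq_len(l), function(j) {
    p <- table(prof[, j]) / n
    n / (n - 1) * (1 - sum(p^2))
  })
  (vd / sum(h * (1 - h)) - 1) / (l - 1)
}

# independent plain-loop Nei-Gojobori: no unique-sequence collapsing,
# direct per-pair counting with the same stop-handling conventions
ng86_oracle <- function(aln) {
  code <- mlstpg:::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      syn <- 0; tot <- 0
      for (b in setdiff(bases, substr(cod, p, p))) {
        mut <- cod; substr(mut, p, p) <- b
        if (code[[mut]] == "*") next
        tot <- tot + 1
        if (code[[mut]] == code[[cod]]) syn <- syn + 1
      }
      if (tot > 0) s <- s + syn / tot
    }
    s
  }
  path_diffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    perms <- if (length(pos) == 1) list(pos)
             else if (length(pos) == 2) list(pos, rev(pos))
             else unlist(lapply(combinat_perms(pos), list), recursive = FALSE)
    res <- list()
    for (ord in perms) {
      cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] == "*") { ok <- FALSE; break }
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res[[length(res) + 1]] <- c(sd, nd)
    }
    Reduce(`+`, res) / length(res)
  }
  aln <- toupper(aln)
  n <- length(aln)
  nc <- nchar(aln[1]) %/% 3
  cods <- lapply(aln, function(s) substring(s, 3 * (0:(nc - 1)) + 1,
                                            3 * (0:(nc - 1)) + 3))
  S <- sapply(cods, function(cs) sum(sapply(cs, syn_sites)))
  sum_dn <- 0; sum_ds <- 0; npair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    Sp <- (S[i] + S[j]) / 2; Np <- 3 * nc - Sp
    sd <- 0; nd <- 0
    for (k in seq_len(nc)) if (cods[[i]][k] != cods[[j]][k]) {
      dd <- path_diffs(cods[[i]][k], cods[[j]][k])
      sd <- sd + dd[1]; nd <- nd + dd[2]
    }
    jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NaN
    sum_ds <- sum_ds + jc(sd / Sp)
    sum_dn <- sum_dn + jc(nd / Np)
    npair <- npair + 1
  }
  list(dn = sum_dn / npair, ds = sum_ds / npair)
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# random-walk profile set: guarantees a non-trivial SLV graph
walk_profiles <- function(n, l = 8, seed = 1) {
  set.seed(seed)
  prof <- matrix(0L, n, l)
  prof[1, ] <- rep(1L, l)
  max_allele <- rep(1L, l)
  for (i in 2:n) {
    base <- prof[sample.int(i - 1, 1), ]
    k <- sample(c(1L, 1L, 2L, 3L), 1)  # mostly SLVs
    for (j in sample.int(l, k)) {
      max_allele[j] <- max_allele[j] + 1L
      base[j] <- max_allele[j]
    }
    prof[i, ] <- base
  }
  prof <- prof[!duplicated(apply(prof, 1, paste, collapse = "_")), , drop = FALSE]
  rownames(prof) <- as.character(seq_len(nrow(prof)))
  colnames(prof) <- paste0("L", seq_len(l))
  prof
}

# clonal single-locus alignment used for PHI calibration experiments
clonal_alignment <- function(seed, mu = 1.2e-2, n = 40, len = 400) {
  cfg <- simulation_config(loci = locus_def("L1", len), n_lineages = 1,
                           ancestor_divergence = 0, n_isolates = n,
                           mu = mu, rho = 0, seed = seed)
  evolve_population(cfg)$sequences[[1]]
}
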