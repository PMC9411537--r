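# independent brute-force oracles: literal, loop-based evaluations of the
# defining formulas, structured nothing like the package's vectorized code

# Weir & Cockerham (1984) two-population estimator, one site at a time;
# genotype vectors of alt dosages, NA allowed
oracle_wc_site <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                            hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

oracle_wc_fst <- function(callsA, callsB) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(callsA))) {
    gA <- callsA[i, ]; gB <- callsB[i, ]
    if (sum(!is.na(gA)) < 2 || sum(!is.na(gB)) < 2) next
    pooled <- c(gA, gB); pooled <- pooled[!is.na(pooled)]
    p <- sum(pooled) / (2 * length(pooled))
    if (p == 0 || p == 1) next
    abc <- oracle_wc_site(gA, gB)
    num <- num + abc["a"]
    den <- den + sum(abc)
  }
  unname(num / den)
}

# derived-allele frequency of a genotype vector given the ancestral state
oracle_derived_freq <- function(g, ancestral) {
  g <- g[!is.na(g)]
  if (length(g) == 0) return(NA_real_)
  alt_freq <- sum(g) / (2 * length(g))
  if (ancestral == "ref") alt_freq
  else if (ancestral == "alt") 1 - alt_freq
  else NA_real_
}

oracle_d_stat <- function(callsA, callsB, callsX, ancestral) {
  abba <- 0; baba <- 0
  for (i in seq_len(nrow(callsA))) {
    pa <- oracle_derived_freq(callsA[i, ], ancestral[i])
    pb <- oracle_derived_freq(callsB[i, ], ancestral[i])
    px <- oracle_derived_freq(callsX[i, ], ancestral[i])
    if (anyNA(c(pa, pb, px))) next
    abba <- abba + (1 - pa) * pb * px
    baba <- baba + pa * (1 - pb) * px
  }
  (abba - baba) / (abba + baba)
}

oracle_f3 <- function(callsX, callsA, callsB, ancestral) {
  vals <- c()
  for (i in seq_len(nrow(callsX))) {
    x <- oracle_derived_freq(callsX[i, ], ancestral[i])
    a <- oracle_derived_freq(callsA[i, ], ancestral[i])
    b <- oracle_derived_freq(callsB[i, ], ancestral[i])
    nhap <- 2 * sum(!is.na(callsX[i, ]))
    if (anyNA(c(x, a, b)) || nhap < 2) next
    vals <- c(vals, (x - a) * (x - b) - x * (1 - x) / (nhap - 1))
  }
  mean(vals)
}

oracle_pi <- function(calls, window_length) {
  tot <- 0
  for (i in seq_len(nrow(calls))) {
    g <- calls[i, ]; g <- g[!is.na(g)]
    n <- 2 * length(g)
    if (n < 2) next
    p <- sum(g) / n
    tot <- tot + 2 * p * (1 - p) * n / (n - 1)
  }
  tot / window_length
}

# zygosity ratio by explicit enumeration of a category's sites
oracle_zygosity <- function(calls, ancestral, in_category) {
  hom <- 0; het <- 0
  for (i in seq_len(nrow(calls))) {
    if (!in_category[i] || ancestral[i] == "unknown") next
    for (j in seq_len(ncol(calls))) {
      g <- calls[i, j]
      if (is.na(g)) next
      d <- if (ancestral[i] == "ref") g else 2 - g
      if (d == 2) hom <- hom + 1
      if (d == 1) het <- het + 1
    }
  }
  hom / (hom + het)
}

# per-donor introduced-LoF counts by explicit set arithmetic
oracle_translocation <- function(calls, ancestral, is_lof, donor_cols,
                                 receiver_cols) {
  derived <- function(g, anc) {
    if (is.na(g)) return(NA_integer_)
    if (anc == "ref") g else 2L - g
  }
  sapply(donor_cols, function(j) {
    cnt <- 0
    for (i in seq_len(nrow(calls))) {
      if (!is_lof[i] || ancestral[i] == "unknown") next
      d <- derived(calls[i, j], ancestral[i])
      if (is.na(d) || d < 1) next
      rec <- sapply(receiver_cols,
                    function(k) derived(calls[i, k], ancestral[i]))
      rec <- rec[!is.na(rec)]
      if (length(rec) > 0 && all(rec == 0)) cnt <- cnt + 1
    }
    cnt
  })
}
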