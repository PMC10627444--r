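# Independent brute-force oracles.  These reimplement the stated
# conventions (linear-interpolation quantiles, lower-bin ties, signs,
# weights, negation, thresholds) from scratch with plain loops, without
# calling any scoring code from the package.

ORACLE_METRICS <- list(
  condition = c("area_to_edge_ratio", "unveg_edge_ratio", "pct_impervious",
                "pct_natural", "pct_agricultural"),
  vulnerability = c("soil_erodibility", "tidal_range_m", "pct_below_mhhw",
                    "pct_below_mtl"),
  adaptive = c("pct_hardened", "shoreline_complexity", "migration_ratio",
               "connectedness")
)
ORACLE_SIGN <- c(
  area_to_edge_ratio = 1, unveg_edge_ratio = -1, pct_impervious = -1,
  pct_natural = 1, pct_agricultural = -1, soil_erodibility = -1,
  tidal_range_m = 1, pct_below_mhhw = -1, pct_below_mtl = -1,
  pct_hardened = -1, shoreline_complexity = 1, migration_ratio = 1,
  connectedness = 1)
ORACLE_WEIGHT <- c(
  area_to_edge_ratio = 1, unveg_edge_ratio = 1, pct_impervious = 1,
  pct_natural = 1, pct_agricultural = 1, soil_erodibility = 1,
  tidal_range_m = 1, pct_below_mhhw = 1, pct_below_mtl = 1,
  pct_hardened = 1.5, shoreline_complexity = 1, migration_ratio = 2,
  connectedness = 1)

# linear-interpolation quantile (type 7) by hand
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_breaks <- function(v) {
  sapply(seq(0.1, 0.9, by = 0.1), function(p) oracle_quantile(v, p))
}

oracle_rank <- function(x, breaks) {
  r <- 1
  for (b in breaks) if (b < x) r <- r + 1
  r
}

# full scoring pipeline, loop-by-loop
oracle_score <- function(metrics) {
  n <- nrow(metrics)
  mets <- unlist(ORACLE_METRICS, use.names = FALSE)
  scores <- matrix(NA_real_, n, length(mets), dimnames = list(NULL, mets))
  for (m in mets) {
    br <- oracle_breaks(metrics[[m]])
    for (i in seq_len(n)) {
      scores[i, m] <- ORACLE_SIGN[[m]] * oracle_rank(metrics[[m]][i], br)
    }
  }
  sums <- list()
  for (cat in names(ORACLE_METRICS)) {
    s <- numeric(n)
    for (m in ORACLE_METRICS[[cat]]) s <- s + ORACLE_WEIGHT[[m]] * scores[, m]
    sums[[cat]] <- s
  }
  cat_score <- list()
  for (cat in names(ORACLE_METRICS)) {
    v <- if (cat == "vulnerability") -sums[[cat]] else sums[[cat]]
    br <- oracle_breaks(v)
    r <- sapply(v, oracle_rank, breaks = br)
    cat_score[[cat]] <- if (cat == "vulnerability") -r else r
  }
  tot <- cat_score$condition + cat_score$vulnerability + cat_score$adaptive
  brt <- oracle_breaks(tot)
  total_score <- sapply(tot, oracle_rank, breaks = brt)
  key <- character(n)
  for (i in seq_len(n)) {
    key[i] <- paste(
      if (cat_score$condition[i] >= 6) "High" else "Low",
      if (cat_score$vulnerability[i] <= -6) "High" else "Low",
      if (cat_score$adaptive[i] >= 6) "High" else "Low", sep = "-")
  }
  list(metric_scores = scores, sums = sums, cat_score = cat_score,
       total_sum = tot, total_score = total_score, key = key)
}

# brute-force core/edge classification over a code matrix
oracle_core_edge <- function(codes, ct, mask, connectivity = 4) {
  nr <- nrow(codes); nc <- ncol(codes)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    do.call(c, lapply(-1:1, function(a) lapply(-1:1, function(b)
      if (a || b) c(a, b))))
  }
  offs <- Filter(Negate(is.null), offs)
  flag <- function(code, f) {
    if (is.na(code)) return(NA)
    ct[[f]][match(code, ct$code)]
  }
  n_core <- n_edge <- n_unveg <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    if (!isTRUE(flag(codes[r, c], "is_marsh"))) next
    edge <- FALSE; unveg <- FALSE
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      code <- codes[rr, cc]
      if (is.na(code)) next
      if (!isTRUE(flag(code, "is_marsh"))) {
        edge <- TRUE
        if (!isTRUE(flag(code, "is_vegetated"))) unveg <- TRUE
      }
    }
    if (edge) { n_edge <- n_edge + 1; if (unveg) n_unveg <- n_unveg + 1 }
    else n_core <- n_core + 1
  }
  list(n_core = n_core, n_edge = n_edge, n_unveg_edge = n_unveg)
}

# union-find connected components of a logical mask
oracle_components <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- seq_len(nr * nc)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  offs <- if (connectivity == 4) list(c(0, 1), c(1, 0)) else
    list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (mask[rr, cc]) union((c - 1) * nr + r, (cc - 1) * nr + rr)
    }
  }
  lab <- matrix(0L, nr, nc)
  roots <- list()
  nxt <- 0L
  for (i in which(mask)) {
    r <- find(i)
    key <- as.character(r)
    if (is.null(roots[[key]])) { nxt <- nxt + 1L; roots[[key]] <- nxt }
    lab[i] <- roots[[key]]
  }
  lab
}
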