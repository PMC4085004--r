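# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders.  Everything here is kept
# deliberately naive and separate from the code under test.

# explicit sums-of-squares ANOVA for balanced 2x2(+batch) layouts
oracle_anova <- function(y, design, include_batch = TRUE) {
  grand <- mean(y)
  ss_margin <- function(f) {
    means <- tapply(y, f, mean)
    cnt <- tapply(y, f, length)
    sum(cnt * (means - grand)^2)
  }
  ss_sex <- ss_margin(design$sex)
  ss_gen <- ss_margin(design$genotype)
  cell <- interaction(design$sex, design$genotype)
  cell_means <- tapply(y, cell, mean)
  cnt <- tapply(y, cell, length)
  sm <- tapply(y, design$sex, mean)
  gm <- tapply(y, design$genotype, mean)
  lev <- do.call(rbind, strsplit(names(cell_means), ".", fixed = TRUE))
  ss_int <- sum(cnt * (cell_means - sm[lev[, 1]] - gm[lev[, 2]] + grand)^2)
  out <- list(sex = ss_sex, genotype = ss_gen, interaction = ss_int)
  n_par <- 4L
  if (include_batch && !is.null(design$batch) &&
      length(unique(design$batch)) > 1) {
    out$batch <- ss_margin(design$batch)
    n_par <- n_par + length(unique(design$batch)) - 1L
  }
  ss_tot <- sum((y - grand)^2)
  out$residual <- ss_tot - sum(unlist(out))
  out$df_res <- length(y) - n_par
  out
}

oracle_anova_p <- function(orc, term, df_term = 1L) {
  mse <- orc$residual / orc$df_res
  if (mse <= 1e-12) return(1)
  f <- (orc[[term]] / df_term) / mse
  stats::pf(f, df_term, orc$df_res, lower.tail = FALSE)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * p[r >= r[i]] / r[r >= r[i]]))
  q
}

# exact hypergeometric upper tail from binomial coefficients
oracle_hyper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# naive O(n^3) agglomerative complete linkage on a distance matrix
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# plain breadth-first search shortest-path lengths on a directed edge list
oracle_bfs <- function(edges, from, to) {
  adj <- split(edges$to, edges$from)
  dist <- stats::setNames(Inf, from)
  frontier <- from; d <- 0
  seen <- character(0)
  while (length(frontier)) {
    if (to %in% frontier) return(d)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    d <- d + 1
  }
  Inf
}

# balanced random 2x2(+batch) toy design
toy_design <- function(n_per_cell = 2, n_batches = 2) {
  cells <- expand.grid(sex = c("male", "female"), genotype = c("WT", "KO"),
                       stringsAsFactors = FALSE)
  design <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    data.frame(sex = cells$sex[i], genotype = cells$genotype[i],
               rep = seq_len(n_per_cell), stringsAsFactors = FALSE)))
  design$sample_id <- sprintf("T%02d", seq_len(nrow(design)))
  design$batch <- paste0("chip", ((design$rep - 1) %% n_batches) + 1)
  design[c("sample_id", "sex", "genotype", "batch")]
}

write_toy_profile <- function(path, probes, samples, signal, det,
                              symbols = probes) {
  tab <- data.frame(ProbeID = probes, Symbol = symbols, check.names = FALSE)
  for (j in seq_along(samples)) {
    tab[[paste0(samples[j], ".AVG_Signal")]] <- signal[, j]
    tab[[paste0(samples[j], ".Detection Pval")]] <- det[, j]
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small typed interaction graph used across network tests
toy_graph <- function() {
  sif <- c("TF1\ttf_target\tG1",
           "TF1\tother\tM1",
           "M1\tother\tR1",
           "TF1\tother\tM2",
           "M2\tother\tR1",
           "L1\tligand_receptor\tR1",
           "R1\tother\tG1",
           "TF2\ttf_target\tG2",
           "TF2\tother\tR2",
           "R2\tother\tG2")
  roles <- data.frame(
    node = c("TF1", "TF2", "R1", "R2", "L1"),
    role = c("transcription_factor", "transcription_factor",
             "receptor", "receptor", "ligand"),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".sif")
  writeLines(sif, f)
  read_sif(f, roles = roles)
}
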