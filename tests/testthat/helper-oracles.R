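# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops and exhaustive enumeration only.

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# position-by-position sliding comparison; N in the subject never matches
naive_motif_scan <- function(seq, pattern) {
  seq <- toupper(chartr("U", "T", seq))
  pattern <- toupper(chartr("U", "T", pattern))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(p) > length(s)) return(hits)
  for (i in seq_len(length(s) - length(p) + 1)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (!s[i + j - 1] %in% IUPAC_TABLE[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# all in-frame stop triplets by explicit offset loop
brute_stop_scan <- function(seq, frame) {
  seq <- toupper(seq)
  pos <- integer(0)
  i <- frame
  while (i + 2 <= nchar(seq)) {
    if (substr(seq, i, i + 2) %in% c("TAG", "TAA", "TGA")) pos <- c(pos, i)
    i <- i + 3
  }
  pos
}

# exact two-sided rank-sum p by recursive enumeration of group assignments
wilcox_exact_oracle <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(x); N <- length(r)
  sums <- c()
  rec <- function(start, left, acc) {
    if (left == 0) { sums <<- c(sums, acc); return(invisible()) }
    for (i in start:(N - left + 1)) rec(i + 1, left - 1, acc + r[i])
  }
  rec(1, n, 0)
  w <- sum(r[seq_len(n)])
  p_le <- mean(sums <= w + 1e-9)
  p_ge <- mean(sums >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# hypergeometric upper tail by direct summation of the pmf
hyper_tail_oracle <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one-row event tibble with explicit fields, defaults filled with NA
make_event <- function(event_class, chrom = "chr1", strand = "+",
                       event_id = paste0(event_class, "_t1"),
                       gene_id = "G1", gene_symbol = "G1", ...,
                       inc_trt = c(10L, 10L), skip_trt = c(10L, 10L),
                       inc_ctl = c(10L, 10L), skip_ctl = c(10L, 10L),
                       inc_len = 2, skip_len = 1,
                       pvalue = NA_real_, fdr = NA_real_,
                       delta_psi = NA_real_) {
  ev <- splicedown:::empty_events()
  ev[1, "event_id"] <- event_id
  ev[1, "event_class"] <- event_class
  ev[1, "gene_id"] <- gene_id
  ev[1, "gene_symbol"] <- gene_symbol
  ev[1, "chrom"] <- chrom
  ev[1, "strand"] <- strand
  coords <- list(...)
  for (nm in names(coords)) ev[[nm]][1] <- as.integer(coords[[nm]])
  ev$inc_counts_trt[[1]] <- as.integer(inc_trt)
  ev$skip_counts_trt[[1]] <- as.integer(skip_trt)
  ev$inc_counts_ctl[[1]] <- as.integer(inc_ctl)
  ev$skip_counts_ctl[[1]] <- as.integer(skip_ctl)
  ev$inc_len[1] <- inc_len
  ev$skip_len[1] <- skip_len
  ev$pvalue[1] <- pvalue
  ev$fdr[1] <- fdr
  ev$delta_psi[1] <- delta_psi
  ev
}
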