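test_that("IUPAC motif scanning agrees with a naive sliding comparison", {
  hits <- motif_scan("ATGCATGCATG", "TGCATG")
  expect_equal(hits$start, c(2, 6))
  expect_equal(nrow(motif_scan("AG", "RY")), 0)  # A matches R, G is not Y
  expect_equal(motif_scan("AC", "RY")$start, 1)
  expect_equal(nrow(motif_scan(strrep("N", 40), "TGCATG")), 0)
  set.seed(101)
  pats <- c("TGCATG", "RGAAG", "YYYY", "SSNG", "ACGT")
  for (r in 1:40) {
    s <- random_dna_str(sample(20:400, 1))
    p <- sample(pats, 1)
    expect_equal(motif_scan(s, p)$start, naive_motif_scan(s, p),
                 info = paste(p, s))
  }
})

test_that("region layouts have bounded lengths, unique ordered labels", {
  cfg <- synthetic_config(seed = 13,
                          events_per_class = c(SE = 4, MXE = 2, RI = 3,
                                               A3SS = 3, A5SS = 3),
                          intron_size = c(80, 900))
  b <- simulate_dataset(cfg)
  for (i in seq_len(nrow(b$events))) {
    lay <- build_region_layout(b$events[i, ], b$genome)
    expect_false(any(duplicated(lay$label)))
    expect_true(all(nchar(lay$seq) <= lay$nominal))
    expect_true(all(lay$collapsed %in% c("Upstream", "Exon", "Downstream")))
    # collapsed regions come in transcript order
    ord <- unique(lay$collapsed)
    expect_equal(ord, intersect(c("Upstream", "Exon", "Downstream"), ord))
    # sub-regions tile without double counting inside their parent feature
    expect_true(all(lay$gend >= lay$gstart))
  }
  # RI: the retained intron is the Exon collapsed region
  ri <- b$events[b$events$event_class == "RI", ][1, ]
  lay <- build_region_layout(ri, b$genome)
  intron_len <- ri$downstream_start - ri$upstream_end
  expect_equal(sum(nchar(lay$seq[lay$collapsed == "Exon"])),
               min(500, intron_len))
})

test_that("a 40-nt exon truncates exonic sub-regions without double counting", {
  g <- c(ctg = random_dna_str(3000))
  ev <- make_event("SE", chrom = "ctg",
                   upstream_start = 100, upstream_end = 400,
                   exon_start = 1400, exon_end = 1440,
                   downstream_start = 2440, downstream_end = 2740)
  lay <- build_region_layout(ev, g)
  exonic <- lay[lay$collapsed == "Exon", ]
  expect_equal(sum(nchar(exonic$seq)), 40)
  full <- build_region_layout(
    make_event("SE", chrom = "ctg", upstream_start = 100, upstream_end = 400,
               exon_start = 1400, exon_end = 1700,
               downstream_start = 2700, downstream_end = 2999), g)
  expect_true(all(nchar(full$seq) == full$nominal))
})

test_that("minus-strand layouts mirror plus-strand layouts", {
  set.seed(111)
  s <- random_dna_str(3000)
  g <- c(ctg = s)
  coords <- list(upstream_start = 100, upstream_end = 400,
                 exon_start = 1400, exon_end = 1700,
                 downstream_start = 2400, downstream_end = 2700)
  plus <- do.call(make_event, c(list("SE", chrom = "ctg", strand = "+"), coords))
  minus <- do.call(make_event, c(list("SE", chrom = "ctg", strand = "-"), coords))
  lp <- build_region_layout(plus, g)
  lm <- build_region_layout(minus, g)
  # the minus-strand R1 (transcript upstream) is the reverse complement of
  # the plus-strand last region's genomic slice counterpart
  expect_equal(lm$collapsed, lp$collapsed)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(lm$seq[1], rc(lp$seq[length(lp$seq)]))
  expect_equal(lm$seq[length(lm$seq)], rc(lp$seq[1]))
})

test_that("window densities follow the coverage-fraction definition", {
  # a single 6-nt occurrence inside a 50-nt window gives 6/50
  g <- c(ctg = paste0(strrep("A", 1000), strrep("A", 300)))
  ev <- make_event("SE", chrom = "ctg",
                   upstream_start = 0, upstream_end = 100,
                   exon_start = 400, exon_end = 450,
                   downstream_start = 800, downstream_end = 900,
                   delta_psi = 0.5)
  # plant one TGCATG in the middle of the target exon; background events sit
  # on a motif-free contig
  gg <- c(g, ctg_bg = strrep("A", 1300))
  substr(gg["ctg"], 420, 425) <- "TGCATG"
  ev$group <- "up"
  bg <- ev; bg$event_id <- "bg1"; bg$group <- "background"; bg$chrom <- "ctg_bg"
  bg2 <- bg; bg2$event_id <- "bg2"
  bg3 <- bg; bg3$event_id <- "bg3"
  evs <- dplyr::bind_rows(ev, bg, bg2, bg3)
  pr <- density_profile(evs, gg, "RBFOX1", "TGCATG")
  pf <- pr$profile
  expect_true(all(pf$density_up >= 0 & pf$density_up <= 1, na.rm = TRUE))
  # the exon sub-region R4 covers the planted occurrence entirely
  exon_first <- pf[pf$label == "R4", ]
  expect_equal(max(exon_first$density_up, na.rm = TRUE), 6 / 50)
  # motif-free background is all-zero
  expect_true(all(pf$density_bg == 0 | is.nan(pf$density_bg), na.rm = TRUE))
})

test_that("mean window density matches the i.i.d. closed-form expectation", {
  # expected coverage fraction ~ match_rate * motif_len (non-overlap regime)
  set.seed(121)
  n_ev <- 400
  pat <- "TGCA"
  rate <- (1 / 4)^4
  dens <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    cov <- splicedown:::coverage_in_window(random_dna_str(50), 50, "left", pat)
    dens[i] <- mean(cov)
  }
  expected <- rate * 4
  se <- sd(dens) / sqrt(n_ev)
  expect_lt(abs(mean(dens) - expected), 3 * se + 1e-4)
})

test_that("rank-sum test: exact example, degeneracy, and oracle equivalence", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), 1)
  set.seed(131)
  for (r in 1:60) {
    n <- sample(1:8, 1); m <- sample(2:8, 1)
    # draws with heavy ties to exercise midranks
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, m, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    expect_equal(wilcoxon_rank_sum(x, y), wilcox_exact_oracle(x, y),
                 tolerance = 1e-12, info = paste(n, m))
  }
  # large-sample approximation close to exact at n = m = 8
  set.seed(141)
  diffs <- replicate(100, {
    x <- rnorm(8); y <- rnorm(8)
    abs(wilcoxon_rank_sum(x, y, exact_max = 8) -
          wilcoxon_rank_sum(x, y, exact_max = 1))
  })
  expect_lt(max(diffs), 0.011)
})

test_that("enrichment summary flags planted regions and respects alpha", {
  set.seed(151)
  cfg <- synthetic_config(
    seed = 99, events_per_class = c(SE = 90),
    frac_regulated = 1 / 3, dpsi_sign = -1,
    exon_size = c(60, 120), intron_size = c(320, 420),
    plant_motif = list(rbp = "PTBP1", event_class = "SE", direction = "down",
                       region = "Upstream", rate_multiplier = 8))
  b <- simulate_dataset(cfg)
  ev <- b$events
  ev$group <- ifelse(b$truth$events$regulated[
    match(ev$event_id, b$truth$events$event_id)], "down", "background")
  pr <- density_profile(ev, b$genome, "PTBP1", "TCTT")
  summ <- summarize_enrichment(pr, alpha = 0.05)
  expect_true(any(summ$direction == "down" & summ$region == "Upstream"))
  expect_equal(nrow(summarize_enrichment(pr, alpha = 0)), 0)
})

test_that("coherence filter keeps only occurrences matching the summary", {
  g <- c(ctg = random_dna_str(3000))
  ev <- make_event("SE", chrom = "ctg", delta_psi = -0.4,
                   upstream_start = 100, upstream_end = 400,
                   exon_start = 1400, exon_end = 1700,
                   downstream_start = 2400, downstream_end = 2700)
  gg <- g
  substr(gg["ctg"], 360, 365) <- "TGCATG"  # upstream exonic flank
  motifs <- tibble::tibble(rbp = "RBFOX1", patterns = list("TGCATG"))
  summary_yes <- tibble::tibble(rbp = "RBFOX1", event_class = "SE",
                                direction = "down", region = "Upstream",
                                min_p = 0.01, n_sig_windows = 3L)
  out <- coherent_occurrences(ev, gg, motifs, summary_yes)
  expect_equal(nrow(out), 1)
  expect_equal(out$region, "Upstream")
  expect_equal(out$n_occurrences, 1)
  # absent tuple -> dropped
  summary_no <- summary_yes
  summary_no$direction <- "up"
  expect_equal(nrow(coherent_occurrences(ev, gg, motifs, summary_no)), 0)
  # delta PSI exactly 0 excluded
  ev0 <- ev; ev0$delta_psi <- 0
  expect_message(out0 <- coherent_occurrences(ev0, gg, motifs, summary_yes),
                 "exactly 0")
  expect_equal(nrow(out0), 0)
})
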