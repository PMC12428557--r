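test_that("compute_psi matches the length-normalised formula and edge cases", {
  expect_equal(compute_psi(18, 2, 2, 1), 9 / (9 + 2))
  expect_equal(compute_psi(5, 0, 2, 1), 1)
  expect_equal(compute_psi(0, 7, 2, 1), 0)
  expect_true(is.na(compute_psi(0, 0, 2, 1)))
  # monotone in I, antitone in S, invariant to joint scaling
  set.seed(11)
  for (r in 1:50) {
    i <- sample(1:100, 1); s <- sample(1:100, 1)
    li <- runif(1, 0.5, 3); ls <- runif(1, 0.5, 3)
    p <- compute_psi(i, s, li, ls)
    expect_gt(compute_psi(i + 5, s, li, ls), p)
    expect_lt(compute_psi(i, s + 5, li, ls), p)
    expect_equal(compute_psi(3 * i, 3 * s, li, ls), p)
  }
})

test_that("mean coverage averages inclusion+skipping over all replicates", {
  ev <- make_event("SE", inc_trt = c(10L, 2L), skip_trt = c(0L, 2L),
                   inc_ctl = c(3L, 0L), skip_ctl = c(3L, 0L))
  expect_equal(mean_event_coverage(ev), 5)
  ev0 <- make_event("SE", inc_trt = c(0L, 0L), skip_trt = c(0L, 0L),
                    inc_ctl = c(0L, 0L), skip_ctl = c(0L, 0L))
  expect_equal(mean_event_coverage(ev0), 0)
})

test_that("DASE filter applies FDR, |dPSI| and strict coverage thresholds", {
  evs <- dplyr::bind_rows(
    make_event("SE", event_id = "keep", fdr = 0.0043, delta_psi = 0.357,
               inc_trt = c(30L, 30L), skip_trt = c(20L, 20L),
               inc_ctl = c(25L, 25L), skip_ctl = c(25L, 25L)),
    make_event("SE", event_id = "low_dpsi", fdr = 0.04, delta_psi = 0.09),
    make_event("SE", event_id = "high_fdr", fdr = 0.06, delta_psi = 0.5),
    make_event("SE", event_id = "cov5", fdr = 0.01, delta_psi = 0.5,
               inc_trt = c(3L, 2L), skip_trt = c(0L, 0L),
               inc_ctl = c(10L, 5L), skip_ctl = c(0L, 0L)))
  out <- filter_dases(evs)
  expect_equal(out$event_id, "keep")
  # coverage exactly 5 is rejected (strict >)
  expect_equal(mean_event_coverage(evs[4, ]), 5)
  # subset + idempotence
  expect_true(all(out$event_id %in% evs$event_id))
  expect_equal(filter_dases(out)$event_id, out$event_id)
  # missing FDR rejected with a warning
  evna <- make_event("SE", event_id = "nofdr", delta_psi = 0.4)
  expect_warning(res <- filter_dases(dplyr::bind_rows(evs, evna)),
                 "missing FDR")
  expect_false("nofdr" %in% res$event_id)
})

test_that("target regions follow the class-specific extraction rules", {
  ri <- make_event("RI", upstream_start = 50, upstream_end = 100,
                   downstream_start = 200, downstream_end = 260,
                   exon_start = 50, exon_end = 260)
  r <- dase_region(ri)
  expect_equal(c(r$start, r$end), c(100, 200))

  a3 <- make_event("A3SS", exon_start = 100, exon_end = 300,
                   exon2_start = 250, exon2_end = 300,
                   flanking_start = 10, flanking_end = 60)
  r <- dase_region(a3)
  expect_equal(c(r$start, r$end), c(100, 250))

  a5 <- make_event("A5SS", exon_start = 100, exon_end = 300,
                   exon2_start = 100, exon2_end = 180,
                   flanking_start = 400, flanking_end = 460)
  r <- dase_region(a5)
  expect_equal(c(r$start, r$end), c(180, 300))

  mxe_minus <- make_event("MXE", strand = "-", exon_start = 10, exon_end = 20,
                          exon2_start = 50, exon2_end = 60,
                          upstream_start = 0, upstream_end = 5,
                          downstream_start = 70, downstream_end = 80)
  r <- dase_region(mxe_minus)
  expect_equal(c(r$start, r$end), c(50, 60))
  mxe_plus <- mxe_minus
  mxe_plus$strand <- "+"
  r <- dase_region(mxe_plus)
  expect_equal(c(r$start, r$end), c(10, 20))

  se <- make_event("SE", exon_start = 30, exon_end = 70)
  expect_equal(dase_region(se)$end - dase_region(se)$start, 40)

  bad <- make_event("A3SS", exon_start = 100, exon_end = 300,
                    exon2_start = 150, exon2_end = 250,
                    flanking_start = 10, flanking_end = 60)
  expect_error(dase_region(bad), "flush")
})

test_that("region length equals brute-force interval subtraction for A3SS/A5SS", {
  set.seed(21)
  for (r in 1:40) {
    ls <- sample(0:100, 1); le <- ls + sample(60:300, 1)
    flush_left <- runif(1) < 0.5
    short_len <- sample(10:(le - ls - 10), 1)
    if (flush_left) { ss <- ls; se <- ls + short_len }
    else { se <- le; ss <- le - short_len }
    ev <- make_event(sample(c("A3SS", "A5SS"), 1),
                     exon_start = ls, exon_end = le,
                     exon2_start = ss, exon2_end = se,
                     flanking_start = le + 500, flanking_end = le + 560)
    reg <- dase_region(ev)
    covered <- setdiff(seq(ls, le - 1), seq(ss, se - 1))
    expect_equal(reg$end - reg$start, length(covered))
    expect_equal(seq(reg$start, reg$end - 1), covered)
  }
})

test_that("sequence extraction is strand aware and bounds checked", {
  g <- c(chrA = "ACGTACGT")
  fwd <- extract_region_seq(g, tibble::tibble(chrom = "chrA", start = 2,
                                              end = 5, strand = "+"))
  expect_equal(fwd, "GTA")
  rev <- extract_region_seq(g, tibble::tibble(chrom = "chrA", start = 2,
                                              end = 5, strand = "-"))
  expect_equal(rev, "TAC")
  expect_error(extract_region_seq(g, tibble::tibble(chrom = "chrA", start = 6,
                                                    end = 12, strand = "+")),
               "out of bounds")
  expect_error(extract_region_seq(g, tibble::tibble(chrom = "nope", start = 0,
                                                    end = 2, strand = "+")),
               "not in genome")
  # double reverse complement is identity
  set.seed(5)
  s <- random_dna_str(200)
  g2 <- c(c1 = s)
  reg <- tibble::tibble(chrom = "c1", start = 20, end = 120, strand = "-")
  rc <- extract_region_seq(g2, reg)
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rc)))
  expect_equal(rc2, substr(s, 21, 120))
})

test_that("rMATS tables round-trip through the reader", {
  cfg <- synthetic_config(seed = 42,
                          events_per_class = c(SE = 3, MXE = 2, RI = 2,
                                               A3SS = 2, A5SS = 2),
                          intron_size = c(80, 400))
  dir <- withr::local_tempdir()
  b <- simulate_dataset(cfg, out_dir = dir)
  ev <- read_rmats_dir(dir)
  expect_equal(nrow(ev), nrow(b$events))
  expect_equal(sort(ev$event_id), sort(b$events$event_id))
  m <- match(b$events$event_id, ev$event_id)
  expect_equal(ev$inc_counts_trt[m], b$events$inc_counts_trt)
  expect_equal(ev$exon_start[m], b$events$exon_start)
  expect_equal(ev$strand[m], b$events$strand)
  # malformed input errors name the offending column
  tab <- readLines(file.path(dir, "SE.MATS.JC.txt"))
  tab[2] <- sub("^(\\S+\t\\S+\t\\S+\t\\S+\t\\S+\t)\\d+", "\\1-5", tab[2])
  bad <- file.path(dir, "SE_bad.txt")
  writeLines(tab, bad)
  expect_error(read_rmats_events(bad, "SE"), "negative coordinate")
  expect_error(read_rmats_events(file.path(dir, "SE.MATS.JC.txt"), "XX"),
               "unknown event class")
})

test_that("count-based DASE calling: null, extreme and BH behaviour", {
  same <- make_event("SE", inc_trt = c(12L, 8L), skip_trt = c(6L, 4L),
                     inc_ctl = c(12L, 8L), skip_ctl = c(6L, 4L),
                     inc_len = 1, skip_len = 1)
  out <- call_dases(same)
  expect_equal(out$delta_psi, 0)
  expect_equal(out$pvalue, 1)

  extreme <- make_event("SE", inc_trt = c(0L), skip_trt = c(100L),
                        inc_ctl = c(100L), skip_ctl = c(0L),
                        inc_len = 1, skip_len = 1)
  out <- call_dases(extreme)
  expect_equal(out$delta_psi, -1)
  expect_lt(out$pvalue, 1e-6)

  # BH over (0.01, 0.02, 0.03) -> all 0.03, computed by the joint adjust
  three <- dplyr::bind_rows(lapply(1:3, function(i)
    make_event("SE", event_id = paste0("e", i))))
  called <- call_dases(three)
  called$pvalue <- c(0.01, 0.02, 0.03)
  fdr <- stats::p.adjust(called$pvalue, "BH")
  expect_equal(fdr, rep(0.03, 3))
  # BH is monotone over sorted p-values
  set.seed(3)
  p <- sort(runif(20))
  expect_true(all(diff(stats::p.adjust(p, "BH")) >= -1e-12))

  zero <- make_event("SE", inc_trt = c(0L, 0L), skip_trt = c(0L, 0L))
  expect_false(call_dases(zero)$testable)
})
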