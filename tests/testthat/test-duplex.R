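test_that("a forced perfect helix reproduces the additive stack energy", {
  m <- default_energy_model()
  h <- duplex_mfe("GGGGGG", "AAACCCCCCAAA", m)
  expect_equal(h$mfe, m$duplex_init + 5 * m$stack["GC", "GC"])
  expect_equal(nrow(h$pairing), 6)
  expect_true(all(h$pairing$type == "GC"))
  expect_true(all(h$pairing_map == "WC"))
  # nothing favourable to pair -> mfe 0, empty pairing
  m0 <- m
  m0$stack["AU", "AU"] <- 0
  m0$stack["UA", "UA"] <- 0
  m0$stack["AU", "UA"] <- 0
  m0$stack["UA", "AU"] <- 0
  h0 <- duplex_mfe("UUUUUU", "AAAAAAAAAA", m0)
  expect_equal(h0$mfe, 0)
  expect_equal(nrow(h0$pairing), 0)
  expect_equal(suppressWarnings(classify_seed(h0$pairing_map)), "Unclassified")
  # target below the minimum length -> no-hit
  expect_equal(duplex_mfe("GGGGGG", "CCCC")$mfe, 0)
})

test_that("reported energies are self-consistent with the pairing map", {
  m <- default_energy_model()
  set.seed(61)
  for (r in 1:40) {
    mi <- random_rna(sample(18:24, 1))
    tg <- random_rna(sample(30:120, 1))
    h <- duplex_mfe(mi, tg, m)
    if (nrow(h$pairing) > 0) {
      expect_equal(duplex_energy(h, m), h$mfe, tolerance = 1e-6)
      # WC-marked positions have complementary partners
      wc <- h$pairing$type %in% c("AU", "UA", "CG", "GC")
      expect_equal(unname(h$pairing_map[h$pairing$mi_pos[wc]]),
                   rep("WC", sum(wc)))
    }
  }
})

test_that("extending the target never worsens the minimum free energy", {
  m <- default_energy_model()
  set.seed(71)
  for (r in 1:20) {
    mi <- random_rna(20)
    tg <- random_rna(60)
    e1 <- duplex_mfe(mi, tg, m)$mfe
    e2 <- duplex_mfe(mi, paste0(tg, random_rna(40)), m)$mfe
    expect_lte(e2, e1 + 1e-9)
  }
})

test_that("duplex DP equals exhaustive enumeration on small instances", {
  m <- default_energy_model()
  set.seed(81)
  for (r in 1:300) {
    mi <- random_rna(sample(4:9, 1))
    tg <- random_rna(sample(8:9, 1))
    dp <- duplex_mfe(mi, tg, m)$mfe
    oracle <- splicedown:::.duplex_enum(splicedown:::rna_codes(mi),
                                        splicedown:::rna_codes(tg),
                                        unclass(m))
    expect_equal(dp, oracle, tolerance = 1e-9)
  }
})

test_that("duplex energy is symmetric in the two strands", {
  # the same physical duplex read from the other strand (roles swapped,
  # chain reversed, every pair letter-swapped) must score identically;
  # this exercises the symmetry of the expanded stack table
  m <- default_energy_model()
  set.seed(91)
  for (r in 1:25) {
    mi <- random_rna(12)
    tg <- random_rna(30)
    e1 <- duplex_mfe(mi, tg, m)$mfe
    e2 <- duplex_mfe(tg, mi, m, min_target_len = 1)$mfe
    expect_equal(e1, e2, tolerance = 1e-9)
  }
})

test_that("seed classification follows the three-class definition", {
  map <- rep("WC", 22)
  expect_equal(classify_seed(map), "Strong")
  map14 <- map; map14[14] <- "unpaired"
  expect_equal(classify_seed(map14), "Canonical")
  map4 <- map; map4[4] <- "wobble"  # wobble counts as non-WC
  expect_equal(classify_seed(map4), "Compensatory")
  both <- map; both[4] <- "unpaired"; both[13] <- "unpaired"
  expect_equal(classify_seed(both), "Unclassified")
  expect_warning(cl <- classify_seed(rep("WC", 12)), "16")
  expect_equal(cl, "Unclassified")
})

test_that("mfe filter boundary is inclusive at -30", {
  hits <- tibble::tibble(mfe = c(-36.9, -30, -29.9, NA))
  out <- filter_by_mfe(hits)
  expect_equal(out$mfe, c(-36.9, -30))
  expect_equal(nrow(filter_by_mfe(hits[0, ])), 0)
})

test_that("A1 annotation inspects the base opposite miRNA position 1", {
  m <- default_energy_model()
  # position 1 is C so it cannot pair an A: the base opposite position 1 is
  # the target base immediately 3' of the partner of position 2
  mi <- paste0("C", strrep("G", 17))
  site <- strrep("C", 17)  # complement of positions 2-18
  h <- duplex_mfe(mi, paste0("UU", site, "A", "UU"), m)
  expect_true(as.logical(annotate_a1(h)))
  expect_false(attr(annotate_a1(h), "edge"))
  # a U there is not an adenosine (and pairs position 1 as a wobble)
  h2 <- duplex_mfe(mi, paste0("UU", site, "U", "UU"), m)
  expect_false(as.logical(annotate_a1(h2)))
  # duplex flush with the target 3' end: edge flag, FALSE
  h3 <- duplex_mfe(mi, paste0("UU", site), m)
  a <- annotate_a1(h3)
  expect_false(as.logical(a))
  expect_true(attr(a, "edge"))
})

test_that("percentile filter uses linear interpolation and inclusive bound", {
  expr <- tibble::tibble(mirna_id = paste0("m", 1:10),
                         expression = seq(10, 100, by = 10))
  kept <- percentile_filter(expr, 85)
  expect_equal(sort(kept), c("m10", "m9"))  # threshold 86.5
  allsame <- tibble::tibble(mirna_id = c("a", "b"), expression = c(5, 5))
  expect_equal(sort(percentile_filter(allsame)), c("a", "b"))
  single <- tibble::tibble(mirna_id = "solo", expression = 3)
  expect_equal(percentile_filter(single), "solo")
  empty <- tibble::tibble(mirna_id = "z", expression = 0)
  expect_warning(out <- percentile_filter(empty), "positive")
  expect_equal(out, character(0))
})

test_that("hybridization cascade keeps planted sites and is monotone", {
  cfg <- synthetic_config(seed = 7,
                          events_per_class = c(SE = 6, MXE = 3, RI = 6,
                                               A3SS = 3, A5SS = 3),
                          intron_size = c(80, 1200), plant_mirna_sites = 2)
  b <- simulate_dataset(cfg)
  dases <- filter_dases(call_dases(b$events))
  hy <- predict_hybridizations(dases, b$genome, b$mirnas, b$expression)
  sc <- attr(hy, "stage_counts")
  expect_true(sc[["pass_mfe"]] <= sc[["scanned"]])
  expect_true(sc[["classified"]] <= sc[["pass_mfe"]])
  expect_true(sc[["expressed"]] <= sc[["classified"]])
  # the planted perfect sites survive the full cascade as Strong
  planted <- b$truth$mirna_sites
  planted <- planted[planted$event_id %in% dases$event_id, ]
  expect_gt(nrow(planted), 0)
  for (i in seq_len(nrow(planted))) {
    row <- hy[hy$event_id == planted$event_id[i] &
                hy$mirna_id == planted$mirna_id[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$seed_class, "Strong")
    expect_lte(row$mfe, -30)
  }
  # removing the planted miRNA from the expression table removes the pair
  # at the expression stage
  expr2 <- b$expression[!b$expression$mirna_id %in% planted$mirna_id, ]
  hy2 <- predict_hybridizations(dases, b$genome, b$mirnas, expr2)
  expect_equal(nrow(hy2[hy2$event_id %in% planted$event_id &
                          hy2$mirna_id %in% planted$mirna_id, ]), 0)
})
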