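IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

random_dna <- function(n, base_probs) {
  paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs),
        collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# expected per-nucleotide match rate of an IUPAC pattern under iid bases
pattern_match_rate <- function(pattern, base_probs) {
  pattern <- toupper(chartr("U", "T", pattern))
  prod(vapply(strsplit(pattern, "")[[1]], function(code) {
    sum(base_probs[IUPAC_BASES[[code]]])
  }, numeric(1)))
}

sample_iupac <- function(pattern) {
  pattern <- toupper(chartr("U", "T", pattern))
  paste(vapply(strsplit(pattern, "")[[1]], function(code) {
    b <- IUPAC_BASES[[code]]
    if (length(b) == 1) b else sample(b, 1)
  }, character(1)), collapse = "")
}

#' Configuration for the synthetic splicing dataset generator
#'
#' Defaults mirror the emulated study design: two biological replicates per
#' group, binomial junction counts at a target depth per event, exon sizes
#' that exercise flank truncation, and uniform base composition.
#'
#' @param seed RNG seed (all generation is a deterministic function of it).
#' @param events_per_class Named counts of events to simulate per class.
#' @param n_replicates Replicates per group (default 2).
#' @param depth Junction reads per replicate per event (binomial size).
#' @param frac_regulated Fraction of events given a true PSI shift (the
#'   regulated count per class is `round(frac_regulated * n)`, sampled
#'   without replacement).
#' @param dpsi_range Magnitude range of true delta PSI for regulated events.
#' @param dpsi_sign `NULL` for a random shift direction per event, or `-1` /
#'   `1` to force all regulated events down or up.
#' @param psi_ctl_range Range of control-group true PSI.
#' @param exon_size,intron_size Feature length ranges (nt).
#' @param base_probs Base composition (named, sums to 1).
#' @param plant_stops For RI events: clean the intron reading frame and plant
#'   this range of premature stop codons (set `NULL` to skip planting).
#' @param n_mirnas Number of synthetic miRNAs.
#' @param mirna_length miRNA length range (18-26 nt allowed).
#' @param plant_mirna_sites Number of regulated events that receive a planted
#'   perfect (0-mutation) miRNA complement in their DASE region.
#' @param motifs Tibble of `rbp`/`pattern` rows for the motif fixture.
#' @param plant_motif `NULL`, or a list with `rbp`, `event_class`,
#'   `direction` (`"up"`/`"down"`), `region` (`Upstream`/`Exon`/`Downstream`)
#'   and `rate_multiplier`: motif occurrences are planted in that collapsed
#'   region of matching regulated events so the total rate is about
#'   `rate_multiplier` times the background expectation.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             events_per_class = c(SE = 12, MXE = 6, RI = 10,
                                                  A3SS = 6, A5SS = 6),
                             n_replicates = 2,
                             depth = 200,
                             frac_regulated = 0.4,
                             dpsi_range = c(0.3, 0.6),
                             dpsi_sign = NULL,
                             psi_ctl_range = c(0.15, 0.85),
                             exon_size = c(30, 500),
                             intron_size = c(80, 5000),
                             base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             plant_stops = c(1, 4),
                             n_mirnas = 25,
                             mirna_length = c(20, 24),
                             plant_mirna_sites = 0,
                             motifs = default_synthetic_motifs(),
                             plant_motif = NULL) {
  stopifnot(abs(sum(base_probs) - 1) < 1e-8, depth >= 1,
            n_replicates >= 1, frac_regulated >= 0, frac_regulated <= 1)
  cfg <- list(seed = seed, events_per_class = events_per_class,
              n_replicates = n_replicates, depth = depth,
              frac_regulated = frac_regulated, dpsi_range = dpsi_range,
              dpsi_sign = dpsi_sign,
              psi_ctl_range = psi_ctl_range, exon_size = exon_size,
              intron_size = intron_size, base_probs = base_probs,
              plant_stops = plant_stops, n_mirnas = n_mirnas,
              mirna_length = mirna_length,
              plant_mirna_sites = plant_mirna_sites,
              motifs = motifs, plant_motif = plant_motif)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default synthetic RBP motif set
#'
#' A small plain-text-style fixture of RBP to IUPAC patterns covering a
#' UGCAUG-class motif, SR-protein-like purine-rich patterns and a pyrimidine
#' tract. The authoritative motif list of a real analysis is user-supplied.
#'
#' @return Tibble with `rbp` and `patterns` list-column.
#' @export
default_synthetic_motifs <- function() {
  tibble(rbp = c("RBFOX1", "SRSF1", "SRSF2", "PTBP1", "HNRNPK"),
         patterns = list("TGCATG", "RGAAGAAC", "SSNG", "TCTT", "CCCC"))
}

# effective junction lengths by class (inclusion, skipping), in junction
# equivalents: two inclusion junctions where the alternative segment is
# bounded by two splice sites
class_lengths <- function(cls) {
  switch(cls,
         SE = c(2, 1), MXE = c(2, 2), RI = c(2, 1),
         A3SS = c(1, 1), A5SS = c(1, 1))
}

new_event_row <- function() {
  ev <- empty_events()
  ev[1, ] <- NA
  ev
}

#' Generate a synthetic splicing study with ground truth
#'
#' Builds a toy genome (one contig per event/gene), a GTF-style annotation
#' (exons, plus phased CDS for RI genes), per-class junction-count tables,
#' miRNA sequences with a brain-expression table, an RBP motif list, a PPI
#' network with DEG flags, a term-to-gene annotation map, and a truth record
#' from which every planted feature can be re-derived. With `out_dir` set,
#' the bundle is additionally written as FASTA / GTF / rMATS-dialect TSV /
#' TSV / JSON files; the same seed yields byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return A list (`genome`, `events`, `cds`, `mirnas`, `expression`,
#'   `motifs`, `network_nodes`, `network_edges`, `degs`, `annotation_map`,
#'   `truth`, `config`).
#' @export
simulate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  bp <- config$base_probs
  rint <- function(rng) {
    s <- seq(rng[1], rng[2])
    if (length(s) == 1) s else sample(s, 1)
  }
  pad <- 60L

  contigs <- character(0)
  events <- list()
  cds <- list()
  truth_events <- list()
  truth_stops <- list()

  # exactly round(frac * n) regulated events per class
  reg_flags <- lapply(config$events_per_class, function(n) {
    flags <- rep(FALSE, n)
    flags[sample.int(n, round(config$frac_regulated * n))] <- TRUE
    flags
  })

  idx <- 0L
  for (cls in names(config$events_per_class)) {
    for (k in seq_len(config$events_per_class[[cls]])) {
      idx <- idx + 1L
      strand <- sample(c("+", "-"), 1)
      gene <- sprintf("SYNG%03d", idx)
      contig <- sprintf("ctg%03d", idx)
      ev <- new_event_row()
      ev$event_id <- paste0(cls, "_", idx)
      ev$event_class <- cls
      ev$gene_id <- gene
      ev$gene_symbol <- gene
      ev$chrom <- contig
      ev$strand <- strand

      if (cls %in% c("SE", "MXE", "RI")) {
        exA <- rint(config$exon_size); exC <- rint(config$exon_size)
        pos <- pad
        ev$upstream_start <- pos; pos <- pos + exA; ev$upstream_end <- pos
        if (cls == "SE") {
          i1 <- rint(config$intron_size); exB <- rint(config$exon_size)
          i2 <- rint(config$intron_size)
          pos <- pos + i1
          ev$exon_start <- pos; pos <- pos + exB; ev$exon_end <- pos
          pos <- pos + i2
        } else if (cls == "MXE") {
          i1 <- rint(config$intron_size); e1 <- rint(config$exon_size)
          i2 <- rint(config$intron_size); e2 <- rint(config$exon_size)
          i3 <- rint(config$intron_size)
          pos <- pos + i1
          ev$exon_start <- pos; pos <- pos + e1; ev$exon_end <- pos
          pos <- pos + i2
          ev$exon2_start <- pos; pos <- pos + e2; ev$exon2_end <- pos
          pos <- pos + i3
        } else { # RI
          il <- rint(config$intron_size)
          pos <- pos + il
        }
        ev$downstream_start <- pos; pos <- pos + exC; ev$downstream_end <- pos
        if (cls == "RI") {
          ev$exon_start <- ev$upstream_start; ev$exon_end <- ev$downstream_end
        }
        total <- pos + pad
      } else { # A3SS / A5SS
        exF <- rint(config$exon_size)
        alt <- rint(c(max(30, config$exon_size[1]), 80))
        exS <- rint(config$exon_size)
        il <- rint(config$intron_size)
        # alt segment flush-left pattern when (class, strand) puts the
        # alternative splice site on the genomic right of the short exon
        flush_left <- (cls == "A5SS") == (strand == "+")
        pos <- pad
        if (flush_left) {
          ev$exon2_start <- pos; ev$exon_start <- pos
          pos <- pos + exS; ev$exon2_end <- pos
          pos <- pos + alt; ev$exon_end <- pos
          pos <- pos + il
          ev$flanking_start <- pos; pos <- pos + exF; ev$flanking_end <- pos
        } else {
          ev$flanking_start <- pos; pos <- pos + exF; ev$flanking_end <- pos
          pos <- pos + il
          ev$exon_start <- pos
          pos <- pos + alt; ev$exon2_start <- pos
          pos <- pos + exS; ev$exon2_end <- pos; ev$exon_end <- pos
        }
        total <- pos + pad
      }

      contigs[contig] <- random_dna(total, bp)

      # group truth + counts
      regulated <- reg_flags[[cls]][k]
      psi_ctl <- runif(1, config$psi_ctl_range[1], config$psi_ctl_range[2])
      if (regulated) {
        sgn <- if (is.null(config$dpsi_sign)) sample(c(-1, 1), 1)
               else config$dpsi_sign
        shift <- runif(1, config$dpsi_range[1], config$dpsi_range[2]) * sgn
        # reposition the control PSI if needed so the full shift magnitude
        # fits inside (0.03, 0.97) and the true delta is exactly `shift`
        psi_ctl <- min(max(psi_ctl, 0.03 + max(0, -shift)),
                       0.97 - max(0, shift))
        psi_trt <- psi_ctl + shift
      } else {
        psi_trt <- psi_ctl
      }
      ll <- class_lengths(cls)
      pinc <- function(psi) psi * ll[1] / (psi * ll[1] + (1 - psi) * ll[2])
      draw <- function(psi) {
        i <- rbinom(config$n_replicates, config$depth, pinc(psi))
        list(inc = i, skip = config$depth - i)
      }
      dt <- draw(psi_trt); dc <- draw(psi_ctl)
      ev$inc_counts_trt <- list(dt$inc); ev$skip_counts_trt <- list(dt$skip)
      ev$inc_counts_ctl <- list(dc$inc); ev$skip_counts_ctl <- list(dc$skip)
      ev$inc_len <- ll[1]; ev$skip_len <- ll[2]
      events[[idx]] <- ev
      truth_events[[idx]] <- tibble(
        event_id = ev$event_id, event_class = cls, strand = strand,
        regulated = regulated, true_psi_trt = psi_trt, true_psi_ctl = psi_ctl,
        true_delta_psi = psi_trt - psi_ctl)
    }
  }
  events <- bind_rows(events)
  truth_events <- bind_rows(truth_events)

  # phased CDS on the transcript-upstream exon of each RI gene, and planted
  # premature stops in a cleaned reading frame
  for (i in which(events$event_class == "RI")) {
    ev <- events[i, ]
    frame <- sample(1:3, 1)
    carry <- (3L - (frame - 1L)) %% 3L
    up_tx_start <- if (ev$strand == "+") ev$upstream_start else ev$downstream_start
    up_tx_end <- if (ev$strand == "+") ev$upstream_end else ev$downstream_end
    cds_len <- up_tx_end - up_tx_start
    phase <- (cds_len - carry) %% 3L
    cds[[length(cds) + 1L]] <- tibble(
      transcript_id = paste0(ev$gene_id, ".t1"), chrom = ev$chrom,
      strand = ev$strand, start = up_tx_start, end = up_tx_end,
      phase = phase)

    if (!is.null(config$plant_stops)) {
      istart <- ev$upstream_end; iend <- ev$downstream_start
      iseq <- extract_region_seq(contigs, tibble(
        chrom = ev$chrom, start = istart, end = iend, strand = ev$strand))
      res <- plant_stop_codons(iseq, frame,
                               n_stops = rint(config$plant_stops))
      gseq <- if (ev$strand == "-") revcomp_chr(res$sequence) else res$sequence
      substr(contigs[[ev$chrom]], istart + 1, iend) <- gseq
      truth_stops[[length(truth_stops) + 1L]] <- tibble(
        event_id = ev$event_id, frame = frame,
        positions = list(res$positions), codons = list(res$codons))
    }
  }
  truth_stops <- bind_rows(truth_stops)

  # miRNAs, brain expression, planted perfect sites
  mirnas <- tibble(
    mirna_id = sprintf("syn-miR-%d", seq_len(config$n_mirnas)),
    sequence = vapply(seq_len(config$n_mirnas), function(i) {
      chartr("T", "U", random_dna(rint(config$mirna_length), bp))
    }, character(1)))
  expression <- tibble(mirna_id = mirnas$mirna_id,
                       expression = round(stats::rlnorm(config$n_mirnas,
                                                        meanlog = 4, sdlog = 1), 3),
                       tissue = "brain")
  truth_sites <- tibble(event_id = character(), mirna_id = character(),
                        offset = integer(), n_mutations = integer())
  if (config$plant_mirna_sites > 0) {
    reg <- dase_region(events)
    reg_len <- reg$end - reg$start
    # RI regions are excluded: their DASE region is the retained intron,
    # which carries the planted stop-codon truth
    cand <- which(truth_events$regulated & events$event_class != "RI" &
                    reg_len >= max(nchar(mirnas$sequence)) + 4)
    cand <- utils::head(cand, config$plant_mirna_sites)
    for (i in cand) {
      mi <- sample(nrow(mirnas), 1)
      res <- plant_mirna_site(extract_region_seq(contigs, reg[i, ]),
                              mirnas$sequence[mi], n_mutations = 0)
      gseq <- if (reg$strand[i] == "-") revcomp_chr(res$sequence) else res$sequence
      substr(contigs[[reg$chrom[i]]], reg$start[i] + 1, reg$end[i]) <- gseq
      truth_sites <- bind_rows(truth_sites, tibble(
        event_id = reg$event_id[i], mirna_id = mirnas$mirna_id[mi],
        offset = res$site_start, n_mutations = 0L))
    }
    # planted miRNAs are part of the planted truth: place them in the
    # high-expression range so they survive the tissue-expression stage
    planted_ids <- unique(truth_sites$mirna_id)
    expression$expression[expression$mirna_id %in% planted_ids] <-
      round(max(expression$expression) * 1.1, 3)
  }

  # planted motif enrichment in a chosen collapsed region / direction
  truth_motifs <- tibble(event_id = character(), rbp = character(),
                         region = character(), n_planted = integer())
  if (!is.null(config$plant_motif)) {
    pm <- config$plant_motif
    pat <- config$motifs$patterns[[match(pm$rbp, config$motifs$rbp)]][1]
    rate <- pattern_match_rate(pat, bp)
    sel <- which(events$event_class == pm$event_class &
                   truth_events$regulated &
                   sign(truth_events$true_delta_psi) ==
                   (if (pm$direction == "up") 1 else -1))
    for (i in sel) {
      lay <- build_region_layout(events[i, ], contigs)
      lay <- lay[lay$collapsed == pm$region, , drop = FALSE]
      n_extra <- rpois(1, max(0, (pm$rate_multiplier - 1)) * rate *
                         sum(nchar(lay$seq)))
      planted <- 0L
      for (e in seq_len(n_extra)) {
        j <- sample(nrow(lay), 1)
        w <- nchar(pat)
        if (nchar(lay$seq[j]) < w) next
        off <- sample(nchar(lay$seq[j]) - w + 1, 1)
        inst <- sample_iupac(pat)
        # transcript-relative offset -> genomic position, strand aware
        if (events$strand[i] == "+") {
          gpos <- lay$gstart[j] + off
          substr(contigs[[events$chrom[i]]], gpos, gpos + w - 1) <- inst
        } else {
          gpos <- lay$gend[j] - off - w + 2
          substr(contigs[[events$chrom[i]]], gpos, gpos + w - 1) <-
            revcomp_chr(inst)
        }
        planted <- planted + 1L
      }
      truth_motifs <- bind_rows(truth_motifs, tibble(
        event_id = events$event_id[i], rbp = pm$rbp, region = pm$region,
        n_planted = planted))
    }
  }

  # PPI fixture over the motif RBPs + decoys, with DEG flags
  rbps <- config$motifs$rbp
  nodes <- tibble(rbp = c(rbps, "DECOY1", "DECOY2"),
                  deg = c(sample(c("up", "down", "none"), length(rbps),
                                 replace = TRUE, prob = c(0.3, 0.3, 0.4)),
                          "none", "none"))
  edges <- tibble(a = rbps[-1], b = rbps[1])  # star on the first RBP
  degs <- tibble(gene = nodes$rbp[nodes$deg != "none"],
                 log2fc = round(runif(sum(nodes$deg != "none"), -2, 2), 3),
                 padj = round(runif(sum(nodes$deg != "none"), 0, 0.05), 4))

  # term -> gene annotation: one term enriched in regulated genes
  reg_genes <- events$gene_id[truth_events$regulated]
  other_genes <- events$gene_id[!truth_events$regulated]
  annotation_map <- tibble(
    term = c("SYN:0001", "SYN:0002", "SYN:0003"),
    description = c("regulated module", "random module A", "random module B"),
    genes = list(
      unique(c(reg_genes, utils::head(other_genes, 2))),
      sample(events$gene_id, min(8, nrow(events))),
      sample(events$gene_id, min(8, nrow(events)))))

  # re-derive stop truth from the final sequences so the record stays
  # consistent even if later planting touched a retained intron
  if (nrow(truth_stops) > 0) {
    for (i in seq_len(nrow(truth_stops))) {
      ev <- events[events$event_id == truth_stops$event_id[i], ]
      iseq <- extract_region_seq(contigs, tibble(
        chrom = ev$chrom, start = ev$upstream_end, end = ev$downstream_start,
        strand = ev$strand))
      scan <- scan_premature_stops(iseq, truth_stops$frame[i])
      truth_stops$positions[[i]] <- scan$stop_positions[[1]]
      truth_stops$codons[[i]] <- scan$stop_codons[[1]]
    }
  }

  genome <- Biostrings::DNAStringSet(contigs)
  cds <- if (length(cds)) bind_rows(cds) else NULL
  truth <- list(events = truth_events, stops = truth_stops,
                mirna_sites = truth_sites, motifs = truth_motifs)
  bundle <- list(genome = genome, events = sort_events(events), cds = cds,
                 mirnas = mirnas, expression = expression,
                 motifs = config$motifs, network_nodes = nodes,
                 network_edges = edges, degs = degs,
                 annotation_map = annotation_map, truth = truth,
                 config = config)
  class(bundle) <- "synthetic_bundle"
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Plant premature stop codons into a sequence at a fixed frame
#'
#' Removes accidental in-frame stop codons (first base T is rewritten to C),
#' then overwrites `n_stops` random in-frame codons with stop codons.
#'
#' @param sequence DNA sequence (transcript orientation).
#' @param frame Reading frame 1:3.
#' @param n_stops Number of stops to plant.
#' @return List: `sequence`, `positions` (1-based first-nucleotide offsets,
#'   sorted), `codons`.
#' @export
plant_stop_codons <- function(sequence, frame, n_stops) {
  n <- nchar(sequence)
  starts <- if (n >= frame + 2) seq.int(frame, n - 2, by = 3) else integer(0)
  for (s in starts) {
    if (substr(sequence, s, s + 2) %in% STOP_CODONS) {
      substr(sequence, s, s) <- "C"
    }
  }
  n_stops <- min(n_stops, length(starts))
  pos <- sort(starts[sample.int(length(starts), n_stops)])
  codons <- sample(STOP_CODONS, n_stops, replace = TRUE)
  for (j in seq_len(n_stops)) {
    substr(sequence, pos[j], pos[j] + 2) <- codons[j]
  }
  list(sequence = sequence, positions = pos, codons = codons)
}

#' Plant a miRNA complement into a target region
#'
#' Inserts (overwrites) the reverse complement of the miRNA at a random
#' position, with `n_mutations` random substitutions at recorded miRNA
#' positions. With 0 mutations the site is a Strong-class site by
#' construction; the returned `pairing_map` reflects the construction
#' (WC except at mutated positions).
#'
#' @param region_seq Target region sequence (DNA, transcript orientation).
#' @param mirna miRNA sequence (RNA or DNA, 5'->3').
#' @param n_mutations Number of substitutions to apply.
#' @param positions Optional miRNA positions (1-based) to mutate; sampled
#'   uniformly when `NULL`.
#' @return List: `sequence` (modified region), `site_start` (1-based),
#'   `mutated_positions` (miRNA positions), `pairing_map`.
#' @export
plant_mirna_site <- function(region_seq, mirna, n_mutations = 0,
                             positions = NULL) {
  mi_dna <- chartr("Uu", "Tt", toupper(mirna))
  L <- nchar(mi_dna)
  if (nchar(region_seq) < L) {
    abort(sprintf("region (%d nt) shorter than miRNA (%d nt)",
                  nchar(region_seq), L))
  }
  site <- revcomp_chr(mi_dna)
  if (is.null(positions)) {
    positions <- if (n_mutations > 0) sort(sample(L, n_mutations)) else integer(0)
  } else {
    positions <- sort(unique(as.integer(positions)))
  }
  map <- rep("WC", L)
  site_chr <- strsplit(site, "")[[1]]
  for (p in positions) {
    # mutate the target base opposite miRNA position p so it can no longer
    # pair (WC or wobble) with the miRNA base
    tpos <- L - p + 1
    mi_b <- substr(mi_dna, p, p)
    partner <- c(A = "T", C = "G", G = "C", T = "A")[[mi_b]]
    wobble <- c(G = "T", T = "G", U = "G")[mi_b]
    bad <- c(partner, wobble[!is.na(wobble)])
    site_chr[tpos] <- sample(setdiff(c("A", "C", "G", "T"), bad), 1)
    map[p] <- "mismatch"
  }
  site <- paste(site_chr, collapse = "")
  start <- sample(nchar(region_seq) - L + 1, 1)
  substr(region_seq, start, start + L - 1) <- site
  list(sequence = region_seq, site_start = start,
       mutated_positions = positions, pairing_map = map)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %d events, %d contigs, %d miRNAs (seed %s)\n",
              nrow(x$events), length(x$genome), nrow(x$mirnas),
              format(x$config$seed)))
  invisible(x)
}
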