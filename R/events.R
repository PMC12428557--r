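#' Alternative-splicing event tables
#'
#' Events live in an ordinary tibble, one row per event, with a unified
#' coordinate schema across the five event classes (SE, MXE, RI, A3SS, A5SS).
#' All coordinates are 0-based half-open genomic intervals; replicate junction
#' counts are integer list-columns, split by group (`_trt` = treatment,
#' `_ctl` = control).
#'
#' Coordinate columns by class:
#' * `exon_start/exon_end`: SE target exon; MXE first exon; RI retained-intron
#'   span (upstream exon start to downstream exon end); A3SS/A5SS long exon.
#' * `exon2_start/exon2_end`: MXE second exon; A3SS/A5SS short exon.
#' * `upstream_*`, `downstream_*`: flanking exons (SE, MXE, RI).
#' * `flanking_*`: the single flanking exon of A3SS/A5SS.
#'
#' @name event-tables
NULL

EVENT_CLASSES <- c("SE", "MXE", "RI", "A3SS", "A5SS")

rmats_coord_map <- list(
  SE = c(exon_start = "exonStart_0base", exon_end = "exonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  MXE = c(exon_start = "X1stExonStart_0base", exon_end = "X1stExonEnd",
          exon2_start = "X2ndExonStart_0base", exon2_end = "X2ndExonEnd",
          upstream_start = "upstreamES", upstream_end = "upstreamEE",
          downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  RI = c(exon_start = "riExonStart_0base", exon_end = "riExonEnd",
         upstream_start = "upstreamES", upstream_end = "upstreamEE",
         downstream_start = "downstreamES", downstream_end = "downstreamEE"),
  A3SS = c(exon_start = "longExonStart_0base", exon_end = "longExonEnd",
           exon2_start = "shortES", exon2_end = "shortEE",
           flanking_start = "flankingES", flanking_end = "flankingEE"),
  A5SS = c(exon_start = "longExonStart_0base", exon_end = "longExonEnd",
           exon2_start = "shortES", exon2_end = "shortEE",
           flanking_start = "flankingES", flanking_end = "flankingEE")
)

coord_cols <- c("exon_start", "exon_end", "exon2_start", "exon2_end",
                "upstream_start", "upstream_end",
                "downstream_start", "downstream_end",
                "flanking_start", "flanking_end")

split_counts <- function(x, row_ids, col) {
  out <- lapply(seq_along(x), function(i) {
    parts <- strsplit(as.character(x[[i]]), ",", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts) & parts != "NA"]
    v <- suppressWarnings(as.integer(parts))
    if (length(v) == 0 || anyNA(v) || any(v < 0)) {
      abort(sprintf("malformed junction counts in row %d, column '%s': '%s'",
                    row_ids[i], col, x[[i]]))
    }
    v
  })
  out
}

#' Read an rMATS per-class event table
#'
#' Parses one tab-separated rMATS (JC flavour) output table into the unified
#' event tibble. Replicate counts such as `"18,22"` are split into integer
#' vectors; missing inclusion levels are recomputed from counts with
#' [compute_psi()].
#'
#' @param path Path to the per-class table.
#' @param event_class One of `"SE"`, `"MXE"`, `"RI"`, `"A3SS"`, `"A5SS"`.
#' @return A tibble, one row per event (see [event-tables]).
#' @export
read_rmats_events <- function(path, event_class) {
  if (!event_class %in% EVENT_CLASSES) {
    abort(sprintf("unknown event class '%s' (expected one of %s)",
                  event_class, paste(EVENT_CLASSES, collapse = ", ")))
  }
  raw <- utils::read.delim(path, check.names = TRUE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(empty_events())
  cmap <- rmats_coord_map[[event_class]]
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("table '%s' lacks %s column(s): %s", path, event_class,
                  paste(missing_cols, collapse = ", ")))
  }
  rows <- seq_len(nrow(raw))
  ev <- tibble(
    event_id = paste0(event_class, "_", as.character(raw$ID)),
    event_class = event_class,
    gene_id = as.character(raw$GeneID),
    gene_symbol = as.character(if ("geneSymbol" %in% names(raw)) raw$geneSymbol else raw$GeneID),
    chrom = as.character(raw$chr),
    strand = as.character(raw$strand)
  )
  for (col in coord_cols) ev[[col]] <- NA_integer_
  for (nm in names(cmap)) {
    v <- raw[[cmap[[nm]]]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      abort(sprintf("negative coordinate in row %d, column '%s'",
                    bad[1], cmap[[nm]]))
    }
    ev[[nm]] <- as.integer(v)
  }
  if (!all(ev$strand %in% c("+", "-"))) {
    abort(sprintf("invalid strand in row %d, column 'strand'",
                  which(!ev$strand %in% c("+", "-"))[1]))
  }
  ev$inc_counts_trt <- split_counts(raw$IJC_SAMPLE_1, rows, "IJC_SAMPLE_1")
  ev$skip_counts_trt <- split_counts(raw$SJC_SAMPLE_1, rows, "SJC_SAMPLE_1")
  ev$inc_counts_ctl <- split_counts(raw$IJC_SAMPLE_2, rows, "IJC_SAMPLE_2")
  ev$skip_counts_ctl <- split_counts(raw$SJC_SAMPLE_2, rows, "SJC_SAMPLE_2")
  ev$inc_len <- as.numeric(raw$IncFormLen)
  ev$skip_len <- as.numeric(raw$SkipFormLen)
  ev$pvalue <- if ("PValue" %in% names(raw)) as.numeric(raw$PValue) else NA_real_
  ev$fdr <- if ("FDR" %in% names(raw)) as.numeric(raw$FDR) else NA_real_
  ev$psi_trt <- psi_levels(raw, "IncLevel1", ev, "trt")
  ev$psi_ctl <- psi_levels(raw, "IncLevel2", ev, "ctl")
  ev$delta_psi <- if ("IncLevelDifference" %in% names(raw)) {
    as.numeric(raw$IncLevelDifference)
  } else {
    vapply(rows, function(i) mean(ev$psi_trt[[i]], na.rm = TRUE) -
             mean(ev$psi_ctl[[i]], na.rm = TRUE), numeric(1))
  }
  ev
}

psi_levels <- function(raw, col, ev, grp) {
  n <- nrow(ev)
  inc <- ev[[paste0("inc_counts_", grp)]]
  skp <- ev[[paste0("skip_counts_", grp)]]
  lapply(seq_len(n), function(i) {
    if (col %in% names(raw) && !is.na(raw[[col]][i]) && nzchar(raw[[col]][i])) {
      suppressWarnings(as.numeric(strsplit(as.character(raw[[col]][i]), ",")[[1]]))
    } else {
      compute_psi(inc[[i]], skp[[i]], ev$inc_len[i], ev$skip_len[i])
    }
  })
}

empty_events <- function() {
  ev <- tibble(event_id = character(), event_class = character(),
               gene_id = character(), gene_symbol = character(),
               chrom = character(), strand = character())
  for (col in coord_cols) ev[[col]] <- integer()
  ev$inc_counts_trt <- list(); ev$skip_counts_trt <- list()
  ev$inc_counts_ctl <- list(); ev$skip_counts_ctl <- list()
  ev$inc_len <- numeric(); ev$skip_len <- numeric()
  ev$pvalue <- numeric(); ev$fdr <- numeric()
  ev$psi_trt <- list(); ev$psi_ctl <- list(); ev$delta_psi <- numeric()
  ev
}

#' Read a directory of rMATS tables
#'
#' Looks for `<CLASS>.MATS.JC.txt` (or `<CLASS>.txt`) for each of the five
#' event classes and row-binds whatever is present, sorted by
#' (class, chrom, start, event id).
#'
#' @param dir Directory containing per-class tables.
#' @return Combined event tibble.
#' @export
read_rmats_dir <- function(dir) {
  found <- list()
  for (cls in EVENT_CLASSES) {
    for (cand in file.path(dir, c(paste0(cls, ".MATS.JC.txt"), paste0(cls, ".txt")))) {
      if (file.exists(cand)) {
        found[[cls]] <- read_rmats_events(cand, cls)
        break
      }
    }
  }
  if (length(found) == 0) abort(sprintf("no rMATS tables found under '%s'", dir))
  sort_events(bind_rows(found))
}

sort_events <- function(events) {
  arrange(events, .data$event_class, .data$chrom, .data$exon_start, .data$event_id)
}

#' Percent spliced in from junction counts
#'
#' PSI = (I/lI) / (I/lI + S/lS), the length-normalised fraction of junction
#' reads supporting inclusion. Vectorised over counts. When a replicate has
#' neither inclusion nor skipping reads its PSI is undefined and `NA` is
#' returned (the event is flagged, never silently set to 0).
#'
#' @param inclusion_count,skipping_count Non-negative integer junction counts.
#' @param inclusion_length,skipping_length Positive effective lengths.
#' @return Numeric vector of PSI values in `[0, 1]` (`NA` where undefined).
#' @export
compute_psi <- function(inclusion_count, skipping_count,
                        inclusion_length = 1, skipping_length = 1) {
  stopifnot(all(inclusion_length > 0), all(skipping_length > 0))
  i <- inclusion_count / inclusion_length
  s <- skipping_count / skipping_length
  out <- i / (i + s)
  out[inclusion_count == 0 & skipping_count == 0] <- NA_real_
  out
}

#' Mean junction coverage of each event
#'
#' Mean over all replicates of both groups of (inclusion + skipping) junction
#' reads; the quantity thresholded by the coverage filter in [filter_dases()].
#'
#' @param events Event tibble.
#' @return Numeric vector, one value per event.
#' @export
mean_event_coverage <- function(events) {
  vapply(seq_len(nrow(events)), function(i) {
    tot <- c(events$inc_counts_trt[[i]] + events$skip_counts_trt[[i]],
             events$inc_counts_ctl[[i]] + events$skip_counts_ctl[[i]])
    mean(tot)
  }, numeric(1))
}

#' Filter events to differential alternative splicing events (DASEs)
#'
#' Keeps events with FDR <= `fdr_max`, |delta PSI| >= `min_abs_dpsi` and
#' mean junction coverage strictly greater than `min_mean_coverage`
#' (defaults 0.05 / 0.1 / 5). Events with missing FDR are rejected with a
#' warning. Input order is preserved; the filter is idempotent.
#'
#' @param events Event tibble with `fdr` and `delta_psi` populated.
#' @param fdr_max,min_abs_dpsi,min_mean_coverage Filter thresholds.
#' @return The retained rows, with a `mean_coverage` column added.
#' @export
filter_dases <- function(events, fdr_max = 0.05, min_abs_dpsi = 0.1,
                         min_mean_coverage = 5) {
  if (nrow(events) == 0) {
    events$mean_coverage <- numeric()
    return(events)
  }
  events$mean_coverage <- mean_event_coverage(events)
  na_fdr <- is.na(events$fdr)
  if (any(na_fdr)) {
    warn(sprintf("%d event(s) with missing FDR rejected: %s",
                 sum(na_fdr), paste(utils::head(events$event_id[na_fdr], 5),
                                    collapse = ", ")))
  }
  keep <- !na_fdr & events$fdr <= fdr_max &
    !is.na(events$delta_psi) & abs(events$delta_psi) >= min_abs_dpsi &
    events$mean_coverage > min_mean_coverage
  events[keep, , drop = FALSE]
}

#' Class-specific DASE target region
#'
#' Resolves each event to the single genomic interval that downstream
#' sequence analyses consume: SE, the target exon; MXE, the first exon on
#' `+` and the second exon on `-`; RI, the retained intron (upstream exon end
#' to downstream exon start); A3SS/A5SS, the long exon minus its overlap
#' with the short exon (the alternative segment).
#'
#' @param events Event tibble.
#' @return Tibble with `event_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
dase_region <- function(events) {
  n <- nrow(events)
  start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    cls <- events$event_class[i]
    if (cls == "SE") {
      start[i] <- events$exon_start[i]; end[i] <- events$exon_end[i]
    } else if (cls == "MXE") {
      if (events$strand[i] == "+") {
        start[i] <- events$exon_start[i]; end[i] <- events$exon_end[i]
      } else {
        start[i] <- events$exon2_start[i]; end[i] <- events$exon2_end[i]
      }
    } else if (cls == "RI") {
      start[i] <- events$upstream_end[i]; end[i] <- events$downstream_start[i]
    } else { # A3SS / A5SS: long exon minus short exon
      ls <- events$exon_start[i]; le <- events$exon_end[i]
      ss <- events$exon2_start[i]; se <- events$exon2_end[i]
      if (ss == ls && se < le) {          # short flush with long 5' (genomic)
        start[i] <- se; end[i] <- le
      } else if (se == le && ss > ls) {   # short flush with long 3' (genomic)
        start[i] <- ls; end[i] <- ss
      } else {
        abort(sprintf(
          "event %s: short exon [%d,%d) does not sit flush at one boundary of long exon [%d,%d)",
          events$event_id[i], ss, se, ls, le))
      }
    }
    if (is.na(start[i]) || is.na(end[i]) || start[i] >= end[i]) {
      abort(sprintf("event %s: degenerate target region [%s,%s)",
                    events$event_id[i], start[i], end[i]))
    }
  }
  tibble(event_id = events$event_id, chrom = events$chrom,
         start = start, end = end, strand = events$strand)
}

#' DASE regions as BED6
#'
#' @param events Event tibble (typically the output of [filter_dases()]).
#' @return BED6 tibble: chrom, start, end, name (event id),
#'   score (`round(1000 * |delta PSI|)`), strand.
#' @export
dase_region_bed <- function(events) {
  reg <- dase_region(events)
  tibble(chrom = reg$chrom, start = reg$start, end = reg$end,
         name = reg$event_id,
         score = round(1000 * abs(events$delta_psi)),
         strand = reg$strand)
}

#' Load a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by contig name (first header word).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  abort("genome must be a named character vector or a DNAStringSet")
}

#' Extract strand-oriented sequences for genomic regions
#'
#' Forward sequence on `+`, reverse complement on `-`; regions are 0-based
#' half-open. Out-of-bounds regions raise an error naming the contig and
#' coordinates.
#'
#' @param genome Named character vector or `DNAStringSet` of contigs.
#' @param regions Tibble with `chrom`, `start`, `end`, `strand`.
#' @return Character vector of DNA sequences (length `end - start` each).
#' @export
extract_region_seq <- function(genome, regions) {
  genome <- as_genome(genome)
  vapply(seq_len(nrow(regions)), function(i) {
    chrom <- regions$chrom[i]
    s <- regions$start[i]; e <- regions$end[i]
    if (!chrom %in% names(genome)) {
      abort(sprintf("contig '%s' not in genome", chrom))
    }
    len <- Biostrings::width(genome[chrom])
    if (s < 0 || e > len || s >= e) {
      abort(sprintf("region %s:%d-%d out of bounds (contig length %d)",
                    chrom, s, e, len))
    }
    x <- Biostrings::subseq(genome[[chrom]], start = s + 1, end = e)
    if (regions$strand[i] == "-") x <- Biostrings::reverseComplement(x)
    as.character(x)
  }, character(1))
}

#' Call differential splicing from junction counts
#'
#' A simplified two-group test used on synthetic data (it is not the
#' hierarchical replicate model of event-calling tools): per event, a
#' likelihood-ratio test of equal versus separate binomial inclusion
#' probabilities on the pooled junction counts of each group, with
#' Benjamini-Hochberg FDR across all events jointly. Delta PSI is the mean
#' treatment PSI minus the mean control PSI, using the length-normalised
#' PSI of [compute_psi()].
#'
#' @param events Event tibble with count list-columns populated.
#' @return `events` with `psi_trt`, `psi_ctl`, `delta_psi`, `pvalue`, `fdr`
#'   and a logical `testable` column populated.
#' @export
call_dases <- function(events) {
  n <- nrow(events)
  pv <- rep(NA_real_, n); dps <- rep(NA_real_, n); testable <- rep(TRUE, n)
  psi_t <- vector("list", n); psi_c <- vector("list", n)
  for (i in seq_len(n)) {
    it <- events$inc_counts_trt[[i]]; st <- events$skip_counts_trt[[i]]
    ic <- events$inc_counts_ctl[[i]]; sc <- events$skip_counts_ctl[[i]]
    li <- events$inc_len[i]; ls <- events$skip_len[i]
    psi_t[[i]] <- compute_psi(it, st, li, ls)
    psi_c[[i]] <- compute_psi(ic, sc, li, ls)
    dps[i] <- mean(psi_t[[i]], na.rm = TRUE) - mean(psi_c[[i]], na.rm = TRUE)
    x1 <- sum(it); n1 <- sum(it) + sum(st)
    x2 <- sum(ic); n2 <- sum(ic) + sum(sc)
    if (n1 == 0 || n2 == 0) {
      testable[i] <- FALSE
      next
    }
    pv[i] <- binom_lrt_p(x1, n1, x2, n2)
  }
  events$psi_trt <- psi_t
  events$psi_ctl <- psi_c
  events$delta_psi <- dps
  events$pvalue <- pv
  events$testable <- testable
  events$fdr <- p.adjust(pv, method = "BH")
  events
}

binom_ll <- function(x, n, p) {
  # log-likelihood up to the binomial coefficient (cancels in the ratio)
  t1 <- if (x > 0) x * log(p) else 0
  t2 <- if (n - x > 0) (n - x) * log(1 - p) else 0
  t1 + t2
}

binom_lrt_p <- function(x1, n1, x2, n2) {
  p0 <- (x1 + x2) / (n1 + n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  lrt <- 2 * (binom_ll(x1, n1, p1) + binom_ll(x2, n2, p2) -
                binom_ll(x1, n1, p0) - binom_ll(x2, n2, p0))
  pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
}
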