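#' Read an RBP motif list
#'
#' @param path TSV with columns `rbp` and `pattern` (IUPAC degenerate
#'   nucleotide strings, RNA or DNA alphabet; one row per pattern, several
#'   rows per RBP allowed).
#' @return Tibble with `rbp` and a `patterns` list-column.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("rbp", "pattern") %in% names(tab)))
  ok <- grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]+$", tab$pattern)
  if (!all(ok)) {
    abort(sprintf("non-IUPAC motif pattern: '%s'", tab$pattern[!ok][1]))
  }
  tab |>
    group_by(.data$rbp) |>
    summarise(patterns = list(toupper(chartr("Uu", "Tt", .data$pattern)))) |>
    ungroup()
}

#' Scan a sequence for IUPAC motif occurrences
#'
#' All (overlapping) start positions where any pattern matches under IUPAC
#' expansion; `N` in the scanned sequence never matches a degenerate pattern
#' position.
#'
#' @param sequence DNA/RNA sequence (character scalar).
#' @param patterns Character vector of IUPAC patterns (U read as T).
#' @return Tibble with `start` (1-based, sorted), `width`, `pattern`.
#' @export
motif_scan <- function(sequence, patterns) {
  seq <- Biostrings::DNAString(chartr("Uu", "Tt", toupper(sequence)))
  out <- lapply(patterns, function(p) {
    p <- toupper(chartr("Uu", "Tt", p))
    if (nchar(p) > length(seq)) return(NULL)
    m <- Biostrings::matchPattern(p, seq, fixed = "subject")
    if (length(m) == 0) return(NULL)
    tibble(start = Biostrings::start(m), width = nchar(p), pattern = p)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(start = integer(), width = integer(), pattern = character()))
  }
  arrange(res, .data$start)
}

# genomic slice helpers: [s, e) half-open; fully truncated slices stay in
# the layout (empty sequence) so labels are canonical across events
first_slice <- function(s, e, k) c(s, min(e, s + k))
last_slice <- function(s, e, k, reserved = 0) {
  lo <- max(s + reserved, e - k)
  c(min(lo, e), e)
}

layout_rows <- function(event) {
  cls <- event$event_class
  acc <- vector("list", 16)
  n_acc <- 0L
  r <- function(gs, ge, ganchor, group, nominal) {
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- list(gs, ge, ganchor, group, nominal)
    invisible(NULL)
  }
  two <- function(s, e, k, group) {
    a <- first_slice(s, e, k)
    b <- last_slice(s, e, k, reserved = a[2] - a[1])
    r(a[1], a[2], "left", group, k)
    r(b[1], b[2], "right", group, k)
  }
  if (cls == "SE") {
    r(last_slice(event$upstream_start, event$upstream_end, 50)[1],
      event$upstream_end, "right", "left", 50)
    two(event$upstream_end, event$exon_start, 250, "left")
    two(event$exon_start, event$exon_end, 50, "mid")
    two(event$exon_end, event$downstream_start, 250, "right")
    r(event$downstream_start,
      first_slice(event$downstream_start, event$downstream_end, 50)[2],
      "left", "right", 50)
  } else if (cls == "MXE") {
    r(last_slice(event$upstream_start, event$upstream_end, 50)[1],
      event$upstream_end, "right", "left", 50)
    two(event$upstream_end, event$exon_start, 250, "left")
    two(event$exon_start, event$exon_end, 50, "mid")
    two(event$exon_end, event$exon2_start, 250, "mid")
    two(event$exon2_start, event$exon2_end, 50, "mid")
    two(event$exon2_end, event$downstream_start, 250, "right")
    r(event$downstream_start,
      first_slice(event$downstream_start, event$downstream_end, 50)[2],
      "left", "right", 50)
  } else if (cls == "RI") {
    r(last_slice(event$upstream_start, event$upstream_end, 50)[1],
      event$upstream_end, "right", "left", 50)
    two(event$upstream_end, event$downstream_start, 250, "mid")
    r(event$downstream_start,
      first_slice(event$downstream_start, event$downstream_end, 50)[2],
      "left", "right", 50)
  } else { # A3SS / A5SS
    ls <- event$exon_start; le <- event$exon_end
    ss <- event$exon2_start; se <- event$exon2_end
    fs <- event$flanking_start; fe <- event$flanking_end
    if (is.na(ss) || is.na(se) || is.na(ls) || is.na(le)) {
      abort(sprintf("event %s: missing flank coordinates for class %s",
                    event$event_id, cls))
    }
    if (ss == ls && se < le) {
      # short exon flush at genomic left; alternative segment [se, le),
      # intron and flanking exon to the genomic right
      r(last_slice(ss, se, 50)[1], se, "right", "left", 50)
      two(se, le, 50, "mid")
      two(le, fs, 250, "right")
      r(fs, first_slice(fs, fe, 50)[2], "left", "right", 50)
    } else if (se == le && ss > ls) {
      # short exon flush at genomic right; alternative segment [ls, ss)
      r(last_slice(fs, fe, 50)[1], fe, "right", "left", 50)
      two(fe, ls, 250, "left")
      two(ls, ss, 50, "mid")
      r(ss, first_slice(ss, se, 50)[2], "left", "right", 50)
    } else {
      abort(sprintf("event %s: short exon not flush with long exon",
                    event$event_id))
    }
  }
  acc <- acc[seq_len(n_acc)]
  data.frame(
    gstart = vapply(acc, function(x) as.numeric(x[[1]]), numeric(1)),
    gend = vapply(acc, function(x) as.numeric(x[[2]]), numeric(1)),
    ganchor = vapply(acc, `[[`, character(1), 3),
    group = vapply(acc, `[[`, character(1), 4),
    nominal = vapply(acc, function(x) as.numeric(x[[5]]), numeric(1)),
    stringsAsFactors = FALSE)
}

# layouts for many events at once, with a single vectorised sequence
# extraction; returns a plain data.frame
layout_table <- function(events, genome) {
  genome <- as_genome(genome)
  parts <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    event <- events[i, ]
    rows <- layout_rows(event)
    if (anyNA(rows$gstart) || anyNA(rows$gend)) {
      abort(sprintf("event %s: missing flank coordinates for class %s",
                    event$event_id, event$event_class))
    }
    minus <- event$strand == "-"
    if (minus) {
      rows <- rows[rev(seq_len(nrow(rows))), , drop = FALSE]
      rows$anchor <- ifelse(rows$ganchor == "left", "right", "left")
      rows$collapsed <- unname(c(left = "Downstream", mid = "Exon",
                                 right = "Upstream")[rows$group])
    } else {
      rows$anchor <- rows$ganchor
      rows$collapsed <- unname(c(left = "Upstream", mid = "Exon",
                                 right = "Downstream")[rows$group])
    }
    rows$label <- paste0("R", seq_len(nrow(rows)))
    rows$event_id <- event$event_id
    rows$chrom <- event$chrom
    rows$strand <- event$strand
    parts[[i]] <- rows
  }
  all <- do.call(rbind, parts)
  # one vectorised extraction for every non-empty slice
  all$seq <- ""
  ok <- all$gend > all$gstart
  if (any(ok)) {
    contig_len <- setNames(Biostrings::width(genome), names(genome))
    if (any(all$gstart[ok] < 0) ||
        any(all$gend[ok] > contig_len[all$chrom[ok]])) {
      bad <- which(ok)[which(all$gstart[ok] < 0 |
                               all$gend[ok] > contig_len[all$chrom[ok]])[1]]
      abort(sprintf("region %s:%d-%d out of bounds", all$chrom[bad],
                    all$gstart[bad], all$gend[bad]))
    }
    seqs <- Biostrings::subseq(genome[all$chrom[ok]],
                               start = all$gstart[ok] + 1, end = all$gend[ok])
    neg <- all$strand[ok] == "-"
    if (any(neg)) seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
    all$seq[ok] <- as.character(seqs)
  }
  all
}

#' Sub-region layout around a splicing event
#'
#' Builds the ordered, labelled sub-regions scanned by the motif map:
#' exonic flanks of up to 50 nt and intronic flanks of up to 250 nt around
#' the class-specific splice sites, labelled `R1..Rn` 5'->3' in transcript
#' orientation and collapsed to `Upstream` / `Exon` / `Downstream` (for RI
#' the retained intron itself is the `Exon` region). Sub-regions shorter
#' than their nominal size are truncated at feature boundaries without
#' double-counting; each sequence is flush against its splice-site-proximal
#' end (`anchor`) within the nominal window.
#'
#' @param event One-row event tibble.
#' @param genome Genome object.
#' @return Tibble: `event_id`, `label`, `collapsed`, `seq` (transcript
#'   orientation), `nominal`, `anchor` (`"left"`/`"right"` end of the
#'   nominal window the sequence is flushed to), `gstart`, `gend`.
#' @export
build_region_layout <- function(event, genome) {
  stopifnot(nrow(event) == 1)
  rows <- layout_table(event, genome)
  tibble(event_id = rows$event_id, label = rows$label,
         collapsed = rows$collapsed, seq = rows$seq,
         nominal = rows$nominal, anchor = rows$anchor,
         gstart = rows$gstart, gend = rows$gend)
}

# per-sequence motif match starts for several sequences at once
scan_starts_many <- function(seqs, patterns) {
  subj <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(seqs)))
  out <- rep(list(integer(0)), length(seqs))
  widths <- rep(list(integer(0)), length(seqs))
  for (p in patterns) {
    p <- toupper(chartr("Uu", "Tt", p))
    m <- Biostrings::vmatchPattern(p, subj, fixed = "subject")
    st <- Biostrings::startIndex(m)
    for (i in seq_along(out)) {
      if (!is.null(st[[i]]) && length(st[[i]])) {
        out[[i]] <- c(out[[i]], st[[i]])
        widths[[i]] <- c(widths[[i]], rep(nchar(p), length(st[[i]])))
      }
    }
  }
  list(starts = out, widths = widths)
}

# motif nucleotide coverage laid into the nominal window;
# NA outside the actual sequence extent
coverage_from_hits <- function(len, nominal, anchor, starts, widths) {
  cov <- rep(FALSE, len)
  for (i in seq_along(starts)) {
    cov[starts[i]:min(len, starts[i] + widths[i] - 1)] <- TRUE
  }
  out <- rep(NA, nominal)
  if (len > 0) {
    if (anchor == "left") out[seq_len(len)] <- cov
    else out[(nominal - len + 1):nominal] <- cov
  }
  out
}

coverage_in_window <- function(seq, nominal, anchor, patterns) {
  hits <- motif_scan(seq, patterns)
  coverage_from_hits(nchar(seq), nominal, anchor, hits$start, hits$width)
}

window_density <- function(cov, window) {
  n <- length(cov)
  if (n < window) return(numeric(0))
  x <- as.numeric(cov)
  x[is.na(x)] <- NA
  cs <- cumsum(ifelse(is.na(x), 0, x))
  nas <- cumsum(is.na(x))
  starts <- seq_len(n - window + 1)
  ends <- starts + window - 1
  dens <- (cs[ends] - c(0, cs)[starts]) / window
  bad <- (nas[ends] - c(0, nas)[starts]) > 0
  dens[bad] <- NA
  dens
}

#' Sliding-window motif density profile with rank-sum enrichment
#'
#' For events of a single class, split by delta-PSI direction (`up`:
#' delta PSI > 0, `down`: < 0, `background`), computes per-event motif
#' nucleotide-coverage densities in 50-nt windows sliding (step 1) within
#' each sub-region of the event layout, the per-window group means, and
#' two-sided Wilcoxon rank-sum p-values of each regulated group against
#' background. Events whose truncated sub-region does not fully contain a
#' window do not contribute to it.
#'
#' @param events Event tibble of one class with a `group` column
#'   (`"up"`, `"down"`, `"background"`); see [assign_direction()].
#' @param genome Genome object.
#' @param rbp RBP name (carried into the result).
#' @param patterns IUPAC patterns for the RBP.
#' @param window Window size in nt (default 50).
#' @return A `density_profile` object wrapping a per-window tibble
#'   (`label`, `collapsed`, `window`, `density_up/down/bg`, `n_up/down/bg`,
#'   `p_up`, `p_down`).
#' @export
density_profile <- function(events, genome, rbp, patterns, window = 50) {
  stopifnot(length(unique(events$event_class)) == 1,
            "group" %in% names(events))
  cls <- events$event_class[1]
  lay <- layout_table(events, genome)
  hits <- scan_starts_many(lay$seq, patterns)
  labels <- unique(lay[, c("label", "collapsed", "nominal")])
  groups <- events$group
  n_events <- nrow(events)
  per_region <- vector("list", nrow(labels))
  for (rix in seq_len(nrow(labels))) {
    lab <- labels$label[rix]
    nominal <- labels$nominal[rix]
    nwin <- max(0, nominal - window + 1)
    if (nwin == 0) next
    dens <- matrix(NA_real_, nrow = nwin, ncol = n_events)
    rsel <- which(lay$label == lab)
    ev_of_row <- match(lay$event_id[rsel], events$event_id)
    for (k in seq_along(rsel)) {
      j <- rsel[k]
      cov <- coverage_from_hits(nchar(lay$seq[j]), nominal, lay$anchor[j],
                                hits$starts[[j]], hits$widths[[j]])
      d <- window_density(cov, window)
      dens[seq_along(d), ev_of_row[k]] <- d
    }
    gmean <- function(g) rowMeans(dens[, groups == g, drop = FALSE], na.rm = TRUE)
    gn <- function(g) rowSums(!is.na(dens[, groups == g, drop = FALSE]))
    pvals <- function(g) {
      vapply(seq_len(nwin), function(w) {
        x <- dens[w, groups == g]; x <- x[!is.na(x)]
        y <- dens[w, groups == "background"]; y <- y[!is.na(y)]
        if (length(x) < 3 || length(y) < 3) return(NA_real_)
        wilcoxon_rank_sum(x, y)
      }, numeric(1))
    }
    per_region[[rix]] <- tibble(
      label = lab, collapsed = labels$collapsed[rix], window = seq_len(nwin),
      density_up = gmean("up"), density_down = gmean("down"),
      density_bg = gmean("background"),
      n_up = gn("up"), n_down = gn("down"), n_bg = gn("background"),
      p_up = pvals("up"), p_down = pvals("down"))
  }
  out <- list(rbp = rbp, event_class = cls, window = window,
              profile = bind_rows(per_region))
  class(out) <- "density_profile"
  out
}

#' Label events by delta-PSI direction against a DASE set
#'
#' Events present in `dases` are `"up"` (delta PSI > 0) or `"down"`
#' (delta PSI < 0); all other (tested but non-regulated) events are
#' `"background"`. Events with delta PSI exactly 0 in `dases` are excluded
#' from both directions (moved to background with a message).
#'
#' @param events Full tested event tibble.
#' @param dases Filtered event tibble (subset of `events`).
#' @return `events` with a `group` column.
#' @export
assign_direction <- function(events, dases) {
  events$group <- "background"
  idx <- match(dases$event_id, events$event_id)
  dir <- ifelse(dases$delta_psi > 0, "up",
                ifelse(dases$delta_psi < 0, "down", "background"))
  if (any(dir == "background")) {
    inform(sprintf("%d DASE(s) with delta PSI exactly 0 assigned to background",
                   sum(dir == "background")))
  }
  events$group[idx[!is.na(idx)]] <- dir[!is.na(idx)]
  events
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution (ties handled by midranks)
#' when both samples have at most `exact_max` observations; otherwise the
#' normal approximation with tie and continuity corrections. Degenerate
#' input (all values identical) gives p = 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Enumerate exactly when `max(n, m) <= exact_max`
#'   (default 8).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 8) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) return(1)
  r <- rank(all_v)
  w <- sum(r[seq_len(n)])
  if (n <= exact_max && m <= exact_max) {
    sums <- utils::combn(r, n, FUN = sum)
    p_le <- mean(sums <= w + 1e-9)
    p_ge <- mean(sums >= w - 1e-9)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  N <- n + m
  mu <- n * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Summarise motif-map enrichment into the three-region matrix
#'
#' A `(RBP, event class, direction, collapsed region)` combination is
#' enriched iff at least one window of that collapsed region has
#' `p < alpha` in the matching direction-versus-background test.
#'
#' @param profiles A `density_profile` or list of them.
#' @param alpha Per-window significance level (default 0.05, uncorrected).
#' @return Tibble: `rbp`, `event_class`, `direction` (`"up"`/`"down"`),
#'   `region` (`Upstream`/`Exon`/`Downstream`), `min_p`, `n_sig_windows`.
#' @export
summarize_enrichment <- function(profiles, alpha = 0.05) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(pr) {
    pf <- pr$profile
    out <- list()
    for (dir in c("up", "down")) {
      pcol <- paste0("p_", dir)
      sig <- pf[!is.na(pf[[pcol]]) & pf[[pcol]] < alpha, , drop = FALSE]
      if (nrow(sig) == 0) next
      agg <- sig |>
        group_by(region = .data$collapsed) |>
        summarise(min_p = min(.data[[pcol]]), n_sig_windows = n()) |>
        ungroup()
      agg$rbp <- pr$rbp; agg$event_class <- pr$event_class; agg$direction <- dir
      out[[dir]] <- agg
    }
    bind_rows(out)
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0) {
    return(tibble(rbp = character(), event_class = character(),
                  direction = character(), region = character(),
                  min_p = numeric(), n_sig_windows = integer()))
  }
  res[, c("rbp", "event_class", "direction", "region", "min_p", "n_sig_windows")]
}

#' Motif occurrences coherent with the enrichment summary
#'
#' Scans each collapsed region of each DASE for each RBP's motifs and keeps
#' occurrences only where `(event class, delta-PSI direction, region)` is an
#' enriched combination for that RBP. DASEs with delta PSI exactly 0 are
#' excluded (logged).
#'
#' @param dases DASEs of interest (event tibble).
#' @param genome Genome object.
#' @param motifs Motif tibble from [read_motifs()].
#' @param summary Enrichment summary from [summarize_enrichment()].
#' @return Tibble: `event_class`, `direction`, `gene_symbol`, `event_id`,
#'   `rbp`, `region`, `n_occurrences`, `positions` (list, region-relative).
#' @export
coherent_occurrences <- function(dases, genome, motifs, summary) {
  zero <- !is.na(dases$delta_psi) & dases$delta_psi == 0
  if (any(zero)) {
    inform(sprintf("%d DASE(s) with delta PSI exactly 0 excluded", sum(zero)))
    dases <- dases[!zero, , drop = FALSE]
  }
  rows <- list()
  lay_all <- if (nrow(dases) > 0) layout_table(dases, genome) else NULL
  for (i in seq_len(nrow(dases))) {
    lay <- lay_all[lay_all$event_id == dases$event_id[i], , drop = FALSE]
    dir <- if (dases$delta_psi[i] > 0) "up" else "down"
    for (k in seq_len(nrow(motifs))) {
      keep_regions <- summary$region[
        summary$rbp == motifs$rbp[k] &
          summary$event_class == dases$event_class[i] &
          summary$direction == dir]
      if (length(keep_regions) == 0) next
      for (reg in unique(keep_regions)) {
        sub <- lay[lay$collapsed == reg, , drop = FALSE]
        pos <- integer(0)
        offset <- 0L
        for (j in seq_len(nrow(sub))) {
          hits <- motif_scan(sub$seq[j], motifs$patterns[[k]])
          pos <- c(pos, hits$start + offset)
          offset <- offset + nchar(sub$seq[j])
        }
        if (length(pos) == 0) next
        rows[[length(rows) + 1L]] <- tibble(
          event_class = dases$event_class[i], direction = dir,
          gene_symbol = dases$gene_symbol[i], event_id = dases$event_id[i],
          rbp = motifs$rbp[k], region = reg,
          n_occurrences = length(pos), positions = list(pos))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(event_class = character(), direction = character(),
                  gene_symbol = character(), event_id = character(),
                  rbp = character(), region = character(),
                  n_occurrences = integer(), positions = list()))
  }
  bind_rows(rows)
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s on %s events, %d-nt windows, %d windows\n",
              x$rbp, x$event_class, x$window, nrow(x$profile)))
  invisible(x)
}

#' @export
tidy.density_profile <- function(x, ...) {
  tidyr::pivot_longer(x$profile,
                      cols = c("density_up", "density_down", "density_bg"),
                      names_to = "group", names_prefix = "density_",
                      values_to = "density") |>
    mutate(rbp = x$rbp, event_class = x$event_class)
}

#' @export
glance.density_profile <- function(x, alpha = 0.05, ...) {
  pf <- x$profile
  tibble(rbp = x$rbp, event_class = x$event_class,
         n_windows = nrow(pf),
         n_sig_up = sum(pf$p_up < alpha, na.rm = TRUE),
         n_sig_down = sum(pf$p_down < alpha, na.rm = TRUE),
         min_p_up = suppressWarnings(min(pf$p_up, na.rm = TRUE)),
         min_p_down = suppressWarnings(min(pf$p_down, na.rm = TRUE)))
}

#' Plot a motif density profile
#'
#' Mean motif density per window for the up, down and background groups,
#' faceted by sub-region, with dotted -log10 p curves on a secondary panel
#' style familiar from RNA-map servers.
#'
#' @param object A `density_profile`.
#' @param alpha Significance line for the p-value panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, alpha = 0.05, ...) {
  pf <- tidy(object)
  pf$label <- factor(pf$label, levels = unique(object$profile$label))
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$window, y = .data$density,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(. ~ label, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            bg = "grey30")) +
    ggplot2::labs(title = sprintf("%s motif density (%s events)",
                                  object$rbp, object$event_class),
                  x = "window start (nt within sub-region)",
                  y = "mean motif coverage") +
    ggplot2::theme_minimal()
}
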