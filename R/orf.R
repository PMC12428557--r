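STOP_CODONS <- c("TAG", "TAA", "TGA")

#' Scan a sequence for in-frame premature termination codons
#'
#' Codons are read from offset `frame - 1` (so frame 1 starts at the first
#' nucleotide) in steps of 3; only codons lying fully inside the sequence are
#' considered and codons containing `N` never match. The sequence must be in
#' transcript orientation (already reverse-complemented for `-` strand
#' regions).
#'
#' @param sequence DNA sequence over `A,C,G,T,N` (character scalar; `U` is
#'   accepted and treated as `T`).
#' @param frame Reading frame, 1, 2 or 3.
#' @return A one-row tibble: `frame`, `stop_count`, `first_stop_position`
#'   (1-based offset of the first stop codon's first nucleotide, `NA` when
#'   none), and list-columns `stop_positions`, `stop_codons`.
#' @export
scan_premature_stops <- function(sequence, frame) {
  stopifnot(length(sequence) == 1, frame %in% 1:3)
  seq <- chartr("uU", "tT", sequence)
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- if (n >= frame + 2) seq.int(frame, n - 2, by = 3) else integer(0)
  codons <- if (length(starts)) substring(seq, starts, starts + 2) else character(0)
  hit <- codons %in% STOP_CODONS
  tibble(
    frame = as.integer(frame),
    stop_count = sum(hit),
    first_stop_position = if (any(hit)) starts[which(hit)[1]] else NA_integer_,
    stop_positions = list(starts[hit]),
    stop_codons = list(codons[hit])
  )
}

#' Read a CDS model from a GTF file
#'
#' Extracts CDS features (with their phase) into a tidy tibble used by
#' [determine_frame()]. Requires the rtracklayer package.
#'
#' @param path GTF file with CDS features carrying `transcript_id` attributes.
#' @return Tibble: `transcript_id`, `chrom`, `strand`, `start` (0-based),
#'   `end` (exclusive), `phase`.
#' @export
read_cds_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF files requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  tibble(
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    phase = as.integer(as.character(gr$phase))
  )
}

#' Reading frame of a retained intron from a CDS model
#'
#' Finds CDS segments whose transcript-orientation 3' end abuts the retained
#' intron (the upstream exon end on `+`, the downstream exon start on `-`),
#' carries the codon phase across the junction, and returns the frame in
#' which codons should be read within the intron sequence (transcript
#' orientation): `frame = 1 + ((3 - carry) %% 3)` where `carry` is the number
#' of bases of the interrupted codon already consumed by the exon. When
#' several transcripts disagree the transcript with the longest total CDS
#' wins and a warning is logged. `user_frame`, when given, overrides the
#' annotation (provenance `"user"`).
#'
#' @param event One-row event tibble (RI class).
#' @param cds Tibble as returned by [read_cds_gtf()], or `NULL`.
#' @param user_frame Optional frame in 1:3 supplied by the caller.
#' @return List with `frame` (integer) and `provenance` (`"annotation"` or
#'   `"user"`).
#' @export
determine_frame <- function(event, cds = NULL, user_frame = NULL) {
  if (!is.null(user_frame)) {
    stopifnot(user_frame %in% 1:3)
    return(list(frame = as.integer(user_frame), provenance = "user"))
  }
  if (is.null(cds)) {
    abort(sprintf("event %s: no CDS annotation and no user frame supplied",
                  event$event_id[1]))
  }
  plus <- event$strand[1] == "+"
  junction <- if (plus) event$upstream_end[1] else event$downstream_start[1]
  hit <- cds[cds$chrom == event$chrom[1] & cds$strand == event$strand[1] &
               (if (plus) cds$end == junction else cds$start == junction), ,
             drop = FALSE]
  if (nrow(hit) == 0) {
    abort(sprintf("event %s: no CDS segment ends at the intron junction; supply user_frame",
                  event$event_id[1]))
  }
  frames <- vapply(seq_len(nrow(hit)), function(i) {
    carry <- (hit$end[i] - hit$start[i] - hit$phase[i]) %% 3
    as.integer(1 + ((3 - carry) %% 3))
  }, integer(1))
  if (length(unique(frames)) > 1) {
    cds_len <- vapply(hit$transcript_id, function(tx) {
      sum(cds$end[cds$transcript_id == tx] - cds$start[cds$transcript_id == tx])
    }, numeric(1))
    warn(sprintf("event %s: transcripts disagree on frame; using longest CDS (%s)",
                 event$event_id[1], hit$transcript_id[which.max(cds_len)]))
    frames <- frames[which.max(cds_len)]
  }
  list(frame = frames[1], provenance = "annotation")
}

#' Premature-stop report for retained-intron events
#'
#' For each RI event: extracts the retained-intron sequence (strand
#' oriented), scans it in the event's reading frame, and reports the stop
#' count and the 1-based intron-relative position of the first stop.
#'
#' @param ri_events Event tibble, all rows of class RI.
#' @param genome Genome (named character vector or `DNAStringSet`).
#' @param frames Named integer vector or list mapping `event_id` to frame
#'   (1:3), or a single frame recycled to all events; alternatively `cds`
#'   may be given to derive frames from annotation.
#' @param cds Optional CDS tibble (see [determine_frame()]).
#' @return Tibble: `event_id`, `gene_symbol`, `region`, `delta_psi`, `frame`,
#'   `stop_count`, `first_stop_position`, plus `stop_positions`/`stop_codons`
#'   list-columns.
#' @export
ri_stop_report <- function(ri_events, genome, frames = NULL, cds = NULL) {
  stopifnot(all(ri_events$event_class == "RI"))
  reg <- dase_region(ri_events)
  seqs <- extract_region_seq(genome, reg)
  out <- vector("list", nrow(ri_events))
  for (i in seq_len(nrow(ri_events))) {
    id <- ri_events$event_id[i]
    fr <- if (is.null(frames)) {
      determine_frame(ri_events[i, ], cds = cds)$frame
    } else if (length(frames) == 1 && is.null(names(frames))) {
      as.integer(frames)
    } else {
      if (!id %in% names(frames)) {
        abort(sprintf("no frame supplied for event %s", id))
      }
      as.integer(frames[[id]])
    }
    scan <- scan_premature_stops(seqs[i], fr)
    out[[i]] <- mutate(scan,
                       event_id = id,
                       gene_symbol = ri_events$gene_symbol[i],
                       region = sprintf("%s:%d-%d (%s)", reg$chrom[i],
                                        reg$start[i], reg$end[i], reg$strand[i]),
                       delta_psi = ri_events$delta_psi[i],
                       .before = 1)
  }
  bind_rows(out)
}
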