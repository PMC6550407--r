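#' Find in-frame stop codons
#'
#' Scans a transcript (or any DNA string) for stop codons (TAA, TAG, TGA) in a
#' given reading frame and returns the 1-based start position of each in-frame
#' stop codon, in ascending order.
#'
#' @param seq A DNA string (uppercase A/C/G/T only).
#' @param frame_offset Reading-frame offset, 0, 1 or 2: codons start at
#'   positions `frame_offset + 1, frame_offset + 4, ...`.
#' @return Integer vector of 1-based codon start positions (possibly empty).
#' @examples
#' find_inframe_stops("AAATGACATAGCCC", 0)  # TGA at 4, TAG at 10
#' @export
find_inframe_stops <- function(seq, frame_offset = 0) {
  stopifnot(length(seq) == 1L, is.character(seq))
  stopifnot(frame_offset %in% 0:2)
  chars <- check_dna(seq)
  n <- length(chars)
  starts <- seq.int(frame_offset + 1L, length.out = max(0L, (n - frame_offset) %/% 3L),
                    by = 3L)
  if (length(starts) == 0L) return(integer(0))
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  starts[codons %in% STOP_CODONS]
}

#' Delineate region 1 and region 2 downstream of the canonical stop codon
#'
#' Region 1 is the transcript segment between the canonical (first) stop codon
#' and the second in-frame stop codon in the 3'UTR; region 2 lies between the
#' second and third in-frame stops. Both are taken in the CDS reading frame and
#' exclude the bounding stop codons. Searching never proceeds past
#' `cds_end + cap_nt` (nor past the transcript end); a region cut short by the
#' cap is flagged `truncated_at_cap`.
#'
#' Coordinates are 1-based inclusive; an empty region has `end = start - 1`.
#' `cds_end` is the position of the last nucleotide of the canonical stop
#' codon.
#'
#' @param transcript_seq Transcript sequence (A/C/G/T).
#' @param cds_end 1-based position of the last CDS nucleotide (including the
#'   canonical stop codon).
#' @param gene_id Optional identifier carried into the output.
#' @param cap_nt Maximum number of nucleotides considered downstream of the
#'   canonical stop codon (default 300).
#' @return A one-row `data.frame` with columns `gene_id`, `region1_start`,
#'   `region1_end`, `region2_start`, `region2_end` (NA when region 2 is
#'   absent), `region1_seq`, `region2_seq`, `truncated_at_cap`.
#' @export
extract_regions <- function(transcript_seq, cds_end, gene_id = NA_character_,
                            cap_nt = 300) {
  stopifnot(length(transcript_seq) == 1L, is.numeric(cds_end), cap_nt >= 3)
  n <- nchar(transcript_seq)
  if (cds_end < 3 || cds_end > n) {
    stop(sprintf("cds_end (%d) outside transcript of length %d", cds_end, n),
         call. = FALSE)
  }
  stop_codon <- substr(transcript_seq, cds_end - 2L, cds_end)
  if (!stop_codon %in% STOP_CODONS) {
    stop(sprintf("codon ending at cds_end is '%s', not a stop codon (corrupt annotation for gene %s)",
                 stop_codon, gene_id), call. = FALSE)
  }
  win_end <- min(n, cds_end + cap_nt)
  utr <- substr(transcript_seq, cds_end + 1L, win_end)
  stops <- if (nchar(utr) >= 3L) find_inframe_stops(utr, 0L) else integer(0)

  r1_start <- cds_end + 1L
  truncated <- FALSE
  if (length(stops) >= 1L) {
    r1_end <- cds_end + stops[1L] - 1L
  } else {
    r1_end <- win_end
    truncated <- TRUE
  }
  if (length(stops) >= 1L) {
    r2_start <- cds_end + stops[1L] + 3L
    if (length(stops) >= 2L) {
      r2_end <- cds_end + stops[2L] - 1L
    } else {
      r2_end <- win_end
      truncated <- TRUE
    }
    if (r2_start > win_end && length(stops) < 2L) {
      # second stop flush with the cap: nothing left for region 2
      r2_start <- NA_integer_
      r2_end <- NA_integer_
    }
  } else {
    r2_start <- NA_integer_
    r2_end <- NA_integer_
  }

  r1_seq <- if (r1_end >= r1_start) substr(transcript_seq, r1_start, r1_end) else ""
  r2_seq <- if (!is.na(r2_start) && r2_end >= r2_start)
    substr(transcript_seq, r2_start, r2_end) else ""

  data.frame(
    gene_id = gene_id,
    region1_start = as.integer(r1_start), region1_end = as.integer(r1_end),
    region2_start = as.integer(r2_start), region2_end = as.integer(r2_end),
    region1_seq = r1_seq, region2_seq = r2_seq,
    truncated_at_cap = truncated,
    stringsAsFactors = FALSE
  )
}

#' Extract regions for a table of genes
#'
#' Applies [extract_regions()] to every row of a gene table.
#'
#' @param genes A `data.frame` with columns `gene_id`, `transcript_seq`,
#'   `cds_end`.
#' @param cap_nt Downstream cap in nucleotides (default 300).
#' @return A `data.frame` with one row per gene (see [extract_regions()]).
#' @export
extract_regions_table <- function(genes, cap_nt = 300) {
  stopifnot(all(c("gene_id", "transcript_seq", "cds_end") %in% names(genes)))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    extract_regions(genes$transcript_seq[i], genes$cds_end[i],
                    gene_id = genes$gene_id[i], cap_nt = cap_nt)
  })
  do.call(rbind, out)
}
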