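# 16S rRNA marker handling: Sanger read-pair consensus, anchored cropping
# to a standardized partial sequence, percent identity between marker
# sequences, and identity-based selection of query genomes for the
# unique-region subtraction.

#' Conserved U515 motif inside the 16S rRNA gene, used as the crop anchor
#' @format A 19-base character string.
#' @export
U515 <- "GTGCCAGCAGCCGCGGTAA"

#' Anchored-cropping specification for processed 16S sequences
#'
#' Defaults keep 385 bases 5' of the anchor start and 216 bases 3' of the
#' anchor end around the conserved U515 motif, yielding a 620 bp processed
#' sequence (385 + 19 + 216).
#'
#' @param anchor Anchor motif (default U515, `GTGCCAGCAGCCGCGGTAA`).
#' @param upstream_keep Bases kept 5' of the anchor match.
#' @param downstream_keep Bases kept 3' of the anchor match.
#' @return List of class `consensus_spec`.
#' @export
consensus_spec <- function(anchor = U515, upstream_keep = 385L,
                           downstream_keep = 216L) {
  anchor <- .normalize_seq(anchor)
  stopifnot(nzchar(anchor), upstream_keep >= 0L, downstream_keep >= 0L)
  structure(list(anchor = anchor,
                 upstream_keep = as.integer(upstream_keep),
                 downstream_keep = as.integer(downstream_keep)),
            class = "consensus_spec")
}

.nucleo_mat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE, type = "DNA")
}

#' Merge a forward/reverse Sanger read pair into a consensus
#'
#' The reverse read is reverse-complemented, the two reads are aligned
#' end-gap-free (overlap alignment, match +1, mismatch -1, gap -2), and
#' the consensus emits the agreed base at agreement positions, `N` at
#' disagreements, and retains both non-overlapping flanks. Gapped columns
#' emit the base of whichever read has one.
#'
#' @param fwd Forward read sequence.
#' @param rev Raw reverse read sequence (reverse-complemented internally).
#' @param min_overlap_score Minimum alignment score below which the pair
#'   is rejected with a "no overlap" error.
#' @return Consensus sequence.
#' @export
merge_reads_to_consensus <- function(fwd, rev, min_overlap_score = 10) {
  fwd <- .normalize_seq(fwd); rev <- .normalize_seq(rev)
  if (!nzchar(fwd) || !nzchar(rev)) stop("merge_reads_to_consensus: empty read")
  revc <- reverse_complement(rev)
  aln <- Biostrings::pairwiseAlignment(
    fwd, revc, type = "overlap", substitutionMatrix = .nucleo_mat(),
    gapOpening = 0, gapExtension = 2)
  if (Biostrings::score(aln) < min_overlap_score) {
    stop("merge_reads_to_consensus: no overlap (alignment score ",
         round(Biostrings::score(aln), 1), " < ", min_overlap_score, ")")
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  core <- mapply(function(a, b) {
    if (a == "-") b
    else if (b == "-") a
    else if (a == b) a
    else "N"
  }, pa, sa)
  p_start <- Biostrings::start(Biostrings::pattern(aln))
  p_end <- Biostrings::end(Biostrings::pattern(aln))
  s_start <- Biostrings::start(Biostrings::subject(aln))
  s_end <- Biostrings::end(Biostrings::subject(aln))
  left <- if (p_start > 1) substr(fwd, 1, p_start - 1)
          else if (s_start > 1) substr(revc, 1, s_start - 1) else ""
  right <- if (p_end < nchar(fwd)) substr(fwd, p_end + 1, nchar(fwd))
           else if (s_end < nchar(revc)) substr(revc, s_end + 1, nchar(revc))
           else ""
  paste0(left, paste(core, collapse = ""), right)
}

#' Crop a consensus around the conserved anchor
#'
#' Requires exactly one exact anchor match. If the anchor is found only on
#' the reverse strand, the consensus is reverse-complemented first
#' (auto-orientation). The output spans `upstream_keep` bases before the
#' match through `downstream_keep` bases after it, so its length is always
#' `upstream_keep + nchar(anchor) + downstream_keep` (620 with defaults).
#'
#' @param consensus Input sequence.
#' @param spec A [consensus_spec()].
#' @return Cropped processed sequence.
#' @export
crop_at_anchor <- function(consensus, spec = consensus_spec()) {
  consensus <- .normalize_seq(consensus)
  hits <- gregexpr(spec$anchor, consensus, fixed = TRUE)[[1]]
  n_fwd <- if (hits[1] == -1L) 0L else length(hits)
  if (n_fwd == 0L) {
    rc <- reverse_complement(consensus)
    rhits <- gregexpr(spec$anchor, rc, fixed = TRUE)[[1]]
    if (rhits[1] != -1L) {
      consensus <- rc
      hits <- rhits
      n_fwd <- length(rhits)
    }
  }
  if (n_fwd == 0L) stop("crop_at_anchor: anchor not found on either strand")
  if (n_fwd > 1L) stop("crop_at_anchor: anchor matches ", n_fwd,
                       " times; need exactly one")
  a_start <- hits[1]                          # 1-based
  a_end <- a_start + nchar(spec$anchor) - 1L
  avail_up <- a_start - 1L
  avail_down <- nchar(consensus) - a_end
  if (avail_up < spec$upstream_keep) {
    stop("crop_at_anchor: only ", avail_up, " bases upstream of anchor; need ",
         spec$upstream_keep)
  }
  if (avail_down < spec$downstream_keep) {
    stop("crop_at_anchor: only ", avail_down,
         " bases downstream of anchor; need ", spec$downstream_keep)
  }
  substr(consensus, a_start - spec$upstream_keep, a_end + spec$downstream_keep)
}

#' Percent identity between two sequences
#'
#' Global alignment (match +1, mismatch -1, linear gap -2); identity is
#' 100 x matches / alignment columns, gap columns counted in the
#' denominator. Symmetric, and 100 iff the sequences are identical.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  a <- .normalize_seq(a); b <- .normalize_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("percent_identity: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .nucleo_mat(),
    gapOpening = 0, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Select query genomes by 16S identity to the reference
#'
#' Keeps candidates whose marker identity to the reference 16S is
#' strictly greater than `threshold` (default 97), sorted descending.
#'
#' @param reference_16s Reference 16S sequence.
#' @param candidates Named character vector or named list of candidate
#'   16S sequences (names = genome ids), or a list of
#'   `list(genome_id=, seq=)` pairs.
#' @param threshold Identity threshold in percent, strict.
#' @return data.frame with columns `genome_id`, `percent_identity`,
#'   sorted descending by identity.
#' @export
select_query_genomes <- function(reference_16s, candidates, threshold = 97) {
  stopifnot(threshold > 0, threshold <= 100)
  if (length(candidates) == 0L) {
    return(data.frame(genome_id = character(0), percent_identity = numeric(0)))
  }
  if (is.list(candidates) && !is.null(candidates[[1]]$genome_id)) {
    ids <- vapply(candidates, `[[`, "", "genome_id")
    seqs <- vapply(candidates, `[[`, "", "seq")
  } else {
    ids <- names(candidates)
    seqs <- unlist(candidates, use.names = FALSE)
  }
  pid <- vapply(seqs, function(s) percent_identity(reference_16s, s), 0,
                USE.NAMES = FALSE)
  keep <- pid > threshold
  df <- data.frame(genome_id = ids[keep], percent_identity = pid[keep],
                   stringsAsFactors = FALSE)
  df[order(-df$percent_identity), , drop = FALSE]
}

#' Extract 16S rRNA gene copies from a genome by exemplar alignment
#'
#' Replaces HMM-based rRNA prediction: chained ungapped matches of the
#' exemplar against each contig (both strands) are clustered on nearby
#' diagonals, and clusters covering at least `min_cov` of the exemplar at
#' weighted identity >= `min_identity` are reported as gene copies. The
#' returned sequences are strand-corrected to the exemplar orientation.
#'
#' @param genome Genome ([as_genome()]-coercible).
#' @param exemplar Exemplar 16S sequence (>= 500 bases).
#' @param min_identity Minimum weighted percent identity (default 80).
#' @param min_cov Minimum exemplar coverage fraction (default 0.8).
#' @param params A [match_params()] for the underlying engine.
#' @return List of `list(interval = genomic_interval, seq = character)`;
#'   empty when there is no hit.
#' @export
extract_16s <- function(genome, exemplar, min_identity = 80, min_cov = 0.8,
                        params = match_params()) {
  exemplar <- .normalize_seq(exemplar)
  if (nchar(exemplar) < 500L) stop("extract_16s: exemplar shorter than 500 bases")
  genome <- as_genome(genome)
  ex_len <- nchar(exemplar)
  hits <- list()
  for (contig in genome) {
    segs <- chain_matches(contig$seq, exemplar, params)
    for (strand in c("+", "-")) {
      ss <- segs[segs$strand == strand, , drop = FALSE]
      if (!nrow(ss)) next
      ss <- ss[order(ss$ref_start), , drop = FALSE]
      # cluster segments whose ref gap is small (same gene copy)
      grp <- cumsum(c(TRUE, ss$ref_start[-1] - ss$ref_end[-nrow(ss)] > ex_len))
      for (g in unique(grp)) {
        cl <- ss[grp == g, , drop = FALSE]
        cov_pos <- rep(FALSE, ex_len)
        for (i in seq_len(nrow(cl))) {
          cov_pos[(cl$q_start[i] + 1L):cl$q_end[i]] <- TRUE
        }
        coverage <- mean(cov_pos)
        w_ident <- sum(cl$identity * cl$length) / sum(cl$length)
        if (coverage >= min_cov && w_ident >= min_identity) {
          iv <- genomic_interval(contig$id, min(cl$ref_start),
                                 max(cl$ref_end), strand)
          hits[[length(hits) + 1L]] <- list(interval = iv,
                                            seq = interval_seq(contig, iv))
        }
      }
    }
  }
  hits
}
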