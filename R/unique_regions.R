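# Unique-region discovery: reference sequence absent from every query
# genome. Two modes mirror the two design endpoints:
#   * endpoint mode — fragment the reference, call a fragment novel when no
#     query matches it at or above an identity cutoff, merge and
#     size-filter (long regions for endpoint PCR primers);
#   * qPCR mode — build a per-base coverage mask from all query matches,
#     extract uncovered runs, tile and filter to short GC-balanced regions
#     suitable for a 100-200 bp qPCR product.

#' Configuration for endpoint-mode novel-region finding
#'
#' Defaults mirror the genome-subtraction settings used for endpoint-PCR
#' primer design: minimum novel region 500 bp, fragmentation size 1000 bp,
#' percent identity cutoff 85, core genome threshold 2.
#'
#' @param min_novel_size Minimum merged novel-region length (bp).
#' @param fragment_size Reference fragmentation size (bp).
#' @param identity_cutoff Percent identity at or above which a fragment
#'   counts as present in a query genome.
#' @param core_threshold A fragment is "core" (not novel) when found in at
#'   least this many genomes, counting the reference itself.
#' @return List of class `endpoint_config`.
#' @export
endpoint_config <- function(min_novel_size = 500L, fragment_size = 1000L,
                            identity_cutoff = 85, core_threshold = 2L) {
  stopifnot(min_novel_size > 0L, fragment_size > 0L,
            identity_cutoff > 0, identity_cutoff <= 100, core_threshold >= 1L)
  structure(list(min_novel_size = as.integer(min_novel_size),
                 fragment_size = as.integer(fragment_size),
                 identity_cutoff = identity_cutoff,
                 core_threshold = as.integer(core_threshold)),
            class = "endpoint_config")
}

#' Size/GC filter for qPCR-mode unique regions
#'
#' Defaults keep regions 150-250 bp long with GC content 40-60%.
#'
#' @param min_len,max_len Length bounds (bp).
#' @param gc_min,gc_max GC-fraction bounds.
#' @return List of class `qpcr_region_filter`.
#' @export
qpcr_region_filter <- function(min_len = 150L, max_len = 250L,
                               gc_min = 0.40, gc_max = 0.60) {
  stopifnot(min_len <= max_len, gc_min >= 0, gc_min <= gc_max, gc_max <= 1)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 gc_min = gc_min, gc_max = gc_max),
            class = "qpcr_region_filter")
}

.unique_region <- function(interval, seq, max_offtarget_identity = NA_real_) {
  structure(list(interval = interval, seq = seq, gc = gc_fraction(seq),
                 max_offtarget_identity = max_offtarget_identity),
            class = "unique_region")
}

#' @export
print.unique_region <- function(x, ...) {
  cat(sprintf("<unique_region> %s:[%d, %d) %d bp GC=%.2f%s\n",
              x$interval$genome_id, x$interval$start, x$interval$end,
              nchar(x$seq), x$gc,
              if (!is.na(x$max_offtarget_identity))
                sprintf(" offtarget=%.1f", x$max_offtarget_identity) else ""))
  invisible(x)
}

#' Per-base query-coverage mask of a reference genome
#'
#' A reference position is covered when it lies inside a seeded, extended
#' ungapped match (either query strand) with identity and length above the
#' [match_params()] thresholds, against any query genome. Runs of
#' ambiguous bases (N) in the reference are force-marked covered so that
#' downstream primer design never targets them. An empty query list gives
#' an all-FALSE mask.
#'
#' @param reference Reference genome ([as_genome()]-coercible).
#' @param queries List of query genomes (each [as_genome()]-coercible).
#' @param params A [match_params()] object.
#' @return Named list (one element per reference contig) of logical masks.
#' @export
shared_coverage_mask <- function(reference, queries, params = match_params()) {
  reference <- as_genome(reference)
  masks <- lapply(reference, function(contig) {
    len <- nchar(contig$seq)
    mask <- rep(FALSE, len)
    mask[is.na(encode_acgt(contig$seq))] <- TRUE   # never emit N runs
    for (q in queries) {
      for (qc in as_genome(q)) {
        segs <- chain_matches(contig$seq, qc$seq, params)
        for (i in seq_len(nrow(segs))) {
          mask[(segs$ref_start[i] + 1L):segs$ref_end[i]] <- TRUE
        }
      }
    }
    mask
  })
  setNames(masks, vapply(reference, `[[`, "", "id"))
}

#' Maximal uncovered runs of a coverage mask
#'
#' @param mask Logical vector (TRUE = covered) for one contig.
#' @param min_len Minimum run length to report.
#' @param genome_id Contig id used in the returned intervals.
#' @return List of [genomic_interval]s, sorted by start, non-overlapping.
#' @export
uncovered_intervals <- function(mask, min_len = 1L, genome_id = "ref") {
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  mapply(function(s, e) genomic_interval(genome_id, s, e),
         starts[keep], ends[keep], SIMPLIFY = FALSE)
}

# Best match identity of each reference fragment against one query:
# max over overlapping segments of identity * (overlap / fragment length).
.fragment_identities <- function(contig_len, frag_starts, frag_ends, segs) {
  best <- rep(0, length(frag_starts))
  for (i in seq_len(nrow(segs))) {
    s <- segs$ref_start[i]; e <- segs$ref_end[i]
    ov_start <- pmax(frag_starts, s)
    ov_end <- pmin(frag_ends, e)
    ov <- pmax(0L, ov_end - ov_start)
    sc <- segs$identity[i] * ov / (frag_ends - frag_starts)
    best <- pmax(best, sc)
  }
  best
}

#' Endpoint-mode novel regions
#'
#' The reference is split into `fragment_size` fragments; a fragment is
#' novel when the number of genomes containing it (reference included,
#' queries counted at identity >= `identity_cutoff`) is below
#' `core_threshold`. Adjacent novel fragments are merged and merged
#' regions shorter than `min_novel_size` are dropped. Fragment identity
#' against a query is the best overlapping chained-match identity scaled
#' by its fragment coverage (an unmatched fragment scores 0).
#'
#' @param reference,queries Genomes as in [shared_coverage_mask()].
#' @param cfg An [endpoint_config()].
#' @param params A [match_params()] used by the underlying match engine.
#' @return List of `unique_region` objects.
#' @export
novel_regions_endpoint <- function(reference, queries,
                                   cfg = endpoint_config(),
                                   params = match_params()) {
  reference <- as_genome(reference)
  if (length(queries) == 0L) stop("novel_regions_endpoint: need >= 1 query genome")
  out <- list()
  for (contig in reference) {
    len <- nchar(contig$seq)
    frag_starts <- seq(0L, len - 1L, by = cfg$fragment_size)
    frag_ends <- pmin(frag_starts + cfg$fragment_size, len)
    present_in <- rep(1L, length(frag_starts))  # the reference itself
    for (q in queries) {
      qbest <- rep(0, length(frag_starts))
      for (qc in as_genome(q)) {
        segs <- chain_matches(contig$seq, qc$seq, params)
        if (nrow(segs)) {
          qbest <- pmax(qbest, .fragment_identities(len, frag_starts,
                                                    frag_ends, segs))
        }
      }
      present_in <- present_in + (qbest >= cfg$identity_cutoff)
    }
    novel <- present_in < cfg$core_threshold
    r <- rle(novel)
    ie <- cumsum(r$lengths); is <- ie - r$lengths + 1L
    for (j in which(r$values)) {
      s <- frag_starts[is[j]]; e <- frag_ends[ie[j]]
      if (e - s >= cfg$min_novel_size) {
        iv <- genomic_interval(contig$id, s, e)
        out[[length(out) + 1L]] <- .unique_region(iv, interval_seq(contig, iv))
      }
    }
  }
  out
}

#' qPCR-mode unique sequences
#'
#' Extracts uncovered runs of the [shared_coverage_mask()], tiles runs
#' longer than `max_len` into non-overlapping `max_len` windows (a
#' trailing window shorter than `min_len` is dropped), and keeps windows
#' whose length and GC content fall inside the filter bounds.
#'
#' @param reference,queries Genomes as in [shared_coverage_mask()].
#' @param params A [match_params()].
#' @param filt A [qpcr_region_filter()].
#' @return List of `unique_region` objects, sorted by position.
#' @export
unique_seqs_qpcr <- function(reference, queries, params = match_params(),
                             filt = qpcr_region_filter()) {
  reference <- as_genome(reference)
  if (length(queries) == 0L) stop("unique_seqs_qpcr: need >= 1 query genome")
  masks <- shared_coverage_mask(reference, queries, params)
  out <- list()
  for (contig in reference) {
    runs <- uncovered_intervals(masks[[contig$id]], filt$min_len, contig$id)
    for (run in runs) {
      if (run$end - run$start <= filt$max_len) {
        windows <- list(run)
      } else {
        ws <- seq(run$start, run$end - filt$min_len, by = filt$max_len)
        we <- pmin(ws + filt$max_len, run$end)
        keep <- we - ws >= filt$min_len
        windows <- mapply(function(s, e) genomic_interval(contig$id, s, e),
                          ws[keep], we[keep], SIMPLIFY = FALSE)
      }
      for (w in windows) {
        s <- interval_seq(contig, w)
        gc <- gc_fraction(s)
        if (gc >= filt$gc_min && gc <= filt$gc_max) {
          out[[length(out) + 1L]] <- .unique_region(w, s)
        }
      }
    }
  }
  out
}

#' Confirm uniqueness against a background sequence collection
#'
#' Annotates each region with its best off-target score against a local
#' background collection (a user-supplied stand-in for a nucleotide
#' database search): for each background record the chained local matches
#' are summarized as mean segment identity weighted by region coverage,
#' and the region score is the maximum over records
#' (identity x coverage, in percent; 0 = no hit, 100 = verbatim present).
#' Regions come back sorted ascending by score, most unique first.
#'
#' @param regions List of `unique_region`s.
#' @param background List of [genome_record]s (may be empty: scores are 0
#'   and a warning is raised).
#' @param params A [match_params()]; identity threshold is relaxed to the
#'   engine floor so weak off-target hits still score.
#' @return The regions, annotated and re-ordered.
#' @export
confirm_uniqueness <- function(regions, background, params = match_params()) {
  if (length(regions) == 0L) return(regions)
  if (length(background) == 0L) {
    warning("confirm_uniqueness: empty background; off-target scores set to 0")
    regions <- lapply(regions, function(r) { r$max_offtarget_identity <- 0; r })
    return(regions)
  }
  background <- as_genome(background)
  scored <- lapply(regions, function(r) {
    len <- nchar(r$seq)
    best <- 0
    for (b in background) {
      segs <- chain_matches(r$seq, b$seq, params)
      if (!nrow(segs)) next
      cov_pos <- rep(FALSE, len)
      for (i in seq_len(nrow(segs))) {
        cov_pos[(segs$ref_start[i] + 1L):segs$ref_end[i]] <- TRUE
      }
      coverage <- mean(cov_pos)
      w_ident <- sum(segs$identity * segs$length) / sum(segs$length)
      best <- max(best, w_ident * coverage)
    }
    r$max_offtarget_identity <- best
    r
  })
  ord <- order(vapply(scored, `[[`, 0, "max_offtarget_identity"),
               vapply(scored, function(r) r$interval$start, 0L))
  scored[ord]
}

#' Tabulate unique regions
#'
#' @param regions List of `unique_region`s.
#' @return data.frame with 1-based inclusive coordinates for human reading
#'   (BED/FASTA output keep 0-based half-open).
#' @export
unique_region_table <- function(regions) {
  data.frame(
    genome_id = vapply(regions, function(r) r$interval$genome_id, ""),
    start1 = vapply(regions, function(r) r$interval$start + 1L, 0L),
    end1 = vapply(regions, function(r) r$interval$end, 0L),
    length = vapply(regions, function(r) nchar(r$seq), 0L),
    gc = vapply(regions, `[[`, 0, "gc"),
    max_offtarget_identity = vapply(regions, function(r)
      if (is.na(r$max_offtarget_identity)) NA_real_ else r$max_offtarget_identity, 0),
    stringsAsFactors = FALSE
  )
}
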