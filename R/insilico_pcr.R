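# In silico PCR: primer binding-site scanning with a 3'-end mismatch rule,
# amplicon enumeration, specificity reports, and predicted RISA
# fingerprints.
#
# The specificity rule mirrors the published screening criterion for
# unintended targets: a binding site is considered NON-functional only
# when it has at least `reject_if_total_ge` total mismatches AND at least
# `reject_if_3p_ge` mismatches within the primer's last 3 bases at the 3'
# end; any site with more than `max_mismatch_per_primer` total mismatches
# is outside the scan entirely.

#' Amplification rule for in silico PCR
#'
#' @param max_mismatch_per_primer Scan cap on total mismatches (default 4).
#' @param reject_if_total_ge Sites with at least this many total
#'   mismatches AND at least `reject_if_3p_ge` mismatches in the 3'
#'   last-3 window are non-functional (defaults 5 and 2).
#' @param reject_if_3p_ge See above.
#' @param max_product Maximum product length screened (default 4000 bp;
#'   the 100-200 bp design window applies only to candidate generation).
#' @return List of class `amplification_rule`.
#' @export
amplification_rule <- function(max_mismatch_per_primer = 4L,
                               reject_if_total_ge = 5L,
                               reject_if_3p_ge = 2L,
                               max_product = 4000L) {
  stopifnot(max_mismatch_per_primer >= 0L, reject_if_total_ge >= 0L,
            reject_if_3p_ge >= 0L, max_product >= 1L)
  structure(list(max_mismatch_per_primer = as.integer(max_mismatch_per_primer),
                 reject_if_total_ge = as.integer(reject_if_total_ge),
                 reject_if_3p_ge = as.integer(reject_if_3p_ge),
                 max_product = as.integer(max_product)),
            class = "amplification_rule")
}

#' Stringent rule for reference amplicon counting (0 mismatches)
#' @rdname amplification_rule
#' @export
perfect_match_rule <- function(max_product = 4000L) {
  amplification_rule(max_mismatch_per_primer = 0L, max_product = max_product)
}

# Mismatch details of `primer` (IUPAC-aware) against `text` at footprints
# given by 1-based starts; returns total and last3 (text read 5'->3' in
# primer orientation).
.mismatch_details <- function(pv, tv, starts) {
  plen <- length(pv)
  total <- integer(length(starts))
  last3 <- integer(length(starts))
  for (j in seq_len(plen)) {
    mm <- bitwAnd(pv[j], tv[starts + j - 1L]) == 0L
    total <- total + mm
    if (j > plen - 3L) last3 <- last3 + mm
  }
  list(total = total, last3 = last3)
}

#' Find primer binding sites on a genome record
#'
#' Scans both strands. A `+` site means the primer sequence itself
#' matches the plus-strand text (the primer anneals to the minus strand
#' and extends rightward); a `-` site means the reverse complement of the
#' primer matches the plus-strand text. Mismatches are counted
#' IUPAC-aware in primer orientation; the 3' window is the primer's own
#' last 3 bases as hybridized. Sites are kept when
#' `total <= max_mismatch_per_primer` and NOT
#' (`total >= reject_if_total_ge` AND `last3 >= reject_if_3p_ge`).
#'
#' @param primer Oligo sequence, length >= 10.
#' @param genome_rec A [genome_record] (single contig).
#' @param rule An [amplification_rule()].
#' @return data.frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open footprint), `strand`, `mismatch_total`, `mismatch_3p_last3`.
#' @export
find_binding_sites <- function(primer, genome_rec, rule = amplification_rule()) {
  primer <- .normalize_seq(primer)
  if (nchar(primer) < 10L) stop("find_binding_sites: primer shorter than 10 bases")
  genome_rec <- as_genome(genome_rec)[[1]]
  plen <- nchar(primer)
  glen <- nchar(genome_rec$seq)
  empty <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatch_total = integer(0),
                      mismatch_3p_last3 = integer(0))
  if (plen > glen) return(empty)
  subject <- Biostrings::DNAString(genome_rec$seq)
  tv <- encode_iupac(genome_rec$seq)
  out <- list()
  for (strand in c("+", "-")) {
    patt <- if (strand == "+") primer else reverse_complement(primer)
    m <- Biostrings::matchPattern(patt, subject,
                                  max.mismatch = rule$max_mismatch_per_primer,
                                  fixed = FALSE)
    starts <- Biostrings::start(m)
    # drop edge hits whose footprint hangs off the subject (overhang
    # positions would otherwise be counted as mismatches)
    starts <- starts[starts >= 1L & starts + plen - 1L <= glen]
    if (!length(starts)) next
    # exact counts in primer orientation: for '-' sites the hybridized
    # template window is the revcomp of the plus-strand slice, so compare
    # the primer against the reversed, complemented window. Equivalent:
    # compare revcomp(primer) to the window and count its FIRST 3 bases
    # as the primer's 3' last-3.
    pv <- encode_iupac(patt)
    det <- .mismatch_details(pv, tv, starts)
    if (strand == "-") {
      l3 <- integer(length(starts))
      for (j in 1:3) {
        mm <- bitwAnd(pv[j], tv[starts + j - 1L]) == 0L
        l3 <- l3 + mm
      }
      det$last3 <- l3
    }
    functional <- det$total <= rule$max_mismatch_per_primer &
      !(det$total >= rule$reject_if_total_ge &
          det$last3 >= rule$reject_if_3p_ge)
    if (!any(functional)) next
    out[[strand]] <- data.frame(
      genome_id = genome_rec$id,
      start = starts[functional] - 1L,
      end = starts[functional] - 1L + plen,
      strand = strand,
      mismatch_total = det$total[functional],
      mismatch_3p_last3 = det$last3[functional],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res[order(res$start), , drop = FALSE]
}

#' Enumerate amplicons from forward/reverse binding-site lists
#'
#' Every convergent combination — one site on `+`, one on `-`, the `+`
#' footprint strictly 5' of (non-overlapping) the `-` footprint — with
#' product length at most `rule$max_product`. Either primer may supply
#' either site role. Product length is measured from the `+` footprint
#' start to the `-` footprint end (primer footprints included).
#'
#' @param fwd_sites,rev_sites Site data.frames from
#'   [find_binding_sites()] for the forward and reverse primer on the
#'   same genome.
#' @param rule An [amplification_rule()].
#' @return data.frame with columns `genome_id`, `start`, `end`, `length`,
#'   plus mismatch totals of the two sites.
#' @export
enumerate_amplicons <- function(fwd_sites, rev_sites,
                                rule = amplification_rule()) {
  empty <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      plus_mismatch = integer(0), minus_mismatch = integer(0))
  combos <- list()
  pair_up <- function(plus, minus) {
    if (!nrow(plus) || !nrow(minus)) return(NULL)
    g <- expand.grid(p = seq_len(nrow(plus)), m = seq_len(nrow(minus)))
    len <- minus$end[g$m] - plus$start[g$p]
    ok <- minus$start[g$m] >= plus$end[g$p] & len <= rule$max_product
    if (!any(ok)) return(NULL)
    data.frame(genome_id = plus$genome_id[g$p][ok],
               start = plus$start[g$p][ok],
               end = minus$end[g$m][ok],
               length = as.integer(len[ok]),
               plus_mismatch = plus$mismatch_total[g$p][ok],
               minus_mismatch = minus$mismatch_total[g$m][ok],
               stringsAsFactors = FALSE)
  }
  combos[[1]] <- pair_up(fwd_sites[fwd_sites$strand == "+", , drop = FALSE],
                         rev_sites[rev_sites$strand == "-", , drop = FALSE])
  combos[[2]] <- pair_up(rev_sites[rev_sites$strand == "+", , drop = FALSE],
                         fwd_sites[fwd_sites$strand == "-", , drop = FALSE])
  res <- do.call(rbind, combos)
  if (is.null(res) || !nrow(res)) return(empty)
  res <- unique(res)
  rownames(res) <- NULL
  res[order(res$start, res$end), , drop = FALSE]
}

#' Amplicons of a primer pair on a (multi-contig) genome
#'
#' @param fwd_primer,rev_primer Primer sequences.
#' @param genome Genome ([as_genome()]-coercible).
#' @param rule An [amplification_rule()].
#' @return Combined amplicon data.frame over all contigs.
#' @export
pcr_amplicons <- function(fwd_primer, rev_primer, genome,
                          rule = amplification_rule()) {
  genome <- as_genome(genome)
  out <- lapply(genome, function(contig) {
    enumerate_amplicons(find_binding_sites(fwd_primer, contig, rule),
                        find_binding_sites(rev_primer, contig, rule),
                        rule)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Specificity report for a primer pair
#'
#' Counts amplicons in the reference genome under a stringent rule
#' (perfect match by default, so "1 reference amplicon" means one perfect
#' product) and in each query genome under the permissive
#' unintended-target rule.
#'
#' @param fwd_primer,rev_primer Primer sequences.
#' @param reference Reference genome.
#' @param queries Named list of query genomes (names used as genome ids
#'   in the report; unnamed lists are numbered).
#' @param rule Permissive [amplification_rule()] for queries.
#' @param reference_rule Stringent rule for the reference (default
#'   [perfect_match_rule()]).
#' @return List of class `specificity_report` with fields
#'   `reference_amplicons`, `nontarget_counts` (named integer vector) and
#'   `total_nontarget`.
#' @export
specificity_report <- function(fwd_primer, rev_primer, reference, queries,
                               rule = amplification_rule(),
                               reference_rule = perfect_match_rule()) {
  ref_n <- nrow(pcr_amplicons(fwd_primer, rev_primer, reference,
                              reference_rule))
  if (is.null(names(queries)) && length(queries)) {
    names(queries) <- paste0("query", seq_along(queries))
  }
  counts <- vapply(queries, function(q) {
    nrow(pcr_amplicons(fwd_primer, rev_primer, q, rule))
  }, 0L)
  structure(list(reference_amplicons = ref_n,
                 nontarget_counts = counts,
                 total_nontarget = sum(counts)),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("<specificity_report> reference=%d non-target=%d (%s)\n",
              x$reference_amplicons, x$total_nontarget,
              paste(names(x$nontarget_counts), x$nontarget_counts,
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Predicted RISA fingerprint of a genome
#'
#' Runs in silico PCR with the supplied spacer-flanking primers (e.g. a
#' 16S 3'-end forward primer and a 23S 5'-end reverse primer) and returns
#' the deduplicated sorted amplicon lengths — the predicted
#' electrophoretic banding pattern.
#'
#' @param genome Genome ([as_genome()]-coercible).
#' @param fwd_primer,rev_primer RISA primer sequences (user-supplied).
#' @param rule An [amplification_rule()].
#' @return Sorted integer vector of distinct amplicon lengths (empty when
#'   the genome has no primer sites).
#' @export
risa_profile <- function(genome, fwd_primer, rev_primer,
                         rule = amplification_rule()) {
  amps <- pcr_amplicons(fwd_primer, rev_primer, genome, rule)
  sort(unique(amps$length))
}
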