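# Seed-and-extend ungapped matching between two sequences.
#
# Exact k-mer seeds shared between reference and query are grouped by
# diagonal (ref offset - query offset), chained when consecutive seeds on a
# diagonal are close, and the chained segments are extended outward base by
# base under an X-drop rule (match +1, mismatch -1, stop when the running
# score falls `xdrop` below its maximum). Segments are kept when their
# ungapped identity and length clear the thresholds in `match_params()`.
# This is the native stand-in for a whole-genome aligner in the
# unique-region subtraction step: indels break diagonals, so diverged
# regions simply fall into several shorter segments.

#' Matching parameters for the seed-and-extend engine
#'
#' @param seed_k Exact k-mer seed length (>= 11).
#' @param min_match_identity Minimum ungapped percent identity for a
#'   segment to count as a match (default 85, mirroring the 85% identity
#'   cutoff used for genome subtraction).
#' @param min_anchor_len Minimum segment length in bases (default 31).
#' @param chain_gap Maximum gap between consecutive seeds on one diagonal
#'   that is bridged into the same segment.
#' @param xdrop X-drop threshold for end extension.
#' @return List of class `match_params`.
#' @export
match_params <- function(seed_k = 15L, min_match_identity = 85,
                         min_anchor_len = 31L, chain_gap = 150L,
                         xdrop = 10L) {
  stopifnot(seed_k >= 11L, min_match_identity > 0, min_match_identity <= 100,
            min_anchor_len >= 1L)
  structure(list(seed_k = as.integer(seed_k),
                 min_match_identity = min_match_identity,
                 min_anchor_len = as.integer(min_anchor_len),
                 chain_gap = as.integer(chain_gap),
                 xdrop = as.integer(xdrop)),
            class = "match_params")
}

# k-mer codes at every start position (length L - k + 1); NA where the
# window contains a non-ACGT base.
.kmer_codes <- function(codes2bit, k) {
  L <- length(codes2bit)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  out <- numeric(n)
  for (j in seq_len(k)) {
    out <- out * 4 + codes2bit[j:(n + j - 1L)]
  }
  out
}

# Extend from segment edges: given logical match vector ordered from the
# segment edge outward, return how many positions to extend (prefix ending
# at the maximum cumulative score, subject to X-drop).
.xdrop_extend <- function(match_vec, xdrop) {
  if (length(match_vec) == 0L) return(0L)
  sc <- cumsum(ifelse(match_vec, 1L, -1L))
  run_max <- cummax(sc)
  stop_at <- which(run_max - sc >= xdrop)
  lim <- if (length(stop_at)) stop_at[1] - 1L else length(sc)
  if (lim == 0L) return(0L)
  which.max(sc[seq_len(lim)])
}

# Ungapped matched segments of `query` against `ref` on one strand.
# Returns data.frame(ref_start, ref_end, q_start, q_end, identity, length)
# with 0-based half-open ref coordinates.
.chain_one_strand <- function(ref2, q2, params) {
  k <- params$seed_k
  rk <- .kmer_codes(ref2, k)
  qk <- .kmer_codes(q2, k)
  if (!length(rk) || !length(qk)) return(.empty_segments())
  m <- match(rk, qk)                 # first query hit per ref seed
  idx <- which(!is.na(m))
  if (!length(idx)) return(.empty_segments())
  diag <- idx - m[idx]
  ord <- order(diag, idx)
  idx <- idx[ord]; diag <- diag[ord]
  new_seg <- c(TRUE, diff(diag) != 0L | diff(idx) > params$chain_gap)
  seg_id <- cumsum(new_seg)
  starts <- tapply(idx, seg_id, min)
  ends <- tapply(idx, seg_id, max)
  diags <- tapply(diag, seg_id, `[`, 1L)

  out <- vector("list", length(starts))
  E <- 200L  # max end-extension probe
  for (s in seq_along(starts)) {
    rs <- starts[[s]]; re <- ends[[s]] + k - 1L   # 1-based ref span
    d <- diags[[s]]
    qs <- rs - d; qe <- re - d
    # left extension
    nleft <- min(E, rs - 1L, qs - 1L)
    if (nleft > 0L) {
      rr <- ref2[(rs - 1L):(rs - nleft)]
      qq <- q2[(qs - 1L):(qs - nleft)]
      ext <- .xdrop_extend(!is.na(rr) & !is.na(qq) & rr == qq, params$xdrop)
      rs <- rs - ext; qs <- qs - ext
    }
    # right extension
    nright <- min(E, length(ref2) - re, length(q2) - qe)
    if (nright > 0L) {
      rr <- ref2[(re + 1L):(re + nright)]
      qq <- q2[(qe + 1L):(qe + nright)]
      ext <- .xdrop_extend(!is.na(rr) & !is.na(qq) & rr == qq, params$xdrop)
      re <- re + ext; qe <- qe + ext
    }
    rr <- ref2[rs:re]; qq <- q2[qs:qe]
    nmatch <- sum(!is.na(rr) & !is.na(qq) & rr == qq)
    len <- re - rs + 1L
    out[[s]] <- c(rs - 1L, re, qs - 1L, qe, 100 * nmatch / len, len)
  }
  res <- do.call(rbind, out)
  res <- as.data.frame(res)
  names(res) <- c("ref_start", "ref_end", "q_start", "q_end", "identity", "length")
  res[res$identity >= params$min_match_identity &
        res$length >= params$min_anchor_len, , drop = FALSE]
}

.empty_segments <- function() {
  data.frame(ref_start = integer(0), ref_end = integer(0),
             q_start = integer(0), q_end = integer(0),
             identity = numeric(0), length = integer(0))
}

#' Ungapped matched segments between a reference contig and a query contig
#'
#' Runs the seed-and-extend engine on both query strands. Coordinates are
#' 0-based half-open on the reference; `strand` gives the query strand of
#' the match (query coordinates for `-` refer to the reverse-complemented
#' query).
#'
#' @param ref_seq,query_seq Nucleotide strings.
#' @param params A [match_params()] object.
#' @return data.frame with columns `ref_start`, `ref_end`, `q_start`,
#'   `q_end`, `identity`, `length`, `strand`.
#' @export
chain_matches <- function(ref_seq, query_seq, params = match_params()) {
  ref2 <- encode_acgt(ref_seq)
  fw <- .chain_one_strand(ref2, encode_acgt(query_seq), params)
  rv <- .chain_one_strand(ref2, encode_acgt(reverse_complement(query_seq)), params)
  if (nrow(fw)) fw$strand <- "+"
  if (nrow(rv)) rv$strand <- "-"
  out <- rbind(fw, rv)
  if (!nrow(out)) out$strand <- character(0)
  out[order(out$ref_start), , drop = FALSE]
}
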