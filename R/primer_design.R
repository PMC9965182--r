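# Primer candidate enumeration and pair design inside unique regions.
#
# Melting temperatures use the unified nearest-neighbor thermodynamic
# parameter set (SantaLucia 1998) at 50 mM monovalent salt and 50 nM total
# oligo — the regime most design tools default to. Suitability screening
# mirrors the usual PCR primer checks: homopolymer runs, short-unit
# repeats, 3' GC clamp, and self-complementarity.

# Unified NN parameters: dH in kcal/mol, dS in cal/(mol K), 5'->3' stacks.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)
# Duplex initiation per terminal base pair.
.NN_INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.NN_INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor dH/dS sum with terminal initiation terms, the
#' entropic monovalent-salt correction `dS + 0.368 * N_stacks * ln[Na+]`,
#' and `Tm = 1000 * dH / (dS_salt + R * ln(C_T / 4)) - 273.15` for
#' non-self-complementary oligos (divisor 1 and a symmetry entropy term
#' for self-complementary ones). Deterministic to well below 0.01 degC.
#'
#' @param primer Unambiguous A/C/G/T sequence, length >= 8.
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Total oligo concentration in nM (default 50).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(primer, na_mM = 50, oligo_nM = 50) {
  primer <- .normalize_seq(primer)
  if (nchar(primer) < 8L) stop("melting_temp: primer shorter than 8 bases")
  if (grepl("[^ACGT]", primer)) {
    stop("melting_temp: ambiguous base in primer '", primer, "'")
  }
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  n <- length(chars)
  stacks <- paste0(chars[-n], chars[-1])
  dH <- sum(.NN_DH[stacks]) + .NN_INIT_DH[[chars[1]]] + .NN_INIT_DH[[chars[n]]]
  dS <- sum(.NN_DS[stacks]) + .NN_INIT_DS[[chars[1]]] + .NN_INIT_DS[[chars[n]]]
  selfcomp <- identical(primer, reverse_complement(primer))
  if (selfcomp) dS <- dS - 1.4
  dS_salt <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  x <- if (selfcomp) 1 else 4
  1000 * dH / (dS_salt + 1.987 * log(ct / x)) - 273.15
}

# Longest run of a repeated unit of length `unit` (in units, not bases).
.max_repeat_units <- function(chars, unit) {
  n <- length(chars)
  if (n < 2 * unit) return(1L)
  same <- chars[seq_len(n - unit)] == chars[(unit + 1):n]
  r <- rle(same)
  best <- 0L
  runs <- r$lengths[r$values]
  if (length(runs)) best <- max(runs)
  # a run of L consecutive period-`unit` agreements spans L + unit bases
  as.integer((best + unit) %/% unit)
}

#' Pair/self complementarity scores
#'
#' `any_score` is the best ungapped complementary alignment score of `a`
#' against `b` over all relative offsets: at each offset the aligned
#' positions score +1 when complementary and -1 otherwise, and the best
#' contiguous stretch (floored at 0) is taken. `3p_score` is the same
#' restricted to stretches that include `a`'s 3'-terminal base.
#' `any_score` is symmetric in its arguments.
#'
#' @param a,b Oligo sequences (the two primers of a pair, or the same
#'   primer twice for self-complementarity).
#' @return Named numeric vector `c(any_score, p3_score)`.
#' @export
complementarity_scores <- function(a, b) {
  av <- encode_iupac(a)
  # b read 3'->5' against a 5'->3': complement of reversed b
  bv <- encode_iupac(reverse_complement(b))
  # after reverse_complement, bv[i] pairs a's position i at zero offset;
  # complementarity of a[i] with original b base = match of a[i] vs bv[j]
  na <- length(av); nb <- length(bv)
  best_any <- 0L; best_3p <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    i1 <- max(1L, 1L + off); i2 <- min(na, nb + off)
    if (i2 < i1) next
    ai <- av[i1:i2]; bi <- bv[(i1 - off):(i2 - off)]
    sc <- ifelse(bitwAnd(ai, bi) > 0L, 1L, -1L)
    # Kadane with floor 0
    run <- 0L
    ends_at <- integer(length(sc))
    for (k in seq_along(sc)) {
      run <- max(0L, run + sc[k])
      ends_at[k] <- run
    }
    best_any <- max(best_any, max(ends_at))
    if (i2 == na) {
      # best stretch ending exactly at a's 3' terminus
      best_3p <- max(best_3p, ends_at[length(ends_at)])
    }
  }
  c(any_score = best_any, p3_score = best_3p)
}

#' Primer suitability statistics
#'
#' Reports the classic PCR-suitability checks: maximum homopolymer run,
#' 3' GC clamp (at least one of the last two bases is G/C), longest
#' short-unit repeat (units of 2-4 bases, reported in units), and
#' self-complementarity scores. `pass` is TRUE when max homopolymer run
#' <= 4, no 2-4-base unit repeats more than 4 times, self any-score <= 8
#' and self 3'-score <= 3 (thresholds configurable).
#'
#' @param primer Oligo sequence, length >= 10.
#' @param max_run Homopolymer-run threshold.
#' @param max_repeat Repeat-unit threshold.
#' @param max_self_any,max_self_3p Self-complementarity thresholds.
#' @return List of class `suitability_report`.
#' @export
primer_stats <- function(primer, max_run = 4L, max_repeat = 4L,
                         max_self_any = 8L, max_self_3p = 3L) {
  primer <- .normalize_seq(primer)
  if (nchar(primer) < 10L) stop("primer_stats: primer shorter than 10 bases")
  chars <- strsplit(primer, "", fixed = TRUE)[[1]]
  run <- max(rle(chars)$lengths)
  clamp <- any(chars[(length(chars) - 1):length(chars)] %in% c("G", "C"))
  rep_units <- max(vapply(2:4, function(u) .max_repeat_units(chars, u), 0L))
  self <- complementarity_scores(primer, primer)
  pass <- run <= max_run && rep_units <= max_repeat &&
    self[["any_score"]] <= max_self_any && self[["p3_score"]] <= max_self_3p
  structure(list(max_homopolymer_run = run,
                 has_gc_clamp = clamp,
                 self_any_score = unname(self[["any_score"]]),
                 self_3p_score = unname(self[["p3_score"]]),
                 dinucleotide_repeat_len = rep_units,
                 pass = pass),
            class = "suitability_report")
}

#' Primer design constraints
#'
#' Two presets mirror the published settings:
#' [endpoint_constraints()] (size 18/20/25, Tm 57/60/63, GC 40-60%) for
#' endpoint PCR, and [qpcr_constraints()] (size 18/22/26, GC 40-60%,
#' product 100-200 bp, 500 pairs returned) for real-time PCR. The qPCR
#' preset carries no published Tm bounds; the endpoint bounds (57-63)
#' are applied there by default.
#'
#' @param len_min,len_opt,len_max Primer length bounds/optimum (bases).
#' @param tm_min,tm_opt,tm_max Melting-temperature bounds/optimum (degC);
#'   `NA` disables Tm filtering.
#' @param gc_min,gc_max GC-fraction bounds.
#' @param product_min,product_max Product-size bounds (bases).
#' @param max_candidates Cap on ranked primer pairs returned.
#' @param max_candidates_per_strand Cap on single-strand candidates kept
#'   (by ascending candidate penalty) before pairing.
#' @return List of class `design_constraints`.
#' @export
design_constraints <- function(len_min = 18L, len_opt = 20L, len_max = 25L,
                               tm_min = 57, tm_opt = 60, tm_max = 63,
                               gc_min = 0.40, gc_max = 0.60,
                               product_min = 100L, product_max = 200L,
                               max_candidates = 500L,
                               max_candidates_per_strand = 200L) {
  stopifnot(len_min <= len_opt, len_opt <= len_max,
            gc_min <= gc_max, product_min <= product_max)
  if (!is.na(tm_min)) stopifnot(tm_min <= tm_opt, tm_opt <= tm_max)
  structure(list(len_min = as.integer(len_min), len_opt = as.integer(len_opt),
                 len_max = as.integer(len_max),
                 tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max,
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 max_candidates = as.integer(max_candidates),
                 max_candidates_per_strand = as.integer(max_candidates_per_strand)),
            class = "design_constraints")
}

#' @rdname design_constraints
#' @export
endpoint_constraints <- function() {
  design_constraints(len_min = 18L, len_opt = 20L, len_max = 25L,
                     tm_min = 57, tm_opt = 60, tm_max = 63,
                     gc_min = 0.40, gc_max = 0.60)
}

#' @rdname design_constraints
#' @export
qpcr_constraints <- function() {
  design_constraints(len_min = 18L, len_opt = 22L, len_max = 26L,
                     tm_min = 57, tm_opt = 60, tm_max = 63,
                     gc_min = 0.40, gc_max = 0.60,
                     product_min = 100L, product_max = 200L,
                     max_candidates = 500L)
}

# Penalty of a lone candidate: Tm deviation + 0.25 * length deviation.
.candidate_penalty <- function(tm, len, constraints) {
  p <- 0.25 * abs(len - constraints$len_opt)
  if (!is.na(constraints$tm_opt)) p <- p + abs(tm - constraints$tm_opt)
  p
}

#' Enumerate primer candidates within a region
#'
#' Every substring of the region (both strands) whose length, GC content
#' and melting temperature fall inside the constraints and whose
#' [primer_stats()] pass, capped at `max_candidates_per_strand` per strand
#' by ascending candidate penalty (Tm and length deviation from optimum).
#'
#' @param region A `unique_region` (or any object with `$seq`), or a
#'   plain character sequence.
#' @param constraints A [design_constraints()].
#' @return data.frame with columns `seq`, `region_offset` (0-based
#'   leftmost template coordinate of the footprint, both strands),
#'   `strand`, `length`, `gc`, `tm`, `self_any`, `self_3p`, `penalty`.
#' @export
enumerate_candidates <- function(region, constraints = qpcr_constraints()) {
  seq <- if (is.character(region)) region else region$seq
  seq <- .normalize_seq(seq)
  L <- nchar(seq)
  if (L < constraints$len_min) {
    stop("enumerate_candidates: region shorter than len_min")
  }
  rows <- list()
  for (strand in c("+", "-")) {
    txt <- if (strand == "+") seq else reverse_complement(seq)
    strand_rows <- list()
    for (len in constraints$len_min:min(constraints$len_max, L)) {
      for (off in 0:(L - len)) {
        cand <- substr(txt, off + 1L, off + len)
        if (grepl("[^ACGT]", cand)) next
        gc <- gc_fraction(cand)
        if (gc < constraints$gc_min || gc > constraints$gc_max) next
        tm <- melting_temp(cand)
        if (!is.na(constraints$tm_min) &&
            (tm < constraints$tm_min || tm > constraints$tm_max)) next
        st <- primer_stats(cand)
        if (!st$pass) next
        region_offset <- if (strand == "+") off else L - off - len
        strand_rows[[length(strand_rows) + 1L]] <- data.frame(
          seq = cand, region_offset = region_offset, strand = strand,
          length = len, gc = gc, tm = tm,
          self_any = st$self_any_score, self_3p = st$self_3p_score,
          penalty = .candidate_penalty(tm, len, constraints),
          stringsAsFactors = FALSE)
      }
    }
    if (length(strand_rows)) {
      df <- do.call(rbind, strand_rows)
      df <- df[order(df$penalty, df$region_offset, df$length), , drop = FALSE]
      rows[[strand]] <- head(df, constraints$max_candidates_per_strand)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    seq = character(0), region_offset = integer(0), strand = character(0),
    length = integer(0), gc = numeric(0), tm = numeric(0),
    self_any = integer(0), self_3p = integer(0), penalty = numeric(0))
  rownames(out) <- NULL
  out
}

#' Design ranked primer pairs within a region
#'
#' Pairs every plus-strand candidate (forward primer) with every
#' minus-strand candidate lying 3' of it (reverse primer) whose product
#' length falls in the constraint bounds. Pair penalty is
#' `1.0 * |Tm_f - Tm_r| + 0.5 * pair_any + 1.0 * pair_3p +
#' 0.25 * (|len_f - len_opt| + |len_r - len_opt|)`; pairs come back
#' sorted ascending by penalty (ties broken by forward then reverse
#' offset) and truncated to `max_candidates`.
#'
#' @param region A `unique_region` or character sequence.
#' @param constraints A [design_constraints()].
#' @param w_tm,w_any,w_3p,w_len Penalty weights.
#' @return data.frame with one row per pair: `fwd_seq`, `rev_seq`,
#'   forward/reverse offsets, Tms, `product_len`, `pair_any`, `pair_3p`,
#'   `penalty`.
#' @export
design_pairs <- function(region, constraints = qpcr_constraints(),
                         w_tm = 1.0, w_any = 0.5, w_3p = 1.0, w_len = 0.25) {
  seq <- if (is.character(region)) region else region$seq
  L <- nchar(seq)
  empty <- data.frame(fwd_seq = character(0), rev_seq = character(0),
                      fwd_offset = integer(0), rev_offset = integer(0),
                      fwd_tm = numeric(0), rev_tm = numeric(0),
                      product_len = integer(0), pair_any = integer(0),
                      pair_3p = integer(0), penalty = numeric(0))
  if (L < constraints$product_min) return(empty)
  cands <- enumerate_candidates(region, constraints)
  fwd <- cands[cands$strand == "+", , drop = FALSE]
  rvs <- cands[cands$strand == "-", , drop = FALSE]
  if (!nrow(fwd) || !nrow(rvs)) return(empty)
  # product spans fwd 5' end .. rev primer 5' end (= its footprint's
  # right edge, region_offset + length)
  rvs$foot_end <- rvs$region_offset + rvs$length
  combos <- expand.grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rvs)))
  plen <- rvs$foot_end[combos$ri] - fwd$region_offset[combos$fi]
  sep_ok <- rvs$region_offset[combos$ri] >= fwd$region_offset[combos$fi] +
    fwd$length[combos$fi]
  keep <- plen >= constraints$product_min & plen <= constraints$product_max & sep_ok
  combos <- combos[keep, , drop = FALSE]
  plen <- plen[keep]
  if (!nrow(combos)) return(empty)
  # pair complementarity per distinct sequence pair
  key <- paste(fwd$seq[combos$fi], rvs$seq[combos$ri])
  ukey <- !duplicated(key)
  sc <- matrix(0L, nrow = sum(ukey), ncol = 2)
  uf <- fwd$seq[combos$fi][ukey]; ur <- rvs$seq[combos$ri][ukey]
  for (i in seq_len(nrow(sc))) sc[i, ] <- complementarity_scores(uf[i], ur[i])
  idx <- match(key, key[ukey])
  pair_any <- sc[idx, 1]; pair_3p <- sc[idx, 2]
  tmf <- fwd$tm[combos$fi]; tmr <- rvs$tm[combos$ri]
  pen <- w_tm * abs(tmf - tmr) + w_any * pair_any + w_3p * pair_3p +
    w_len * (abs(fwd$length[combos$fi] - constraints$len_opt) +
               abs(rvs$length[combos$ri] - constraints$len_opt))
  out <- data.frame(
    fwd_seq = fwd$seq[combos$fi], rev_seq = rvs$seq[combos$ri],
    fwd_offset = fwd$region_offset[combos$fi],
    rev_offset = rvs$region_offset[combos$ri],
    fwd_tm = tmf, rev_tm = tmr,
    product_len = as.integer(plen),
    pair_any = as.integer(pair_any), pair_3p = as.integer(pair_3p),
    penalty = pen, stringsAsFactors = FALSE)
  out <- out[order(out$penalty, out$fwd_offset, out$rev_offset), , drop = FALSE]
  rownames(out) <- NULL
  head(out, constraints$max_candidates)
}
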