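# Independent brute-force oracles used across the suite. These stay
# deliberately naive (per-position loops, full DP matrices) so they share
# no code path with the package implementations they check.

# Random unambiguous sequence.
rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Naive per-character reverse complement over the IUPAC alphabet.
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# Full Needleman-Wunsch DP (match +1, mismatch -1, linear gap -2) with
# traceback; returns percent identity = matches / alignment columns.
oracle_global_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + ifelse(av[i] == bv[j], 1, -1),
                           S[i, j + 1] - 2, S[i + 1, j] - 2)
  }
  i <- n; j <- m; matches <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + ifelse(av[i] == bv[j], 1, -1)) {
      matches <- matches + (av[i] == bv[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  100 * matches / cols
}

# IUPAC match via explicit base sets.
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Pairwise match table computed from the explicit base sets once.
oracle_iupac_table <- local({
  codes <- names(oracle_iupac_sets)
  tab <- matrix(FALSE, length(codes), length(codes),
                dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    tab[a, b] <- any(oracle_iupac_sets[[a]] %in% oracle_iupac_sets[[b]])
  }
  tab
})

# Per-position brute-force binding-site scan: for every footprint on both
# strands count mismatches character by character and apply the rule.
oracle_binding_sites <- function(primer, genome_seq, rule) {
  plen <- nchar(primer); glen <- nchar(genome_seq)
  gchars <- strsplit(genome_seq, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    patt <- if (strand == "+") primer else oracle_revcomp(primer)
    pchars <- strsplit(patt, "")[[1]]
    for (s in 1:(glen - plen + 1)) {
      win <- gchars[s:(s + plen - 1)]
      mm <- !oracle_iupac_table[cbind(pchars, win)]
      total <- sum(mm)
      # primer's own 3' last-3: pattern end for '+', pattern start for '-'
      last3 <- if (strand == "+") sum(mm[(plen - 2):plen]) else sum(mm[1:3])
      functional <- total <= rule$max_mismatch_per_primer &&
        !(total >= rule$reject_if_total_ge && last3 >= rule$reject_if_3p_ge)
      if (functional) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s - 1L, strand = strand, mismatch_total = total,
          mismatch_3p_last3 = last3, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0),
                      mismatch_total = integer(0),
                      mismatch_3p_last3 = integer(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Run-length scan for uncovered intervals.
oracle_uncovered <- function(mask, min_len) {
  res <- list()
  i <- 1; n <- length(mask)
  while (i <= n) {
    if (!mask[i]) {
      j <- i
      while (j < n && !mask[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) res[[length(res) + 1]] <- c(i - 1, j)
      i <- j + 1
    } else i <- i + 1
  }
  res
}

# Brute-force complementarity: try every offset, every sub-stretch.
oracle_complementarity <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])   # b read 3'->5'
  na <- length(av); nb <- length(bv)
  best_any <- 0; best_3p <- 0
  for (off in (-(nb - 1)):(na - 1)) {
    idx <- max(1, 1 + off):min(na, nb + off)
    if (!length(idx)) next
    sc <- ifelse(comp[av[idx]] == bv[idx - off], 1, -1)
    L <- length(sc)
    for (i in 1:L) for (j in i:L) {
      v <- sum(sc[i:j])
      best_any <- max(best_any, v)
      if (idx[j] == na) best_3p <- max(best_3p, v)
    }
  }
  c(any = best_any, p3 = best_3p)
}

# Exhaustive window filter for candidate enumeration (no caps).
oracle_candidates <- function(region_seq, constraints) {
  L <- nchar(region_seq)
  out <- list()
  for (strand in c("+", "-")) {
    txt <- if (strand == "+") region_seq else oracle_revcomp(region_seq)
    for (len in constraints$len_min:min(constraints$len_max, L)) {
      for (off in 0:(L - len)) {
        cand <- substr(txt, off + 1, off + len)
        gc <- strainprimer::gc_fraction(cand)
        if (gc < constraints$gc_min || gc > constraints$gc_max) next
        tm <- strainprimer::melting_temp(cand)
        if (!is.na(constraints$tm_min) &&
            (tm < constraints$tm_min || tm > constraints$tm_max)) next
        if (!strainprimer::primer_stats(cand)$pass) next
        out[[length(out) + 1]] <- cand
      }
    }
  }
  sort(unique(unlist(out)))
}
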