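# Seeded synthetic-data generators: strain panels with a planted unique
# region (exact ground truth for the subtraction pipeline), rrn-operon
# toy genomes for RISA fingerprinting, and simulated qPCR dilution data.
#
# All generators take an explicit seed and restore the caller's RNG
# state, so fixtures are bit-reproducible and never leak randomness.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random genome with a target GC content
#'
#' Bases are i.i.d. with `P(G or C) = gc` (G and C equiprobable, likewise
#' A and T). Deterministic per seed.
#'
#' @param length Genome length (>= 1).
#' @param gc Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param id Record id.
#' @return A [genome_record].
#' @export
random_genome <- function(length, gc = 0.5, seed = 1L, id = "ref") {
  stopifnot(length >= 1L, gc > 0, gc < 1)
  .with_seed(seed, {
    bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    genome_record(id, paste(bases, collapse = ""))
  })
}

# Random sequence with an exact GC base count (planted unique segments
# have deterministic GC so the region filter behaves predictably).
.random_seq_exact_gc <- function(length, gc) {
  n_gc <- round(gc * length)
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), length - n_gc, replace = TRUE))
  paste(sample(bases), collapse = "")
}

#' Mutate a genome with substitutions and indels
#'
#' Per-base substitution with probability `divergence` (uniform over the
#' three alternative bases); insertions/deletions at rate `indel_rate`
#' per base with geometric lengths (mean 2).
#'
#' @param genome_rec A [genome_record] (or coercible single contig).
#' @param divergence Substitution rate per base in `[0, 0.3]`.
#' @param indel_rate Indel initiation rate per base in `[0, 0.3]`.
#' @param seed Integer seed.
#' @return A mutated [genome_record] (id suffixed `_mut`).
#' @export
mutate_genome <- function(genome_rec, divergence = 0.02, indel_rate = 0,
                          seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.3,
            indel_rate >= 0, indel_rate <= 0.3)
  genome_rec <- as_genome(genome_rec)[[1]]
  .with_seed(seed, {
    chars <- strsplit(genome_rec$seq, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (divergence > 0) {
      hit <- which(runif(n) < divergence)
      if (length(hit)) {
        alt <- c("A", "C", "G", "T")
        chars[hit] <- vapply(chars[hit], function(b) {
          sample(setdiff(alt, b), 1L)
        }, "")
      }
    }
    if (indel_rate > 0) {
      events <- which(runif(n) < indel_rate)
      if (length(events)) {
        pieces <- chars
        for (pos in events) {
          len <- rgeom(1L, 0.5) + 1L  # geometric, mean 2
          if (runif(1) < 0.5) {
            # deletion: blank out len bases starting here
            pieces[pos:min(n, pos + len - 1L)] <- ""
          } else {
            ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
            pieces[pos] <- paste0(pieces[pos], ins)
          }
        }
        chars <- pieces
      }
    }
    genome_record(paste0(genome_rec$id, "_mut"), paste(chars, collapse = ""))
  })
}

#' Strain-panel specification
#'
#' Defaults define the standard simulated study condition: 100 kb
#' genomes, 3 query strains at 2% divergence with a low indel rate, and
#' a 200 bp planted unique region at 50% GC.
#'
#' @param genome_len Backbone genome length (bp).
#' @param n_queries Number of query strains.
#' @param divergence Query substitution rate per base.
#' @param indel_rate Query indel rate per base.
#' @param unique_len Planted unique-segment length (bp; 0 = none).
#' @param unique_gc Unique-segment GC fraction.
#' @param seed Integer seed.
#' @return List of class `strain_panel_spec`.
#' @export
strain_panel_spec <- function(genome_len = 100000L, n_queries = 3L,
                              divergence = 0.02, indel_rate = 0.002,
                              unique_len = 200L, unique_gc = 0.5,
                              seed = 1L) {
  stopifnot(genome_len >= 1000L, n_queries >= 1L,
            divergence >= 0, divergence <= 0.3,
            indel_rate >= 0, indel_rate <= 0.3, unique_len >= 0L)
  structure(list(genome_len = as.integer(genome_len),
                 n_queries = as.integer(n_queries),
                 divergence = divergence, indel_rate = indel_rate,
                 unique_len = as.integer(unique_len), unique_gc = unique_gc,
                 seed = as.integer(seed)),
            class = "strain_panel_spec")
}

#' Generate a strain panel with a planted unique region
#'
#' The reference is a random backbone with a random segment of length
#' `unique_len` (exact GC count at `unique_gc`) inserted at a seeded
#' position; queries are mutated copies of the backbone WITHOUT the
#' insert, so uniqueness has an exact ground truth. The truth interval
#' of the insert on the reference is returned for assertions.
#'
#' @param spec A [strain_panel_spec()].
#' @return List with `reference` ([genome_record]), `queries` (named list
#'   of [genome_record]s), `truth` ([genomic_interval] or `NULL` when
#'   `unique_len = 0`).
#' @export
make_strain_panel <- function(spec = strain_panel_spec()) {
  backbone <- random_genome(spec$genome_len, 0.5, seed = spec$seed, id = "ref")
  .with_seed(spec$seed + 1L, {
    if (spec$unique_len > 0L) {
      insert_at <- sample(seq(1000L, spec$genome_len - 1000L), 1L)
      insert <- .random_seq_exact_gc(spec$unique_len, spec$unique_gc)
      ref_seq <- paste0(substr(backbone$seq, 1L, insert_at),
                        insert,
                        substr(backbone$seq, insert_at + 1L, spec$genome_len))
      reference <- genome_record("ref", ref_seq)
      truth <- genomic_interval("ref", insert_at, insert_at + spec$unique_len)
    } else {
      reference <- backbone
      truth <- NULL
    }
  })
  queries <- lapply(seq_len(spec$n_queries), function(i) {
    q <- mutate_genome(backbone, spec$divergence, spec$indel_rate,
                       seed = spec$seed + 100L + i)
    q$id <- paste0("query", i)
    q
  })
  names(queries) <- vapply(queries, `[[`, "", "id")
  list(reference = reference, queries = queries, truth = truth)
}

#' Toy genome with planted rrn operon cassettes for RISA
#'
#' Plants `n_operons` cassettes, each `fwd primer site + spacer +
#' reverse-complemented rev primer site`, separated by random filler, so
#' the predicted fingerprint lengths are `nchar(fwd) + spacer +
#' nchar(rev)` by construction.
#'
#' @param n_operons Number of cassettes (0 allowed).
#' @param spacer_lens Integer vector of spacer lengths, one per operon.
#' @param primer_fwd,primer_rev Primer sequences flanking the spacer.
#' @param seed Integer seed.
#' @param filler_len Random filler length between cassettes; the default
#'   (5000, beyond the default in silico product cap) keeps operons far
#'   apart, as rrn operons are on real chromosomes, so no cross-cassette
#'   product is predicted.
#' @return A [genome_record].
#' @export
make_rrn_toy <- function(n_operons, spacer_lens, primer_fwd, primer_rev,
                         seed = 1L, filler_len = 5000L) {
  stopifnot(length(spacer_lens) == n_operons)
  primer_fwd <- .normalize_seq(primer_fwd)
  primer_rev <- .normalize_seq(primer_rev)
  .with_seed(seed, {
    filler <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")
    parts <- list(filler(filler_len))
    for (i in seq_len(n_operons)) {
      cassette <- paste0(primer_fwd,
                         filler(spacer_lens[i]),
                         reverse_complement(primer_rev))
      parts <- c(parts, cassette, filler(filler_len))
    }
    genome_record("rrn_toy", paste(unlist(parts), collapse = ""))
  })
}

#' qPCR simulation specification
#'
#' @param true_efficiency Per-cycle amplification efficiency in (0.5, 1.2].
#' @param ct_at_1_copy Ct of a single template copy.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Integer seed.
#' @return List of class `qpcr_sim_spec`.
#' @export
qpcr_sim_spec <- function(true_efficiency = 0.95, ct_at_1_copy = 38,
                          noise_sd = 0.1, seed = 1L) {
  stopifnot(true_efficiency > 0.5, true_efficiency <= 1.2, noise_sd >= 0)
  structure(list(true_efficiency = true_efficiency,
                 ct_at_1_copy = ct_at_1_copy,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "qpcr_sim_spec")
}

#' Simulate qPCR Ct values for known copy numbers
#'
#' `Ct = ct_at_1_copy - log10(copies) / log10(1 + efficiency) +
#' Normal(0, noise_sd)`; at efficiency 1.0 tenfold dilutions are spaced
#' by exactly `1/log10(2) ~ 3.3219` cycles.
#'
#' @param copies_list Positive copy numbers.
#' @param spec A [qpcr_sim_spec()].
#' @return Numeric Ct vector.
#' @export
simulate_qpcr <- function(copies_list, spec = qpcr_sim_spec()) {
  stopifnot(all(copies_list > 0))
  .with_seed(spec$seed, {
    spec$ct_at_1_copy - log10(copies_list) / log10(1 + spec$true_efficiency) +
      rnorm(length(copies_list), 0, spec$noise_sd)
  })
}
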