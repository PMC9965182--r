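# End-to-end design pipelines: qPCR mode (unique-region subtraction ->
# primer pairs -> in silico specificity -> ranked selection) and endpoint
# mode (fragment-based novel regions -> primer pairs ranked by design
# penalty).

#' Rank screened primer pairs by specificity criteria
#'
#' Pairs whose reference amplicon count differs from 1 are excluded.
#' Survivors are ordered lexicographically by: total non-target amplicons
#' ascending, pair complementarity (`pair_any + pair_3p`) ascending,
#' design penalty ascending, forward offset ascending.
#'
#' @param pairs data.frame from [design_pairs()].
#' @param reports List of `specificity_report`s, one per row of `pairs`.
#' @return `pairs` with appended columns `reference_amplicons`,
#'   `total_nontarget`, re-ordered; zero rows (with a warning) when every
#'   pair is excluded.
#' @export
rank_pairs <- function(pairs, reports) {
  stopifnot(nrow(pairs) == length(reports))
  pairs$reference_amplicons <- vapply(reports, function(r)
    as.integer(r$reference_amplicons), 0L)
  pairs$total_nontarget <- vapply(reports, function(r)
    as.integer(r$total_nontarget), 0L)
  keep <- pairs$reference_amplicons == 1L
  if (!any(keep)) {
    warning("rank_pairs: no pair yields exactly 1 reference amplicon")
    return(pairs[keep, , drop = FALSE])
  }
  out <- pairs[keep, , drop = FALSE]
  ord <- order(out$total_nontarget, out$pair_any + out$pair_3p,
               out$penalty, out$fwd_offset, out$rev_offset)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.no_design <- function(stage, message) {
  structure(list(stage = stage, message = message), class = "no_design")
}

#' @export
print.no_design <- function(x, ...) {
  cat("<no design possible> at stage '", x$stage, "': ", x$message, "\n",
      sep = "")
  invisible(x)
}

#' Did a design run fail to produce primers?
#' @param x Result of [run_qpcr_design()] or [run_endpoint_design()].
#' @return Logical.
#' @export
is_no_design <- function(x) inherits(x, "no_design")

#' End-to-end strain-specific qPCR primer design
#'
#' Chains the full design flow: optional query selection by 16S identity
#' (strictly > `identity_threshold`), unique-region subtraction against
#' the retained queries, off-target confirmation against a local
#' background collection, primer-pair design on the most unique region
#' (or on every surviving region with `all_regions = TRUE`), in silico
#' specificity screening of the top `screen_top` pairs against the query
#' panel plus background, and ranking by [rank_pairs()]. Deterministic
#' given its inputs.
#'
#' Non-target screening is local-specificity semantics: amplicons are
#' counted against the supplied query genomes and background records, not
#' a remote database.
#'
#' @param reference Reference genome ([as_genome()]-coercible).
#' @param queries Named list of query genomes.
#' @param background List of [genome_record]s standing in for a
#'   nucleotide-database search; may be empty.
#' @param marker_16s Optional list with `reference` (reference 16S
#'   sequence) and `candidates` (named candidate 16S sequences); when
#'   supplied, queries failing the identity filter are dropped.
#' @param constraints A [design_constraints()] (default [qpcr_constraints()]).
#' @param params A [match_params()].
#' @param filt A [qpcr_region_filter()].
#' @param rule Permissive [amplification_rule()] for non-target screening.
#' @param identity_threshold 16S identity threshold in percent (strict >).
#' @param screen_top Number of top pairs (by design penalty) taken into
#'   in silico specificity screening.
#' @param all_regions Design on every surviving region instead of only
#'   the most unique one.
#' @return List of class `design_result` with fields `region` (the region
#'   designed on), `regions` (all surviving regions), `ranked_pairs`,
#'   `queries_used`, `config`; or a `no_design` object naming the failing
#'   stage.
#' @export
run_qpcr_design <- function(reference, queries, background = list(),
                            marker_16s = NULL,
                            constraints = qpcr_constraints(),
                            params = match_params(),
                            filt = qpcr_region_filter(),
                            rule = amplification_rule(),
                            identity_threshold = 97,
                            screen_top = 100L,
                            all_regions = FALSE) {
  if (length(queries) == 0L) stop("run_qpcr_design: need >= 1 query genome")
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))

  if (!is.null(marker_16s)) {
    sel <- select_query_genomes(marker_16s$reference, marker_16s$candidates,
                                identity_threshold)
    queries <- queries[names(queries) %in% sel$genome_id]
    if (length(queries) == 0L) {
      return(.no_design("query_selection",
                        "no query genome passes the 16S identity filter"))
    }
  }

  regions <- unique_seqs_qpcr(reference, queries, params, filt)
  if (length(regions) == 0L) {
    return(.no_design("unique_regions",
                      "no unique region passes the length/GC filters"))
  }
  if (length(background)) {
    regions <- confirm_uniqueness(regions, background, params)
  } else {
    # no background supplied: local-specificity semantics, score 0
    regions <- lapply(regions, function(r) { r$max_offtarget_identity <- 0; r })
  }
  design_on <- if (all_regions) regions else regions[1]

  all_ranked <- list()
  for (region in design_on) {
    pairs <- design_pairs(region, constraints)
    if (!nrow(pairs)) next
    screened <- head(pairs, screen_top)
    reports <- .screen_pairs(screened, reference, queries, background, rule)
    ranked <- suppressWarnings(rank_pairs(screened, reports))
    if (nrow(ranked)) {
      ranked$region_start <- region$interval$start
      all_ranked[[length(all_ranked) + 1L]] <- ranked
    }
  }
  if (length(all_ranked) == 0L) {
    return(.no_design("specificity",
                      "no screened pair yields exactly 1 reference amplicon"))
  }
  ranked_pairs <- do.call(rbind, all_ranked)
  structure(list(region = design_on[[1]], regions = regions,
                 ranked_pairs = ranked_pairs,
                 queries_used = names(queries),
                 config = list(constraints = constraints, params = params,
                               filt = filt, rule = rule,
                               identity_threshold = identity_threshold,
                               screen_top = screen_top)),
            class = "design_result")
}

# Specificity reports for each pair, caching binding sites per distinct
# primer sequence and genome so repeated primers are scanned once.
.screen_pairs <- function(pairs, reference, queries, background, rule) {
  targets <- c(list(.reference = reference), queries)
  if (length(background)) {
    bg <- as_genome(background)
    names(bg) <- paste0(".bg_", vapply(bg, `[[`, "", "id"))
    targets <- c(targets, bg)
  }
  strict <- perfect_match_rule(rule$max_product)
  site_cache <- new.env(parent = emptyenv())
  get_sites <- function(primer, tname, use_rule) {
    key <- paste(primer, tname, use_rule$max_mismatch_per_primer)
    if (exists(key, envir = site_cache, inherits = FALSE)) {
      return(get(key, envir = site_cache))
    }
    contigs <- as_genome(targets[[tname]])
    val <- lapply(contigs, function(ct) find_binding_sites(primer, ct, use_rule))
    assign(key, val, envir = site_cache)
    val
  }
  count_amps <- function(f, r, tname, use_rule) {
    fs <- get_sites(f, tname, use_rule)
    rs <- get_sites(r, tname, use_rule)
    sum(vapply(seq_along(fs), function(i) {
      nrow(enumerate_amplicons(fs[[i]], rs[[i]], use_rule))
    }, 0L))
  }
  lapply(seq_len(nrow(pairs)), function(i) {
    f <- pairs$fwd_seq[i]; r <- pairs$rev_seq[i]
    ref_n <- count_amps(f, r, ".reference", strict)
    nt_names <- setdiff(names(targets), ".reference")
    counts <- vapply(nt_names, function(tn) count_amps(f, r, tn, rule), 0L)
    structure(list(reference_amplicons = ref_n, nontarget_counts = counts,
                   total_nontarget = sum(counts)),
              class = "specificity_report")
  })
}

#' Endpoint-PCR primer design from novel regions
#'
#' Fragment-based novel-region finding followed by primer-pair design
#' with the endpoint constraint preset, ranked by design penalty. In
#' silico specificity screening is optional (`screen = TRUE` adds
#' reference/non-target amplicon counts and re-ranks via [rank_pairs()]).
#'
#' @param reference,queries Genomes as in [run_qpcr_design()].
#' @param cfg An [endpoint_config()].
#' @param constraints A [design_constraints()] (default
#'   [endpoint_constraints()], product window widened to the novel-region
#'   scale 100-1000 bp).
#' @param params A [match_params()].
#' @param screen Add in silico specificity screening.
#' @param rule Rule used when `screen = TRUE`.
#' @return `design_result` or `no_design`, as in [run_qpcr_design()].
#' @export
run_endpoint_design <- function(reference, queries,
                                cfg = endpoint_config(),
                                constraints = NULL,
                                params = match_params(),
                                screen = FALSE,
                                rule = amplification_rule()) {
  if (length(queries) == 0L) stop("run_endpoint_design: need >= 1 query genome")
  if (is.null(names(queries))) names(queries) <- paste0("query", seq_along(queries))
  if (is.null(constraints)) {
    constraints <- endpoint_constraints()
    constraints$product_min <- 100L
    constraints$product_max <- 1000L
  }
  regions <- novel_regions_endpoint(reference, queries, cfg, params)
  if (length(regions) == 0L) {
    return(.no_design("novel_regions", "no novel region >= min_novel_size"))
  }
  all_ranked <- list()
  for (region in regions) {
    pairs <- design_pairs(region, constraints)
    if (!nrow(pairs)) next
    pairs$region_start <- region$interval$start
    all_ranked[[length(all_ranked) + 1L]] <- pairs
  }
  if (length(all_ranked) == 0L) {
    return(.no_design("primer_design", "no valid pair in any novel region"))
  }
  ranked <- do.call(rbind, all_ranked)
  ranked <- ranked[order(ranked$penalty, ranked$region_start,
                         ranked$fwd_offset), , drop = FALSE]
  rownames(ranked) <- NULL
  if (screen) {
    reports <- .screen_pairs(ranked, reference, queries, list(), rule)
    ranked <- rank_pairs(ranked, reports)
  }
  structure(list(region = regions[[1]], regions = regions,
                 ranked_pairs = ranked,
                 queries_used = names(queries),
                 config = list(cfg = cfg, constraints = constraints,
                               params = params)),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> %d region(s), %d ranked pair(s); top region %s:[%d, %d)\n",
              length(x$regions), nrow(x$ranked_pairs),
              x$region$interval$genome_id, x$region$interval$start,
              x$region$interval$end))
  if (nrow(x$ranked_pairs)) {
    top <- x$ranked_pairs[1, ]
    cat(sprintf("  top pair: %s / %s (product %d bp)\n",
                top$fwd_seq, top$rev_seq, top$product_len))
  }
  invisible(x)
}
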