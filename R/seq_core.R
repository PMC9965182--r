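#' @importFrom methods is
#' @importFrom stats lm coef residuals kruskal.test pnorm p.adjust rbinom rnorm runif rgeom setNames
#' @importFrom utils write.table read.delim head
NULL

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_FROM    <- "ACGTRYSWKMBDHVN"
.IUPAC_COMPLEM <- "TGCAYRSWMKVHDBN"

.valid_alphabet <- function(seq) {
  !grepl(sprintf("[^%s]", .IUPAC_FROM), seq)
}

.normalize_seq <- function(seq) {
  chartr("U", "T", toupper(seq))
}

#' Create a genome record
#'
#' A `genome_record` is the unit of comparison throughout the package: an
#' identified nucleotide sequence with an optional free-text description.
#' Sequences are upper-cased on ingest and RNA `U` is normalized to `T`;
#' only IUPAC nucleotide codes are accepted.
#'
#' @param id Identifier token (first word of a FASTA header).
#' @param seq Nucleotide sequence (IUPAC alphabet; `U` converted to `T`).
#' @param description Free-text description (rest of the FASTA header).
#' @return An object of class `genome_record` with fields `id`,
#'   `description` and `seq`.
#' @examples
#' genome_record("chr1", "acgtu")$seq  # "ACGTT"
#' @export
genome_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- .normalize_seq(seq)
  if (!nzchar(seq)) stop("genome_record: sequence for '", id, "' is empty")
  if (!.valid_alphabet(seq)) {
    bad <- regmatches(seq, regexpr(sprintf("[^%s]", .IUPAC_FROM), seq))
    stop("genome_record: illegal character '", bad, "' in sequence '", id, "'")
  }
  structure(list(id = id, description = description, seq = seq),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d bp)%s\n", x$id, nchar(x$seq),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Create a genomic interval
#'
#' Coordinates are 0-based half-open (`[start, end)`) everywhere inside the
#' package; BED output uses the same convention. Intervals never span
#' contigs.
#'
#' @param genome_id Contig/record identifier the interval refers to.
#' @param start 0-based start offset.
#' @param end Exclusive end offset; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(genome_id, start, end, strand = "+") {
  stopifnot(length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || start >= end) {
    stop("genomic_interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-")) stop("genomic_interval: strand must be '+' or '-'")
  structure(list(genome_id = genome_id, start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d, %d) %s\n", x$genome_id, x$start, x$end, x$strand))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]. Sequences
#' are upper-cased, `U` is normalized to `T`, and any character outside the
#' IUPAC nucleotide alphabet raises an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return List of [genome_record] objects in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  if (file.size(path) == 0L) stop("read_fasta: empty file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop("read_fasta: malformed FASTA (line 1 does not start with '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("read_fasta: no records in ", path)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    if (!nzchar(id)) stop("read_fasta: record ", i, " has an empty header")
    genome_record(id, as.character(set[[i]]), desc)
  })
}

#' Write genome records to a FASTA file
#'
#' @param records A [genome_record] or list of them.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  records <- as_genome(records)
  seqs <- vapply(records, `[[`, "", "seq")
  ids <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Coerce to a list of genome records
#'
#' A "genome" anywhere in this package is a list of [genome_record]s (one
#' per contig). Accepts a single record, a list of records, or a named
#' character vector of sequences.
#'
#' @param x Object to coerce.
#' @return List of [genome_record]s.
#' @export
as_genome <- function(x) {
  if (is(x, "genome_record")) return(list(x))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(mapply(genome_record, ids, x, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  if (is.list(x) && all(vapply(x, is, TRUE, "genome_record"))) return(x)
  stop("as_genome: cannot coerce object of class ", class(x)[1], " to a genome")
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Ambiguity codes are complemented onto their partners (R<->Y, K<->M,
#' B<->V, D<->H; S, W and N are self-complementary), so the operation is an
#' involution on the full IUPAC alphabet.
#'
#' @param seq Nucleotide string.
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("GTGCCAGCAGCCGCGGTAA")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- .normalize_seq(seq)
  if (!.valid_alphabet(seq)) stop("reverse_complement: illegal character in sequence")
  comp <- chartr(.IUPAC_FROM, .IUPAC_COMPLEM, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' GC fraction of a sequence
#'
#' Counts G, C and S (strong) positions over the full sequence length;
#' other ambiguity codes count as non-GC. Deterministic and conservative
#' for sequences containing ambiguity codes.
#'
#' @param seq Non-empty nucleotide string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  seq <- .normalize_seq(seq)
  n <- nchar(seq)
  if (n == 0L) stop("gc_fraction: empty sequence")
  gc <- nchar(gsub("[^GCS]", "", seq))
  gc / n
}

#' Do two IUPAC codes match?
#'
#' True iff the unambiguous base sets of the two codes intersect, e.g.
#' `A` matches `R` (= A/G) but not `Y` (= C/T); `N` matches everything.
#'
#' @param a,b Single IUPAC nucleotide codes.
#' @return Logical.
#' @export
iupac_match <- function(a, b) {
  ab <- .IUPAC_BITS[.normalize_seq(a)]
  bb <- .IUPAC_BITS[.normalize_seq(b)]
  if (anyNA(ab) || anyNA(bb)) stop("iupac_match: illegal IUPAC code")
  unname(bitwAnd(ab, bb) > 0L)
}

# Integer bit-mask encoding of a sequence; vector of 4-bit masks.
# Used by mismatch scans (bitwAnd > 0 <=> IUPAC match).
encode_iupac <- function(seq) {
  seq <- .normalize_seq(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) stop("encode_iupac: illegal character in sequence")
  unname(bits)
}

# 2-bit encoding for k-mer seeding: A=0 C=1 G=2 T=3, ambiguity -> NA.
encode_acgt <- function(seq) {
  seq <- .normalize_seq(seq)
  m <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  m - 1L
}

#' Extract the sequence of a genomic interval
#'
#' @param genome Genome (coercible via [as_genome()]).
#' @param interval A [genomic_interval]; `-` strand returns the reverse
#'   complement of the slice.
#' @return Character sequence.
#' @export
interval_seq <- function(genome, interval) {
  genome <- as_genome(genome)
  ids <- vapply(genome, `[[`, "", "id")
  i <- match(interval$genome_id, ids)
  if (is.na(i)) stop("interval_seq: no contig named '", interval$genome_id, "'")
  len <- nchar(genome[[i]]$seq)
  if (interval$end > len) {
    stop("interval_seq: interval end ", interval$end, " beyond contig length ", len)
  }
  s <- substr(genome[[i]]$seq, interval$start + 1L, interval$end)
  if (interval$strand == "-") reverse_complement(s) else s
}

#' Write intervals to a BED file
#'
#' BED keeps the package's native 0-based half-open convention.
#'
#' @param intervals List of [genomic_interval]s.
#' @param path Output path.
#' @param names Optional feature names (4th column).
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, names = NULL) {
  df <- data.frame(
    chrom = vapply(intervals, `[[`, "", "genome_id"),
    start = vapply(intervals, `[[`, 0L, "start"),
    end = vapply(intervals, `[[`, 0L, "end"),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    df$name <- names
    df$score <- 0L
    df$strand <- vapply(intervals, `[[`, "", "strand")
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read primer sequences from a plain-text or FASTA file
#'
#' Accepts either FASTA or one oligo per line (blank lines and `#` comments
#' ignored).
#'
#' @param path Input path.
#' @return Named character vector of upper-cased oligo sequences.
#' @export
read_primers <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0L && startsWith(first, ">")) {
    recs <- read_fasta(path)
    return(setNames(vapply(recs, `[[`, "", "seq"),
                    vapply(recs, `[[`, "", "id")))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  oligos <- .normalize_seq(lines)
  ok <- .valid_alphabet(oligos)
  if (!all(ok)) stop("read_primers: illegal characters in line ", which(!ok)[1])
  setNames(oligos, paste0("primer", seq_along(oligos)))
}
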