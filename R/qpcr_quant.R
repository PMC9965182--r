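# Attachment-qPCR absolute quantification: copy number from DNA mass and
# genome size, standard curves with amplification efficiency, Ct-cutoff
# calling, bacteria-to-plant normalization, and nonparametric group
# comparison (Kruskal-Wallis omnibus + Dunn's post hoc with BH-FDR and a
# compact letter display).

.AVOGADRO <- 6.022e23   # molecules per mol
.MW_PER_BP <- 660       # Da per bp of double-stranded DNA

#' DNA copy number from mass and genome size
#'
#' `copies = quantity_ng * 6.022e23 / (genome_size_bp * 1e9 * 660)`:
#' the number of genome copies in `quantity_ng` nanograms of DNA from a
#' genome of `genome_size_bp` base pairs at 660 Da per base pair.
#'
#' @param quantity_ng DNA mass in nanograms (> 0; vectorized).
#' @param genome_size_bp Genome size in base pairs (>= 1).
#' @return Copy number (real-valued).
#' @examples
#' copy_number(5, 3.39e6)      # ~1.35e6 copies
#' copy_number(50, 398.93e6)   # ~1.14e5 copies
#' @export
copy_number <- function(quantity_ng, genome_size_bp) {
  if (any(quantity_ng <= 0)) stop("copy_number: quantity_ng must be positive")
  if (any(genome_size_bp < 1)) stop("copy_number: genome_size_bp must be >= 1")
  quantity_ng * .AVOGADRO / (genome_size_bp * 1e9 * .MW_PER_BP)
}

#' Serial dilution series
#'
#' Geometric series `top_ng / fold^i`, `i = 0..n-1`; with the defaults of
#' a tenfold series this reproduces standard qPCR dilution ladders such
#' as 5, 0.5, 0.05, 0.005, 0.0005 ng.
#'
#' @param top_ng Top standard quantity (ng).
#' @param fold Dilution factor (> 1).
#' @param n Number of standards (>= 2).
#' @return Numeric vector of length `n`.
#' @export
dilution_series <- function(top_ng, fold = 10, n = 5L) {
  stopifnot(top_ng > 0, fold > 1, n >= 2L)
  top_ng / fold^(seq_len(n) - 1L)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of `Ct = slope * log10(copies) + intercept`.
#' Amplification efficiency is `10^(-1/slope) - 1` (1.0 = perfect
#' per-cycle doubling, slope ~ -3.3219).
#'
#' @param log10_copies Numeric vector of log10 standard copy numbers
#'   (need >= 3 points spanning >= 2 log10 units).
#' @param ct Matching Ct values.
#' @return List of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  stopifnot(length(log10_copies) == length(ct))
  if (length(log10_copies) < 3L) {
    stop("fit_standard_curve: need at least 3 standards")
  }
  if (diff(range(log10_copies)) < 2) {
    stop("fit_standard_curve: standards span < 2 log10 units")
  }
  fit <- lm(ct ~ log10_copies)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  # direct R^2 (summary.lm warns on numerically perfect fits)
  r2 <- 1 - sum(residuals(fit)^2) / sum((ct - mean(ct))^2)
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = eff),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope=%.4f intercept=%.2f R2=%.4f efficiency=%.1f%%\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Interpolate copy number from a Ct value
#'
#' Reactions with `ct > ct_cutoff` (default 30) are not considered
#' positive for amplification and return `NA` (a negative call); a Ct of
#' exactly the cutoff is still positive.
#'
#' @param ct Ct value(s).
#' @param curve A fitted [fit_standard_curve()] object.
#' @param ct_cutoff Positivity cutoff (strict `>` is negative).
#' @return Copies (`10^((ct - intercept)/slope)`), or `NA` for negative
#'   calls.
#' @export
quantify_sample <- function(ct, curve, ct_cutoff = 30) {
  stopifnot(inherits(curve, "standard_curve"))
  copies <- 10^((ct - curve$intercept) / curve$slope)
  copies[ct > ct_cutoff] <- NA_real_
  copies
}

#' Bacteria-to-plant attachment ratio
#'
#' Bacterial DNA copies divided by host-plant DNA copies from the same
#' extract. A negative call (`NA`) on the bacterial side propagates as
#' "not detected" (`NA`); a negative call on the plant side is an error,
#' since the reference marker must amplify for the sample to be usable.
#'
#' @param bacteria_copies,plant_copies Copy numbers (vectorized; `NA` =
#'   negative call).
#' @return Ratio(s); `NA` where bacteria were not detected.
#' @export
attachment_ratio <- function(bacteria_copies, plant_copies) {
  if (any(is.na(plant_copies))) {
    stop("attachment_ratio: reference marker not detected (plant negative-call)")
  }
  if (any(plant_copies <= 0)) {
    stop("attachment_ratio: plant_copies must be positive")
  }
  bacteria_copies / plant_copies
}

# Dunn's post hoc test, tie-corrected, two-sided normal p-values.
.dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  rk <- rank(values)
  mean_rk <- tapply(rk, groups, mean)
  n <- tapply(rk, groups, length)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (mean_rk[[a]] - mean_rk[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z, p = p,
             stringsAsFactors = FALSE)
}

# Compact letter display by insert-and-absorb: groups sharing a letter
# are exactly the pairs NOT significantly different.
.compact_letters <- function(groups, sig_pairs) {
  letters_pool <- c(letters, LETTERS)
  cols <- list(groups)  # start: everyone shares one letter
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[i]; b <- sig_pairs$group2[i]
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (a %in% col && b %in% col) {
        cols[[ci]] <- setdiff(col, a)
        cols[[length(cols) + 1L]] <- setdiff(col, b)
      }
    }
    # drop empty columns and columns contained in another column
    cols <- cols[lengths(cols) > 0L]
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) {
      if (!keep[ci]) next
      for (cj in seq_along(cols)) {
        if (ci == cj || !keep[cj]) next
        if (all(cols[[ci]] %in% cols[[cj]]) &&
            (length(cols[[ci]]) < length(cols[[cj]]) || ci > cj)) {
          keep[ci] <- FALSE
          break
        }
      }
    }
    cols <- cols[keep]
  }
  out <- setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]]) out[g] <- paste0(out[g], letters_pool[ci])
  }
  out
}

#' Nonparametric comparison of attachment ratios across groups
#'
#' Kruskal-Wallis omnibus test, Dunn's tie-corrected pairwise post hoc
#' with Benjamini-Hochberg adjustment, and a compact letter display in
#' which two groups share no letter exactly when their adjusted pairwise
#' p-value is below `fdr`.
#'
#' @param ratios_by_group Named list: group -> numeric vector of ratios
#'   (>= 2 groups, each >= 2 observations).
#' @param fdr FDR level for the letter display (default 0.05).
#' @return List of class `group_comparison` with `kw_statistic`, `kw_p`,
#'   `pairwise` (data.frame with `z`, `p`, `p_adj`), `letters`.
#' @export
compare_groups <- function(ratios_by_group, fdr = 0.05) {
  if (length(ratios_by_group) < 2L) stop("compare_groups: need >= 2 groups")
  sizes <- lengths(ratios_by_group)
  if (any(sizes < 2L)) {
    stop("compare_groups: group '", names(ratios_by_group)[sizes < 2L][1],
         "' has fewer than 2 observations")
  }
  values <- unlist(ratios_by_group, use.names = FALSE)
  groups <- rep(names(ratios_by_group), sizes)
  kw <- kruskal.test(values, factor(groups))
  pw <- .dunn_test(values, groups)
  pw$p_adj <- p.adjust(pw$p, method = "BH")
  sig <- pw[pw$p_adj < fdr, , drop = FALSE]
  letts <- .compact_letters(names(ratios_by_group), sig)
  structure(list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
                 pairwise = pw, letters = letts, fdr = fdr),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H=%.3f p=%.3g\n",
              x$kw_statistic, x$kw_p))
  cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                          collapse = " "), "\n")
  invisible(x)
}

#' Quantify a qPCR experiment from a Ct table
#'
#' Convenience wrapper over the per-sample math: averages technical
#' replicates (mean Ct by default, computed before curve interpolation),
#' interpolates copies from per-target standard curves, applies the Ct
#' cutoff, and forms bacteria/plant ratios.
#'
#' @param ct_table data.frame with columns `sample_id`, `target`
#'   (`"bacteria"` or `"plant"`), `ct`.
#' @param bacteria_curve,plant_curve Fitted [fit_standard_curve()] objects.
#' @param ct_cutoff Positivity cutoff.
#' @param average `"ct"` (default: average replicate Cts, then
#'   interpolate) or `"copies"` (interpolate each replicate, then average
#'   copies).
#' @return data.frame with `sample_id`, `bacteria_copies`, `plant_copies`,
#'   `ratio` (`NA` ratio = bacteria not detected).
#' @export
quantify_attachment <- function(ct_table, bacteria_curve, plant_curve,
                                ct_cutoff = 30, average = c("ct", "copies")) {
  average <- match.arg(average)
  stopifnot(all(c("sample_id", "target", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample_id)
  one <- function(sid, target, curve) {
    cts <- ct_table$ct[ct_table$sample_id == sid & ct_table$target == target]
    if (!length(cts)) return(NA_real_)
    if (average == "ct") {
      quantify_sample(mean(cts), curve, ct_cutoff)
    } else {
      mean(quantify_sample(cts, curve, ct_cutoff))
    }
  }
  bact <- vapply(samples, one, 0, target = "bacteria", curve = bacteria_curve)
  plant <- vapply(samples, one, 0, target = "plant", curve = plant_curve)
  data.frame(sample_id = samples,
             bacteria_copies = bact, plant_copies = plant,
             ratio = attachment_ratio(bact, plant),
             stringsAsFactors = FALSE, row.names = NULL)
}
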