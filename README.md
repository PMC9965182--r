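# strainprimer

Strain-specific PCR/qPCR primer design from genome comparisons, plus
absolute quantification for attachment qPCR assays.

Closely related bacterial strains — for example two *Azospirillum
brasilense* isolates — cannot be told apart by community fingerprints or
16S markers. `strainprimer` designs primers that amplify one strain and
nothing else, by working from what is genuinely unique in its genome,
and then turns the resulting qPCR measurements into colonization levels
(bacterial genome copies per host-plant genome copy). It is aimed at
plant–microbe and microbiome researchers who have assembled genomes for
their isolates and want assay design plus quantification in one tested
toolkit, offline, with no web services involved.

## What it does

1. **Unique-region discovery.** Reference vs. query-panel genome
   subtraction with a native seed-and-extend matcher (exact k-mer seeds,
   diagonal chaining, X-drop ungapped extension; identity ≥ 85%,
   segment ≥ 31 bp by default). Two modes:
   - *endpoint mode*: the reference is cut into 1 kb fragments and a
     fragment is novel when no query reaches the 85% identity cutoff;
     merged novel regions under 500 bp are dropped.
   - *qPCR mode*: a per-base coverage mask is complemented and the
     uncovered runs are tiled and filtered to 150–250 bp regions with
     40–60% GC.
   Queries can be pre-selected by 16S identity to the reference
   (strictly > 97%), and candidate regions are ranked against a local
   background collection (identity × coverage; most unique first).
2. **Primer design.** Exhaustive candidate enumeration under constraint
   presets (endpoint: size 18/20/25, Tm 57/60/63 °C, GC 40–60%; qPCR:
   size 18/22/26, product 100–200 bp, up to 500 ranked pairs), unified
   nearest-neighbor melting temperatures
   (Tm = 1000·ΔH / (ΔS + 0.368·N·ln[Na⁺] + R·ln(C_T/4)) − 273.15),
   suitability screening (homopolymer runs, short-unit repeats, GC
   clamp, self-complementarity) and a documented pair penalty.
3. **In silico PCR.** Binding-site scan on both strands with the
   unintended-target rule: a site is non-functional only when it has
   ≥ 5 total mismatches *and* ≥ 2 mismatches within the last 3 bases at
   the 3′ end. Pairs are ranked by: fewest non-target amplicons, exactly
   1 reference amplicon, lowest pair complementarity. RISA fingerprints
   (16S–23S spacer products) are predicted with the same machinery.
4. **Attachment qPCR quantification.** Copy number
   = m(ng)·6.022×10²³ / (G(bp)·10⁹·660), tenfold dilution ladders,
   standard curves Ct = a·log₁₀(copies) + b with efficiency
   E = 10^(−1/a) − 1, a Ct > 30 negativity cutoff, bacteria/plant copy
   ratios, and Kruskal–Wallis + Dunn (BH-FDR) group comparison with
   compact letters.
5. **Synthetic fixtures.** Seeded generators for strain panels with a
   planted unique region (exact ground truth), rrn-operon toys for RISA
   and simulated qPCR ladders — everything is testable offline.

## Worked example

```r
library(strainprimer)

panel <- make_strain_panel(strain_panel_spec(seed = 7))  # 100 kb, 3 queries
res <- run_qpcr_design(panel$reference, panel$queries)
res
#> <design_result> 1 region(s), 100 ranked pair(s); top region ref:[80157, 80349)
#>   top pair: CGATACTACATCGCCGGACCCTT / ACGTCTTTACCTCTGGTTAGAGCGG (product 150 bp)

top <- res$ranked_pairs[1, ]
top[, c("fwd_tm", "rev_tm", "product_len", "pair_any",
        "reference_amplicons", "total_nontarget")]
#>     fwd_tm   rev_tm product_len pair_any reference_amplicons total_nontarget
#> 1 58.11101 58.09377         150        3                   1               0
```

The designed pair sits inside the 192 bp region unique to the reference
(it overlaps the planted 200 bp segment), melts near 58 °C on both
sides, and in silico PCR confirms one perfect product on the reference
and none on any query — the selection criteria for a strain-specific
qPCR assay.

Quantification side:

```r
copies <- copy_number(dilution_series(5, 10, 5), 3.39e6)  # 3.39 Mbp genome
round(log10(copies), 2)
#> [1] 6.13 5.13 4.13 3.13 2.13          # standards span 10^6 .. 10^2
curve <- fit_standard_curve(log10(copies),
                            simulate_qpcr(copies, qpcr_sim_spec(seed = 1)))
curve
#> <standard_curve> slope=-3.4811 intercept=38.15 R2=0.9998 efficiency=93.8%
```

A command-line wrapper with subcommands `unique-regions`, `design-qpcr`,
`design-endpoint`, `ispcr`, `risa`, `quantify` and `simulate` is
installed at `inst/cli/strainprimer`.

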