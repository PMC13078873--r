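---
title: "redoxQuant: methods and design notes"
author: "redoxQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{redoxQuant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxQuant)
```

# The measurement model

redoxQuant analyzes paired half-sample cysteine-labeling experiments. Each
biological sample (mouse liver, in the motivating application) is split into
two aliquots. In one, free thiols are blocked with iodoacetamide before
reduction, so the subsequent cysteine tag marks only *reversibly oxidized*
thiols; the other aliquot is tagged before and after reduction and quantifies
*total* cysteine. Both aliquots are labeled with TMT reporter channels in the
same multiplex, and after database search (out of scope here) each PSM
carries one reporter signal-to-noise (S/N) value per channel.

The pipeline starts from those quantified S/N values:

1. **Site roll-up** (`aggregatePsmsToSites`). Per site and channel, S/N is
   *summed* over supporting PSMs. Sums, unlike means or medians, keep the
   roll-up linear: duplicating every PSM doubles each site's S/N and leaves
   every downstream ratio unchanged — a property the test suite asserts.
   Peptides with more than one cysteine are excluded because the labeled
   residue cannot be localized; the exclusion count is reported, never
   silently applied.
2. **Oxidation percentage** (`computeOxidationPercent`). For site $i$ and
   sample $s$, $\mathrm{ox\%}_{is} = 100\,\cdot$ oxidized$_{is}$/total$_{is}$.
   Absent parent values (empty cells, which are distinct from zero S/N) and
   zero totals give an absent percentage. Values above 100% — possible under
   reporter noise since the two aliquots are measured independently — are
   kept and counted for QC; clamping them would truncate the error
   distribution and bias the t-test.
3. **Completeness filter** (`filterQuantifiedSites`). A site is testable when
   it has at least `minReps` (default 2, the minimum a two-sample t-test
   supports) quantified replicates in *each* group.
4. **Differential calling** (`callIncreasedOxidation`). Per site, a
   two-tailed Student's t-test with pooled variance compares the depleted
   group's oxidation percentages against control. A site is *called* when
   all of: raw $P < \alpha$ (default 0.05); relative increase
   $\Delta/\bar{x}_{\mathrm{ctrl}} \ge$ `relMin` (default 0.25); absolute
   increase $\Delta$ within the top `topFrac` (default 0.15) of **all
   tested** sites.
5. **Hotspot ranking and domain mapping** (`rankProteins`,
   `mapSitesToDomains`). Proteins are ranked by called-site count; called
   sites fall inside an annotated domain interval when
   `start <= position <= end` (1-based, inclusive ends).
6. **Motif statistics** (`extractFlanks`, `buildMotifResult`). Flanks of
   ±`w` residues (default 6) around called cysteines are compared per
   position and residue against a background flank set with exact binomial
   tails, reported as signed $\log_{10}$ odds, with the Bonferroni line
   $-\log_{10}\!\big(\alpha/(20\cdot 2w)\big)$ — 3.68 for the default
   window at $\alpha = 0.05$:

```{r}
significanceThreshold(alpha = 0.05, R = 20, W = 12)
```

# Statistical choices, and why

**Pooled-variance Student's t, not Welch.** The per-site test is the classic
equal-variance two-sample t-test on untransformed percentages. Both groups
come from the same tissue, labeling chemistry and instrument run, so equal
within-group variance is a reasonable default; a moderated (empirical-Bayes)
test is deliberately out of scope to keep the calling rule transparent.
Degenerate inputs follow fixed conventions so the pipeline is total: zero
pooled variance gives $P = 1$ for equal means and $P = 0$ for different
means; a zero control mean gives relative increase $+\infty$ (any increase
from nothing is called infinite rather than dropped), and 0 when both means
are zero.

**Raw p-values gate calls.** The composite rule uses the unadjusted
$P < \alpha$; the relative-increase and top-percentile criteria are what
control the practical false-call burden. A Benjamini–Hochberg FDR column is
emitted for reference and never used in the rule.

**"Top 15% of all sites".** The top set has $\lceil 0.15\,N\rceil$ members
computed over *all tested* sites — not only nominally significant ones — so
the set is a property of the experiment, not of the other two filters. The
calling direction is enforced by the relative-increase and ranking criteria,
not by a one-tailed test; decreased-oxidation sites appear in the output
with negative $\Delta$ but are never called.

**Deterministic tie-breaks.** Sites tied in $\Delta$ at the top-set boundary
order lexicographically by site id; tied protein ranks order by accession.
Identical inputs give byte-identical outputs on any platform.

**Exact binomial tails.** Foreground sets here are small (tens to hundreds
of called sites), so exact tails are cheap and a normal approximation would
be inaccurate exactly where it matters (small $p_0 \approx 0.05$, small
$n$). Ties $k/n = p_0$ score as overrepresentation (the $\ge$ tail), giving
a deterministic sign. A certain event (tail probability 1) scores 0. The
test suite checks the tails against an independent log-factorial summation
to $10^{-10}$ relative over a $(k, n \le 200)$ grid.

**Motif background.** The default background is the flank set of *all
detected* cysteine sites in the same experiment, which controls for
acquisition and digestion bias and keeps the analysis self-contained; a
whole-proteome background (every cysteine in the FASTA) is available via
`background = "proteome"`. 'X' padding at protein termini is excluded from
both the foreground count $k$ and the per-position denominator $n$, the
standard probability-logo treatment of truncated windows; the Bonferroni
family stays $20 \times 2w$ regardless, which is what reproduces the
conventional 3.68 line.

**Normalization off by default.** The oxidation percentage is a
within-sample ratio, so per-channel loading differences largely cancel; no
channel normalization is applied unless `normalize = TRUE` requests
per-channel median centering (a QC aid, not part of the calling path).

# What the synthetic generator emulates

`generateExperiment()` produces a complete experiment — FASTA proteome, plex
design, PSM table — plus ground truth. Its defaults are the study conditions
the package targets:

| parameter | default | meaning |
|---|---|---|
| `nPerGroup` | 7 | biological replicates per group; 14 samples × 2 fractions span two 16-channel plexes (a sample's two fractions always share a plex) |
| `nSites` | 10,000 | detected cysteine sites |
| `fracPlanted` | 0.018 | fraction of sites with a true oxidation increase |
| `betaShape1/2` | 2, 18 | control oxidation fraction $f_0 \sim \mathrm{Beta}(2,18)$, mean 10% — most cysteines mostly reduced, a long tail of constitutively oxidized sites |
| `delta` | 0.15 | additive planted effect on the fraction scale, clamped at 0.99; an additive truth makes the *relative* increase site-dependent, as in real data |
| `abundanceSigma` | 1.0 | log-normal sdlog of site abundance (about an e-fold typical spread, an ordinary dynamic range for site-level S/N) |
| `noiseCv` | 0.10 | multiplicative log-normal reporter noise per channel, the standard heteroscedastic model for reporter S/N |
| `hotspotSites` | 10 | planted sites on the single hotspot protein (capped at the planted total) |
| `motifBias` | 0.8 | probability a planted site's flank has K or R at both −5 and −6 |

Expected channel values are $f\,A$ (oxidized) and $A$ (total) for site
abundance $A$; with `noiseCv = 0` the downstream oxidation percentage equals
$100 f$ to floating-point accuracy, which anchors the quantification tests.
Flank residues are i.i.d. uniform over the 20 amino acids except the planted
bias, so background frequencies are analytically ≈ 0.05 per residue. Site
layout is structural: the hotspot protein holds its planted sites 15
residues apart; remaining planted sites land at most 2 per "carrier"
protein, so in a strong-effect run no protein but the hotspot can exceed 2
called sites — by construction, making hotspot recovery a sharp test.
Peptides are trimmed around the central cysteine so each carries exactly one
Cys (a tryptic-like single-Cys peptide); the multi-Cys exclusion path is
exercised by handcrafted fixtures instead.

**What it does not emulate:** missed cleavages and shared peptides,
co-isolation interference, intensity-dependent missingness (only "absent
channel" is representable), between-plex batch effects and bridge channels,
protein-level abundance change, and correlated sites within a protein.
Passing tests therefore demonstrate the *statistical machinery* — they do
not certify performance on real LC-MS data, where these artifacts exist.

# Numerical conventions and scales

- Site ids serialize as `accession:position` with 1-based positions
  throughout; flank windows index −w..+w around the cysteine at 0, and
  window slots beyond a terminus are 'X'.
- All tabular I/O is TSV (UTF-8, header row, '.' decimal, empty cell =
  absent); FASTA accessions are the first whitespace-delimited header token.
- The run log (`run_log.json`) records the effective configuration and all
  stage counts, and carries no timestamp, so reruns under a fixed seed are
  byte-identical — determinism is part of the contract, not an accident.
- Test problem sizes: the end-to-end recovery, type-I and motif checks run
  on 2,000-site simulations with 7 replicates per group; the oracle grids
  cover $n \le 200$. These sizes give stable proportions (a 2,000-site null
  puts the $P < 0.05$ fraction within ±3 binomial SE of 0.05, i.e.
  [0.035, 0.065]) while keeping the full suite in seconds.

# Known limitations

- The composite rule is tied to the increase direction; a decreased-oxidation
  caller is intentionally absent.
- No isotopic-impurity correction, inter-plex bridge normalization, or
  moderated variance estimation.
- The motif module tests marginal per-position enrichment only; it does not
  model positional dependencies beyond the fixed central cysteine, and it
  renders no logo graphics — the cell table and PWM are the interface.
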