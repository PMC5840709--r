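---
title: "Inferring gene loss from homology, reciprocal best hits, and microsynteny"
author: "synteloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene loss from homology, reciprocal best hits, and microsynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synteloss)
```

## The problem

Agastric (stomach-less) fish such as the wrasses have independently lost the
anatomical stomach several times across the teleost phylogeny, and
comparative genomics shows those losses coincide with the loss of the genes
behind gastric function — the proton-pump subunits, pepsinogens, gastric
lipase, and, strikingly, the appetite hormone ghrelin and its acylation
enzyme. Establishing that a gene is *absent* from a draft genome is much
harder than establishing presence: a negative BLAST result can mean a real
loss, a diverged ortholog below the similarity threshold, an assembly gap,
or a hit to a paralog masquerading as the target. `synteloss` packages the
decision procedure such studies rely on into tested, reusable functions:

1. **Homology search.** The query protein is searched against the target
   genome (and optionally a transcriptome) with a seed-and-extend local
   aligner over all six reading frames.
2. **Reciprocal top-hit verification.** Each candidate locus is searched
   back against a multi-species ortholog panel (the stand-in for a
   non-redundant protein database); a candidate is only believed if the
   intended gene is among the top-ranking distinct symbols.
3. **Microsynteny validation.** The gene neighborhood around the candidate
   locus is compared with the reference neighborhood; conserved local gene
   order distinguishes the true ortholog from a relocated paralog.
4. **Flank anchoring for absence.** When no candidate survives, the flanks
   of the expected locus are anchored in the target and the intervening
   interval is re-scanned at relaxed thresholds. Only an anchored, empty
   interval (or a candidate unmasked as a paralog) justifies an absent
   call; anything less is *ambiguous*.

Because the real analysis ran on a full genome assembly and public
databases, the package ships a synthetic annotated-genome generator with
ground truth, so every stage is exercisable — and falsifiable — without any
downloads.

## Alignment model and statistics

The aligner is a classical Gotoh affine-gap Smith–Waterman: a gap of length
$L$ costs $o + Le$ (defaults $o=11$, $e=1$ for protein under BLOSUM62;
$o=5$, $e=2$ for nucleotide under +1/−2). The stop-codon sentinel `*`
scores −4 against everything *including itself*, so frames broken by
read-through never accumulate positive score. Raw scores $S$ convert to bit
scores and E-values by the Karlin–Altschul relations

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

with $\lambda = 0.267$, $K = 0.041$ for gapped BLOSUM62 and
$\lambda = 1.28$, $K = 0.46$ for the default nucleotide scheme — standard
published estimates, exposed in `scoring_scheme()` because only the
thresholds built on them matter here. Search significance is governed by
`e_max` (default $10^{-10}$ for candidate detection) and `min_coverage`
(default 0.5, echoing the common annotation practice of discarding gene
models with less than half their bases supported by an alignment). The
interval scan behind absence calls relaxes these to `e_max_interval`
$=10^{-3}$ and coverage 0.3, because there the cost asymmetry is reversed:
a missed weak hit would produce a false loss, while a false hit merely
demotes the call to ambiguous. Sources in this literature sometimes write
such cutoffs as p-values; the package standardizes on E-values throughout.

Search mechanics: exact k-mer seeds (k = 4 for protein/translated, 12 for
nucleotide) are grouped by diagonal within a 32-wide band, clusters with at
least two seeds are extended by a full Smith–Waterman over a padded local
window, and overlapping hits are reduced to the best-scoring one. Ties are
broken deterministically (bit score, then E-value, then coordinates;
traceback prefers diagonal over vertical over horizontal), so identical
inputs give byte-identical hit tables.

## Microsynteny score

A neighborhood is the up-to-`window` (default 5, about what published
gene-order figures display per side) genes on each side of a focal locus.
Two neighborhoods are compared by restricting each to the named genes shared
with the other and taking the longest common subsequence of the two orders;
the score is $|\mathrm{LCS}|$ divided by the smaller named-gene count, and
both orientations of one window are tried because assembly orientation is
arbitrary. A candidate passes the synteny gate when the best score over
reference species reaches `theta` = 0.3 *and* at least two shared named
genes support it — recognizable shared neighbors rather than full
collinearity, which is what the underlying studies actually required. When
no reference neighborhood has two named genes, synteny is uninformative and
a reciprocal-passing candidate stands on its own.

## The decision tree and its asymmetries

`classify_gene()` records every step in an evidence chain and resolves to
`present`, `absent` or `ambiguous`:

* **present** — a reciprocal-passing hit that passes the synteny gate (or
  has no informative reference neighborhood), or a reciprocal-passing
  transcript hit. Transcript evidence can *rescue* presence, but transcript
  silence never argues for loss: a gene can sit in the genome unexpressed
  in the sampled tissues, as the gel-forming gastric mucin does in these
  fish.
* **absent** — either no candidate anywhere plus both flanks anchored on
  one scaffold with an empty relaxed scan of the intervening interval
  (padded 2 kb per side for annotation-boundary tolerance), or every
  candidate unmasked as a paralog. Paralogs are unmasked two ways: the
  reciprocal ranking places only foreign symbols in the top `top_n` = 5
  distinct hits, or — the common desk-scale route — the candidate passes
  the reciprocal check on family resemblance but fails the synteny gate
  while sitting on a target gene annotated with a different family member.
  The second route is deliberate: within a compact gene family, any locus
  similar enough to be hit genome-wide will also rank the query's symbol
  among a short panel's top hits, so neighborhood identity, not rank, is
  the discriminating evidence. The classic case is a peptide-YY query
  landing on the neuropeptide-Y locus: reciprocal rank is equivocal,
  the neighborhood says `npy`, and the call is absent with
  `paralog_note = "npy"`.
* **ambiguous** — everything else: unanchorable flanks (assembly gaps,
  scaffold ends), hits in the scanned interval, reciprocal failures
  without a recognizable paralog. Demonstrating absence is intrinsically
  hard, and the classifier refuses to over-claim: deleting a single flank
  gene from a fixture flips a clean absent call to ambiguous.

Tightening `e_max` can demote calls (present → ambiguous/absent) but never
promote an absent call to present, and no call is present without a
recorded reciprocal pass — both properties are asserted in the test suite
by replaying evidence chains.

## The synthetic genome pair

`generate_pair()` builds a reference genome gene-by-gene (default 5
scaffolds × 20 genes; single-exon CDS of 100–300 codons; intergenic gaps of
200–800 bp at GC 0.45) and derives a target by:

* **codon-aware divergence** at per-site probability `d` (default 0.15,
  a realistic teleost–teleost distance), with two-thirds of substitutions
  placed at third codon positions and substitutions that would create an
  in-frame stop redirected, so planted proteins stay recognizable (mean
  amino-acid identity ≥ 0.7 at the default, asserted statistically);
* **indels in intergenic sequence only** (rate 0.02), keeping reading
  frames intact — the generator models annotation-level loss, not
  pseudogenization;
* **losses** (default 10): the gene body is removed and the flanking
  intergenic sequence retained, so a non-empty candidate interval remains
  between the surviving neighbors, exactly the situation a flank-anchored
  scan must recognize; losses never sit at scaffold ends or adjacent to
  each other, and the expected interval is recorded in the ground truth;
* **paralog duplications** (default 5): extra-diverged copies appended to
  a different scaffold, unlinked from the source neighborhood;
* **inversions** (default 3 blocks of 2–4 genes), reversing gene order and
  strands locally — enough rearrangement to exercise the
  orientation-maximizing synteny score without destroying it.

Event gene sets are disjoint and never touch a lost gene's flanks, which
keeps the ground truth well-defined (every fate partitions the reference
set; every lost gene's flanks survive). The ortholog panel carries each
family's reference protein plus an independently diverged outgroup copy, so
reciprocal rankings have realistic competition. Identical configurations
and seeds produce byte-identical FASTA/GFF3/TSV outputs.

The deterministic fixture bundle (`build_fig1_fixtures()`) encodes, at the
symbol level, the published neighborhoods this class of analysis rests on —
ghrelin between `ccdc174` and `tatdn2` in the reference but missing between
the retained flanks in the wrasse-like target, the motilin receptor next to
`fndc3a`, the transcobalamin-like gene next to `abcg4`, paralog families
(`npy`/`pyya`/`pyyb`, `ccka`/`cckb`, `tcn1`/`tcn2`/`tcnl`) built as diverged
copies of a family base protein — with entirely synthetic placeholder
sequences under a fixed internal seed. What the fixtures encode is gene
*order*, not real sequence content; `ghsrb` is used as the canonical
ghrelin-receptor symbol (alias `ghsr`) and `mln` for motilin (alias `mnl`).

**What passing these tests shows — and what it does not.** The simulator
emulates compact, intron-sparse loci with clean single-isoform annotations,
no repeats, no assembly gaps (except those introduced deliberately via
`drop_gene()`), and divergence without selection. Green tests therefore
demonstrate that the *decision logic* is sound under its stated model:
losses are found because flanks anchor and intervals are empty, paralogs
are rejected on neighborhood evidence, and ambiguity is preferred to
over-claiming. They do not certify performance on real draft assemblies,
where fragmented scaffolds, tandem arrays and intron-rich genes make both
anchoring and coverage thresholds harder.

## Expression gradients

The gradient module is deliberately descriptive — the underlying
differential-expression testing belongs to dedicated count-model packages
and is out of scope here. Counts normalize to FPKM
($10^9 c / (\ell\, N)$ for count $c$, length $\ell$ bp, library size $N$),
segment profiles are arithmetic means of FPKM per ordered segment, fold
changes use a pseudocount `eps` = 0.01 FPKM so single-segment expression
stays finite, and `gradient_class()` labels a profile *declining* when the
segment means are non-increasing within a 10% multiplicative tolerance and
the first/last fold reaches `min_fold` = 2 (symmetrically *increasing*;
*flat* when neither direction reaches the fold; *other* for non-monotone
shapes). The classification is invariant to positive scaling of a gene's
values.

`generate_counts()` emulates the profiling design: 4 ordered segments × 6
replicates, log-normal baseline FPKM (meanlog = log 50, sdlog = 1.2),
negative-binomial counts at dispersion 0.1 (variance $\mu + 0.1\mu^2$;
dispersion 0 degenerates to Poisson, asserted as a distributional-limit
test), and a configurable fraction of genes (default 30% declining, 5%
increasing) carrying geometric per-segment factors spanning a total 4–16
fold — bracketing the single-gene contrasts such studies report. At these
defaults the recovered declining fraction lands within a few tenths of a
percentage point of truth; note that composition (30% of genes declining)
slightly tilts total-count normalization toward the posterior segments,
a real RNA-seq effect the generator reproduces rather than hides.

## Numerical and engineering choices

* Coordinates are 0-based half-open everywhere internally; GFF3's 1-based
  inclusive convention is converted exactly once on read and once on write.
* Gene symbols are looked up from GFF3 attributes in the order `gene_name`,
  `Name`, `ID` (configurable), covering Ensembl- and MAKER-style dialects;
  unnamed genes travel under their ids.
* Codons containing `N` translate to `X` rather than erroring; k-mers
  containing `N`/`X`/`*` are never indexed.
* The interval between anchored flanks is the gap between the innermost
  compatible pair; overlapping anchor loci or split scaffolds yield no
  interval and hence no absent call.
* Problem sizes in the test suite and acceptance script — 100-family
  genomes at three seeds for call recovery, 2 000 genes for gradient
  recovery, 200 random pairs for the aligner oracle — were chosen as the
  smallest sizes at which the statistical assertions are stable.

## Known limitations

* No HSP chaining across introns: queries are proteins against compact
  loci; intron-rich real genes would fragment coverage.
* No pseudogene detection (premature stops at a found locus still count as
  presence), no dN/dS, no tree-based orthology.
* The external-aligner adapter surface (tabular hits into `homology_hits`)
  is intentionally minimal; the internal aligner is the only tested path.
* Absence calls inherit the assembly's quality: the package refuses to
  call loss across unanchorable regions, but it cannot see a gene hiding
  in sequence that simply is not there.
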