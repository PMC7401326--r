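---
title: "Extending partial BLAST matches of non-coding RNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extending partial BLAST matches of non-coding RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaxtender)
```

## The problem

A nucleotide BLAST search for a non-coding RNA returns high-scoring
pairs (HSPs): local alignments between the query RNA and stretches of
database subject sequences. An HSP frequently covers only a fragment of
the subject RNA it hits. Secondary structure, homology and function can
rarely be judged from a fragment, so interpreting such output requires
reconstructing the *full-length* subject sequence behind each partial
match. `rnaxtender` automates that reconstruction and the downstream
characterization: homology classification against the query and
secondary structure prediction for every extended match.

## Coordinates and alphabets

All coordinates in the package are 1-based inclusive, the convention of
both BLAST reports and the Bioconductor ranges infrastructure. We
deliberately use one convention end to end: translating into a second
internal convention at the parse boundary would create, not remove,
off-by-one opportunities in a language whose string and range APIs are
1-based closed. Minus-strand HSPs are stored on the subject plus strand
(`s_start <= s_end`) with a strand flag; extension operates on the
query-oriented reverse complement, so "5' of the query" is always well
defined. T and U are interchangeable on input; every comparison is done
on a canonical RNA form and output preserves the input alphabet.

## Step 1 — extension of partial matches

Three methods extend an HSP to a predicted full-length interval.

**simple.** Pure coordinate arithmetic: the unmatched query stretches are
added to both ends of the subject match. For a plus-strand HSP,
`start = s_start - (q_start - 1)` and `end = s_end + (L - q_end)` with
`L` the query length, clamped to the subject bounds with truncation
flags. The canonical worked example — HSP covering query 14–24 and
subject 21–31 of a 31-nt query — extends to subject interval 8–38:

```{r}
h <- hsp(14, 24, 21, 31, "plus", bit_score = 22.3, e_value = 1e-5)
simple_extend(h, query_length = 31, subject_length = 60)
```

The method is fast but context-blind: any insertion or deletion between
query and subject outside the HSP shifts the ends.

**locarna.** The simple interval is padded by `o_loc` nucleotides on
each side (default 30, the tool's published default) and the padded
window is realigned to the *whole* query, with the HSP's gap-free runs
fixed as anchors. The returned interval is the span of window positions
between the first and last alignment column that pairs a query residue
with a window residue; window overhang aligned to end gaps is trimmed.
The built-in aligner is a sequence-only anchored affine-gap dynamic
program (a gap of length *k* costs `gap_open + k * gap_extend`); a
sequence–structure aligner can be substituted behind the same interface,
and the anchoring/trimming logic — the part that matters for extension —
is identical either way.

Two alignment-scoring decisions deserve emphasis:

* *Free end gaps apply to the window only.* The window is padded by
  construction, so its overhangs must be free. The query, however, is
  aligned globally. If query end gaps were also free, a mutated terminal
  query base would always be dropped (end gap cost 0 beats mismatch
  −1) and the method would systematically trim substituted ends instead
  of assigning them — the opposite of what anchored realignment is for.
* *Scores default to the search scoring* (+1 match, −1 mismatch, gap
  existence 2, extension 1), the least arbitrary choice given that the
  HSPs being extended were produced under it. Tie-breaking in the
  traceback is fixed (aligned column over gap, query-row gap over
  window-row gap), so outputs are deterministic.

**meta.** Both candidates are scored against the query model (below) and
the higher-scoring sequence wins; ties go to the anchored candidate,
which is also the pipeline default. The per-HSP winner is one of the two
candidate intervals by construction.

## Step 2 — homology classification

Each extended match is scored against a model of the query and the bit
score `s` is classified with the query length `l`:

* **homologous** if `s / l >= 0.5` and `s >= 20`,
* **not homologous** if `s < 0`,
* **uncertain** otherwise.

The per-nucleotide condition demands at least half a bit of support per
query nucleotide, filtering out fragments with high local similarity;
its dependence on `l` reflects that longer queries can contain longer
locally similar fragments by chance.

The scoring contract is "sequence in, bits out", so any covariance-model
scorer can be plugged in through `command_scorer()` (a command template
receiving a FASTA file and printing a total bit score). The built-in
scorer is an explicit stand-in, not a covariance-model implementation:
it aligns the candidate to the query globally (candidate overhangs
free) under a ±1-bit log-odds matrix and adds `pair_bonus` (default 2
bits) for every query base pair whose aligned candidate bases can form
a Watson–Crick or GU pair, subtracting it otherwise. It is calibrated
so the thresholds behave sensibly — an identical match of length `l`
with `p` pairs scores exactly `l + 2p` bits, so any identical match of
40 nt or more is homologous — and it makes no claim of bit-score
equivalence with profile-model tools.

## Step 3 — secondary structure prediction

Fifteen method recipes are registered (see `prediction_methods()`),
split into category 1 (pooling reference sequences from the search
output) and category 2 (using the match alone, possibly with a
covariance-model consensus structure). The recipes combine five
primitives:

* `fold()` — constrained maximum-base-pairing folding (Watson–Crick +
  GU, minimum hairpin loop 3). This is a combinatorial stand-in, not a
  thermodynamic model: the package's contribution is the combinator and
  selection logic around folding, and all thermodynamic engines are
  external command adapters behind the registry (`engines` in
  `predict_context()`); when an engine required by a default method is
  absent the pipeline substitutes the built-in consensus-constrained
  fold and records the substitution in the report.
* `suboptimal()` — the k best distinct structures by pair count,
  enumerated exactly at any length with a Lawler-style partition
  search: emit the optimum, then branch into disjoint subproblems that
  force some of its pairs and ban one, each solved by the constrained
  folding kernel. Deterministic, no sampling.
* `query_anchored_msa()` + `consensus_structure()` — references are
  pairwise-aligned to the query and merged on query columns; column
  pairs are scored by the number of rows that can pair plus a
  covariation bonus when two or more distinct pair types occur, pairs
  supported by fewer than `max(2, ceiling(f * rows))` rows (default
  `f = 0.5`) are dropped, and the maximum-weight nested structure is
  taken. Conserved-unpaired columns feed the `-U-` method variants.
* `select_by_reference()` — picks the suboptimal structure closest to a
  reference by tree edit distance.
* `select_reference_sequences()` — homologous-labeled matches, excluding
  sequences nearly identical to the query (default identity threshold
  0.98; near-identical references only echo the query back and distort
  consensus evidence), ordered by model score and dereplicated at 0.99
  mutual identity.

Structure comparison uses the ordered tree edit distance (Zhang–Shasha,
unit costs) on the tree with one internal node per base pair and one
leaf per unpaired base. This fixed encoding is applied to both sides of
every comparison; since the benchmark uses distances only relatively,
the specific coarse-graining convention of other tools need not be
replicated. A cheap base-pair set distance is also provided.

## The synthetic benchmark

The benchmark module doubles as the package's fixture generator and
follows the decoy-database protocol:

1. `generate_synthetic_family()` draws a founder compatible with a
   consensus structure and mutates members (substitutions at paired
   sites compensatory with probability 0.8; indels restricted to
   loops). Defaults follow the published protocol: 3 members held out
   as queries, 1000-nt flanks, 10 dinucleotide-shuffled decoys per
   planted member.
2. `build_artificial_database()` embeds planted members and decoys with
   flanks into one long subject per family and records the truth table;
   every build audits that the truth intervals recover the planted
   sequences. Unavailable natural flanks are filled with seeded i.i.d.
   sequence matching the member's composition (`natural_stub`), or with
   dinucleotide-shuffled copies of the member (`shuffled`, the
   500-nt-flank protocol used by the structure benchmark).
3. `fabricate_search()` emulates BLAST without a network or external
   binary: a seeded fragment of the query (about 60% of its length) is
   locally aligned against a window around each planted interval under
   the search scoring; the local alignment score stands in for the HSP
   bit score. An optional path through real `blastn` output files is
   available since the parser reads the native pairwise dialect.
4. `run_extension_benchmark()` scores each method's predicted interval
   by the total error — the sum of absolute 5' and 3' offsets from the
   planted truth. `run_structure_benchmark()` bins HSPs into bit-score
   tertiles per query (equal truth-match counts up to 1, remainder and
   ties to the higher bins; queries with fewer than 3 truth matches are
   excluded, mirroring the exclusion rule of the original evaluation),
   runs the full characterization and reports mean tree edit distance
   to the family template normalized by query length, with percentile
   bootstrap intervals (default 100 iterations) and a decoy baseline.

Dinucleotide shuffling preserves exact dinucleotide counts via a random
Euler path through the dinucleotide multigraph, the standard decoy
construction for RNA (shuffles preserving only mononucleotide
composition would destroy local stacking statistics and make decoys too
easy); the shuffle kind is configurable where only "shuffled" was
specified.

**What the generator emulates — and what it does not.** Families share
a planted consensus with compensatory variation, members sit in long
flanked contexts, decoys have realistic local composition, and HSP
quality varies through fragment length and mutations. It does not
emulate: thermodynamically realistic structures (the folding stand-in
is maximum-pairing), non-uniform phylogenetic correlation between
members, repeats or low-complexity tracts in flanks, sequencing errors,
or introns (matches containing introns are explicitly out of scope for
coordinate-arithmetic extension). Passing benchmarks therefore
demonstrate the correctness and relative behavior of the pipeline
machinery, not absolute accuracy on curated family data.

**Problem sizes.** The shipped tests and benchmarks use 2–5 families of
6–7 members built on a 48-nt consensus, with 80–200-nt flanks and 2–10
decoys per member — sizes chosen so the whole suite runs in well under
a minute while every code path (binning, reference selection, consensus
prediction, bootstrap) is exercised with dozens of records. The
protocol defaults (1000/500-nt flanks, 10 decoys, 3 held-out queries,
100 bootstrap iterations) remain the documented defaults of the
generator and drivers.

## Numerical choices and degenerate inputs

* Affine gaps: `gap_open = -2`, `gap_extend = -1`; a length-k gap costs
  `gap_open + k * gap_extend`.
* Folding: minimum hairpin loop 3; only A-U, G-C and G-U pairs; other
  IUPAC codes never pair. Contradictory constraints (a position both
  paired and unpaired, a forced pair that cannot form) raise errors
  rather than being silently dropped; consensus pairs mapped onto a
  match are soft constraints and are dropped when unpairable there.
* Tie-breaks are fixed everywhere: alignment (column over gap, query
  gap over window gap, 5'-most end cell), folding traceback (3'-most
  base pairs with its 5'-most admissible partner), structure selection
  (earlier candidate), reference ordering (score, then id).
* Extension across a subject boundary clamps the interval and flags the
  truncated side instead of erroring — short contigs are common.
* Quality binning with all-equal truth scores is flagged degenerate
  (one bin absorbs everything); fewer than three truth matches is an
  error.
* Bootstrap intervals with `n_boot = 1` collapse to the point estimate.

## Limitations

The built-in folder ignores thermodynamics, so absolute structure
accuracy is bounded; use engine adapters for production predictions.
The built-in homology score is not calibrated to covariance-model
E-values. The parser targets the modern `blastn` pairwise dialect (and
tabular outfmt 6/7); older program dialects, XML/JSON and protein
reports are out of scope. Intron-containing subjects cannot be extended
correctly by any of the methods. The interactive report of the original
tool is replaced by a static HTML summary.
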