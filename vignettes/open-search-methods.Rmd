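---
title: "Methods: nonspecific indexing and open modification search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonspecific indexing and open modification search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openpept)
```

## The problem

Shotgun proteomics identifies peptides by comparing experimental tandem-mass
(MS/MS) spectra against theoretical fragments of peptides predicted from a
protein sequence database. Conventional engines restrict the candidate space in
two ways: they assume a digestion enzyme (usually trypsin) produced the observed
peptides, and they search only a handful of pre-declared post-translational
modifications. Both restrictions are guesses; when they are wrong, the spectrum
goes unidentified. An *open* search removes both: candidate peptides are **all**
substrings of the database within a length and mass window (nonspecific
digestion), and a precursor mass that disagrees with the matched peptide is
explained after the fact as a modification, by looking the mass difference up in
a catalogue of known modification masses.

The price of openness is scale: nonspecific digestion inflates the candidate set
by roughly four orders of magnitude relative to the protein count. `openpept`
makes that tractable with (i) a mass-sorted, fixed-width peptide index built
once per database, (ii) a two-stage open search that prunes candidates before
the modification lookup, and (iii) a partitioning scheme that splits database
and spectra across workers without changing the result.

## Peptide enumeration and masses

Three digestion semantics are implemented, distinguished by which peptide
termini must lie at an enzymatic boundary:

* **specific** — both termini (classic digestion; trypsin rule: cleave after K
  or R unless the next residue is P, with up to `max_missed_cleavages` internal
  sites left uncut; default 2, the common community setting);
* **semispecific** — at least one terminus;
* **nonspecific** — neither: every substring qualifies.

All modes share inclusive filters: length 3–60 residues and neutral
monoisotopic mass 300–8000 Da by default. Masses are monoisotopic (the target
instruments are high-resolution); a peptide's neutral mass is the sum of its
residue masses plus one water (18.010565 Da). The residue table covers the 20
canonical amino acids plus selenocysteine; peptides spanning ambiguity codes
(B, J, O, X, Z) are skipped rather than assigned a fabricated mass. Windows are
read as closed intervals on both ends — the conventional reading of a stated
"300–8000 Da" range. Enumeration order is fixed (ascending start, then length)
so every downstream artefact is reproducible.

Coordinates are 0-based, half-open internally — an index term
`(protein_id, start, length)` denotes `sequence[start, start + length)` — and
1-based in user-facing report files.

## The mass-sorted fixed-width index

All enumerated terms are sorted globally by `(mass, protein_id, start, length)`.
Each term is three integers plus its 8-byte mass key, so records are constant
width (20 bytes on disk) and the entry array can be addressed by offset
arithmetic alone. The claim that the first valid position for a queried mass
can be found in constant time is realised with an integer-Dalton *bucket offset
table*: for every integer `b` in the configured mass window, the table stores
the first array position with mass ≥ `b`. A range query `[lo, hi]` jumps to
bucket `floor(lo)`, bisects only within that bucket (whose expected occupancy
is bounded by the index density per Dalton), and finds the upper end by
bisection; a global bisection covers queries outside the table. Range semantics
are inclusive at both ends, matching symmetric tolerance windows.

The on-disk format (documented byte-by-byte in `R/index_io.R`) is
little-endian and versioned: a fixed 148-byte header carrying the digestion
parameters and a database fingerprint, then the mass array, the 12-byte entry
records, and the bucket table as 8-byte unsigned offsets. Loading is bit-exact.
The fingerprint (md5 over accessions and sequences) lets search-time code warn
when an index is stale for the database supplied with it.

## Scoring

The package's scorer is deliberately simple and fully documented, since its
role is to rank candidates reproducibly rather than to reproduce any
proprietary scoring function: theoretical singly-charged b- and y-ions
(`b_i = prefix_i + proton`, `y_i = suffix_i + water + proton`) are matched
greedily one-to-one to observed peaks within `fragment_tol` (default 0.02 Da,
an HCD-typical value), each observed peak claimable once, closest m/z first.
The score is `matched_peaks + matched_intensity / total_intensity`: an integer
fragment count with an explained-intensity fraction as tie-breaker. Ranking is
total and deterministic: score descending, then absolute precursor delta, then
`(protein_id, start, length)`.

## Two-stage open search

For a spectrum with observed neutral mass `M` (from
`M = z·mz − z·1.007276`):

1. **Stage 1 — anchoring.** Candidates are all index terms with mass in
   `[M − δmax, M − δmin]` (default δ range −200 to +500 Da, covering every
   modification in the shipped table). Each candidate is scored with its
   *unmodified* fragments. A single modification shifts only the ions spanning
   its site, so the series on the other side — unmodified y-ions when the
   modification sits N-terminal of a position, and vice versa — still matches;
   this anchors one terminus and justifies discarding candidates with fewer
   than `min_matched_peaks` (default 2) unmodified matches. The implementation
   first applies a vectorised upper bound (fragments with *any* peak within
   tolerance, computed for all candidates at once from cumulative residue
   sums), which can only over-count the greedy matching, then exact greedy
   matching on the survivors — so the surviving set is exactly the one exact
   filtering would produce, at a fraction of the cost.
2. **Stage 2 — delta lookup.** Each survivor's residual `δ = M − mass` is
   interpreted: within `mod_match_tol` (default 0.01 Da) of zero the candidate
   is unmodified; otherwise δ is looked up in the inverted modification index —
   records sorted by signed delta mass with their own 1-Da bucket table, so the
   lookup is constant expected work — and every sequence-compatible site of
   every returned modification is rescored with shifted fragments, keeping the
   best (ties broken towards the closer delta mass, then the smaller site). A
   δ matching no record is reported unmodified and flagged `unexplained-delta`
   rather than silently dropped. Modified and unmodified interpretations then
   compete on score in one ranking.

One modification per peptide is assumed, matching the single-delta design;
combinatorial multi-site search is out of scope. The delta-to-modification
tolerance is a free parameter because no canonical value exists; 0.01 Da
separates all but two pairs in the shipped 25-entry table (phospho/sulfo and
the two −18.010565 losses are intrinsically ambiguous by mass, and are then
decided by fragment evidence or, failing that, by delta-distance rank).

## Distribution

Three mechanisms keep multi-worker search equal to the monolithic run:

* **Database partitioning by amino-acid count.** Digestion and index size are
  driven by residue counts, not protein counts, so parts are balanced on
  residue totals, with the imbalance between parts bounded by the length of
  the longest single protein. A naive greedy against the target
  `ceil(total_residues / n_parts)` can miss that bound on small adversarial
  inputs, so the partition is found by a window-feasibility search instead:
  binary-search the minimax part sum, then scan the maximum `M` upward until a
  contiguous split exists with every part total in `[M − L, M]` (`L` = longest
  protein), checked by a vectorised reachability pass over prefix sums. Parts
  stay contiguous in database order, keeping the plan deterministic. For very
  large databases — where each part holds many proteins and the imbalance is
  negligible by construction — the greedy (with local boundary refinement) is
  used directly.
* **Mass-sorted spectrum chunks.** Spectra are sorted by neutral mass (ties by
  id) and cut into near-equal-count chunks, one per worker, assigned
  statically. Equal count (rather than equal mass span) was chosen because
  per-spectrum work is roughly uniform while the index density per Dalton is
  strongly non-uniform; mass-adjacent spectra in one chunk also touch the same
  index region.
* **Memory-capped blocks with prefetch.** Each part's index is split into
  mass-contiguous blocks of at most `memory_cap` entries. Every chunk is
  searched against every block and per-spectrum results are merged under the
  global ranking rule. Any PSM in the monolithic top-k is in its own block's
  top-k, so merge-then-truncate is exactly equivalent — this is the central
  correctness property of the design, and it is asserted byte-for-byte in the
  tests. Optionally the next block is materialised in a background fork while
  the current one is searched; by the same argument the result is independent
  of whether prefetch happens.

## The synthetic benchmark generator

`simulate_benchmark()` creates the study conditions used throughout the tests:
a uniform-residue database (50 proteins of 80–200 residues by default), one
planted peptide per spectrum drawn from the database under the index's own
length and mass windows (length 7–25, long enough that sequence identity is an
unambiguous recovery criterion in a random database), charges 2–3, optional
planted modifications at sequence-compatible sites, and noise-free peaks unless
dropout or noise peaks are requested. What it does **not** emulate: realistic
residue composition, isotope envelopes, multiply-charged or neutral-loss
fragments, chimeric spectra, or calibrated intensity models. Passing recovery
tests therefore demonstrates the correctness of the indexing, retrieval and
delta-resolution machinery — not real-data identification rates, which depend
on scoring subtleties this package deliberately keeps simple.

Benchmark scales used by the test-suite and the acceptance script (chosen as
the smallest sizes at which the properties are meaningfully exercised): 100
proteins for enumeration conservation, a ~1e5-term index with 1000 random
windows for retrieval equivalence, 200 spectra each for closed and open planted
recovery, and 5000 spectra for the distribution-transparency check.

## Numerical and degenerate-input choices

* All mass constants live in one table (`mass_constants`, `residue_masses`);
  proton 1.007276 Da, water 18.010565 Da.
* Fragment lists are deduplicated at 1e-6 Da; the b/y complementarity identity
  `b_i + y_{n−i} = M + 2·proton` holds to the same tolerance and is asserted
  for 1000 random peptides.
* Empty inputs: an empty FASTA yields an empty database; an empty database a
  valid empty index; an empty peak list scores `(0, 0)`; an empty spectrum set
  returns an empty PSM table without spawning workers. `fraction_below` on an
  empty index is an error (the statistic is undefined), not a silent 0.
* Greedy peak matching breaks distance ties towards the lower m/z peak;
  ranking ties are always resolved by the fixed entry-order chain, so no
  output depends on hash or scheduling order.
* RNG: every generator takes an explicit seed and restores the caller's RNG
  state, so library code never perturbs a session's random stream.

## Known limitations

* The stand-in scorer has no statistical calibration (no e-value, no FDR);
  target-decoy estimation and protein inference are out of scope.
* One modification per peptide; no blind (catalogue-free) modification search.
* Fragment model: singly-charged b/y only; no isotope envelopes or losses.
* MGF and FASTA are the only I/O formats (mzML and Unimod XML are documented
  extension points, not dependencies).
* Parallelism is single-machine fork-based; multi-node execution is not
  reproduced here.
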