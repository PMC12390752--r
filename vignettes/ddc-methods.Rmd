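---
title: "Modelling hierarchical data access on DNA domino-array carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hierarchical data access on DNA domino-array carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddcaccess)
```

## The system being modelled

A DNA-based data carrier (DDC) is a reconfigurable origami domino array. A
message is written onto it as a pattern of biotin-modified staples on a
5 × 5 message lattice plus a 1 × 5 address row — 30 addressable label sites
per carrier. Streptavidin (STV) binds the biotinylated sites and makes the
pattern visible by AFM: an STV-occupied site reads as bit 1, a plain staple
as bit 0.

The carrier has two stable conformations. In the locked (OFF) state the
label lattice sits at a compact pitch and the pattern is ciphertext; when
the thirteen displaceable edge staples are removed and the short-side
scaffold gap regions are resolved, the array relaxes into the unlocked (ON)
state, stretching one lattice axis, and the pattern becomes readable
plaintext geometry. Two always-biotinylated marker sites report the
conformation through their separation — short means OFF, long means ON.

Two triggers unlock a carrier, and they differ in scope:

* **Admin key — polymerase.** Gap-filling and polymerase-triggered strand
  displacement start from primer-bound domains without sequence
  specificity, so one polymerase trigger transforms *every* carrier
  (one-to-many).
* **User key — DNA strand set.** Competing strands pair the gap regions and
  invading strands enter at the edge-staple toeholds; both are exact
  reverse complements of their target regions, so the set transforms *one*
  carrier only (one-to-one).

`ddcaccess` implements this system end to end: codec, carrier geometry,
key semantics and key-space enumeration, stochastic readout simulation,
observation-side decoding, and yield statistics.

## The codec

The printed array capacity forces the default text encoding. A 5 × 5
message array holds 25 bits, but four 8-bit ASCII characters need 32; an
8-bit encoding cannot store a four-letter word on one carrier. The default
scheme `a5` therefore uses a 5-bit alphabet — space/pad = 0, A = 1 … Z = 26
— with one character per column, most-significant bit at the top. An
`ascii8` scheme is provided as the 8-bit alternative; its byte stream is
laid column-major across the grid, which caps a carrier at three ASCII
characters, and longer words are rejected with a capacity error rather than
silently spanned across carriers (word boundaries could not be recovered
from independently addressed carriers on readout).

Because one tetravalent STV molecule can bridge biotins on adjacent sites,
words are spaced: a blank (all-zero) column is inserted between consecutive
character columns whenever the spaced layout fits the grid ("DNA" occupies
columns 0, 2, 4). When it does not fit (four- and five-letter words), the
spacing is dropped with a warning — blank columns are a selectively applied
guard, not a hard constraint.

The address row stores the carrier's word index (MSB leftmost; 2^5 = 32
distinguishable carriers). Before access, the message bits are mixed by an
address-keyed permutation so the OFF-state pattern is ciphertext. The
reference permutation family (`colshift`) cyclically shifts column *c*
downward by `(word_index + c) mod 5`. It was chosen because it is trivially
invertible, uses only information present on the carrier itself (the
address row), and mixes the address into every column. The published
mixing rule behind the ciphertext "PDTDB XUUUI \\PBXDL" is not specified in
enough detail to reproduce; `render_ciphertext()` reproduces its *character
inventory* (column value `v` renders as the character with code `64 + v`,
so `v = 28` is a backslash) but no claim is made that the printed string
itself is regenerated. The scheme records the rule identifier so alternative
permutation families can be plugged in.

```{r codec}
grids <- suppressWarnings(encode_message("DNA NANO TECH"))
render_ciphertext(grids)
decode_message_grids(grids)
```

## Carrier geometry

No physical label-pitch values are published for this carrier, and none of
the algorithms depend on absolute distances — only on the OFF/ON pitch
*ratio*. The defaults are OFF pitch (6, 6) nm and ON pitch (6, 12) nm,
stretching the row axis, with the marker pair two rows apart in a dedicated
column left of the data array (so marker spots never collide with data
sites). All thresholds downstream are expressed as fractions of the design
pitch, never in absolute nanometres.

One consequence of a 2:1 pitch ratio is worth naming: a pattern whose
occupied rows are all even is geometrically ambiguous between OFF and ON
(even OFF rows coincide with ON rows). The shipped message fixtures and the
marker/address geometry keep odd-row content present, and the classifier's
ambiguity band returns UC rather than guessing when a field genuinely
cannot be told apart.

The transformation itself is modelled as a single Bernoulli event per
structure. The underlying anti-junction cascade (base stacking plus the
entropic-spring pull of the gap regions) is treated qualitatively in the
source material, so per-junction propagation is deliberately abstracted
into the per-structure transformation probability; `derive_state()` keeps
the edge/gap bookkeeping (OFF = nothing displaced, ON = everything
displaced and resolved, IC = anything in between) for callers that model
partial progress explicitly.

## Keys and the breakpoint key space

A user key is derived from its carrier: competing strands are reverse
complements of the two 16-nt gap regions, invading strands reverse
complements of the seven 16-nt overhang domains (13 edge staples cycle
through the 7 orthogonal domains). Moving the circular scaffold's
breakpoint relocates every one of those regions, so each breakpoint mints a
distinct key: at the M13mp18 scaffold length of 7,249 nt and 1-nt shifts
the unfiltered key space holds 7,249 > 7,000 candidates.

Since no real scaffold needs to be downloaded, a seeded pseudorandom
circular sequence of the M13mp18 length stands in by default
(`scaffold_model()`); a real sequence is used verbatim when supplied via
FASTA. The shipped `DDC-1.json` / `DDC-2.json` fixtures are two
sequence-resolved designs on the same synthetic scaffold with breakpoints
0 and 1,800 — far enough apart that none of their derived regions overlap.

Orthogonality screening uses a k-mer rule with k = 8 by default, a standard
strand-displacement heuristic: two keys are orthogonal iff they share no
complementary 8-mer with each other's target regions. Because every
target region is the exact reverse complement of its trigger strand, the
score reduces to the longest common substring between the two keys' raw
strands; this formulation is symmetric and scores a key against itself at
the full strand length, which is the behaviour an orthogonality screen
must have. `enumerate_breakpoint_keys()` applies the screen as a greedy
first-come scan in breakpoint order; maximal-independent-set optimisation
over the candidate graph is out of scope.

## The readout simulator

`simulate_structure()` draws, per structure:

1. a conformation — ON with the key-conditioned probability `p`,
   otherwise IC with conditional probability `p_ic`, else OFF;
2. an STV outcome per biotin site — bound independently with probability
   `q` (false spots on "0" sites with probability `fp_rate`, zero by
   default);
3. spot positions — the realized conformation's lattice coordinates plus
   isotropic Gaussian localization noise (`loc_sigma_nm`).

The parameter defaults are the measured study conditions: `p_user = 0.89`
and `p_admin = 0.76` (ON-conformation yields under the strand-set and
polymerase triggers), `p_spont = 0.14` (86% of untriggered structures stay
locked), and `q = 0.95` (the fraction of biotin sites correctly bound by
STV when STV is supplied in excess). A mismatched user key transforms at
`p_spont` — no partial cross-talk — consistent with mismatched-key yields
matching untriggered baselines.

Two modelling points deserve emphasis:

* **`p` is the probability of reaching ON.** The transformation ratios were
  measured *as* ON-conformation yields, so the simulator draws ON with
  probability `p` exactly and carves the intermediate conformation out of
  the complement (`P(IC) = (1 - p) · p_ic`). This makes the analytic
  CorrInfo yield `p · qⁿ` the exact expectation of the Monte-Carlo CorrInfo
  frequency, which the test suite verifies across a grid of `(p, q, n)`.
  The IC rate itself is unquantified in the source material; `p_ic = 0.05`
  is a documented placeholder, as are `fp_rate = 0` and
  `loc_sigma_nm = 0.6` (10% of the minimum pitch).
* **STV multivalency is folded into `1 - q`.** One STV bridging adjacent
  biotins is mitigated at the design level (blank columns, excess STV), and
  no separate failure rate is published to calibrate it, so it is not a
  distinct simulation channel.

CorrInfo — the success criterion — is "the carrier reached ON *and* every
biotin site of the data + address array bound STV *and* no false spot
appeared". The two marker sites are biotinylated and simulated like any
other site but are excluded from CorrInfo and from the site count `n`
by default, because marker-only experiments tally them separately
(`count_biotin_sites(include_markers = TRUE)` restores them).

Reproducibility: an ensemble draws one child seed per structure from the
root seed and records them, so any single structure can be regenerated
bit-for-bit.

## The decoder

`decode_message()` runs the observation chain: classify the conformation,
register the spots on the lattice, call bits, read the address row,
descramble, decode.

* **Classification** fits the field to the OFF, ON and intermediate
  templates (full lattice plus markers) by translation-only registration
  and picks the smallest mean nearest-site residual. Registration starts at
  zero offset (simulated fields live in design coordinates); when that fit
  is not clean, an anchor search seeds iterated-closest-point refinement
  with every translation that maps the first spot onto a template site,
  which recovers arbitrary rigid translations without falling into
  lattice-shifted local optima. Rotation search is out of scope (carriers
  are read under fixed shape-based rules); an optional 90° axis swap is
  available for rotated inputs.
* **Acceptance and ambiguity.** A fit is accepted when its residual is
  below `tol × min(pitch)` with `tol = 0.35`; if the runner-up fit is
  within 10% relative residual of the winner the call is UC. Both numbers
  are configurable; they are expressed design-relative so they survive any
  pitch rescaling. An empty field is UC, not an error.
* **Bit calling** assigns each spot to its nearest site within the same
  radius; ties break deterministically toward the lower (row, col) index,
  two spots on one site collapse to a single 1 (logged), and unassigned
  spots are logged as noise. Degraded inputs degrade the call — decoding
  never raises on noisy data, and unknown column codes render as `?`.
* Plaintext is produced only from ON fields; an OFF field yields ciphertext
  bit calls and no text. With ground truth attached, `corrinfo` is the
  strict criterion above, so `corrinfo = TRUE` implies an ON call.

## Yield statistics

`yield_exp()` is the exact count ratio M/N with a 95% Wilson score interval
— chosen over the Wald interval because AFM-style condition counts are
small (tens to low hundreds) and can sit near 0 or 1, where Wald intervals
collapse or escape [0, 1]. `yield_theo()` is the exact product `p · qⁿ`,
strictly decreasing in `n` for `q < 1`: carriers storing sparse words
("DNA", 5 biotin sites) outperform dense ones ("NANO", 12 including its
address bit), and the simulated word yields reproduce that ordering.

`run_condition()` chains simulate → decode → tabulate for one condition and
attaches the matching analytic yield; `hierarchy_matrix()` tallies
simulator-truth CorrInfo for every key × carrier pair, which is the exact
Monte-Carlo counterpart of `p · qⁿ` per cell and keeps the permission-matrix
experiment fast. The shipped `fig2.json`, `fig3.json`, `fig4.json` configs
reproduce the three experiment shapes (marker-only transformation,
three-word access, two-user hierarchy) with fixed seeds.

```{r yield}
yield_theo(0.89, 0.95, 5)   # a sparse word under the user key
yield_exp(73, 85)           # an OFF-retention count reading 86%
```

## What the synthetic data does and does not show

The generator emulates: key-conditioned transformation at the measured
rates, independent per-site binding dropout, optional false spots,
localization noise, and OFF/ON/IC geometry including marker separation.
It does not emulate: AFM tip–sample convolution, scanner drift, tip
doubling, structure damage/aggregation (the "intact structures" filter is
assumed upstream), per-junction transformation dynamics, or thermodynamic
sequence effects on transformation efficiency. Passing tests therefore
demonstrate the internal consistency of codec, simulator, decoder and
statistics under the stated stochastic model — not instrument-level
performance on real micrographs.

Problem sizes used by the test suite were chosen to make binomial 3-SE
bands decisive while keeping runs desk-scale: 10,000 structures per
Monte-Carlo condition (SE ≤ 0.5 percentage points), 5,000 per
permission-matrix cell, 10,000 random messages for the codec identity, and
10,000 simulated fields for classifier agreement (≥ 99% against simulation
truth at noise σ = 10% of the minimum pitch).

## Known limitations

* The scramble rule is a documented stand-in for the unpublished mixing
  rule; ciphertext strings are not expected to match published renderings
  character-for-character.
* Translation-only registration assumes at most a rigid offset and an
  optional axis swap; rotated or sheared fields are out of scope.
* The anchor search seeds registration from the first spot; a field whose
  first spot is a false positive can mis-register when a global offset and
  false spots occur together (not a configuration the defaults produce).
* The k = 8 orthogonality threshold is a heuristic screen, not a
  thermodynamic model; no nearest-neighbour ΔG calculation is performed.
* Breakpoint-derived region layout (two 16-nt gaps, seven 16-nt domains at
  20-nt spacing) is a concrete stand-in for the unpublished staple-level
  layout; all key-space results are relative to it.
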