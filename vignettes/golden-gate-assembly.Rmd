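---
title: "Golden Gate assembly in silico: the gatekit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Golden Gate assembly in silico: the gatekit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatekit)
```

## The reaction being modeled

A Golden Gate (GG) reaction mixes a destination backbone and many inserts
with a type IIS enzyme and ligase, and thermocycles digestion against
ligation. Type IIS enzymes cut at a fixed offset outside a non-palindromic
recognition sequence; the cut leaves a short 5′ overhang whose sequence is
free, so each junction between fragments can be programmed independently.
Correctly designed inputs put every recognition site on the *discarded* side
of each cut: entry clones carry inward-cutting sites on their KanR backbone,
so the released insert is site-free, while the destination vector carries
outward-cutting sites in its stuffer, so its AmpR backbone is released
site-free. The designed product therefore contains no site and, once ligated,
is never re-cut — it accumulates as the only stable circular species.

`gatekit` models this at the reaction's fixed point rather than kinetically:

1. every input is digested to completion (`digest()`);
2. fragments still carrying an internal recognition site of the assembly
   enzyme are excluded from circularization — in the real reaction any
   circle containing them is re-linearized;
3. all circular closures over the remaining fragments are enumerated, and
   anything other than exactly one closure through the destination backbone
   is an error (`assemble()`).

Partial digestion, methylation sensitivity, star activity, ligase fidelity
toward near-cognate overhangs, and concentration effects are deliberately
not modeled (see *Limitations*).

## Cut arithmetic and the fragment representation

Coordinates are 0-based and half-open on the top strand throughout; GenBank's
1-based inclusive convention is converted only at the I/O boundary. For an
enzyme with recognition length $k$ and offsets $(o_t, o_b)$, a top-strand
site starting at $r$ cuts the top strand at boundary $r + k + o_t$ and the
bottom strand at $r + k + o_b$; a bottom-strand site whose recognition
reverse-complement starts at $r$ cuts at $r - o_b$ and $r - o_t$. The duplex
region between the two boundaries — $o_b - o_t$ nucleotides — is the 5′
overhang. Circular molecules are scanned with a prefix extension of length
$k - 1$ so origin-spanning sites are found, and positions are reduced modulo
the length.

A `sticky_fragment` stores its *physical top strand* plus explicit end
chemistry. The left end's overhang (top strand protruding) is the prefix of
the stored sequence; the right end's overhang protrudes on the bottom strand,
so its bases are stored only as the right-end label — in a ligated product
they are the first bases of the next fragment. Two consequences make the rest
of the package simple:

* ligation is plain concatenation of top strands, with each junction's
  overlap counted exactly once, and the multiset of top-strand nucleotides is
  conserved by digestion nucleotide-for-nucleotide;
* a 100 bp circle with one SapI site digests to a fragment whose strands are
  each 100 nt — reported length 100 — with the same 3-mer as both end labels.

An end's **label** is the top-strand 5′→3′ sequence of the duplex its
overhang will form. Two ends are ligatable iff their labels are *equal*, not
reverse complements: both fragments are expressed in assembly orientation,
and the reverse-complement pairing is absorbed when a fragment is flipped
(`revcomp()` swaps and complements the labels). This makes the assembly graph
a pure label-matching graph. Fragments are orientation-blind by default, as
real ligation is; directionality comes only from overhang design.

## The unique-closure contract

`assemble()` anchors the search at the destination backbone in fixed
orientation and enumerates every simple cycle in the label graph, each
remaining fragment usable once in either orientation. Distinct closures are
keyed by the canonical rotation of the product sequence. The contract is
strict by design:

* zero closures → `MissingJunction`, naming the unmatched labels;
* more than one closure, or a unique closure that skips a supplied part
  (possible only through duplicate labels) → `AmbiguousAssembly`;
* an input contributing no usable fragment → an `InertInput` warning and a
  diagnostics entry.

On the bench, wrong products are invisible only because marker selection
hides them; in silico they are surfaced as errors. Linear concatemers and
backbone-less circles are not reported — they are not selectable states.
Self-complementary 4-nt overhangs (possible with BsaI, impossible for odd
3-nt SapI overhangs) permit inverted ligation and are rejected unless
explicitly allowed. Output ordering is deterministic everywhere; no
randomness enters assembly.

Re-digesting a product (`verify_product()`) checks the residual-site
invariant directly; a recognition site could in principle be *created* across
a junction by unlucky label/flank juxtaposition, which is why verification
re-scans the full product rather than trusting fragment-level checks.

## The slot architecture

The default scheme orders six slots — 5′ arm, CT, FP, SEC, NT, 3′ arm —
with seven pairwise-distinct 3-nt junction labels (vector-left, five
internal, vector-right). A part may span several consecutive slots and then
uses the outer labels of its span ("slot skipping"): a promoter-only
construct takes a 5′arm–CT promoter, an FP, and a SEC–3′arm UTR. The slot
convention this package follows fixes the slot order and roles but not the
seven overhang sequences as printed constants, so the shipped label table is
this package's own default; every test builds its labels from fixture
schemes, so nothing depends on the default values. CRISPR-style schemes
(homology arms in the outer slots) are just other `slot_scheme` objects, and
bipartite-system drivers are ordinary ORF-kind parts.

`classify_part()` digests a candidate and finds the unique span whose outer
labels match the released site-free fragment in either orientation; because
scheme labels are pairwise distinct, a label pair determines at most one
span, and a validated kit can never produce an ambiguous build — a property
the tests exercise over random selections.

## Design tools

**Primer tails.** A tail is 5′-spacer + recognition + one offset base +
junction label + homology. The spacer is fixed to `AA` (cutting-efficiency
padding; configurable constant), the offset base to `A`. Homology length
starts at 18 nt and grows until a Wallace-rule melting temperature
($2(A{+}T) + 4(G{+}C)$ °C) reaches 55 °C, clamped to [18, 35] nt — a
deliberately crude, stated rule, chosen because no sharper rule is fixed by
the workflow being modeled.

**Entry clones via BsaI.** New SapI entry clones are made by amplifying an
insert with BsaI tails and cloning into a span-specific empty KanR vector
whose stuffer carries outward BsaI sites and whose backbone carries the
inward SapI sites. The geometry embeds the span's 3-nt SapI label inside the
4-nt BsaI cloning overhang (label + one pad base on the left, pad + label on
the right; pads chosen to avoid self-complementary 4-mers). The direct-PCR
route (`design_direct_pcr_part()`) appends SapI tails and carries the same
pad bases in its amplified cargo, so a part delivered as a PCR product and
the same part delivered as an entry clone yield sequence-identical final
constructs — an equivalence the tests assert.

**PCR simulation.** Primers anneal by an exact, unique 12-nt 3′ anchor; the
product carries the full primer sequence, so mutations placed upstream of the
anchor are incorporated, as in mutagenic PCR. This is what lets domestication
lesions ride in on primers.

**Domestication.** For a linear insert with $n$ internal SapI/BsaI sites,
`plan_domestication()` designs $n{+}1$ sub-amplicons and $2(n{+}1)$ primers.
Lesion choice is deterministic and seed-free: with a reading frame supplied,
the first third-codon position inside the site (lowest coordinate, alt bases
in A<C<G<T order) whose substitution is synonymous, kills the occurrence, and
creates no net new site; without a frame, the same search without the
synonymy constraint, with `synonymous` recorded as `"unknown"`. Split-point
overhangs are the native 4-mers adjacent to each lesion, slid downstream past
collisions (including reverse-complement collisions) and self-complementary
4-mers; the outer cloning labels are the insert's native terminal 4-mers, so
the reassembled chain reconstructs the lesioned target exactly.
Homology regions are extended so that every lesion sits more than 12 nt from
a primer 3′ end, keeping the anchors template-exact. Above a configurable
site count (default 4) the planner refuses and recommends synthesis, which is
the expedient route for heavily contaminated inserts. Frame preservation is
verified by translation; whether fusion linkers must preserve frame is left
to the optional `check_frame()` validation rather than a hard gate, since
slot contents other than CDS fusions have no frame to preserve.

## The synthetic kit generator

`make_kit()` and `make_stress_set()` stand in for a physical kit: junction
labels are drawn uniformly from the overhang alphabet subject to pairwise
distinctness, no self-complements, and no label equal to another's reverse
complement; backbones, stuffers and insert bodies are uniform random DNA
scrubbed of SapI/BsaI sites (one base inside each offending occurrence is
resampled until clean); marker features are short placeholder ORFs labeled
KanR/AmpR, because the marker logic is annotation-driven, not
homology-driven. Generated molecules are re-screened for stray sites created
at sequence junctions and regenerated if any appear. All randomness flows
through an explicit seed (the caller's RNG state is saved and restored), so
the same call is byte-identical — a property the tests assert on written
files.

What the fixtures emulate: the slot/label wiring, marker logic, entry-clone
and destination-vector geometry, combined-slot parts, multi-option slots, and
chain lengths up to 20 inserts (21 distinct labels). What they do not
emulate: real regulatory sequences (a "promoter" part is a labeled random
body), repeat structure, GC skew, or the actual sequences of any published
plasmid library. Passing tests therefore demonstrate the correctness of the
simulator's logic on well-formed kits, not sequence-level properties of any
real reagent collection.

## Numerical and degenerate-input choices

* Ambiguity codes other than N are rejected; N is allowed in sequences but
  forbidden in recognition sites and overhang labels, since overhang identity
  must be unambiguous.
* A linear molecule whose site would cut beyond its ends reports the site as
  uncuttable and digestion skips it.
* Zero-site molecules pass through digestion whole, flagged uncut; uncut
  circles are inert in assembly (and warned about as inputs).
* A site-free circular vector assembled with zero parts is returned
  unchanged (idempotence); a vector whose own two labels match
  re-circularizes to an empty backbone.
* Duplicate cut positions from overlapping site predictions are collapsed
  before fragmentation.
* Product feature tables are de-duplicated on (label, kind, interval,
  strand) because a feature lying wholly inside an overhang is seen by both
  flanking fragments.
* GenBank support covers the subset the package emits — LOCUS topology,
  simple spans, `complement()`, and two-span `join()` across the origin —
  and round-trips exactly; this is a flat-file dialect choice, not a general
  GenBank parser.

## Verification strategy and problem sizes

The test suite pits the implementation against deliberately naive
independent oracles: digestion against a quadratic substring scanner with
separately derived cut arithmetic (1000 random molecules of 50–5000 nt,
linear and circular, in the full-scale suite); closure search against a
recursive exhaustive enumeration over orderings and orientations (up to 10
fragments, including planted duplicate-label collisions); primer design
against 200 seeded end-to-end round trips (design → mutagenic PCR → BsaI
cloning → classification); domestication against 30 random inserts with 1–3
planted sites, checking sequence-exact reconstruction, zero residual sites,
and translation preservation. These sizes keep the full suite under a minute
on one core while covering the label, orientation and wrap-around edge cases
that matter.

## Known limitations

* No ligase-fidelity model: near-cognate overhang pairs (one mismatch) are
  treated as non-ligatable, which is optimistic for some 4-nt label sets.
* No kinetics or stoichiometry: "equimolar inputs" is bench guidance the
  simulator does not need, but it also means relative yields of competing
  mis-products are not predicted — they are reported as hard errors instead.
* Primer design checks neither dimers nor hairpins; the Tm rule is
  intentionally simple.
* Colony counts, transformation efficiency and anything else downstream of
  the ligation fixed point are out of scope: the simulator predicts the
  product, not the yield.
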