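# gatekit

In-silico Golden Gate cloning for people who build plasmids — in particular
for *C. elegans* transgenesis labs assembling complex targeting constructs
(reporters, fusions, bipartite driver/effector lines) from slot-based entry
clone libraries, and for anyone who wants to validate a type IIS assembly
before touching a tube.

## The method

Type IIS restriction enzymes such as SapI (GCTCTTC 1/4) and BsaI
(GGTCTC 1/5) cleave at a fixed offset *outside* their non-palindromic
recognition sequence, leaving short 5′ overhangs (3 nt for SapI, 4 nt for
BsaI) whose sequence is unconstrained. In a Golden Gate (GG) reaction a
destination backbone and up to ~20 inserts are cycled through digestion and
ligation in one pot; every junction is programmed by a distinct overhang, and
only the designed product — which no longer contains any recognition site —
survives as a circular plasmid. Entry clones ride KanR backbones with
inward-cutting SapI sites; the destination vector is AmpR with the sites in
its stuffer, so backbone marker logic mirrors the bench selection.

`gatekit` models the reaction at its fixed point: every input is digested to
completion, fragments still carrying a recognition site of the assembly
enzyme are excluded from closure (they would be re-cut), and all circular
closures over the overhang-label matching graph are enumerated. Anything
other than exactly one closure through the destination backbone is an error,
not a ranked alternative. An end's label is the top-strand 5′→3′ sequence of
the duplex its overhang will form, so two ends ligate iff their labels are
equal; orientation flips are handled by enumerating both orientations of
every fragment.

On top of the simulator sit:

* a six-slot scheme (5′ arm, CT, FP, SEC, NT, 3′ arm) with combined
  "slot-skipping" spans, a parts registry, and a construct builder that emits
  annotated GenBank plus plain FASTA ([`build_construct()`]);
* multiplexed reactions — several alternative parts in one slot, full
  Cartesian product out ([`multiplex_assemble()`]);
* design tools: BsaI-tailed primers that create new SapI entry clones,
  SapI-tailed direct PCR parts, annealed oligo duplexes, and domestication
  plans that silently lesion internal SapI/BsaI sites and reassemble the
  fragments by BsaI GG ([`design_entry_primers()`], [`plan_domestication()`]);
* a deterministic synthetic kit generator so everything is testable offline
  ([`make_kit()`], [`make_stress_set()`]);
* a command-line front end (`inst/cli/gatekit`).

## Worked example

Generate a synthetic six-slot kit, assemble one part per slot into the
destination vector, and verify the product:

```r
library(gatekit)

kit <- make_kit(scheme_size = 6, parts_per_slot = 1, seed = 1)
print(kit$scheme)
#> <slot_scheme> kit6_seed1 (SapI): [AAG] 5arm [TGT] CT [CCT] FP [TCG] SEC [TAG] NT [ACG] 3arm [AAC]

parts <- kit$registry$molecules[paste0("p_", kit$scheme$slots)]
product <- assemble(kit$vector, parts, enzyme = "SapI")
print(product)
#> <assembly_product> pDEST_product: 1101 bp circular, 7 fragment(s), enzyme SapI
#>   parts: pDEST(+) -> p_5arm(+) -> p_CT(+) -> p_FP(+) -> p_SEC(+) -> p_NT(+) -> p_3arm(+)
#>   diagnostics: clean

verify_product(product, "SapI")$clean
#> [1] TRUE
```

The scheme line reads as the chain of junction overhangs: the destination
backbone's right end exposes `AAG`, the 5′ arm part bridges `AAG`→`TGT`, and
so on to `AAC`, which closes the circle back onto the backbone. The product
is the unique circular closure — 1101 bp, backbone plus all six inserts, no
residual SapI site, AmpR marker only — exactly what the bench reaction
selects for. `write_record(product$molecule, "product.gb")` saves the
annotated sequence.

The same run from a shell:

```sh
gatekit make-fixtures --out kit --slots 6 --seed 1
gatekit validate-kit --kit-dir kit
gatekit build --kit-dir kit --pick 5arm=p_5arm --pick CT=p_CT --pick FP=p_FP \
              --pick SEC=p_SEC --pick NT=p_NT --pick 3arm=p_3arm --out-prefix product
```

(`gatekit` here is the script at `system.file("cli", "gatekit", package =
"gatekit")`, runnable as `Rscript <path> ...`.)

## Vignette

`vignettes/golden-gate-assembly.Rmd` documents the model and its
assumptions: the fragment/end-label representation, the unique-closure
contract, what the synthetic kits emulate (and what they deliberately do
not), the primer and domestication design rules, and known limitations.
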