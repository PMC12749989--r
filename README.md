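# rndcensus

Conformational-state census of trimeric RND efflux pumps from atomic
coordinates.

Resistance–nodulation–division (RND) multidrug efflux pumps (AcrB, OqxB
and their relatives) are homotrimers whose protomers cycle through the
loose (L), tight (T) and open (O) states of the functional-rotation
transport cycle; a fourth conformation, O\* (O architecture with a closed
exit channel), appears in several pumps. Single-particle cryo-EM assigns
a state to every protomer of every particle, and the biology is read off
the resulting distributions: the fraction of monomers in each state and
the fraction of trimers in each composition (LTO, TTO, TTT,
O\*O\*O\*, ...). This package implements that census as a tested,
reusable pipeline for structural biologists who have trimer coordinates
and/or per-monomer class labels and want defensible counts, intervals and
classifications rather than one-off scripts.

## What it computes

Given a trimer with chains in symmetry order, the pipeline

1. estimates the pseudo-C3 axis (rotation axis of the Kabsch fit of
   chain 1 onto chain 2) and **symmetry-expands** the chains into three
   aligned monomers, the coordinate analogue of symmetry expansion of
   particle images;
2. **assigns each monomer a state** by core-anchored superposition onto
   L/T/O reference protomers and porter-domain Cα RMSD
   (argmin, precedence L &lt; T &lt; O &lt; O\* on ties), optionally
   relabelling O winners as O\* when the exit-channel bottleneck radius
   *r*<sub>b</sub> &lt; 1.5 Å;
3. **aggregates the census**: trimer-composition counts over complete
   particles and monomer frequencies through the exact identity
   *f*<sub>s</sub> = Σ<sub>c</sub> *p*<sub>c</sub> · *n*<sub>s</sub>(c)/3,
   with particle-level bootstrap intervals and a multinomial G-test of
   monomer independence;
4. estimates **channel bottlenecks** as the maximin (widest-path)
   clearance over a 26-connected grid from a seed to the solvent
   exterior — a verifiable simplification of Voronoi channel finders;
5. scores **phenotypes**: plate-dilution steps (variant − wildtype), MIC
   calls (growth = background-corrected OD600 &gt; 0.18; MIC = lowest
   concentration with no growth there and above) and replicate
   time-course summaries.

A synthetic-data generator produces state templates, trimer particle sets
with known composition distributions, label tables with a
misclassification channel, and analytic channel fixtures; it stands in
for the raw particle stacks and makes every stage testable end to end.

## Worked example

Simulate 2,000 trimers from a known composition distribution with 0.2 Å
coordinate noise, run the full extract → assign → census pipeline, and
summarise:

```r
library(rndcensus)

spec <- synthetic_spec(
  composition = c(TTO = 0.549, TTT = 0.318, TOO = 0.128, OOO = 0.005),
  n_particles = 2000, coord_noise_sd = 0.2, seed = 7)
res <- run_census_pipeline(spec)
res$census
#> # state census: 2000 complete particles (0 dropped)
#> # monomer %: L 0.0, T 72.2, O 27.8, O* 0.0
#> # trimer  %: TTT 30.5, TTO 56.2, TOO 12.7, OOO 0.5

tidy(bootstrap_census(res$labels, B = 200, seed = 7), "trimer")
#> # A tibble: 4 × 5
#>   composition count   freq conf.low conf.high
#>   <chr>       <int>  <dbl>    <dbl>     <dbl>
#> 1 TTT           610 0.305    0.284      0.324
#> 2 TTO          1125 0.562    0.539      0.583
#> 3 TOO           254 0.127    0.113      0.142
#> 4 OOO            11 0.0055   0.0025     0.009

glance(independence_test(res$census))
#> # A tibble: 1 × 3
#>   statistic    df  p.value
#>       <dbl> <int>    <dbl>
#> 1      153.     2 6.44e-34
```

Reading the output: every simulated particle was recovered (labels match
the generating truth exactly at this noise level, which is far below the
2.8 Å inter-state separation), the recovered composition frequencies sit
within sampling error of the generating distribution, and the monomer
panel (72.2 % T) is the composition-weighted projection of the trimer
panel — the two levels are consistent by construction. The tiny G-test
p-value says trimer compositions are *not* what independent monomer
states would produce: the generating distribution has correlated
protomers (e.g. no TTL trimers), and the test detects exactly that. The
bootstrap resamples whole particles, so its intervals honour that
correlation. `autoplot(res$census)` draws the two frequency panels.

Real structures enter the same way: `read_structure("trimer.pdb")` (PDB
or mmCIF), `estimate_symmetry_axis()`, `symmetry_expand()`,
`assign_state()` against a `reference_library()` built from deposited
protomers, then `aggregate_census()` on the label table — or
`read_label_table()` if classification happened upstream.

## Design notes

The methods vignette (`vignettes/state-census-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with units and
defaults, what the synthetic generator does and does not emulate, the
numerical tolerances and tie-breaks, and known limitations — start there
before changing thresholds such as the O\* bottleneck cut-off or the
classification statistic.
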