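---
title: "Steric effects and cis/trans isomerization of secondary amides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steric effects and cis/trans isomerization of secondary amides: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amidescan)
```

## Scope and model system

Secondary amides interconvert between a trans form (amide torsion
$\omega \approx 180^\circ$) and a cis form ($\omega \approx 0^\circ$) by
rotation about the C–N bond. The model system is glycylglycine methyl
ester (GGMe) and its tert-butyl-substituted derivatives: substitution is
possible at the N-terminal amino nitrogen (R1), the N-terminal alpha
carbon (R2, always S when present) and the C-terminal alpha carbon (R3,
S or R), giving ten compounds named by N-codes such as `N0000`, `N1010`
or `N011'0` (the prime marks the R configuration at R3; the final digit
denotes the methyl ester).

`amidescan` is the analysis layer over such a study: the
quantum-chemical energies themselves are inputs, either as the packaged
data tables (`amide_table(1)` through `amide_table(12)`) or as synthetic
surfaces and tables with known ground truth. No electronic-structure
calculation is performed; all energies are handled in kcal/mol
(`hartree_kcal` is provided for unit conversion when ingesting raw
output).

## The additivity model for steric energies

The steric energy of a substituted compound is defined against an
additive reference. Two transferable tert-butyl increments are derived
from small-molecule pairs by simple energy difference
(`derive_increment`): attachment at sp³ nitrogen from
ammonia/tert-butylamine, attachment at sp³ carbon from
methane/neopentane, each in both phases. The additive energy of a
compound with $n_N$ substitutions on nitrogen and $n_C$ on carbon is

$$E_\mathrm{add} = E_\mathrm{base}(\text{isomer, phase})
  + n_N\,E_{tb}^{N}(\text{phase}) + n_C\,E_{tb}^{C}(\text{phase}),$$

with the unsubstituted scaffold's optimized energy as the base, and the
steric energy is $E_\mathrm{st} = E_\mathrm{opt} - E_\mathrm{add}$. The
sign convention was fixed so that the packaged tables' steric energies
are positive, i.e. substitution is always destabilizing relative to the
additive estimate; the base compound has $E_\mathrm{st} = 0$ by
construction.

Each (isomer, phase) block carries its own base energy and blocks are
never mixed: the packaged trans-water table sits on a different absolute
energy scale than the other three blocks (a property of the source data
this package treats as given), so cross-block differences of raw
energies are meaningful only within a block.

```{r steric}
model <- study_additivity_model()
st <- steric_table(conformer_records(5, "trans", "gas"), model)
st[st$compound %in% c("N0000", "N0100", "N1110"),
   c("compound", "opt_e", "n_tbu_n", "n_tbu_c", "add_e", "st_e")]
```

Machine values are kept unrounded; the printed tables round to three
decimals, and comparisons in the test suite use ±0.001 kcal/mol
accordingly.

## Geometry analytics

Torsions are signed IUPAC dihedrals in $(-180, 180]$, with 180 preferred
over −180 to match the reporting convention of the dihedral tables. The
implementation uses the atan2 cross-product formulation; the test suite
checks it against an independent projection-based oracle and against
`bio3d::torsion.xyz`. Note one symmetry fact the tests encode: the
signed torsion is *invariant* under reversal of the point order
(A–B–C–D and D–C–B–A read the same) and changes sign under mirror
reflection.

Amide planarity is measured as the angular distance of $\omega$ to the
nearer of 0° and 180°, so one rule serves cis and trans rows alike; a
geometry is called distorted when the deviation exceeds 5° (the `tol`
argument of `is_distorted`). The hydrogen bond between the N-terminal
amino nitrogen and the amide hydrogen is scored by distance only,
present when $d_{N\cdots H} \le 2.3$ Å (inclusive at the cutoff; the
source convention states absence strictly beyond 2.3 Å, and no angular
term is used because the criterion is defined purely on the distance).

Rigid superposition (`superpose`) is a Kabsch least-squares fit with a
determinant guard: reflections are never admitted, since they would
invert molecular chirality — a chiral set and its mirror image fit
imperfectly rather than exactly. Atom correspondence, like the
torsion-to-atom-index binding (`atom_map`), is user input: optimized
geometries carry no standardized atom order, so no automatic inference
from connectivity is attempted.

## Cis/trans energetics and effective barriers

Relative energies are cis minus trans within one compound and phase
(`relative_energy` on an `isomer_pair`), for electronic energies and
free energies alike. Gas-phase relative energies are recomputed from the
optimized energies and cross-checked against the printed values; the
water-phase relative energies are taken from the printed table because
the two water-phase blocks sit on different absolute scales (see above)
and are not recomputable from raw differences.

For barriers, each compound has up to four directional entries: syn
barrier geometries (near $\omega = \pm 60^\circ$, reached from trans
starts) and anti ones (near $\pm 120^\circ$, from cis starts), in the
positive and negative rotation senses. The effective barrier
$\Delta G_\mathrm{eff}$ is the minimum free-energy entry
(`effective_barrier`), the operative assumption being that
isomerization proceeds over the cheapest available path. Entries marked
"not determined" (symmetric compounds scanned in one sense only) are
treated as absent, never as zero. Ties are resolved to the
lexicographically first key (anti before syn, + before −), which does
not affect the value. `equilibrium_cis_fraction` converts a cis/trans
free-energy gap into a two-state Boltzmann population at a given
temperature (default 298.15 K, R = 1.987204 × 10⁻³ kcal/(mol K)).

```{r barriers}
water <- barrier_summaries(12)
water[["N011'0"]]
```

## The relaxed-coordinate-scan driver

The scan driver reproduces the study's three-round directional protocol
over a pluggable one-dimensional energy backend: energy as a function of
$\omega$, deterministic and 360°-periodic. Geometry relaxation at fixed
$\omega$ (the "relaxed" in relaxed coordinate scan) is the backend's
responsibility; this keeps the driver exactly testable with analytic
potentials while remaining correct over a future backend that calls a
quantum-chemistry program per point.

Round 1 sweeps 180° of arc from the starting minimum to the opposite
isomer at the coarse step (default 15°). Each later round re-scans a
window of ± one previous-round step around the incumbent maximum at the
finer step (defaults 2°, then 0.125° for gas or 0.25° for water). The
window width is a driver decision — the protocol fixes only the step
sizes — and one previous step is the narrowest window guaranteed to
bracket the maximum given the previous round's resolution. The driver
checks that the start is a local minimum within one coarse step, keeps
every evaluated point in the profile, and never loses the incumbent
peak between rounds (each round's barrier estimate is monotonically
non-decreasing). A full scan costs about 60 backend evaluations under
the default schedule — no fine grid is ever swept globally.

The located energy-barrier geometry (EBG) is the profile maximum, a
transition-state proxy (no eigenvector verification is attempted, as in
the source protocol); its height is reported relative to the scan's own
starting minimum, and `barrier_set` re-references cis-start barriers to
the trans minimum using the cis backend's own two well energies so all
four directional entries share the trans reference. When distinct
trans-start and cis-start backends are supplied (emulating relaxation
hysteresis — the study derives syn barriers only from trans starts and
anti barriers only from cis starts, and does not assume the reverse
scans find the same maxima), the re-referencing offset is computed
entirely on the cis-start surface; this is a modelling choice the
protocol leaves open.

Classification of an EBG is by angular proximity: nearer ±60° is syn,
nearer ±120° is anti. The exact ties at $|\omega^*| = 90°$ are
classified syn with an ambiguity flag rather than raising an error, so
batch runs stay alive; 0° and 180° (where the + and − references of the
nearer class are equidistant) are flagged likewise.

## Synthetic data and what the tests do and do not show

Three generators provide inputs with known ground truth, all
bit-reproducible for a fixed seed:

* `make_potential` builds Fourier torsion surfaces
  $E(\omega) = E_0 + \sum_k \tfrac{V_k}{2}(1 - \cos k(\omega - \gamma_k))$.
  A dominant 2-fold term produces the cis/trans double well; a 1-fold
  term biases one well (the cis/trans gap); 3-fold terms and phase
  shifts make the + and − paths inequivalent, emulating the asymmetry
  chiral substitution introduces. The validation battery draws
  $V_2 \sim U(8, 20)$ kcal/mol with 1- and 3-fold perturbations capped
  at 30% and 12% of $V_2$ and phases within ±20°, spanning the 11–28
  kcal/mol barrier range of the study while guaranteeing exactly two
  wells. `ground_truth` locates wells and barriers on a 0.001° grid
  (an order of magnitude below the finest scan step, so oracle error is
  negligible) with quadratic refinement.
* `make_energy_table` emits additive conformer-energy records plus
  known injected steric offsets — half-normal (scale 1.5 kcal/mol per
  substitution, echoing the uniformly positive printed steric energies
  that grow with substitution count, typically reaching a few kcal/mol
  at three substitutions), zero for the base compound. Defaults use the
  packaged base energies and increments, i.e. the study conditions.
* `make_backbone_fragment` places a minimal nine-atom dipeptide-ester
  fragment by internal-coordinate (NeRF) construction with fixed
  canonical bond lengths (C–N 1.33 Å, C(sp³)–C 1.52 Å, C=O 1.23 Å,
  N–H 1.01 Å, N–Cα 1.47 Å) and 120°/109.5° angles; only the four
  backbone torsions vary. This is sufficient for exercising torsion and
  alignment code, not for energetics.

Passing tests therefore demonstrate that the analysis pipeline is
faithful: increments, additive references, steric energies, relative
energies, planarity flags and effective barriers reproduce the packaged
study tables, and the scan driver locates barriers of smooth analytic
two-well surfaces to within its final step. They do not re-derive the
quantum-chemical inputs, do not validate the scan driver against
surfaces with more than two wells or discontinuities (multiple rotamers
along the path are the backend's concern), and say nothing about
solvation models or thermochemistry, which enter only as printed
numbers.

## Numerical choices and degenerate inputs

* Angles are wrapped into $(-180, 180]$ everywhere, 180 preferred over
  −180.
* Printed-table cells are parsed verbatim: thousands separators
  stripped, typographic minus normalized, `ND`/empty mapped to `NA`
  (never 0). Both the ASCII `'` and the typographic `’` prime are
  accepted in compound codes; the canonical form is ASCII.
* Torsions are undefined for coincident consecutive points or collinear
  triples and raise errors naming the failing torsion; superposition
  requires at least three non-collinear pairs; `min_group_distance`
  requires disjoint non-empty groups.
* Steric-table comparisons use ±0.001 kcal/mol (printed rounding);
  recomputed gas-phase relative energies use ±0.005 kcal/mol (two
  3-decimal roundings); effective barriers are exact selections and are
  compared exactly.
* Problem sizes in the shipped analyses: ten compounds × two isomers ×
  two phases for the table pipelines, and a 20-potential × 4-scan
  battery for the driver validation — comfortably desk-scale, with the
  dense oracle grid (360,000 points per potential) the dominant cost.

## Known limitations

The scan driver is strictly one-dimensional in $\omega$; 2-D surfaces
(e.g. $\omega \times \psi$) and explicit rotamer branching are out of
scope. Nitrogen pyramidalization measures are not computed. The XYZ
reader handles the standard dialect only, and no quantum-chemistry
output parsing beyond XYZ is attempted. Dipole moments appear in the
data model but no packaged fixture carries them, so the
dipole/solvation correlation is not reproduced quantitatively.
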