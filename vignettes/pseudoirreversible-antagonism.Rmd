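---
title: "Modelling pseudoirreversible antagonism: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pseudoirreversible antagonism: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metakin)
```

# The problem

Some competitive receptor antagonists dissociate from their target so slowly
that, on the timescale of a functional assay, they behave as if bound
irreversibly — *pseudoirreversible* inhibition. Operationally this shows up
as insurmountable antagonism: after pretreatment with the antagonist, even a
saturating agonist cannot restore the full maximal response, and the fitted
maximal response Emax falls as the pretreatment concentration rises. In vivo
the same property produces efficacy that outlasts drug exposure whenever the
dissociation half-life of the drug–receptor complex exceeds the
pharmacokinetic elimination half-life.

Structurally, slow dissociation can arise from a metastable binding pocket
on the unbinding path: the ligand leaving the primary ("deep") pocket is
parked in a secondary pocket formed around a gatekeeper residue — here a
methionine whose hydrophobic side chain grips a trifluoromethylated distal
ring — before it finally escapes to bulk. Mutating the gatekeeper
(methionine to valine) weakens the secondary pocket and largely abolishes
the pseudoirreversible behaviour.

`metakin` implements this entire story at a deliberately coarse scale, so
that each mechanism is exposed as an inspectable, testable model rather than
an expensive all-atom simulation.

# The coarse-grained landscape

The receptor is a fixed external potential in 1 or 2 dimensions; the ligand
is a rigid pair of probe beads: the carbon of the CF3 group on the distal
ring and a carboxylate oxygen (O1) at the zwitterionic end, separated by a
fixed bond length (default 6.6 length units). The potential is a sum of
Gaussian wells plus a soft harmonic confinement wall:

* a *deep pocket* well at the origin (default depth 6 kBT per bead, width
  3.5) acting on both beads — the docking site;
* a *Met pocket* well (default depth 7 kBT, width 3) acting **on the CF3
  bead only**, centred 6 units beyond the gatekeeper anchor along the exit
  axis. The bead selectivity encodes the chemistry: the secondary pocket
  grips the hydrophobic distal ring, not the polar end.

Reduced units are used throughout: energies in kBT, lengths in
ångström-like units, so that the conventional "30 Å" dissociation threshold
becomes 30 length units, and the customary metadynamics hill height 0.3 is
0.3 kBT. The gatekeeper anchor sits at distance 8 from the deep pocket;
with the default geometry a ligand parked in the Met pocket shows a
CF3–anchor distance near 6.3 and an O1–anchor distance near 12–13, while
the deep pose shows both distances near 9–10 — the distance signatures the
gate windows (below) are built around.

The `M124V` genotype multiplies the Met-pocket depth by `met_scale_m124v`
(default 0.1): the mutant's pocket is weakened, not abolished, consistent
with the mutant occasionally visiting the pocket in biased runs.

Depths and widths were chosen once, when the landscape was designed, such
that (i) the unbiased ligand stays bound on the simulated timescale, (ii)
biased runs escape within a few hundred thousand steps, and (iii) the
wild-type/mutant contrast in Met-pocket occupancy and escape fraction is
clearly resolved at a few dozen runs. They are not fitted to any measured
quantity.

# Dynamics

`run_langevin()` integrates overdamped (Brownian) Langevin dynamics with the
Euler–Maruyama scheme and a rigid-bond projection after every step: the bond
vector is rescaled to its reference length about the midpoint, keeping the
constraint exact to machine precision rather than merely within a drift
tolerance. Defaults: kBT = 1, friction 1, timestep 0.005 (small enough that
the stiffest default feature, the confinement wall, is integrated stably).
Noise comes from R's RNG, so `set.seed`-style seeding gives bit-identical
trajectories on every platform; every public entry point takes an explicit
`seed`.

Setting the bond length to zero selects *point-ligand mode* (a single
probe), used for one-dimensional free-energy benchmarks where a two-bead
ligand would only add noise.

Divergent coordinates (non-finite values, e.g. from an absurd timestep)
abort with the step index in the error message.

# Metadynamics and free-energy reconstruction

`run_metad()` adds a history-dependent bias on the collective variable (CV)

\[ s = \lVert \tfrac12(\mathbf{x}_{CF3} + \mathbf{x}_{O1}) - \mathbf{a} \rVert, \]

the distance between the ligand probe centroid and the anchor centroid
**a**. The default anchor is the deep-pocket centre, i.e. the binding-site
centroid: with the default two-pocket geometry this makes the CV increase
monotonically along the exit path (deep pose ≈ 0–4, Met pose ≈ 11–17,
bulk > 30). Using the centroid of *both* pocket centres is possible but
degenerate here — the deep and Met poses then sit at nearly the same CV
value — which is why the single-anchor convention is the default.

Hills are Gaussian, default width 0.5 CV units deposited every 500 steps;
the width is well below the basin separation and the pace slow enough for
near-quasistatic filling on this landscape. Well-tempered damping is the
default (bias factor γ = 10): each new hill's height is
\(h = h_0 \exp[-V(s)/((\gamma-1) k_BT)]\) with \(h_0 = 0.3\) kBT. A
non-tempered mode is provided as well, since either variant is common in
ligand-unbinding work. Inside the compiled engine the accumulated bias is
tabulated on a dense CV grid (spacing 0.02, refreshed at each deposition)
so the per-step force is O(1) in the number of hills; hill heights
themselves are always computed from the exact Gaussian sum, and the R-side
`deposit_hill()` replays the engine's heights to 1e-10.

`estimate_free_energy()` reconstructs \(F(s) = -V(s)\) (non-tempered) or
\(-\tfrac{\gamma}{\gamma-1} V(s)\) (well-tempered), shifted so the minimum
is zero. Because the instantaneous bias fluctuates around the converging
profile, the estimate is by default averaged over the final half of the
deposition history (`average_tail = 0.5`) — the standard variance-reduction
device for well-tempered runs, and the difference between a basin
free-energy difference that fluctuates by ±1 kBT and one that settles
within a few tenths.

Two numerical conventions matter for benchmarks:

* a distance CV has a reflective boundary at \(s = 0\); Gaussians deposited
  near it leak mass into \(s < 0\) and the reconstructed profile is biased
  upward there. Free-energy benchmarks therefore place the CV anchor away
  from any basin minimum so that all basins lie in the CV interior;
* the CV maps \(x\) and its mirror image about the anchor onto the same
  value, so the equilibrium reference for 1-D checks
  (`quadrature_delta_f()`) integrates the *folded* Boltzmann density
  \(e^{-U(a+s)} + e^{-U(a-s)}\).

The test suite checks the reconstruction on a 1-D double well against this
quadrature reference: ten seeds of 10^6 steps give a median basin
free-energy difference within 0.5 kBT of quadrature, and the median
absolute error decreases when the run length is quadrupled. Those problem
sizes (10 seeds × 10^6 steps; 20 × 2·10^5 for the 2-D genotype contrast)
were chosen as the smallest at which the checked properties are stable
across seed blocks.

# Trajectory analysis conventions

**RMSD.** Ligand RMSD against the docking pose is computed in the fixed
receptor frame, without superposition — the toy receptor is rigid, so the
protein alignment step of the all-atom workflow is the identity here.

**Dissociation rule.** A run counts as dissociated at the first frame where
RMSD exceeds the threshold (default 30) for `persistence` consecutive
frames. Persistence defaults to 1, the bare threshold rule; the parameter
exists because a single-frame excursion near the threshold is occasionally
a noise artifact at other settings.

**Gate windows.** Poses are classified in the plane of the two
gatekeeper-anchor distances (CF3, O1). The default windows are gate A
(deep, near-docking): CF3 7.8–12.5 and O1 7.5–12.5; gate B (Met pocket):
CF3 2.5–7.8 and O1 10–15; both distances ≥ 25 is unbound; anything else is
other-bound. The canonical gate medians — (9.42, 9.97) for the deep pose
and (6.27, 12.95) for the Met-pocket pose — fall inside their own gates
under this orientation, which is the reason for it: the alternative
assignment of the two printed rectangles to the two gates puts each median
in the *other* gate's window, contradicting the deep-pocket/Met-pocket
semantics (the Met-pocket pose is precisely the one with the CF3 probe
close to the gatekeeper). The windows are fully configurable; intervals are
closed on the lower bound and open on the upper, and the label partition is
total and exclusive by construction.

**Medians.** Per-gate medians use the usual midpoint convention (average of
the central pair for even counts).

**Clustering.** `cluster_poses()` runs k-medoids (PAM) on the pairwise
frame-RMSD matrix — for a rigid two-probe ligand the frame RMSD is the
Euclidean distance between concatenated coordinates divided by √2. PAM with
BUILD initialization is deterministic; the `seed` argument pins the RNG
anyway so the reproducibility contract is explicit. With exactly k frames
the partition is the singleton one.

# The fingerprint statistic

Surface-contact bits reduce the full interaction-fingerprint taxonomy to
the one type the coarse model can detect: residue r's bit is set in a
snapshot iff the nearer probe is within the contact cutoff (default 4.5) of
r's anchor. The schema carries the other bit types (hydrogen bond, ionic)
for file compatibility, without detectors.

For two ligands A and B with per-bit set counts \(C_b\) out of \(C_0\)
snapshots and probabilities \(p = C_b/C_0\):

\[ P_b = \frac{p_A}{p_A + p_B}, \qquad
   Q_b = p_A \cdot 2\left(P_b - \tfrac12\right), \]

with \(P_b = 1/2\) (hence \(Q_b = 0\)) when both probabilities vanish. The
prose definition of \(P_b\) as a "relative probability" of A versus B
admits several formalizations; the ratio form above is the simple one under
which \(P_b \in [0,1]\) and \(Q_b\) respects the stated [−1, 1] bounds. The
statistic is directional — it scores ligand A against B and weights by A's
own contact frequency, so \(Q_b = 0\) whenever \(p_A = 0\) regardless of
\(p_B\). Two consequences worth knowing:

* the maximum 1 is attained (at \(p_A = 1, p_B = 0\)), but the minimum over
  attainable configurations is above −1 (at \(p_A > 0\) the weight \(p_A\)
  shrinks exactly when the preference term is most negative);
* \(Q_b\) is *not* globally monotone in \(p_A\) at fixed \(p_B\): for
  \(0 < p_A < (\sqrt2 - 1)\,p_B\) it dips below zero before rising.
  Monotonicity holds on \(p_A \ge p_B\), and that is what the property
  tests assert.

Ranking is by \(Q_b\) descending with lexicographic tie-break on the
residue label.

# Pharmacology models

**Fitters.** All three fitters use deterministic initialization and
Levenberg–Marquardt least squares:

* one-phase decay \(y = \text{plateau} - \text{span}\,e^{-kt}\), half-life
  \(\ln 2/k\); plateau initialized from the response at the latest time,
  rate from a log-linear pre-fit; the plateau can optionally be constrained
  (e.g. to 100%) since assay conventions differ on this point. Constant
  responses are a degenerate-data error; a non-positive fitted rate flags
  the fit unconverged rather than reporting a meaningless half-life.
* log-linear PK: linear regression of log concentration on time over the
  terminal phase (optionally the last *m* points); a non-negative slope is
  flagged, not fitted through.
* 4PL \(y = \text{bottom} + (\text{top}-\text{bottom})/(1 + (c/\text{IC}_{50})^{h})\),
  initialized from the data extremes and the concentration nearest the
  half-maximal response.

On noiseless model-generated data all three recover their generating
parameters to better than 1e-6 relative; under noise, the recovery RMSE
shrinks with the noise level (both covered by tests).

**Two-step induced fit.** Insurmountable antagonism is modelled by mass
action on a unit pool of receptors,

\[ R + A \rightleftharpoons RA, \qquad
   R + I \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} RI
     \underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} RI^{*}, \]

integrated with lsoda (rtol 1e-10, atol 1e-12): first a pretreatment phase
(antagonist only), then an agonist phase, by default with the antagonist
still in the bath (co-incubation format) or optionally washed out. The
response proxy is the agonist-occupied fraction normalized to a matched
no-antagonist control — linear transduction without receptor reserve, which
is sufficient for the Emax phenomenology and avoids unidentifiable spare
parameters. Emax is the fitted plateau of the response-versus-agonist
curve, using a hyperbolic (Hill slope 1) model with a baseline — exactly
the shape this transduction model produces; an unconstrained-slope logistic
here over-extrapolates the plateau from partially saturated curves.

Preset rate constants are the package's own calibration, anchored to the
measured half-lives: the pseudoirreversible ("ksi6666") preset has
encounter Kd 30 nM, k2/k−2 = 4 giving apparent Kd 6 nM, and
k−2·k−1/(k−1+k2) = ln2/9.41 h⁻¹ so the tight-state residence half-life is
9.41 h; the surmountable ("w146") preset has no isomerization and residence
0.2 h; the "compound4" preset keeps the encounter kinetics and sets
residence 0.98 h. The underlying study reports the half-lives but not the
microscopic rates; the decomposition into k1, k−1, k2, k−2 is ours.

A useful exact limit, covered by a test: with washout and \(k_{-2} = 0\),
each encounter complex at agonist addition either isomerizes into the trap
or releases, so the unavailable receptor fraction is
\(RI^* + RI\,k_2/(k_2 + k_{-1})\) and Emax approaches 100 times the
complement.

**Residence-time PK-PD.** `simulate_receptor_occupancy_pk()` integrates
\(d\mathrm{Occ}/dt = k_{on} C(t)(1-\mathrm{Occ}) - k_{off}\mathrm{Occ}\)
with \(C(t) = C_0 e^{-k_{el} t}\). With the measured values — dissociation
half-life 9.41 h against PK half-life 6.65 h — occupancy outlasts exposure
(the time above 50% occupancy exceeds the PK half-life), whereas a
0.98 h-residence compound under identical exposure does not: the
residence-time criterion for persistent efficacy, reproduced as a
direction. `persistence_metric()` integrates time-above-threshold with
linear interpolation at crossings.

Units are hours and nM throughout the pharmacology layer.

# What the generators do and do not emulate

The synthetic layer generates (i) ligand-probe trajectories on the
two-pocket landscape, (ii) per-snapshot contact fingerprints, and (iii)
assay time-courses (washout recovery, IV-bolus PK decay, 4PL
concentration–response) with seeded Gaussian noise and recorded generating
parameters. It does **not** emulate protein flexibility, solvent or
membrane, multi-exponential PK, receptor reserve, or assay-specific
artifacts (plate effects, heteroscedastic noise). Passing tests therefore
demonstrate that the analysis chain is correct on data satisfying its own
model assumptions — the appropriate standard for a methods package — not
that the toy landscape reproduces any particular receptor quantitatively.

# Degenerate inputs and error conventions

Validation errors (negative widths, non-increasing grids, mismatched
dimensions, empty series) are raised eagerly with the offending field in
the message; strict config loading rejects unknown keys. Degenerate data
(constant responses, flat curves) raise errors rather than returning
absurd fits; recoverable fit pathologies (non-positive rate, rising
concentrations) return `converged = FALSE`. File round trips write numerics
at 17 significant digits so reloads are bit-exact, and sidecar JSON carries
seeds, schema versions and generating parameters.

# Known limitations

* The 2-D landscape has a single exit channel; pathway heterogeneity
  (multiple escape routes) is out of scope.
* The free-energy estimator is the negative-bias formula (plus time
  averaging); reweighting estimators are not implemented.
* Only the surface-contact fingerprint bit has a detector.
* The two-step model treats agonist and antagonist concentrations as
  clamped baths (no depletion) and transduction as linear in agonist
  occupancy.
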